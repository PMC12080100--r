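# The networks: input encoders, transformer message-passing layers, readouts
# and output MLP heads, as pure parameterized functions on the autodiff tape.
#
# Two variants share the machinery:
#   gsnet  - global residue graph, 150-d nodes, 6 layers, 1 attention head
#   alcnet - local atom graph, 75-d nodes, 3 layers, 3 attention heads
# Per layer and head, edge features are transformed by ssp(W e + b) to the
# head width; attention follows the transformer-convolution form
#   alpha_ij ~ exp(<W_q h_i, W_k h_j + e_ij> / sqrt(d_head)),
#   message_i = sum_j alpha_ij (W_v h_j + e_ij),
# plus a learned root transform of h_i, then a residual + LayerNorm update.

CHECKPOINT_VERSION <- 1L

#' Model configuration
#'
#' @param variant `"gsnet"` (residue graph) or `"alcnet"` (atom graph).
#' @param head_spec one of `"global6"` (six targets), `"global1"`,
#'   `"residue1"` (per-residue scalar from the node embedding),
#'   `"pka_gsnet"` (7 x node_dim concatenated readout), `"pka_alcnet"`
#'   (3 x node_dim readout).
#' @param node_dim,n_layers,n_heads architecture sizes; defaults follow the
#'   variant (150/6/1 for gsnet, 75/3/3 for alcnet).
#' @param edge_in_dim smeared edge feature width.
#' @param aa_embed_dim,atom_embed_dim,cont_dim embedding and continuous
#'   encoder widths.
#' @param head_hidden hidden width of the output MLP.
#' @param dropout dropout fraction of the pKa heads (0.2); 0 otherwise.
#' @param root_term include the learned root/self transform inside attention.
#' @param pool_radii radii (angstrom) for the pKa radius-pooled means.
#' @return a `ModelConfig`.
#' @export
model_config <- function(variant = c("gsnet", "alcnet"),
                         head_spec = c("global6", "global1", "residue1",
                                       "pka_gsnet", "pka_alcnet"),
                         node_dim = NULL, n_layers = NULL, n_heads = NULL,
                         edge_in_dim = 300L, aa_embed_dim = 64L,
                         atom_embed_dim = 64L, cont_dim = 64L,
                         head_hidden = 1024L, dropout = NULL,
                         root_term = TRUE,
                         pool_radii = c(6, 8, 10, 12, 15)) {
  variant <- match.arg(variant)
  head_spec <- match.arg(head_spec)
  if (is.null(node_dim)) node_dim <- if (variant == "gsnet") 150L else 75L
  if (is.null(n_layers)) n_layers <- if (variant == "gsnet") 6L else 3L
  if (is.null(n_heads)) n_heads <- if (variant == "gsnet") 1L else 3L
  if (node_dim %% n_heads != 0L) stop("node_dim must be divisible by n_heads")
  if (is.null(dropout)) {
    dropout <- if (head_spec %in% c("pka_gsnet", "pka_alcnet")) 0.2 else 0
  }
  cfg <- structure(list(variant = variant, head_spec = head_spec,
                        node_dim = as.integer(node_dim),
                        n_layers = as.integer(n_layers),
                        n_heads = as.integer(n_heads),
                        edge_in_dim = as.integer(edge_in_dim),
                        aa_embed_dim = as.integer(aa_embed_dim),
                        atom_embed_dim = as.integer(atom_embed_dim),
                        cont_dim = as.integer(cont_dim),
                        head_hidden = as.integer(head_hidden),
                        dropout = dropout, root_term = root_term,
                        pool_radii = pool_radii),
                   class = "ModelConfig")
  cfg$head_in_dim <- head_input_dim(cfg)
  cfg$out_dim <- if (head_spec == "global6") 6L else 1L
  cfg
}

head_input_dim <- function(cfg) {
  switch(cfg$head_spec,
         global6 = , global1 = , residue1 = cfg$node_dim,
         pka_gsnet = (2L + length(cfg$pool_radii)) * cfg$node_dim,
         pka_alcnet = 3L * cfg$node_dim)
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

linear_params <- function(fan_in, fan_out) {
  list(W = glorot(fan_in, fan_out), b = matrix(0, 1L, fan_out))
}

#' Initialize model parameters
#'
#' Glorot-uniform linear weights, standard-normal embeddings, unit LayerNorm
#' scales; shapes determined entirely by the configuration.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for initialization.
#' @return a `pgnn_model`: list with `config` and `params`.
#' @export
init_model <- function(config, seed = 1L) {
  set.seed(seed)
  nd <- config$node_dim; dh <- nd %/% config$n_heads
  ce <- config$cont_dim
  p <- list(emb_aa = matrix(stats::rnorm(20L * config$aa_embed_dim), 20L))
  enc_in <- config$aa_embed_dim
  if (config$variant == "gsnet") {
    p$enc_dih <- list(l1 = linear_params(15L, ce), l2 = linear_params(ce, ce))
    p$enc_com <- list(l1 = linear_params(1L, ce), l2 = linear_params(ce, ce))
    enc_in <- enc_in + 2L * ce
  } else {
    p$emb_atom <- matrix(stats::rnorm(5L * config$atom_embed_dim), 5L)
    p$enc_charge <- list(l1 = linear_params(1L, ce), l2 = linear_params(ce, ce))
    enc_in <- enc_in + config$atom_embed_dim + ce
  }
  p$reduce <- list(l1 = linear_params(enc_in, 2L * nd),
                   l2 = linear_params(2L * nd, nd))
  p$layers <- lapply(seq_len(config$n_layers), function(l) {
    heads <- lapply(seq_len(config$n_heads), function(c_) {
      list(q = linear_params(nd, dh), k = linear_params(nd, dh),
           v = linear_params(nd, dh),
           e = linear_params(config$edge_in_dim, dh))
    })
    list(heads = heads, root = linear_params(nd, nd),
         ln_gamma = matrix(1, 1L, nd), ln_beta = matrix(0, 1L, nd))
  })
  p$head <- head_params(config)
  structure(list(config = config, params = p, norm_stats = NULL),
            class = "pgnn_model")
}

# global heads: 4 linear layers (1024 hidden), 3 SSP activations.
# pKa heads: 6 linear layers (1024 hidden), 5 SSP activations, 6 dropouts.
head_params <- function(cfg) {
  n_lin <- if (cfg$head_spec %in% c("pka_gsnet", "pka_alcnet")) 6L else 4L
  dims <- c(cfg$head_in_dim, rep(cfg$head_hidden, n_lin - 1L), cfg$out_dim)
  lapply(seq_len(n_lin), function(i) linear_params(dims[i], dims[i + 1L]))
}

#' Shifted softplus activation
#'
#' `ln(1 + e^x) - ln 2`, elementwise, zero at the origin; numerically
#' stabilized for large magnitudes.
#' @param x numeric vector or matrix.
#' @return same shape as `x`.
#' @export
ssp <- function(x) ssp_mat(x)

mlp2 <- function(x, pp) {
  ad_linear(ad_ssp(ad_linear(x, pp$l1$W, pp$l1$b)), pp$l2$W, pp$l2$b)
}

#' Encode graph nodes to the initial node-state matrix
#'
#' Discrete inputs (amino-acid index; atom type for the atom variant) pass
#' through learned embeddings; continuous inputs (dihedral 15-vector and
#' center-of-mass distance, or partial charge) through two-layer MLPs; the
#' concatenation is reduced by an MLP to `node_dim`.
#'
#' @param graph a `ProteinGraph` (single or batched).
#' @param wp wrapped (`ad`) or plain parameter tree.
#' @param config the `ModelConfig`.
#' @return an `ad` node, `n_nodes x node_dim`.
#' @export
encode_nodes <- function(graph, wp, config) {
  e_aa <- ad_rows(wp$emb_aa, graph$aa_index + 1L)
  if (config$variant == "gsnet") {
    d <- mlp2(ad_const(graph$dihedral_feats), wp$enc_dih)
    cd <- mlp2(ad_const(matrix(graph$com_dist, ncol = 1L)), wp$enc_com)
    x <- ad_cbind(e_aa, d, cd)
  } else {
    e_at <- ad_rows(wp$emb_atom, graph$atom_type + 1L)
    q <- mlp2(ad_const(matrix(graph$charge, ncol = 1L)), wp$enc_charge)
    x <- ad_cbind(e_aa, e_at, q)
  }
  mlp2(x, wp$reduce)
}

#' One transformer message-passing layer
#'
#' Multi-head attention over each receiver's in-neighbors with
#' edge-augmented keys and values, an optional learned root transform, then
#' residual + LayerNorm.
#'
#' @param h `ad` node state (n x node_dim).
#' @param graph `ProteinGraph` providing `edge_index` and `edge_feat`.
#' @param lp wrapped layer parameters.
#' @param config the `ModelConfig`.
#' @param edge_const optional pre-wrapped `ad_const` of the edge features.
#' @return updated `ad` node state.
#' @export
mp_layer <- function(h, graph, lp, config, edge_const = NULL) {
  n <- nrow(ad_value(h))
  recv <- graph$edge_index[1L, ]
  send <- graph$edge_index[2L, ]
  dh <- config$node_dim %/% config$n_heads
  E <- if (is.null(edge_const)) ad_const(graph$edge_feat) else edge_const
  heads <- vector("list", config$n_heads)
  if (length(recv) == 0L) {
    # edgeless graph: attention contributes nothing; only root + residual
    hhat <- ad_const(matrix(0, n, config$node_dim))
    if (config$root_term) hhat <- ad_add(hhat, ad_linear(h, lp$root$W, lp$root$b))
    return(ad_layernorm(ad_add(h, hhat), lp$ln_gamma, lp$ln_beta))
  }
  for (c_ in seq_len(config$n_heads)) {
    hp <- lp$heads[[c_]]
    q <- ad_linear(h, hp$q$W, hp$q$b)
    k <- ad_linear(h, hp$k$W, hp$k$b)
    v <- ad_linear(h, hp$v$W, hp$v$b)
    e <- ad_ssp(ad_linear(E, hp$e$W, hp$e$b))
    ke <- ad_add(ad_rows(k, send), e)
    score <- ad_scalar_mul(ad_rowsums(ad_mul(ad_rows(q, recv), ke)),
                           1 / sqrt(dh))
    alpha <- ad_segment_softmax(score, recv, n)
    msg <- ad_segment_sum(ad_scale_rows(ad_add(ad_rows(v, send), e), alpha),
                          recv, n)
    heads[[c_]] <- msg
  }
  hhat <- if (config$n_heads > 1L) do.call(ad_cbind, heads) else heads[[1L]]
  if (config$root_term) {
    hhat <- ad_add(hhat, ad_linear(h, lp$root$W, lp$root$b))
  }
  ad_layernorm(ad_add(h, hhat), lp$ln_gamma, lp$ln_beta)
}

# mean over the rows listed in idx, as a 1 x k feature
ad_subset_mean <- function(h, idx) ad_colmeans(ad_rows(h, idx))

#' Readout features from the final node states
#'
#' - `global6` / `global1`: per-graph elementwise mean over all nodes.
#' - `residue1`: the embedding of the residue of interest.
#' - `pka_gsnet`: `[mu, h_i, mu_6, mu_8, mu_10, mu_12, mu_15]` where `mu_r`
#'   averages nodes whose CA lies within `r` angstrom of residue `i`'s CA
#'   (self always included).
#' - `pka_alcnet`: `[mu, h_Calpha, mu_aa]` with `mu_aa` the mean over the
#'   atoms of the residue of interest.
#'
#' @param h `ad` node state after message passing.
#' @param graph single or batched `ProteinGraph`.
#' @param config the `ModelConfig`.
#' @param residues integer vector of center residue indices (0-based,
#'   one per graph in the batch); required for residue-level heads.
#' @return `ad` feature matrix, one row per graph/sample.
#' @export
readout <- function(h, graph, config, residues = NULL) {
  batched <- !is.null(graph$graph_id)
  n_graphs <- if (batched) graph$n_graphs else 1L
  offs <- if (batched) graph$node_offset else c(0L, graph$n_nodes)
  hs <- config$head_spec
  if (hs %in% c("global6", "global1")) {
    if (batched) return(ad_segment_mean(h, graph$graph_id, n_graphs))
    return(ad_colmeans(h))
  }
  if (is.null(residues) && hs %in% c("residue1", "pka_gsnet"))
    stop("residue indices required for head_spec ", hs)
  if (hs == "residue1") {
    node_idx <- offs[seq_len(n_graphs)] + residues + 1L
    return(ad_rows(h, node_idx))
  }
  if (hs == "pka_gsnet") {
    feats <- vector("list", n_graphs)
    for (g in seq_len(n_graphs)) {
      nodes <- (offs[g] + 1L):offs[g + 1L]
      i_node <- offs[g] + residues[g] + 1L
      mu <- ad_subset_mean(h, nodes)
      hi <- ad_rows(h, i_node)
      co <- graph$coords[nodes, , drop = FALSE]
      dref <- sqrt(rowSums(sweep(co, 2L, graph$coords[i_node, ])^2))
      parts <- list(mu, hi)
      for (r in config$pool_radii) {
        vr <- nodes[dref <= r]
        parts[[length(parts) + 1L]] <- ad_subset_mean(h, vr)
      }
      feats[[g]] <- do.call(ad_cbind, parts)
    }
    return(if (n_graphs > 1L) ad_rbind(feats) else feats[[1L]])
  }
  # pka_alcnet
  ca_nodes <- if (batched) graph$ca_node else graph$ca_node
  res_sets <- if (batched) graph$residue_node_sets else list(graph$residue_node_set)
  feats <- vector("list", n_graphs)
  for (g in seq_len(n_graphs)) {
    nodes <- (offs[g] + 1L):offs[g + 1L]
    feats[[g]] <- ad_cbind(ad_subset_mean(h, nodes),
                           ad_rows(h, ca_nodes[g]),
                           ad_subset_mean(h, res_sets[[g]]))
  }
  if (n_graphs > 1L) ad_rbind(feats) else feats[[1L]]
}

#' Output MLP head
#'
#' Global heads: four linear layers (1024 hidden channels) with three
#' shifted-softplus activations. pKa heads: six linear layers, five
#' activations and six dropout layers (20% dropout, active only in training
#' mode).
#'
#' @param features `ad` feature matrix (rows = samples).
#' @param wh wrapped head parameters.
#' @param config the `ModelConfig`.
#' @param train_mode enable dropout.
#' @return `ad` prediction matrix (n_samples x out_dim).
#' @export
head_forward <- function(features, wh, config, train_mode = FALSE) {
  if (ncol(ad_value(features)) != config$head_in_dim)
    stop("head input width ", ncol(ad_value(features)),
         " does not match configured ", config$head_in_dim)
  x <- features
  n_lin <- length(wh)
  use_drop <- config$dropout > 0
  for (i in seq_len(n_lin)) {
    if (use_drop && train_mode) {
      v <- ad_value(x)
      mask <- matrix(stats::runif(length(v)) >= config$dropout,
                     nrow(v), ncol(v)) * 1
      x <- ad_dropout(x, config$dropout, mask)
    }
    x <- ad_linear(x, wh[[i]]$W, wh[[i]]$b)
    if (i < n_lin) x <- ad_ssp(x)
  }
  x
}

#' Full forward pass
#'
#' @param model a `pgnn_model`.
#' @param graph single or batched `ProteinGraph`.
#' @param residues center residue indices for residue-level heads.
#' @param train_mode enable dropout in the head.
#' @param wp optionally pre-wrapped parameters (reused across a batch loop).
#' @return list with `pred` (`ad` node), `features` (`ad` readout), and
#'   `wp` (the wrapped parameters, for gradient collection).
#' @export
forward_pass <- function(model, graph, residues = NULL, train_mode = FALSE,
                         wp = NULL) {
  cfg <- model$config
  if (is.null(wp)) wp <- ad_wrap_params(model$params)
  h <- encode_nodes(graph, wp, cfg)
  E <- ad_const(graph$edge_feat)
  for (l in seq_len(cfg$n_layers)) {
    h <- mp_layer(h, graph, wp$layers[[l]], cfg, edge_const = E)
  }
  feats <- readout(h, graph, cfg, residues)
  pred <- head_forward(feats, wp$head, cfg, train_mode)
  list(pred = pred, features = feats, node_state = h, wp = wp)
}

#' Predict (numeric) from a model
#'
#' Forward pass in evaluation mode returning a plain matrix.
#' @inheritParams forward_pass
#' @return numeric matrix of predictions.
#' @export
predict_raw <- function(model, graph, residues = NULL) {
  ad_value(forward_pass(model, graph, residues, train_mode = FALSE)$pred)
}

#' Save a model checkpoint
#'
#' Single-container checkpoint holding a format version, the configuration
#' echo, all parameter arrays and any normalization statistics; refuses to
#' load into a mismatched configuration.
#'
#' @param model a `pgnn_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = CHECKPOINT_VERSION, config = model$config,
               params = model$params, norm_stats = model$norm_stats), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path checkpoint file.
#' @param expect_config optional `ModelConfig` that must match the stored one.
#' @return a `pgnn_model`.
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$version, CHECKPOINT_VERSION))
    stop("checkpoint version ", ck$version, " not supported")
  if (!is.null(expect_config) && !identical(unclass(ck$config)[names(unclass(expect_config))],
                                            unclass(expect_config)))
    stop("checkpoint configuration does not match the expected configuration")
  structure(list(config = ck$config, params = ck$params,
                 norm_stats = ck$norm_stats), class = "pgnn_model")
}
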