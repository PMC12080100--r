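# Training: target normalization, masked multi-target MSE, Adam with the
# epoch-50 learning-rate switch, early stopping, repeat-and-select training
# and the transfer-learning modes (frozen encoder vs fine-tuned).

#' Training configuration
#'
#' Defaults follow the global-property regime: Adam at 1e-4 switched to 1e-5
#' after 50 epochs, batch size 64, early stopping after ten epochs without
#' validation improvement. Residue-level SASA and pKa regimes instead train
#' for a fixed number of epochs (10 and 100 respectively).
#'
#' @param lr_initial,lr_after_epoch50 Adam learning rates.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience in epochs; `Inf` disables it.
#' @param max_epochs hard epoch cap (fixed-epoch regimes set this and
#'   disable patience).
#' @param n_repeats independent training repeats for [train_repeats()].
#' @param seed integer; determines shuffling and initialization streams.
#' @return a `TrainConfig`.
#' @export
train_config <- function(lr_initial = 1e-4, lr_after_epoch50 = 1e-5,
                         batch_size = 64L, patience = 10L, max_epochs = 200L,
                         n_repeats = 20L, seed = 1L) {
  stopifnot(lr_initial > 0, lr_after_epoch50 > 0, batch_size >= 1L,
            max_epochs >= 1L)
  structure(list(lr_initial = lr_initial,
                 lr_after_epoch50 = lr_after_epoch50,
                 batch_size = as.integer(batch_size), patience = patience,
                 max_epochs = as.integer(max_epochs),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Fit per-target normalization statistics on the training split
#'
#' Mean and sd per target over masked-in values only.
#' @param targets n x k target matrix.
#' @param mask n x k logical availability mask.
#' @return `NormStats`: list with `mean` and `sd` k-vectors.
#' @export
fit_normalization <- function(targets, mask = NULL) {
  targets <- as.matrix(targets)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(targets), ncol(targets))
  k <- ncol(targets)
  mu <- sd <- numeric(k)
  for (j in seq_len(k)) {
    v <- targets[mask[, j], j]
    if (length(v) < 2L) stop("target ", j, " has fewer than 2 masked-in values")
    mu[j] <- mean(v); sd[j] <- stats::sd(v)
    if (sd[j] == 0) stop("target ", j, " has zero variance on the training split")
  }
  structure(list(mean = mu, sd = sd), class = "NormStats")
}

#' Apply z-scoring with training-set statistics
#' @param targets matrix (or vector) of targets.
#' @param stats a `NormStats`.
#' @return normalized matrix.
#' @export
apply_normalization <- function(targets, stats) {
  targets <- as.matrix(targets)
  sweep(sweep(targets, 2L, stats$mean), 2L, stats$sd, "/")
}

#' Invert z-scoring
#' @inheritParams apply_normalization
#' @return denormalized matrix.
#' @export
invert_normalization <- function(targets, stats) {
  targets <- as.matrix(targets)
  sweep(sweep(targets, 2L, stats$sd, "*"), 2L, stats$mean, "+")
}

#' Masked mean-squared-error loss (numeric)
#'
#' Squared errors of masked-out entries contribute nothing to the loss; the
#' denominator counts masked-in entries only. The autodiff counterpart used
#' in training routes exactly zero gradient through masked-out entries.
#'
#' @param pred,target numeric matrices.
#' @param mask logical matrix; `NULL` means all-in.
#' @return scalar loss.
#' @export
masked_mse <- function(pred, target, mask = NULL) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pred), ncol(pred))
  n_in <- sum(mask)
  if (n_in == 0) {
    warning("all targets masked out; loss defined as 0")
    return(0)
  }
  sum(((pred - target) * mask)^2) / n_in
}

## ---- Adam ----
# Operates on one concatenated parameter vector; with a couple of million
# parameters the per-matrix bookkeeping would otherwise dominate each step.

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(vec, gvec, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gvec
  state$v <- beta2 * state$v + (1 - beta2) * gvec * gvec
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(vec = vec - lr * mhat / (sqrt(vhat) + eps), state = state)
}

## ---- dataset containers ----

#' Assemble a global-property training dataset
#'
#' Builds residue graphs for each structure and normalizes targets with
#' statistics fitted on this (training) set, or with supplied statistics
#' for validation data.
#'
#' @param structures list of `ProteinStructure`.
#' @param targets n x k matrix.
#' @param mask n x k logical or `NULL`.
#' @param stats `NormStats` to reuse (validation); fitted here when `NULL`.
#' @param spec smearing spec for graph construction.
#' @return list with `graphs`, `targets_norm`, `mask`, `stats`.
#' @export
make_global_dataset <- function(structures, targets, mask = NULL,
                                stats = NULL, spec = smearing_spec(300L, 0, 15)) {
  targets <- as.matrix(targets)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(targets), ncol(targets))
  if (is.null(stats)) stats <- fit_normalization(targets, mask)
  graphs <- lapply(structures, build_residue_graph, spec = spec)
  list(graphs = graphs, targets_norm = apply_normalization(targets, stats),
       mask = mask * 1, stats = stats)
}

# trainable-parameter selection for transfer modes: in frozen mode only the
# head trains; otherwise everything does.
trainable_names <- function(flat, mode) {
  if (mode == "transfer_frozen") grep("^head\\.", names(flat), value = TRUE)
  else names(flat)
}

#' Train a model
#'
#' Runs minibatch Adam with the configured schedule (learning rate switched
#' after epoch 50, optimizer moments kept), early stopping on validation
#' loss (strict improvement, no minimum delta) and per-epoch history.
#'
#' Modes: `"fresh"` trains all parameters from the given initialization;
#' `"transfer_finetune"` does the same starting from a checkpointed encoder;
#' `"transfer_frozen"` keeps every GNN parameter (embeddings, encoders,
#' message-passing layers) bit-identical and trains only the output MLP —
#' readout features are then precomputed once per sample.
#'
#' @param model a `pgnn_model` (already carrying checkpoint parameters for
#'   the transfer modes).
#' @param train_data,val_data datasets from [make_global_dataset()] or, for
#'   residue-level heads, lists with `graphs`, `residues`, `targets_norm`
#'   (n x 1), `mask`, `stats`.
#' @param config a [train_config()].
#' @param mode `"fresh"`, `"transfer_frozen"` or `"transfer_finetune"`.
#' @return list with `model` (best-validation parameters), `history` (data
#'   frame: epoch, lr, train_loss, val_loss), `best_epoch`, `best_val`.
#' @export
train_model <- function(model, train_data, val_data = NULL,
                        config = train_config(), mode = c("fresh",
                        "transfer_frozen", "transfer_finetune")) {
  mode <- match.arg(mode)
  cfg <- model$config
  set.seed(config$seed)
  flat <- flatten_params(model$params)
  trn <- trainable_names(flat, mode)
  lens <- vapply(flat[trn], length, integer(1L))
  ends <- cumsum(lens); starts <- ends - lens + 1L
  vec <- unlist(flat[trn], use.names = FALSE)
  vec_into_flat <- function(vec, flat) {
    for (i in seq_along(trn)) flat[[trn[i]]][] <- vec[starts[i]:ends[i]]
    flat
  }
  opt <- adam_init(length(vec))
  n <- length(train_data$graphs)
  residue_head <- cfg$head_spec %in% c("residue1", "pka_gsnet", "pka_alcnet")

  frozen_feats <- NULL; frozen_val_feats <- NULL
  if (mode == "transfer_frozen") {
    frozen_feats <- precompute_features(model, train_data)
    if (!is.null(val_data)) frozen_val_feats <- precompute_features(model, val_data)
  }

  eval_loss <- function(params, data, feats = NULL) {
    model_eval <- model; model_eval$params <- params
    pred <- if (!is.null(feats)) {
      ad_value(head_forward(ad_const(feats), ad_wrap_params(params)$head, cfg,
                            train_mode = FALSE))
    } else {
      predict_dataset(model_eval, data)
    }
    masked_mse(pred, data$targets_norm, data$mask)
  }

  best_val <- Inf; best_flat <- flat; best_epoch <- 0L; stall <- 0L
  hist <- list()
  for (epoch in seq_len(config$max_epochs)) {
    lr <- if (epoch > 50L) config$lr_after_epoch50 else config$lr_initial
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bi in batches) {
      params <- unflatten_params(flat, model$params)
      tmat <- train_data$targets_norm[bi, , drop = FALSE]
      mmat <- train_data$mask[bi, , drop = FALSE]
      if (mode == "transfer_frozen") {
        wp <- ad_wrap_params(params)
        pred <- head_forward(ad_const(frozen_feats[bi, , drop = FALSE]),
                             wp$head, cfg, train_mode = TRUE)
      } else {
        bg <- batch_graphs(train_data$graphs[bi])
        res <- if (residue_head) train_data$residues[bi] else NULL
        fp <- forward_pass(list(config = cfg, params = params), bg,
                           residues = res, train_mode = TRUE)
        wp <- fp$wp; pred <- fp$pred
      }
      loss <- ad_masked_mse(pred, tmat, mmat)
      ad_backward(loss)
      grads <- flatten_params(ad_collect_grads(wp))
      gvec <- unlist(grads[trn], use.names = FALSE)
      st <- adam_step(vec, gvec, opt, lr)
      vec <- st$vec; opt <- st$state
      flat <- vec_into_flat(vec, flat)
      ep_loss <- ep_loss + ad_value(loss)[1L] * length(bi)
      ep_n <- ep_n + length(bi)
    }
    params <- unflatten_params(flat, model$params)
    vl <- if (is.null(val_data)) NA_real_
          else eval_loss(params, val_data, frozen_val_feats)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = ep_loss / ep_n, val_loss = vl)
    crit <- if (is.null(val_data)) ep_loss / ep_n else vl
    if (crit < best_val) {
      best_val <- crit; best_flat <- flat; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (is.finite(config$patience) && stall >= config$patience) break
    }
  }
  out <- model
  out$params <- unflatten_params(best_flat, model$params)
  list(model = out, history = do.call(rbind, hist), best_epoch = best_epoch,
       best_val = best_val, mode = mode)
}

#' Evaluation-mode predictions for a whole dataset
#'
#' Runs the model over every sample of a dataset container (batched,
#' dropout off) and returns the stacked prediction matrix on the
#' normalized scale.
#'
#' @param model a `pgnn_model`.
#' @param data dataset from [make_global_dataset()] (or the residue-level
#'   equivalent).
#' @param batch_size graphs per forward pass.
#' @return numeric matrix, one row per sample.
#' @export
predict_dataset <- function(model, data, batch_size = 64L) {
  n <- length(data$graphs)
  residue_head <- model$config$head_spec %in% c("residue1", "pka_gsnet",
                                                "pka_alcnet")
  out <- vector("list", ceiling(n / batch_size))
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (k in seq_along(idx)) {
    bi <- idx[[k]]
    bg <- batch_graphs(data$graphs[bi])
    res <- if (residue_head) data$residues[bi] else NULL
    out[[k]] <- predict_raw(model, bg, res)
  }
  do.call(rbind, out)
}

# readout features for every sample with the current (frozen) GNN parameters
precompute_features <- function(model, data, batch_size = 64L) {
  n <- length(data$graphs)
  residue_head <- model$config$head_spec %in% c("residue1", "pka_gsnet",
                                                "pka_alcnet")
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    bi <- idx[[k]]
    bg <- batch_graphs(data$graphs[bi])
    res <- if (residue_head) data$residues[bi] else NULL
    wp <- ad_wrap_params(model$params)
    h <- encode_nodes(bg, wp, model$config)
    for (l in seq_len(model$config$n_layers))
      h <- mp_layer(h, bg, wp$layers[[l]], model$config)
    out[[k]] <- ad_value(readout(h, bg, model$config, res))
  }
  do.call(rbind, out)
}

#' Repeat training and select the best model
#'
#' Trains `config$n_repeats` models from independent initializations (or
#' from the same checkpoint in transfer modes, with independent shuffling /
#' dropout streams) and selects by validation loss.
#'
#' @inheritParams train_model
#' @param init_fn function(seed) returning the starting `pgnn_model`.
#' @return list with `best` (result of [train_model()]), `best_index`,
#'   `val_losses`.
#' @export
train_repeats <- function(init_fn, train_data, val_data, config, mode = "fresh") {
  runs <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    m0 <- init_fn(cfg_r$seed)
    runs[[r]] <- train_model(m0, train_data, val_data, cfg_r, mode)
  }
  losses <- vapply(runs, `[[`, numeric(1L), "best_val")
  best <- select_best(losses)
  list(best = runs[[best]], best_index = best, val_losses = losses,
       runs = runs)
}

#' Select the repeat with the lowest validation criterion
#'
#' Deterministic tie-break: the lowest repeat index wins.
#' @param losses numeric vector of per-repeat validation losses.
#' @return index of the selected repeat.
#' @export
select_best <- function(losses) {
  stopifnot(length(losses) >= 1L)
  which.min(losses)[1L]
}

#' Mean and standard error over the top-k repeats
#'
#' Reporting mode that averages a metric over the best `k` repeats by
#' validation criterion.
#' @param val_losses per-repeat validation criterion (selects the top `k`).
#' @param metric per-repeat metric to summarize (defaults to `val_losses`).
#' @param k number of repeats to keep.
#' @return list with `mean`, `sem`, `indices`.
#' @export
top_k_summary <- function(val_losses, metric = val_losses, k = 10L) {
  k <- min(k, length(val_losses))
  idx <- order(val_losses)[seq_len(k)]
  m <- metric[idx]
  list(mean = mean(m), sem = stats::sd(m) / sqrt(k), indices = idx)
}
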