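test_that("shifted softplus is exact at the origin, asymptote and monotone", {
  expect_equal(ssp(0), 0)
  expect_lt(abs(ssp(50) - (50 - log(2))), 1e-9)
  x <- seq(-30, 30, length.out = 201)
  expect_true(all(diff(ssp(x)) > 0))
  # stability far into the tails
  expect_equal(ssp(1000), 1000 - log(2))
  expect_equal(ssp(-1000), -log(2))
})

test_that("edge transform has per-head widths and matches dense algebra", {
  cfg <- small_gsnet_config()  # node_dim 30, 3 heads -> d_head 10
  m <- init_model(cfg, seed = 1)
  lp <- m$params$layers[[1]]
  widths <- vapply(lp$heads, function(h) ncol(h$e$W), integer(1))
  expect_equal(sum(widths), cfg$node_dim)
  expect_equal(nrow(lp$heads[[1]]$e$W), cfg$edge_in_dim)

  set.seed(2)
  e_ij <- matrix(rnorm(300), 1)
  W <- lp$heads[[2]]$e$W; b <- lp$heads[[2]]$e$b
  got <- pgnn:::ad_value(pgnn:::ad_ssp(pgnn:::ad_linear(
    pgnn:::ad_const(e_ij), pgnn:::ad_param(W), pgnn:::ad_param(b))))
  manual <- log1p(exp(e_ij %*% W + as.numeric(b))) - log(2)
  expect_equal(got, manual, tolerance = 1e-9)

  # zero parameters force a zero transformed edge (ssp(0) = 0)
  z <- pgnn:::ad_value(pgnn:::ad_ssp(pgnn:::ad_linear(
    pgnn:::ad_const(e_ij), pgnn:::ad_param(W * 0), pgnn:::ad_param(b * 0))))
  expect_equal(max(abs(z)), 0)
})

test_that("attention weights normalize over each receiver's neighborhood", {
  set.seed(4)
  scores <- matrix(rnorm(10), ncol = 1)
  seg <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 5L)
  a <- pgnn:::ad_value(pgnn:::ad_segment_softmax(pgnn:::ad_const(scores), seg, 5L))
  sums <- tapply(a[, 1], seg, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-12)
})

test_that("message-passing layer matches a hand-rolled dense attention oracle", {
  cfg <- small_gsnet_config()
  m <- init_model(cfg, seed = 6)
  nd <- cfg$node_dim; nh <- cfg$n_heads; dh <- nd / nh
  set.seed(8)
  n <- 3L
  h0 <- matrix(rnorm(n * nd), n)
  E <- matrix(rnorm(4 * 300), 4)  # path graph, both orientations
  graph <- list(edge_index = rbind(c(1L, 2L, 2L, 3L), c(2L, 1L, 3L, 2L)),
                edge_feat = E)
  lp <- m$params$layers[[1]]
  got <- pgnn:::ad_value(mp_layer(pgnn:::ad_const(h0), graph,
                                  pgnn:::ad_wrap_params(lp), cfg))

  # oracle: explicit loops over receivers and neighbors
  lin <- function(x, p) x %*% p$W + matrix(p$b, nrow(x), ncol(p$W), byrow = TRUE)
  sspo <- function(x) log1p(exp(x)) - log(2)
  hhat <- matrix(0, n, 0)
  for (c_ in seq_len(nh)) {
    hp <- lp$heads[[c_]]
    q <- lin(h0, hp$q); k <- lin(h0, hp$k); v <- lin(h0, hp$v)
    e <- sspo(lin(E, hp$e))
    mc <- matrix(0, n, dh)
    for (i in seq_len(n)) {
      eids <- which(graph$edge_index[1, ] == i)
      if (!length(eids)) next
      js <- graph$edge_index[2, eids]
      sc <- vapply(seq_along(eids), function(t)
        sum(q[i, ] * (k[js[t], ] + e[eids[t], ])) / sqrt(dh), numeric(1))
      al <- exp(sc - max(sc)); al <- al / sum(al)
      for (t in seq_along(eids))
        mc[i, ] <- mc[i, ] + al[t] * (v[js[t], ] + e[eids[t], ])
    }
    hhat <- cbind(hhat, mc)
  }
  hhat <- hhat + lin(h0, lp$root)
  pre <- h0 + hhat
  mu <- rowMeans(pre); va <- apply(pre, 1, function(r) mean((r - mean(r))^2))
  xhat <- (pre - mu) / sqrt(va + 1e-5)
  oracle <- xhat * matrix(lp$ln_gamma, n, nd, byrow = TRUE) +
    matrix(lp$ln_beta, n, nd, byrow = TRUE)
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("zeroed messages reduce the layer to LayerNorm of the residual input", {
  cfg <- small_gsnet_config()
  m <- init_model(cfg, seed = 9)
  lp <- m$params$layers[[1]]
  for (c_ in seq_along(lp$heads)) {
    lp$heads[[c_]]$v$W[] <- 0; lp$heads[[c_]]$v$b[] <- 0
    lp$heads[[c_]]$e$W[] <- 0; lp$heads[[c_]]$e$b[] <- 0
  }
  lp$root$W[] <- 0; lp$root$b[] <- 0
  set.seed(10)
  h0 <- matrix(rnorm(4 * cfg$node_dim), 4)
  graph <- list(edge_index = rbind(c(1L, 2L), c(2L, 1L)),
                edge_feat = matrix(rnorm(2 * 300), 2))
  got <- pgnn:::ad_value(mp_layer(pgnn:::ad_const(h0), graph,
                                  pgnn:::ad_wrap_params(lp), cfg))
  ln <- pgnn:::ad_value(pgnn:::ad_layernorm(pgnn:::ad_const(h0),
                                            pgnn:::ad_param(lp$ln_gamma),
                                            pgnn:::ad_param(lp$ln_beta)))
  expect_equal(got, ln, tolerance = 1e-12)
})

test_that("encoders emit the configured node widths", {
  s <- fix_structure(6, "helix", seed = 12)
  g <- build_residue_graph(s)
  m <- init_model(model_config("gsnet", "global6"), seed = 1)
  h <- pgnn:::ad_value(encode_nodes(g, pgnn:::ad_wrap_params(m$params),
                                    m$config))
  expect_equal(dim(h), c(6L, 150L))

  ag <- build_atom_graph(s, 2L)
  m2 <- init_model(model_config("alcnet", "pka_alcnet"), seed = 1)
  h2 <- pgnn:::ad_value(encode_nodes(ag, pgnn:::ad_wrap_params(m2$params),
                                     m2$config))
  expect_equal(ncol(h2), 75L)
})

test_that("readout means collapse correctly and match subset-mean oracles", {
  s <- fix_structure(7, "coil", seed = 14, charges = FALSE)
  g <- build_residue_graph(s)
  cfg <- small_gsnet_config("pka_gsnet", dropout = 0)
  n <- g$n_nodes; nd <- cfg$node_dim

  # identical embeddings: global mean and every radius mean equal them
  hconst <- matrix(rep(seq_len(nd), each = n), n)
  f <- pgnn:::ad_value(readout(pgnn:::ad_const(hconst), g, cfg, residues = 2L))
  expect_equal(length(f), 7L * nd)
  for (blk in seq_len(7L))
    expect_equal(unname(f[1, ((blk - 1) * nd + 1):(blk * nd)]),
                 as.numeric(seq_len(nd)), tolerance = 1e-12)

  # random embeddings: mu_8 equals the brute-force distance-filtered mean
  set.seed(15)
  hr <- matrix(rnorm(n * nd), n)
  fr <- pgnn:::ad_value(readout(pgnn:::ad_const(hr), g, cfg, residues = 2L))
  dref <- sqrt(rowSums(sweep(g$coords, 2, g$coords[3, ])^2))
  mu8 <- colMeans(hr[dref <= 8, , drop = FALSE])
  blk8 <- (3 * nd + 1):(4 * nd)  # [mu, h_i, mu_6, mu_8, ...]
  expect_equal(unname(fr[1, blk8]), unname(mu8), tolerance = 1e-12)

  # tiny protein: every radius set is the whole graph
  tiny <- fix_ca_structure(cbind(c(0, 1.5, 3), 0, 0))
  gt <- build_residue_graph(tiny)
  ht <- matrix(rnorm(3 * nd), 3)
  ft <- pgnn:::ad_value(readout(pgnn:::ad_const(ht), gt, cfg, residues = 0L))
  mu <- ft[1, 1:nd]
  for (blk in 3:7)
    expect_equal(unname(ft[1, ((blk - 1) * nd + 1):(blk * nd)]), unname(mu),
                 tolerance = 1e-12)

  expect_error(readout(pgnn:::ad_const(hr), g, cfg), "residue")
})

test_that("output heads have the quoted layer counts and input widths", {
  mg <- init_model(model_config("gsnet", "global6"), seed = 1)
  expect_length(mg$params$head, 4L)  # 4 linear layers, 3 SSP between
  expect_equal(nrow(mg$params$head[[1]]$W), 150L)
  expect_equal(ncol(mg$params$head[[4]]$W), 6L)

  mp <- init_model(model_config("gsnet", "pka_gsnet"), seed = 1)
  expect_length(mp$params$head, 6L)
  expect_equal(nrow(mp$params$head[[1]]$W), 1050L)
  expect_equal(mp$config$dropout, 0.2)

  ma <- init_model(model_config("alcnet", "pka_alcnet"), seed = 1)
  expect_equal(nrow(ma$params$head[[1]]$W), 225L)

  feats <- pgnn:::ad_const(matrix(0, 1, 999))
  expect_error(head_forward(feats, pgnn:::ad_wrap_params(mp$params)$head,
                            mp$config), "width")
})

test_that("dropout is active only in training mode", {
  cfg <- small_gsnet_config("pka_gsnet")
  expect_equal(cfg$dropout, 0.2)
  m <- init_model(cfg, seed = 16)
  wh <- pgnn:::ad_wrap_params(m$params)$head
  feats <- pgnn:::ad_const(matrix(rnorm(cfg$head_in_dim), 1))
  e1 <- pgnn:::ad_value(head_forward(feats, wh, cfg, train_mode = FALSE))
  e2 <- pgnn:::ad_value(head_forward(feats, wh, cfg, train_mode = FALSE))
  expect_identical(e1, e2)
  set.seed(1)
  t1 <- pgnn:::ad_value(head_forward(feats, wh, cfg, train_mode = TRUE))
  t2 <- pgnn:::ad_value(head_forward(feats, wh, cfg, train_mode = TRUE))
  expect_false(identical(t1, t2))
})

test_that("whole-network gradients match finite differences", {
  s <- fix_structure(6, "coil", seed = 18)
  g <- build_residue_graph(s)
  cfg <- small_gsnet_config("global6")
  m <- init_model(cfg, seed = 19)
  target <- matrix(rnorm(6), 1)
  maskm <- matrix(c(1, 1, 0, 1, 1, 1), 1)
  loss_at <- function(params) {
    fp <- forward_pass(list(config = cfg, params = params), g)
    masked_mse(pgnn:::ad_value(fp$pred), target, maskm)
  }
  fp <- forward_pass(m, g)
  loss <- pgnn:::ad_masked_mse(fp$pred, target, maskm)
  pgnn:::ad_backward(loss)
  grads <- pgnn:::flatten_params(pgnn:::ad_collect_grads(fp$wp))
  flat <- pgnn:::flatten_params(m$params)
  set.seed(20)
  eps <- 1e-6
  for (nm in sample(names(flat), 10)) {
    ii <- sample(length(flat[[nm]]), 1)
    f1 <- flat; f1[[nm]][ii] <- f1[[nm]][ii] + eps
    f2 <- flat; f2[[nm]][ii] <- f2[[nm]][ii] - eps
    num <- (loss_at(pgnn:::unflatten_params(f1, m$params)) -
            loss_at(pgnn:::unflatten_params(f2, m$params))) / (2 * eps)
    expect_equal(grads[[nm]][ii], num, tolerance = 1e-4)
  }
})

test_that("predictions are invariant to rigid motions and node relabeling", {
  s <- fix_structure(9, "coil", seed = 22)
  cfg <- small_gsnet_config("global6")
  m <- init_model(cfg, seed = 23)
  g <- build_residue_graph(s)
  p0 <- predict_raw(m, g)
  set.seed(24)
  for (k in 1:3) {
    st <- transform_structure(s, random_rotation(), rnorm(3, sd = 20))
    expect_equal(predict_raw(m, build_residue_graph(st)), p0,
                 tolerance = 1e-6)
  }

  # permuting node order permutes embeddings and leaves the mean readout
  perm <- c(3L, 1L, 2L, 9L, 5L, 4L, 8L, 7L, 6L)
  gp <- g
  gp$aa_index <- g$aa_index[perm]
  gp$dihedral_feats <- g$dihedral_feats[perm, ]
  gp$com_dist <- g$com_dist[perm]
  gp$coords <- g$coords[perm, ]
  inv <- order(perm)
  gp$edge_index <- rbind(inv[g$edge_index[1, ]], inv[g$edge_index[2, ]])
  expect_equal(predict_raw(m, gp), p0, tolerance = 1e-9)
  wp <- pgnn:::ad_wrap_params(m$params)
  h <- pgnn:::ad_value(encode_nodes(g, wp, cfg))
  hp <- pgnn:::ad_value(encode_nodes(gp, wp, cfg))
  expect_equal(hp, h[perm, ], tolerance = 1e-12)
})

test_that("checkpoints reload bit-identically and refuse mismatched configs", {
  cfg <- small_gsnet_config("global1")
  m <- init_model(cfg, seed = 25)
  m$norm_stats <- fit_normalization(matrix(rnorm(20), 10))
  tf <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, tf)
  m2 <- load_checkpoint(tf, expect_config = cfg)
  expect_identical(m2$params, m$params)
  s <- fix_structure(5, "helix", seed = 26, charges = FALSE)
  g <- build_residue_graph(s)
  expect_identical(predict_raw(m, g), predict_raw(m2, g))
  expect_error(load_checkpoint(tf, expect_config = small_alcnet_config()),
               "configuration")
})

test_that("a full-size network forward pass is fast enough for screening", {
  s <- fix_structure(50, "helix", seed = 27, charges = FALSE, jitter = 0.3)
  g <- build_residue_graph(s)
  m <- init_model(model_config("gsnet", "global6"), seed = 1)
  el <- system.time(predict_raw(m, g))[["elapsed"]]
  expect_lt(el, 1)
})
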