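test_that("normalization z-scores the masked subset and round-trips", {
  set.seed(41)
  targets <- matrix(rnorm(60, mean = 5, sd = 3), 20)
  mask <- matrix(runif(60) > 0.2, 20)
  st <- fit_normalization(targets, mask)
  z <- apply_normalization(targets, st)
  for (j in 1:3) {
    v <- z[mask[, j], j]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  expect_equal(invert_normalization(z, st), targets, tolerance = 1e-12)

  # validation normalized with training stats keeps nonzero means
  val <- matrix(rnorm(30, mean = 9, sd = 3), 10)
  zv <- apply_normalization(val, st)
  expect_gt(abs(mean(zv[, 1])), 0.1)

  expect_error(fit_normalization(matrix(rep(1, 10), 5)), "variance")
  expect_error(fit_normalization(matrix(1:4, 2),
                                 matrix(c(TRUE, FALSE, TRUE, TRUE), 2)),
               "fewer than 2")
})

test_that("masked MSE zeroes loss and gradients through missing targets", {
  expect_equal(masked_mse(matrix(1:6, 1), matrix(1:6, 1)), 0)
  # hand arithmetic: ((1-0)^2 + 0) / 2
  expect_equal(masked_mse(matrix(c(1, 2), 1), matrix(c(0, 2), 1)), 0.5)
  expect_warning(v <- masked_mse(matrix(1), matrix(5), matrix(FALSE)),
                 "masked out")
  expect_equal(v, 0)

  # perturbing a masked-out prediction changes neither loss nor gradients
  s <- fix_structure(5, "helix", seed = 42, charges = FALSE)
  g <- build_residue_graph(s)
  cfg <- small_gsnet_config("global6")
  m <- init_model(cfg, seed = 43)
  target <- matrix(rnorm(6), 1)
  maskm <- matrix(c(0, 1, 1, 1, 1, 1), 1)  # first target missing
  fp <- forward_pass(m, g)
  loss <- pgnn:::ad_masked_mse(fp$pred, target, maskm)
  pgnn:::ad_backward(loss)
  g1 <- pgnn:::flatten_params(pgnn:::ad_collect_grads(fp$wp))
  target2 <- target; target2[1] <- target2[1] + 100
  fp2 <- forward_pass(m, g)
  loss2 <- pgnn:::ad_masked_mse(fp2$pred, target2, maskm)
  pgnn:::ad_backward(loss2)
  g2 <- pgnn:::flatten_params(pgnn:::ad_collect_grads(fp2$wp))
  expect_equal(pgnn:::ad_value(loss), pgnn:::ad_value(loss2))
  for (nm in names(g1)) expect_identical(g1[[nm]], g2[[nm]])
  # and the head row feeding only the masked output has exactly zero grad
  expect_equal(max(abs(g1$`head.4.W`[, 1])), 0)
  expect_equal(g1$`head.4.b`[1, 1], 0)
})

test_that("frozen transfer keeps GNN parameters bit-identical; fine-tune moves them", {
  ds <- generate_dataset(5, seed = 44, n_residues_range = c(6L, 10L))
  tr <- make_global_dataset(ds$structures, ds$targets, ds$mask)
  cfg <- small_gsnet_config("global6")
  m <- init_model(cfg, seed = 45)
  tc <- train_config(batch_size = 4L, max_epochs = 5L, patience = Inf,
                     seed = 45)
  fit <- train_model(m, tr, config = tc, mode = "transfer_frozen")
  before <- pgnn:::flatten_params(m$params)
  after <- pgnn:::flatten_params(fit$model$params)
  gnn <- grep("^head\\.", names(before), invert = TRUE, value = TRUE)
  for (nm in gnn) expect_identical(after[[nm]], before[[nm]])
  expect_false(identical(after[["head.1.W"]], before[["head.1.W"]]))

  fit2 <- train_model(m, tr, config = tc, mode = "transfer_finetune")
  after2 <- pgnn:::flatten_params(fit2$model$params)
  expect_false(identical(after2[["layers.1.root.W"]],
                         before[["layers.1.root.W"]]))
})

test_that("the learning-rate schedule switches after epoch 50", {
  ds <- generate_dataset(3, seed = 46, n_residues_range = c(5L, 6L))
  tr <- make_global_dataset(ds$structures, ds$targets, ds$mask)
  cfg <- small_gsnet_config("global6")
  m <- init_model(cfg, seed = 47)
  tc <- train_config(batch_size = 4L, max_epochs = 52L, patience = Inf,
                     seed = 47)
  fit <- train_model(m, tr, config = tc, mode = "transfer_frozen")
  expect_equal(fit$history$lr[50], 1e-4)
  expect_equal(fit$history$lr[51], 1e-5)
  expect_equal(fit$history$lr[52], 1e-5)
})

test_that("a small network overfits a tiny dataset", {
  ds <- generate_dataset(5, seed = 48, n_residues_range = c(6L, 9L))
  tr <- make_global_dataset(ds$structures, matrix(ds$targets[, "Rg"]))
  cfg <- small_gsnet_config("global1")
  m <- init_model(cfg, seed = 49)
  tc <- train_config(lr_initial = 1e-3, lr_after_epoch50 = 1e-3,
                     batch_size = 5L, max_epochs = 300L, patience = Inf,
                     seed = 49)
  fit <- train_model(m, tr, config = tc, mode = "fresh")
  expect_lt(tail(fit$history$train_loss, 1),
            0.01 * fit$history$train_loss[1])
})

test_that("training is reproducible at a fixed seed", {
  ds <- generate_dataset(4, seed = 50, n_residues_range = c(5L, 7L))
  tr <- make_global_dataset(ds$structures, ds$targets, ds$mask)
  cfg <- small_gsnet_config("global6")
  run <- function() {
    m <- init_model(cfg, seed = 51)
    train_model(m, tr, config = train_config(batch_size = 2L,
                                             max_epochs = 3L, patience = Inf,
                                             seed = 51), mode = "fresh")
  }
  a <- run(); b <- run()
  expect_identical(a$history$train_loss, b$history$train_loss)
  expect_identical(pgnn:::flatten_params(a$model$params),
                   pgnn:::flatten_params(b$model$params))
})

test_that("repeat selection takes the argmin with deterministic tie-break", {
  expect_equal(select_best(c(0.5, 0.3, 0.9)), 2L)
  expect_equal(select_best(c(0.3, 0.3)), 1L)
  sm <- top_k_summary(c(5, 1, 3, 2), metric = c(50, 10, 30, 20), k = 2L)
  expect_equal(sort(sm$indices), c(2L, 4L))
  expect_equal(sm$mean, 15)
  expect_equal(sm$sem, sd(c(10, 20)) / sqrt(2))
})
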