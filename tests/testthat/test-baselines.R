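test_that("hsic matches a naive double-loop oracle and its symmetries", {
  set.seed(3)
  n <- 40
  x <- matrix(rnorm(n * 5), n, 5)
  y <- matrix(rnorm(n * 2), n, 2)
  # oracle: trace(Kx H Ky H) / (n-1)^2 with explicit n x n kernels
  h <- diag(n) - matrix(1 / n, n, n)
  kx <- tcrossprod(x)
  ky <- tcrossprod(y)
  oracle <- sum(diag(kx %*% h %*% ky %*% h)) / (n - 1)^2
  expect_equal(hsic(x, y), oracle, tolerance = 1e-8)
  expect_equal(hsic(x, y), hsic(y, x), tolerance = 1e-12)
  expect_gt(hsic(x, x), 0)
  # independence: permuting one argument kills the dependence
  xdep <- cbind(rowSums(y), rnorm(n))
  expect_gt(hsic(xdep, y), 10 * hsic(xdep[sample(n), ], y))
  expect_error(hsic(x[1:3, ], y), "equal sample counts")
})

test_that("smida with mu = gamma = 0 reduces to PCA up to sign", {
  set.seed(5)
  x <- matrix(rnorm(60 * 8), 60, 8)
  dom <- rep(c("a", "b", "c"), each = 20)
  cfg <- smida_config(subspace_dim = 4, mu = 0, gamma = 0, augment = FALSE)
  proj <- fit_smida(x, dom, rep(NA_real_, 60), cfg)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  for (j in 1:4) {
    expect_equal(abs(sum(proj$w[, j] * pc$rotation[, j])), 1,
                 tolerance = 1e-6)
  }
  # orthonormal columns
  expect_equal(crossprod(proj$w), diag(4), tolerance = 1e-8)
})

test_that("a large independence weight strips participant mean offsets", {
  set.seed(8)
  n_per <- 25
  doms <- rep(sprintf("P%d", 1:4), each = n_per)
  offset <- matrix(rnorm(4 * 6, sd = 4), 4, 6)[rep(1:4, each = n_per), ]
  x <- offset + matrix(rnorm(4 * n_per * 6), 4 * n_per, 6)
  dmat <- stats::model.matrix(~ factor(doms) - 1)
  cfg <- smida_config(subspace_dim = 3, mu = 50, gamma = 0, augment = FALSE)
  proj <- fit_smida(x, doms, rep(NA_real_, nrow(x)), cfg)
  z <- smida_transform(proj, x)
  expect_lt(hsic(z, dmat), hsic(scale(x, scale = FALSE), dmat))
})

test_that("the smida regression head recovers linear structure and masks test labels", {
  set.seed(11)
  n <- 80
  x <- matrix(rnorm(n * 6), n, 6)
  y_true <- x %*% c(2, -1, 0.5, 0, 0, 1)
  doms <- rep(c("a", "b"), each = n / 2)
  y <- as.numeric(y_true)
  y[61:80] <- NA   # held out
  cfg <- smida_config(subspace_dim = 6, mu = 0, gamma = 1)
  proj <- fit_smida(x, doms, y, cfg)
  pred <- smida_predict(proj, x, doms, y)
  expect_gt(cor(pred[61:80], y_true[61:80]), 0.99)

  yshuf <- y
  yshuf[1:60] <- sample(y[1:60])
  proj2 <- fit_smida(x, doms, yshuf, cfg)
  pred2 <- smida_predict(proj2, x, doms, yshuf)
  expect_lt(abs(cor(pred2[61:80], y_true[61:80])), 0.45)
})

test_that("fnn baseline learns strong linear signal, not shuffled labels", {
  gen <- tiny_cohort(n_participants = 10, n_days = 14, signal_strength = 4,
                     subject_shift_scale = 0.2, missing_rate = 0, seed = 16)
  d <- gen$dataset
  ids <- participants(d)
  tr <- subset_participants(d, ids[1:7])
  va <- subset_participants(d, ids[8:10])
  st <- fit_minmax(tr)
  fcols <- schema_columns(d$feature_schema)
  x_tr <- as.matrix(apply_minmax(tr, st)$data[, fcols])
  x_va <- as.matrix(apply_minmax(va, st)$data[, fcols])
  cfg <- model_config(dropout = 0.1, patience = 10, max_epochs = 60,
                      seed = 2)
  m <- train_fnn_baseline(x_tr, tr$data$stress, x_va, va$data$stress, cfg)
  expect_gt(cor(predict_model(m, x_va), va$data$stress), 0.8)

  y_shuf <- withr::with_seed(4, sample(tr$data$stress))
  va_shuf <- withr::with_seed(5, sample(va$data$stress))
  cfg_s <- model_config(dropout = 0.1, patience = 3, max_epochs = 15,
                        seed = 3)
  ms <- train_fnn_baseline(x_tr, y_shuf, x_va, va_shuf, cfg_s)
  expect_lt(abs(cor(predict_model(ms, x_va), va_shuf)),
            3 / sqrt(length(va_shuf)))
})

test_that("fnn baseline parameter count matches the siamese model within 5%", {
  cfg <- model_config(n_shared_layers = 3, seed = 1)
  snn <- build_model(cfg, 69)
  fnn <- build_model(cfg, 69)   # same constructor: identical stack + head
  expect_identical(fnn$n_parameters, snn$n_parameters)
  expect_true(check_parameter_parity(fnn, snn))
  bigger <- snn
  bigger$n_parameters <- round(snn$n_parameters * 1.2)
  expect_error(check_parameter_parity(bigger, snn), "5%")
})
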