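test_that("feature loss follows the 3-4-5 worked example and its symmetries", {
  expect_equal(feature_loss(c(1, 2), c(1, 2), 0.4, 0.4), 0)
  expect_equal(feature_loss(c(0, 0), c(3, 4), 0, 0.5, weight = 1), 4.5)
  expect_equal(feature_loss(-c(0, 0), -c(3, 4), 0, 0.5), 4.5)
  expect_equal(feature_loss(c(3, 4), c(0, 0), 0.5, 0), 4.5)  # symmetric
  expect_error(feature_loss(c(1, 2), c(1, 2, 3), 0, 0), "dimension")
})

test_that("regression loss is weighted squared error", {
  expect_equal(regression_loss(3, 3), 0)
  expect_equal(regression_loss(2, 3), 1)
  expect_equal(regression_loss(0, 5, weight = 2), 50)
})

test_that("model config enforces the protocol ranges", {
  expect_error(model_config(n_shared_layers = 2), "3, 4 or 5")
  expect_error(model_config(dropout = 0.5), "dropout")
  expect_error(model_config(patience = 4), "patience")
  expect_error(model_config(batch_size = 64), "batch_size")
  expect_error(model_config(lambda = 0), "lambda")
  expect_s3_class(model_config(n_shared_layers = 5, dropout = 0.3,
                               patience = 10, batch_size = 512),
                  "model_config")
})

test_that("architecture has the documented parameter count and shapes", {
  m <- build_model(model_config(n_shared_layers = 3, seed = 1), 69)
  # oracle: closed-form count 69*64+64 + 2*(64*64+64) + 64+1
  expect_equal(m$n_parameters, 69 * 64 + 64 + 2 * (64 * 64 + 64) + 64 + 1)
  expect_equal(m$n_parameters, 12865)

  m83 <- build_model(model_config(seed = 1), 83)
  expect_equal(dim(m83$par$W[[1]]), c(83, 64))
  expect_equal(dim(m83$par$V), c(64, 1))

  # seeded initialization is reproducible
  m2 <- build_model(model_config(n_shared_layers = 3, seed = 1), 69)
  expect_identical(m$par, m2$par)
  m3 <- build_model(model_config(n_shared_layers = 3, seed = 2), 69)
  expect_false(identical(m$par$W[[1]], m3$par$W[[1]]))

  expect_error(build_model(model_config(), 0), "input_dim")
})

test_that("prediction composes the head over the embedding, deterministically", {
  m <- build_model(model_config(seed = 3), 10)
  x <- matrix(rnorm(50), 5, 10)
  emb <- embed_model(m, x)
  expect_equal(ncol(emb), 64)
  pred <- predict_model(m, x)
  expect_equal(pred, as.numeric(emb %*% m$par$V + m$par$c))
  expect_identical(pred, predict_model(m, x))
  expect_error(predict_model(m, matrix(0, 2, 9)), "dimension mismatch")
})

test_that("training learns noiseless linear synthetic structure and shuffles do not", {
  gen <- tiny_cohort(n_participants = 10, n_days = 14, signal_strength = 4,
                     subject_shift_scale = 0.2, missing_rate = 0, seed = 6)
  d <- gen$dataset
  ids <- participants(d)
  tr <- subset_participants(d, ids[1:7])
  va <- subset_participants(d, ids[8:10])
  st <- fit_minmax(tr)
  fcols <- schema_columns(d$feature_schema)
  x_tr <- as.matrix(apply_minmax(tr, st)$data[, fcols])
  x_va <- as.matrix(apply_minmax(va, st)$data[, fcols])
  y_va <- va$data$stress
  pairs <- compute_pair_weights(form_pairs(tr, "stress"))
  cfg <- model_config(dropout = 0.1, patience = 10, max_epochs = 60,
                      learning_rate = 0.01, seed = 11)
  m <- train_siamese(build_model(cfg, 69), pairs, x_tr, x_va, y_va)
  expect_gt(cor(predict_model(m, x_va), y_va), 0.8)
  expect_equal(m$best_epoch, which.max(m$history))

  shuf <- shuffle_labels(tr, "stress", seed = 2)
  pairs_s <- compute_pair_weights(form_pairs(shuf, "stress"))
  va_s <- shuffle_labels(va, "stress", seed = 3)
  cfg_s <- model_config(dropout = 0.1, patience = 3, max_epochs = 15,
                        seed = 12)
  ms <- train_siamese(build_model(cfg_s, 69), pairs_s, x_tr, x_va,
                      va_s$data$stress)
  r <- cor(predict_model(ms, x_va), va_s$data$stress)
  expect_lt(abs(r), 3 / sqrt(length(y_va)))
})

test_that("early stopping halts after `patience` non-improving epochs", {
  gen <- tiny_cohort(n_participants = 6, n_days = 8, missing_rate = 0,
                     seed = 14)
  d <- gen$dataset
  ids <- participants(d)
  tr <- subset_participants(d, ids[1:4])
  va <- subset_participants(d, ids[5:6])
  fcols <- schema_columns(d$feature_schema)
  st <- fit_minmax(tr)
  x_tr <- as.matrix(apply_minmax(tr, st)$data[, fcols])
  x_va <- as.matrix(apply_minmax(va, st)$data[, fcols])
  pairs <- compute_pair_weights(form_pairs(tr, "stress"))
  cfg <- model_config(patience = 3, max_epochs = 50, seed = 5)
  m <- train_siamese(build_model(cfg, 69), pairs, x_tr, x_va, va$data$stress)
  h <- m$history
  expect_equal(m$best_epoch, which.max(h))
  if (length(h) < 50) {
    # stopped early: exactly `patience` epochs after the best one
    expect_equal(length(h) - m$best_epoch, 3L)
  }
  # restored weights reproduce the best epoch's validation score
  expect_equal(cor(predict_model(m, x_va), va$data$stress), max(h),
               tolerance = 1e-10)
})

test_that("fine-tune split moves floor(fraction * m) samples and partitions", {
  d <- tiny_cohort(n_participants = 3, n_days = 10, seed = 4)$dataset
  sp0 <- fine_tune_split(d, 0)
  expect_equal(n_records(sp0$fine_tune), 0L)
  expect_equal(sp0$reduced_test$data, d$data)

  sp <- fine_tune_split(d, 0.5, seed = 9)
  moved <- table(sp$fine_tune$data$participant_id)
  expect_true(all(moved == 5))
  keys <- function(x) paste(x$data$participant_id, x$data$day_index)
  expect_length(intersect(keys(sp$fine_tune), keys(sp$reduced_test)), 0L)
  expect_setequal(c(keys(sp$fine_tune), keys(sp$reduced_test)), keys(d))

  sp2 <- fine_tune_split(d, 0.5, seed = 9)
  expect_equal(sp$fine_tune$data, sp2$fine_tune$data)
  expect_error(fine_tune_split(d, 0.95), "fraction")

  sp37 <- fine_tune_split(d, 0.37, seed = 1)
  expect_true(all(table(sp37$fine_tune$data$participant_id) ==
                    floor(0.37 * 10)))
})
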