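test_that("fold plans stratify, partition and rotate validation", {
  gen <- tiny_cohort(n_participants = 139, n_days = 2, seed = 20)
  plan <- make_folds(gen$dataset, "stress", n_folds = 10, seed = 1)
  sizes <- table(plan$assignment)
  expect_true(all(sizes %in% c(13L, 14L)))
  expect_true(audit_fold_plan(plan))
  for (f in seq_len(10)) {
    fo <- plan$folds[[f]]
    expect_setequal(c(fo$train, fo$validation, fo$test),
                    participants(gen$dataset))
  }
  plan2 <- make_folds(gen$dataset, "stress", n_folds = 10, seed = 1)
  expect_identical(plan$assignment, plan2$assignment)
  # stratification: fold-wise mean labels are close to the cohort mean
  mean_label <- tapply(gen$dataset$data$stress,
                       gen$dataset$data$participant_id, mean)
  fold_means <- sapply(plan$folds, function(fo) mean(mean_label[fo$test]))
  expect_lt(max(abs(fold_means - mean(mean_label))), 0.35)

  small <- tiny_cohort(n_participants = 5, n_days = 2)$dataset
  expect_error(make_folds(small, "stress", n_folds = 10), "fewer")
})

test_that("corrupted fold plans fail the leakage audit", {
  gen <- tiny_cohort(n_participants = 12, n_days = 2, seed = 1)
  plan <- make_folds(gen$dataset, "stress", n_folds = 4, seed = 1)
  bad <- plan
  bad$folds[[1]]$train <- c(bad$folds[[1]]$train, bad$folds[[1]]$test[1])
  expect_error(audit_fold_plan(bad), "leakage")
  bad2 <- plan
  bad2$folds[[2]]$test <- bad2$folds[[1]]$test
  expect_error(audit_fold_plan(bad2), "leakage")
})

test_that("pearson_r matches the closed form and flags degenerate input", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  expect_true(is.na(pearson_r(c(2, 2, 2), c(1, 2, 3))))
  expect_error(pearson_r(1:3, 1:4), "length")
})

test_that("paired t-test reproduces hand-computed statistics", {
  expect_equal(paired_ttest(c(1, 2, 3), c(0, 0, 0))$t, 2 / (1 / sqrt(3)),
               tolerance = 1e-6)
  tt <- paired_ttest(rnorm(20) + 1, rnorm(20))
  expect_equal(tt$df, 19)
  same <- paired_ttest(c(1, 2, 4), c(1, 2, 4))
  expect_true(same$degenerate)
  # one-tailed direction: a >> b gives small p; reversed direction large p
  a <- c(1.1, 1.2, 1.3, 1.4, 1.2)
  b <- c(0.1, 0.3, 0.2, 0.4, 0.2)
  expect_lt(paired_ttest(a, b)$p, 0.01)
  expect_gt(paired_ttest(b, a)$p, 0.99)
})

test_that("gp tuner honours its argmin contract on a deterministic objective", {
  # known quadratic bowl over one continuous + one discrete dimension
  objective <- function(v) -( (v$x - 0.3)^2 + 0.1 * (v$k == 1) )
  space <- list(x = c(0, 1), k = c(1L, 2L))
  attr(space$k, "discrete") <- TRUE
  out <- tune_hyperparameters(objective, space, n_calls = 25, n_initial = 8,
                              seed = 42)
  expect_equal(out$best_score, max(out$history$score))
  expect_equal(out$best$k, 2L)
  expect_lt(abs(out$best$x - 0.3), 0.15)
  # determinism
  out2 <- tune_hyperparameters(objective, space, n_calls = 25, n_initial = 8,
                               seed = 42)
  expect_identical(out$best, out2$best)

  # singleton space returns that configuration
  single <- tune_hyperparameters(function(v) v$a, list(a = 5), n_calls = 3)
  expect_equal(single$best$a, 5)

  # objective failures are absorbed, search continues
  flaky <- function(v) if (v$x < 0.5) stop("boom") else v$x
  outf <- tune_hyperparameters(flaky, list(x = c(0, 1)), n_calls = 15,
                               seed = 1)
  expect_gte(outf$best$x, 0.5)
})

test_that("gp tuner approaches the exhaustive grid optimum on discrete dims", {
  # deterministic bumpy objective over a fully discrete space
  objective <- function(v) sin(3 * v$a) + 0.5 * cos(2 * v$b) + 0.3 * v$c
  grid <- expand.grid(a = seq(0, 2, by = 0.25), b = seq(0, 2, by = 0.5),
                      c = c(0, 1))
  best_grid <- max(apply(grid, 1, function(g)
    objective(list(a = g[1], b = g[2], c = g[3]))))
  space <- list(a = seq(0, 2, by = 0.25), b = seq(0, 2, by = 0.5), c = c(0, 1))
  attr(space$c, "discrete") <- TRUE
  out <- tune_hyperparameters(objective, space, n_calls = 20, n_initial = 8,
                              seed = 42)
  expect_gte(out$best_score, best_grid - 0.05)
})

test_that("run_experiment books scores per fold/fraction/restart and audits leakage", {
  gen <- tiny_cohort(n_participants = 8, n_days = 8, seed = 23,
                     signal_strength = 2)
  plan <- make_folds(gen$dataset, "stress", n_folds = 4, seed = 1)
  cfg <- model_config(patience = 3, max_epochs = 4, batch_size = 128)
  rep <- run_experiment("ml-a", gen$dataset, plan, "stress", fractions = 0,
                        restarts = 1, cfg = cfg, folds = 1:2, seed = 5)
  expect_equal(nrow(rep$scores), 2L)
  expect_setequal(rep$scores$fold, 1:2)

  agg <- aggregate_report(rep)
  expect_equal(agg$mean_r, mean(rep$scores$pearson_r))

  # duplicated test participant in train trips the sample-level hard error
  bad <- plan
  bad$folds[[1]]$train <- c(bad$folds[[1]]$train, bad$folds[[1]]$test[1])
  bad$assignment <- plan$assignment
  expect_error(
    run_experiment("ml-a", gen$dataset, bad, "stress", fractions = 0,
                   restarts = 1, cfg = cfg, folds = 1, seed = 5),
    "leakage")
})

test_that("restart-level aggregation feeds the paired comparisons", {
  scores <- expand.grid(fold = 1:2, restart = 1:5)
  scores$variant <- "ml-a"; scores$construct <- "stress"
  scores$fraction <- 0.4
  scores$pearson_r <- scores$restart / 10 + scores$fold / 100
  scores$n_test <- 10L
  rep <- eval_report(scores)
  rs <- restart_scores(rep, 0.4)
  expect_length(rs, 5L)
  expect_equal(rs[1], mean(c(0.1 + 0.01, 0.1 + 0.02)))
  expect_error(restart_scores(rep, 0.9), "no scores")
})

test_that("the identification probe tracks how identifiable a representation is", {
  set.seed(33)
  n_per <- 12
  ids <- rep(sprintf("P%d", 1:5), each = n_per)
  # strongly participant-coded representation: unique corner per participant
  strong <- diag(5)[rep(1:5, each = n_per), ] * 5 +
    matrix(rnorm(5 * n_per * 5, sd = 0.1), ncol = 5)
  acc_strong <- person_id_probe(strong, ids, restarts = 3, seed = 1)
  expect_gt(acc_strong$mean_accuracy, 0.95)
  # uninformative representation: same distribution for everyone
  weak <- matrix(rnorm(5 * n_per * 5), ncol = 5)
  acc_weak <- person_id_probe(weak, ids, restarts = 3, seed = 1)
  expect_lt(acc_weak$mean_accuracy, 0.6)
  expect_error(person_id_probe(strong, rep("P1", nrow(strong))),
               ">= 2 participants")
})
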