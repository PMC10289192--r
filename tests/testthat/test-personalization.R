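test_that("trait augmentation widths follow the leakage rule", {
  d <- tiny_cohort(n_participants = 4, n_days = 3)$dataset
  expect_length(augment_with_traits(d, "stress")$columns, 69 + 14)
  expect_length(augment_with_traits(d, "anxiety")$columns, 83)
  expect_length(augment_with_traits(d, "positive_affect")$columns, 69 + 12)
  expect_length(augment_with_traits(d, "negative_affect")$columns, 81)
  expect_false(any(c("trait_positive_affect", "trait_negative_affect") %in%
                     augment_with_traits(d, "positive_affect")$columns))

  d$data$trait_anxiety[1] <- NA
  expect_error(augment_with_traits(d, "stress"), "missing traits")
})

test_that("trait block is constant within participant", {
  d <- tiny_cohort(n_participants = 3, n_days = 5)$dataset
  tcols <- schema_columns(d$trait_schema)
  for (pid in participants(d)) {
    block <- d$data[d$data$participant_id == pid, tcols]
    expect_equal(nrow(unique(block)), 1L)
  }
})

test_that("cluster fitting is seeded, assigns training ids consistently", {
  gen <- tiny_cohort(n_participants = 24, n_days = 2, seed = 18)
  traits <- trait_matrix_by_participant(gen$dataset)
  cm1 <- fit_trait_clusters(traits, k = 4, seed = 7)
  cm2 <- fit_trait_clusters(traits, k = 4, seed = 7)
  expect_identical(cm1$centroids, cm2$centroids)
  # assign_clusters reproduces the training assignment
  expect_equal(unname(assign_clusters(cm1, traits)),
               unname(cm1$assignments))
  # PCA variance ratios are a non-increasing sub-unit partition
  evr <- cm1$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-8)
  expect_error(fit_trait_clusters(traits[1:3, ], k = 4), "exceeds")
})

test_that("k = 1 clustering reduces to the grand centroid", {
  gen <- tiny_cohort(n_participants = 10, n_days = 2, seed = 3)
  traits <- trait_matrix_by_participant(gen$dataset)
  cm <- fit_trait_clusters(traits, k = 1, seed = 1)
  proj <- ambumetric:::project_traits(cm, traits)
  expect_equal(unname(cm$centroids[1, ]), unname(colMeans(proj)),
               tolerance = 1e-8)
  expect_equal(cm$inertia, sum(sweep(proj, 2, colMeans(proj))^2),
               tolerance = 1e-8)
})

test_that("elbow selection finds ideal cluster geometry and flags flat curves", {
  # three well-separated synthetic trait clusters
  set.seed(1)
  traits <- rbind(matrix(rnorm(10 * 14, 0, 0.1), 10, 14),
                  matrix(rnorm(10 * 14, 5, 0.1), 10, 14),
                  matrix(rnorm(10 * 14, -5, 0.1), 10, 14))
  rownames(traits) <- sprintf("P%02d", 1:30)
  er <- select_k_elbow(traits, k_range = 1:6, seed = 2)
  expect_equal(er$chosen_k, 3L)
  expect_false(er$fallback)
  expect_true(all(diff(er$inertia) <= 1e-8))
  expect_equal(er$distortion, er$inertia / 30)

  # near-uniform traits: no elbow, fall back to the configured default
  flat <- matrix(runif(30 * 14), 30, 14)
  rownames(flat) <- rownames(traits)
  erf <- select_k_elbow(flat, k_range = 1:6, default_k = 4, seed = 2)
  expect_true(erf$fallback)
  expect_equal(erf$chosen_k, 4L)
})

test_that("held-out assignment is nearest-centroid with low-index ties", {
  gen <- tiny_cohort(n_participants = 12, n_days = 2, seed = 5)
  traits <- trait_matrix_by_participant(gen$dataset)
  cm <- fit_trait_clusters(traits, k = 3, seed = 2)
  # a point exactly at a centroid lands in that cluster: invert the pipeline
  # by checking assignment distances directly in the projected space
  proj <- ambumetric:::project_traits(cm, traits)
  lab <- assign_clusters(cm, traits)
  for (i in seq_len(nrow(proj))) {
    d2 <- colSums((t(cm$centroids) - proj[i, ])^2)
    expect_equal(unname(lab[i]), unname(which.min(d2)))
  }
  expect_error(assign_clusters(cm, traits[, 1:5]), "dimension")
})

test_that("cluster ensemble routes every sample to exactly one model", {
  gen <- tiny_cohort(n_participants = 16, n_days = 8, seed = 9,
                     missing_rate = 0)
  d <- gen$dataset
  ids <- participants(d)
  tr <- subset_participants(d, ids[1:10])
  va <- subset_participants(d, ids[11:13])
  te <- subset_participants(d, ids[14:16])
  st <- fit_minmax(tr, columns = c(schema_columns(d$feature_schema),
                                   schema_columns(d$trait_schema)))
  cfg <- model_config(patience = 3, max_epochs = 5, seed = 1)
  cm <- train_cluster_models(apply_minmax(tr, st), apply_minmax(va, st),
                             "stress", cfg, k = 2, seed = 3)
  expect_length(cm$models, 2L)
  pred <- predict_cluster_ensemble(cm, apply_minmax(te, st))
  expect_length(pred, n_records(te))
  expect_false(anyNA(pred))

  profiles <- cluster_trait_profiles(cm, trait_matrix_by_participant(tr))
  expect_equal(dim(profiles), c(14L, 2L))
})
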