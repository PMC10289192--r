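#' Run the full cross-validated experiment for one model variant
#'
#' For each evaluated fold, fine-tune fraction and restart: a fresh model is
#' built, the fine-tuning split moves the selected target-participant samples
#' into the training pool, min-max normalization is refit on the augmented
#' training pool (no state crosses folds), the model is trained, and the
#' Pearson correlation between predictions and raw labels on the reduced
#' test fold is recorded. A sample-level leakage audit (no participant-day
#' shared between the training pool and the reduced test set, on top of
#' [audit_fold_plan()]) hard-errors on violation.
#'
#' Variants: `"ml-a"` (Siamese, ambulatory features), `"ml-at"` (Siamese,
#' ambulatory + trait features), `"ml-c"` (one ML-AT model per trait
#' cluster), `"fnn"` (feed-forward baseline), `"smida"` (maximum-independence
#' domain adaptation + linear regression; deterministic, so restarts repeat
#' one value).
#'
#' @param variant One of `"ml-a"`, `"ml-at"`, `"ml-c"`, `"fnn"`, `"smida"`.
#' @param d A `wb_dataset` (raw; interpolation is applied internally).
#' @param plan A `fold_plan` from [make_folds()].
#' @param construct Construct name.
#' @param fractions Fine-tuning fractions in \[0, 0.9\] (default
#'   `c(0, 0.4, 0.9)`).
#' @param restarts Random restarts per fold and fraction (default 20).
#' @param cfg A [model_config()] (its `seed` is ignored; restart seeds are
#'   derived from `seed`).
#' @param folds Which folds to evaluate (default: all folds in `plan`).
#' @param threshold Pair similarity threshold (default 1).
#' @param k Trait clusters for `"ml-c"` (default 4).
#' @param smida_cfg A [smida_config()] for `"smida"`.
#' @param seed Master seed for fine-tune splits and restart initializations.
#' @return An `eval_report` (see [eval_report()]).
#' @export
run_experiment <- function(variant, d, plan, construct,
                           fractions = c(0, 0.4, 0.9), restarts = 20L,
                           cfg = model_config(), folds = NULL,
                           threshold = 1L, k = 4L,
                           smida_cfg = smida_config(), seed = 1L) {
  variant <- match.arg(variant, c("ml-a", "ml-at", "ml-c", "fnn", "smida"))
  validate_construct(construct, d$label_schemas)
  audit_fold_plan(plan)
  if (any(fractions < 0 | fractions > 0.9))
    stop("fractions must be in [0, 0.9]", call. = FALSE)
  if (is.null(folds)) folds <- seq_len(plan$n_folds)
  d <- interpolate_dataset(d)
  fcols <- schema_columns(d$feature_schema)
  rows <- list()
  for (f in folds) {
    fo <- plan$folds[[f]]
    d_train0 <- subset_participants(d, fo$train)
    d_val <- subset_participants(d, fo$validation)
    d_test0 <- subset_participants(d, fo$test)
    for (fi in seq_along(fractions)) {
      frac <- fractions[fi]
      split_seed <- (seed * 10007L + f * 101L + fi) %% 2147483647L
      sp <- fine_tune_split(d_test0, frac, seed = split_seed)
      d_train <- d_train0
      d_train$data <- rbind(d_train0$data, sp$fine_tune$data)
      rownames(d_train$data) <- NULL
      d_test <- sp$reduced_test
      # sample-level leakage audit
      key <- function(x) paste(x$data$participant_id, x$data$day_index)
      if (length(intersect(key(d_train), key(d_test))) > 0 ||
          length(intersect(key(d_val), key(d_test))) > 0)
        stop("leakage audit failed: train/validation and test share ",
             "participant-days (fold ", f, ", fraction ", frac, ")",
             call. = FALSE)
      # normalization refit on the augmented training pool
      norm_cols <- c(fcols, schema_columns(d$trait_schema))
      stats_mm <- fit_minmax(d_train, columns = norm_cols)
      tr <- apply_minmax(d_train, stats_mm)
      va <- apply_minmax(d_val, stats_mm)
      te <- apply_minmax(d_test, stats_mm)
      y_te <- te$data[[construct]]
      te_keep <- !is.na(y_te)
      if (sum(te_keep) < 2) next
      y_va <- va$data[[construct]]
      va_keep <- !is.na(y_va)
      cols <- switch(variant,
        "ml-a" = fcols,
        "fnn" = fcols,
        "smida" = fcols,
        "ml-at" = augment_with_traits(tr, construct)$columns,
        "ml-c" = augment_with_traits(tr, construct)$columns
      )
      x_tr <- as.matrix(tr$data[, cols, drop = FALSE])
      x_va <- as.matrix(va$data[va_keep, cols, drop = FALSE])
      x_te <- as.matrix(te$data[te_keep, cols, drop = FALSE])
      pairs_tf <- if (variant %in% c("ml-a", "ml-at")) {
        compute_pair_weights(form_pairs(tr, construct, threshold))
      } else NULL
      smida_val <- NULL
      if (variant == "smida") {
        all_x <- rbind(x_tr, x_va, x_te)
        all_dom <- c(tr$data$participant_id, va$data$participant_id[va_keep],
                     te$data$participant_id[te_keep])
        all_y <- c(tr$data[[construct]], y_va[va_keep],
                   rep(NA_real_, sum(te_keep)))   # test labels masked
        proj <- fit_smida(all_x, all_dom, all_y, smida_cfg)
        preds <- smida_predict(proj, all_x, all_dom, all_y)
        te_rows <- (nrow(all_x) - sum(te_keep) + 1):nrow(all_x)
        smida_val <- pearson_r(preds[te_rows], y_te[te_keep])
      }
      for (rs in seq_len(restarts)) {
        r <- if (variant == "smida") {
          smida_val
        } else {
          rcfg <- cfg
          rcfg$seed <- (seed * 7919L + f * 6007L + fi * 331L + rs) %%
            2147483647L
          pred <- switch(variant,
            "ml-a" = ,
            "ml-at" = {
              m <- build_model(rcfg, length(cols))
              m <- train_siamese(m, pairs_tf, x_tr, x_va, y_va[va_keep])
              predict_model(m, x_te)
            },
            "fnn" = {
              m <- train_fnn_baseline(x_tr, tr$data[[construct]],
                                      x_va, y_va[va_keep], rcfg)
              predict_model(m, x_te)
            },
            "ml-c" = {
              cm <- train_cluster_models(tr, va, construct, rcfg, k = k,
                                         threshold = threshold,
                                         seed = rcfg$seed)
              predict_cluster_ensemble(cm, te)[te_keep]
            })
          pearson_r(pred, y_te[te_keep])
        }
        rows[[length(rows) + 1]] <- data.frame(
          variant = variant, construct = construct, fold = f,
          fraction = frac, restart = rs, pearson_r = r,
          n_test = sum(te_keep), stringsAsFactors = FALSE)
      }
    }
  }
  eval_report(do.call(rbind, rows),
              meta = list(variant = variant, construct = construct,
                          restarts = restarts, threshold = threshold,
                          seed = seed,
                          multiple_comparison_correction = "none"))
}

#' Person-identification probe
#'
#' Trains a multinomial logistic classifier to predict participant identity
#' from a representation (raw normalized features or learned embeddings)
#' under a stratified 70/30 sample-level split, repeated `restarts` times;
#' reports the mean held-out accuracy. Lower accuracy means the
#' representation retains less person-specific information.
#'
#' @param x Sample-by-dimension matrix.
#' @param participant_ids Participant id per row (>= 2 participants, >= 2
#'   samples each).
#' @param restarts Number of random splits (default 20).
#' @param seed Integer seed.
#' @param train_frac Fraction of each participant's samples used to train the
#'   probe (default 0.7).
#' @return List with `mean_accuracy` and `accuracies` (per restart).
#' @export
person_id_probe <- function(x, participant_ids, restarts = 20L, seed = 1L,
                            train_frac = 0.7) {
  x <- as.matrix(x)
  ids <- as.character(participant_ids)
  if (length(unique(ids)) < 2)
    stop("need >= 2 participants", call. = FALSE)
  if (any(table(ids) < 2))
    stop("every participant needs >= 2 samples", call. = FALSE)
  accs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(restarts), function(rs) {
      tr_rows <- unlist(lapply(split(seq_along(ids), ids), function(rows) {
        k <- max(1, round(train_frac * length(rows)))
        if (k >= length(rows)) k <- length(rows) - 1
        sample(rows, k)
      }), use.names = FALSE)
      te_rows <- setdiff(seq_along(ids), tr_rows)
      y <- factor(ids)
      fit <- tryCatch(
        glmnet::glmnet(x[tr_rows, , drop = FALSE], y[tr_rows],
                       family = "multinomial", alpha = 0,
                       lambda = c(1, 0.1, 0.01, 0.001)),
        error = function(e) NULL)
      if (is.null(fit)) return(1 / length(levels(y)))  # chance fallback
      pred <- stats::predict(fit, x[te_rows, , drop = FALSE], s = 0.001,
                             type = "class")
      mean(pred == as.character(y[te_rows]))
    }, numeric(1))
  })
  list(mean_accuracy = mean(accs), accuracies = accs)
}
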