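#' Participant-independent stratified fold plan
#'
#' Participants are sorted by their mean construct label, grouped into
#' consecutive blocks of `n_folds`, and each block is distributed across the
#' folds in a seeded random order, so fold label distributions are
#' comparable while assignment stays participant-level (no individual ever
#' appears in more than one of train/validation/test). Per test fold `f` the
#' validation fold is `(f + 1) mod n_folds` and the remaining folds train.
#'
#' @param d A `wb_dataset`.
#' @param construct Construct whose labels drive the stratification.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `fold_plan` with `n_folds`, `assignment`
#'   (named integer vector participant -> fold) and `folds` (list of
#'   `train`/`validation`/`test` id sets).
#' @export
make_folds <- function(d, construct, n_folds = 10L, seed = 1L) {
  validate_construct(construct, d$label_schemas)
  ids <- participants(d)
  if (length(ids) < n_folds)
    stop("fewer participants (", length(ids), ") than folds (", n_folds, ")",
         call. = FALSE)
  mean_label <- tapply(d$data[[construct]], d$data$participant_id,
                       function(v) mean(v, na.rm = TRUE))
  mean_label <- mean_label[ids]
  mean_label[is.nan(mean_label)] <- stats::median(mean_label, na.rm = TRUE)
  ord <- ids[order(mean_label, ids)]
  assignment <- integer(length(ord))
  names(assignment) <- ord
  withr::with_seed(as.integer(seed), {
    for (start in seq(1, length(ord), by = n_folds)) {
      block <- start:min(start + n_folds - 1, length(ord))
      assignment[block] <- sample(n_folds)[seq_along(block)]
    }
  })
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- names(assignment)[assignment == f]
    valf <- (f %% n_folds) + 1L
    validation <- names(assignment)[assignment == valf]
    train <- setdiff(ids, c(test, validation))
    list(test = test, validation = validation, train = train)
  })
  structure(list(n_folds = as.integer(n_folds), assignment = assignment,
                 folds = folds, construct = construct,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Audit a fold plan for participant-level leakage
#'
#' Hard-errors unless, for every fold, train/validation/test participant sets
#' are pairwise disjoint, and test sets across folds are disjoint and cover
#' all participants.
#'
#' @param plan A `fold_plan`.
#' @return `TRUE` invisibly.
#' @export
audit_fold_plan <- function(plan) {
  stopifnot(inherits(plan, "fold_plan"))
  all_ids <- names(plan$assignment)
  tests <- unlist(lapply(plan$folds, `[[`, "test"))
  if (anyDuplicated(tests) || !setequal(tests, all_ids))
    stop("leakage audit failed: test folds do not partition participants",
         call. = FALSE)
  for (f in seq_along(plan$folds)) {
    fo <- plan$folds[[f]]
    if (length(intersect(fo$train, fo$validation)) > 0 ||
        length(intersect(fo$train, fo$test)) > 0 ||
        length(intersect(fo$validation, fo$test)) > 0)
      stop("leakage audit failed: overlapping sets in fold ", f,
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample Pearson correlation with degenerate-input handling
#'
#' @param pred,true Numeric vectors of equal length >= 2.
#' @return Pearson r, or `NA` (flagged missing) when either vector is
#'   constant.
#' @export
pearson_r <- function(pred, true) {
  if (length(pred) != length(true)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 2) stop("need >= 2 observations", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(true) == 0) return(NA_real_)
  stats::cor(pred, true)
}

#' One-tailed paired t-test between per-restart score vectors
#'
#' @param scores_a,scores_b Equal-length (n >= 2) score vectors paired by
#'   restart.
#' @param alternative `"greater"` tests a > b (default), `"less"` the
#'   reverse.
#' @return List with `t`, `df`, `p` and `degenerate` (`TRUE` when the paired
#'   differences have zero variance, in which case `t`/`p` are `NA`).
#' @export
paired_ttest <- function(scores_a, scores_b, alternative = "greater") {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2)
    stop("need equal-length paired vectors of length >= 2", call. = FALSE)
  diffs <- scores_a - scores_b
  if (stats::sd(diffs) == 0) {
    return(list(t = NA_real_, df = length(diffs) - 1L, p = NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE,
                      alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

# ---- Gaussian-process hyperparameter search ---------------------------------

# A dimension is discrete unless it is an untagged numeric range c(lo, hi).
dim_is_discrete <- function(dim) {
  is.list(dim) || is.character(dim) || length(dim) != 2 ||
    isTRUE(attr(dim, "discrete"))
}

space_encode <- function(space, values) {
  vapply(names(space), function(nm) {
    dim <- space[[nm]]
    v <- values[[nm]]
    if (dim_is_discrete(dim)) {
      i <- match(v, unlist(dim))
      if (length(dim) == 1) 0.5 else (i - 1) / (length(dim) - 1)
    } else {
      if (dim[2] == dim[1]) 0.5 else (v - dim[1]) / (dim[2] - dim[1])
    }
  }, numeric(1))
}

space_sample <- function(space) {
  vals <- lapply(space, function(dim) {
    if (dim_is_discrete(dim)) dim[[sample.int(length(dim), 1)]]
    else stats::runif(1, dim[1], dim[2])
  })
  stats::setNames(vals, names(space))
}

#' Gaussian-process Bayesian hyperparameter search
#'
#' Sequential model-based minimization of the negative objective: after a
#' handful of seeded random evaluations, a Gaussian process (RBF kernel,
#' fixed length-scale, small nugget) is fitted to the observed scores and the
#' next candidate is chosen by maximizing expected improvement over a random
#' candidate pool. Deterministic given `seed` and a deterministic objective.
#'
#' A search dimension is either a numeric range `c(lo, hi)` (continuous) or a
#' vector/list of more than two admissible values (discrete); tag a
#' two-element discrete set with `attr(x, "discrete") <- TRUE`.
#'
#' @param objective Function taking a named list of hyperparameter values and
#'   returning a score to MAXIMIZE (e.g. validation Pearson r). Errors are
#'   absorbed as a penalized score and the search continues.
#' @param space Named list of dimensions as described above.
#' @param n_calls Total objective evaluations (default 200).
#' @param n_initial Random evaluations before the GP kicks in (default 10).
#' @param seed Integer seed (default 42).
#' @return List with `best` (named list of values), `best_score`, and
#'   `history` (data.frame of evaluated points and scores).
#' @export
tune_hyperparameters <- function(objective, space, n_calls = 200L,
                                 n_initial = 10L, seed = 42L) {
  stopifnot(length(space) > 0, n_calls >= 1)
  singleton <- all(vapply(space, function(dim)
    (dim_is_discrete(dim) && length(dim) == 1) ||
      (!dim_is_discrete(dim) && dim[1] == dim[2]),
    logical(1)))
  eval_safe <- function(vals) {
    s <- tryCatch(objective(vals), error = function(e) NA_real_)
    if (!is.finite(s)) NA_real_ else s
  }
  withr::with_seed(as.integer(seed), {
    if (singleton) {
      vals <- lapply(space, function(dim)
        if (dim_is_discrete(dim)) dim[[1]] else dim[1])
      vals <- stats::setNames(vals, names(space))
      sc <- eval_safe(vals)
      return(list(best = vals, best_score = sc,
                  history = data.frame(call = 1, score = sc)))
    }
    pts <- list()
    xs <- NULL
    scores <- numeric(0)
    n_initial <- min(n_initial, n_calls)
    for (i in seq_len(n_calls)) {
      if (i <= n_initial || all(is.na(scores))) {
        cand <- space_sample(space)
      } else {
        ok <- !is.na(scores)
        y <- -scores[ok]                       # minimize negative score
        ysd <- stats::sd(y)
        y_std <- if (is.finite(ysd) && ysd > 0) (y - mean(y)) / ysd
                 else y - mean(y)
        xobs <- xs[ok, , drop = FALSE]
        ell <- 0.3
        k_rbf <- function(a, b) {
          d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
          exp(-pmax(d2, 0) / (2 * ell^2))
        }
        kmat <- k_rbf(xobs, xobs) + diag(1e-6, nrow(xobs))
        kinv_y <- solve(kmat, y_std)
        kinv <- solve(kmat)
        # candidate pool: random points plus single-coordinate mutations of
        # the incumbent, so EI can refine one dimension at a time
        cands <- replicate(192L, space_sample(space), simplify = FALSE)
        incumbent <- pts[[which.max(ifelse(is.na(scores), -Inf, scores))]]
        for (j in seq_len(64L)) {
          mut <- incumbent
          nm <- names(space)[1 + (j - 1) %% length(space)]
          mut[[nm]] <- space_sample(space[nm])[[1]]
          cands[[length(cands) + 1]] <- mut
        }
        xc <- do.call(rbind, lapply(cands, function(v)
          space_encode(space, v)))
        # drop candidates already evaluated (objective is deterministic)
        seen <- apply(xs, 1, paste, collapse = "|")
        fresh <- !(apply(xc, 1, paste, collapse = "|") %in% seen)
        if (any(fresh)) {
          cands <- cands[fresh]
          xc <- xc[fresh, , drop = FALSE]
        }
        kx <- k_rbf(xc, xobs)
        mu <- as.numeric(kx %*% kinv_y)
        var <- pmax(1 - rowSums((kx %*% kinv) * kx), 1e-12)
        sdv <- sqrt(var)
        y_best <- min(y_std)
        imp <- y_best - mu
        zz <- imp / sdv
        ei <- imp * stats::pnorm(zz) + sdv * stats::dnorm(zz)
        cand <- cands[[which.max(ei)]]
      }
      s <- eval_safe(cand)
      pts[[i]] <- cand
      xs <- rbind(xs, space_encode(space, cand))
      scores <- c(scores, s)
    }
    if (all(is.na(scores)))
      stop("objective failed on every evaluated configuration",
           call. = FALSE)
    best_i <- which.max(ifelse(is.na(scores), -Inf, scores))
    hist_df <- cbind(
      do.call(rbind, lapply(pts, function(p)
        as.data.frame(p, stringsAsFactors = FALSE))),
      score = scores
    )
    list(best = pts[[best_i]], best_score = scores[best_i],
         history = hist_df)
  })
}

#' Default hyperparameter search space of the Siamese protocol
#'
#' Layers 3-5, dropout 0.1-0.3, patience \{3, 5, 10\}, batch \{128, 256,
#' 512\}.
#'
#' @return Named list usable as `space` in [tune_hyperparameters()].
#' @export
default_search_space <- function() {
  disc <- function(v) { attr(v, "discrete") <- TRUE; v }
  list(n_shared_layers = c(3L, 4L, 5L),
       dropout = c(0.1, 0.3),
       patience = c(3L, 5L, 10L),
       batch_size = c(128L, 256L, 512L),
       learning_rate = disc(c(0.005, 0.01)))
}
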