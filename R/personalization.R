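#' Append trait features to every record (trait augmentation)
#'
#' Traits are measured once per participant, so the participant's trait
#' vector is duplicated onto each of their daily records and appended to the
#' ambulatory feature block. When the target construct is positive or
#' negative affect, the trait versions of both affect scales are dropped
#' first so the model cannot shortcut through the trait form of its own
#' target (12 traits remain instead of 14).
#'
#' @param d A `wb_dataset`.
#' @param construct Target construct (drives the leakage exclusion).
#' @return List with `columns` (character vector: feature columns followed by
#'   the retained trait columns, the model's input order) and `dataset`
#'   (unchanged `d`; augmentation is a column selection, the trait columns
#'   already live on every record).
#' @export
augment_with_traits <- function(d, construct) {
  validate_construct(construct, d$label_schemas)
  tcols <- trait_columns_for(d$trait_schema, construct)
  if (anyNA(d$data[, tcols])) {
    bad <- unique(d$data$participant_id[rowSums(
      is.na(d$data[, tcols, drop = FALSE])) > 0])
    stop("missing traits for participant(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  list(columns = c(schema_columns(d$feature_schema), tcols), dataset = d)
}

#' Fit trait clusters: min-max scaling, PCA to 3 components, K-means
#'
#' Per-participant trait vectors are min-max scaled (training extremes),
#' projected onto the first 3 principal components, and clustered with
#' K-means (10 seeded restarts, best inertia kept). The fitted scaler, PCA
#' rotation and centroids are retained so held-out participants can be
#' assigned without refitting.
#'
#' @param train_traits Numeric matrix of per-participant trait vectors
#'   (rownames = participant ids).
#' @param k Number of clusters (default 4).
#' @param seed Integer seed.
#' @return An object of class `cluster_model` with `scaler`, `rotation`,
#'   `center`, `explained_variance_ratio`, `centroids` (k x 3), `k`,
#'   `assignments` (named integer vector) and an empty `models` slot.
#' @export
fit_trait_clusters <- function(train_traits, k = 4L, seed = 1L) {
  train_traits <- as.matrix(train_traits)
  n <- nrow(train_traits)
  if (k > n) stop("k (", k, ") exceeds participants (", n, ")",
                  call. = FALSE)
  tmin <- apply(train_traits, 2, min)
  tmax <- apply(train_traits, 2, max)
  rng <- pmax(tmax - tmin, .Machine$double.eps)
  scaled <- sweep(sweep(train_traits, 2, tmin), 2, rng, "/")
  pc <- stats::prcomp(scaled, center = TRUE, scale. = FALSE)
  ncomp <- min(3L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  proj <- pc$x[, seq_len(ncomp), drop = FALSE]
  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(proj, centers = k, nstart = 10,
                                       iter.max = 100))
  structure(
    list(scaler = list(min = tmin, range = rng), center = pc$center,
         rotation = rot, explained_variance_ratio = evr,
         centroids = km$centers, k = as.integer(k),
         inertia = km$tot.withinss,
         assignments = stats::setNames(km$cluster, rownames(train_traits)),
         models = list()),
    class = "cluster_model"
  )
}

project_traits <- function(cm, traits) {
  traits <- as.matrix(traits)
  if (ncol(traits) != length(cm$scaler$min))
    stop("trait dimension mismatch: expected ", length(cm$scaler$min),
         ", got ", ncol(traits), call. = FALSE)
  scaled <- sweep(sweep(traits, 2, cm$scaler$min), 2, cm$scaler$range, "/")
  sweep(scaled, 2, cm$center) %*% cm$rotation
}

#' Assign participants to fitted trait clusters
#'
#' Nearest-centroid assignment in the fitted 3-d PCA space; the cluster model
#' is never refit on held-out data. Ties go to the lowest-index cluster.
#'
#' @param cm A `cluster_model`.
#' @param traits Per-participant trait matrix (rownames = ids).
#' @return Named integer vector of cluster labels.
#' @export
assign_clusters <- function(cm, traits) {
  stopifnot(inherits(cm, "cluster_model"))
  proj <- project_traits(cm, traits)
  d2 <- outer(rowSums(proj^2), rowSums(cm$centroids^2), "+") -
    2 * proj %*% t(cm$centroids)
  lab <- apply(d2, 1, which.min)  # which.min breaks ties at lowest index
  stats::setNames(as.integer(lab), rownames(traits))
}

#' Elbow diagnostics for choosing the cluster count
#'
#' Fits K-means for each K in `k_range` on the 3-d PCA projection of the
#' scaled traits and reports distortion (mean squared distance to the
#' assigned centroid) and inertia (summed squared distance). The advisory
#' `chosen_k` is the knee of the inertia curve: the K at maximal distance
#' below the chord joining the normalized curve's endpoints (the kneedle
#' rule). When the curve is too flat to show an elbow (maximal normalized
#' chord distance below 0.25) the configured `default_k` is returned with
#' `fallback = TRUE`. The reference protocol likewise found no clear elbow on
#' real traits and fixed K = 4 empirically, so `chosen_k` is advisory and the
#' default governs.
#'
#' @param train_traits Per-participant trait matrix.
#' @param k_range Integer vector of K values to evaluate (needs >= 3 points
#'   for a curvature estimate).
#' @param default_k Fallback K (default 4).
#' @param seed Integer seed.
#' @return An `elbow_report`: data.frame-backed list with `k`, `distortion`,
#'   `inertia`, `chosen_k`, `fallback`.
#' @export
select_k_elbow <- function(train_traits, k_range = 1:8, default_k = 4L,
                           seed = 1L) {
  train_traits <- as.matrix(train_traits)
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(train_traits)
  if (any(k_range < 1) || any(k_range > n))
    stop("k_range must lie within [1, n_participants]", call. = FALSE)
  fits <- lapply(k_range, function(k)
    fit_trait_clusters(train_traits, k = k, seed = seed))
  inertia <- vapply(fits, function(f) f$inertia, numeric(1))
  distortion <- inertia / n
  chosen <- as.integer(default_k)
  fallback <- TRUE
  if (length(k_range) >= 3 && max(inertia) > min(inertia)) {
    xk <- (k_range - min(k_range)) / (max(k_range) - min(k_range))
    yk <- (inertia - min(inertia)) / (max(inertia) - min(inertia))
    chord <- yk[1] + (yk[length(yk)] - yk[1]) * xk
    dist <- (chord - yk) / sqrt(2)
    if (max(dist) > 0.25) {
      chosen <- k_range[which.max(dist)]
      fallback <- FALSE
    }
  }
  structure(
    list(k = k_range, distortion = distortion, inertia = inertia,
         chosen_k = chosen, fallback = fallback),
    class = "elbow_report"
  )
}

#' Train one trait-augmented model per trait cluster
#'
#' The cluster-specific variant: trait clusters are fitted on the training
#' participants' traits, then a trait-augmented Siamese model is trained on
#' each cluster's within-participant pairs. Held-out samples are routed by
#' [assign_clusters()] to their cluster's model. A cluster with no usable
#' training participant gets no model; its held-out members are routed to the
#' nearest non-empty centroid at prediction time (with a warning at fit
#' time).
#'
#' @param train A `wb_dataset` (training pool, normalized features).
#' @param val A `wb_dataset` (validation fold, normalized features).
#' @param construct Construct name.
#' @param cfg A [model_config()].
#' @param k Number of clusters (default 4).
#' @param threshold Pair similarity threshold.
#' @param seed Seed for the clustering.
#' @return A `cluster_model` with `models` filled (one `siamese_model` per
#'   non-empty cluster) and `input_columns` recorded.
#' @export
train_cluster_models <- function(train, val, construct, cfg, k = 4L,
                                 threshold = 1L, seed = 1L) {
  aug <- augment_with_traits(train, construct)
  cols <- aug$columns
  traits_train <- trait_matrix_by_participant(train)
  cm <- fit_trait_clusters(traits_train, k = k, seed = seed)
  cm$input_columns <- cols
  cm$construct <- construct
  val_assign <- assign_clusters(cm, trait_matrix_by_participant(val))
  for (cl in seq_len(cm$k)) {
    ids <- names(cm$assignments)[cm$assignments == cl]
    d_cl <- subset_participants(train, ids)
    ok <- length(ids) > 0 && {
      y <- d_cl$data[[construct]]
      any(table(d_cl$data$participant_id[!is.na(y)]) >= 2)
    }
    if (!ok) {
      warning("cluster ", cl, " has no trainable participant; held-out ",
              "members will be routed to the nearest non-empty centroid")
      cm$models[cl] <- list(NULL)
      next
    }
    pairs <- compute_pair_weights(form_pairs(d_cl, construct, threshold))
    x_cl <- as.matrix(d_cl$data[, cols, drop = FALSE])
    val_ids <- names(val_assign)[val_assign == cl]
    v <- subset_participants(val, val_ids)
    vy <- v$data[[construct]]
    if (sum(!is.na(vy)) < 2) {
      # too few same-cluster validation samples: validate on the whole fold
      v <- val
      vy <- v$data[[construct]]
    }
    keep <- !is.na(vy)
    vx <- as.matrix(v$data[keep, cols, drop = FALSE])
    model <- build_model(cfg, length(cols))
    cm$models[[cl]] <- train_siamese(model, pairs, x_cl, vx, vy[keep])
  }
  cm
}

#' Predict with a cluster-specific ensemble
#'
#' Each sample is scored by exactly one cluster model, selected by its
#' participant's nearest fitted centroid; clusters without a model fall back
#' to the nearest non-empty centroid.
#'
#' @param cm A `cluster_model` from [train_cluster_models()].
#' @param d A `wb_dataset` (normalized features).
#' @return Numeric predictions aligned with `d$data` rows.
#' @export
predict_cluster_ensemble <- function(cm, d) {
  stopifnot(inherits(cm, "cluster_model"), length(cm$models) > 0)
  assign <- assign_clusters(cm, trait_matrix_by_participant(d))
  nonempty <- which(!vapply(cm$models, is.null, logical(1)))
  if (length(nonempty) == 0) stop("no trained cluster models", call. = FALSE)
  proj <- project_traits(cm, trait_matrix_by_participant(d))
  x <- as.matrix(d$data[, cm$input_columns, drop = FALSE])
  pred <- rep(NA_real_, nrow(x))
  for (pid in names(assign)) {
    cl <- assign[[pid]]
    if (is.null(cm$models[[cl]])) {
      cen <- cm$centroids[nonempty, , drop = FALSE]
      p <- proj[pid, ]
      cl <- nonempty[which.min(colSums((t(cen) - p)^2))]
    }
    rows <- which(d$data$participant_id == pid)
    pred[rows] <- predict_model(cm$models[[cl]], x[rows, , drop = FALSE])
  }
  pred
}

#' Per-cluster mean profiles of min-max-normalized traits
#'
#' Inspection report: the mean of each scaled trait within each fitted
#' cluster (rows = traits, columns = clusters).
#'
#' @param cm A `cluster_model`.
#' @param traits Per-participant trait matrix used at fit time.
#' @return Numeric matrix, traits x clusters.
#' @export
cluster_trait_profiles <- function(cm, traits) {
  traits <- as.matrix(traits)
  scaled <- sweep(sweep(traits, 2, cm$scaler$min), 2, cm$scaler$range, "/")
  assign <- assign_clusters(cm, traits)
  out <- sapply(seq_len(cm$k), function(cl)
    colMeans(scaled[assign == cl, , drop = FALSE]))
  colnames(out) <- paste0("cluster_", seq_len(cm$k))
  out
}
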