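#' Fill gaps in an ordered series by linear interpolation
#'
#' Interior runs of missing values are replaced by linear interpolation
#' between the nearest observed neighbours; leading/trailing gaps take the
#' nearest observed value (there is no second anchor to interpolate against).
#'
#' @param series Numeric vector in temporal order, `NA` for missing.
#' @param context Optional label used in the all-missing error message.
#' @return Numeric vector with no missing values; observed values unchanged.
#' @export
interpolate_missing <- function(series, context = NULL) {
  obs <- which(!is.na(series))
  if (length(obs) == 0) {
    stop("all values missing",
         if (!is.null(context)) paste0(" for ", context) else "",
         call. = FALSE)
  }
  if (length(obs) == length(series)) return(series)
  idx <- seq_along(series)
  # rule = 2: extend first/last observed value to the boundaries
  stats::approx(idx[obs], series[obs], xout = idx, method = "linear",
                rule = 2)$y
}

#' Interpolate missing feature values across each participant's day series
#'
#' Applies [interpolate_missing()] per participant and feature, ordered by
#' `day_index`. Samples are treated as independent over time downstream;
#' interpolation is only a missing-data remedy.
#'
#' @param d A `wb_dataset`.
#' @return A `wb_dataset` with complete feature columns.
#' @export
interpolate_dataset <- function(d) {
  cols <- schema_columns(d$feature_schema)
  ord <- order(d$data$participant_id, d$data$day_index)
  inv <- order(ord)
  dat <- d$data[ord, , drop = FALSE]
  pid <- dat$participant_id
  for (col in cols) {
    v <- dat[[col]]
    if (!anyNA(v)) next
    dat[[col]] <- unlist(lapply(split(v, factor(pid, unique(pid))),
                                function(s) {
      if (all(is.na(s))) {
        stop("all values missing for participant ",
             pid[match(TRUE, is.na(v))], ", feature ", col, call. = FALSE)
      }
      interpolate_missing(s)
    }), use.names = FALSE)
  }
  d$data <- dat[inv, , drop = FALSE]
  rownames(d$data) <- NULL
  d
}

#' Aggregate sub-daily records to one record per participant-day
#'
#' Per-feature arithmetic mean over the day's observations, missing values
#' ignored; traits and labels carried through unchanged. Conflicting labels
#' within one day are an error.
#'
#' @param data data.frame with `participant_id`, `day_index`, feature columns
#'   and optionally trait/label columns (possibly several rows per day).
#' @param feature_schema,trait_schema,label_schemas Schemas.
#' @return A `wb_dataset` with one row per participant-day.
#' @export
daily_average <- function(data,
                          feature_schema = feature_schema_default(),
                          trait_schema = trait_schema_default(),
                          label_schemas = label_schemas_default()) {
  fcols <- schema_columns(feature_schema)
  other <- setdiff(names(data), fcols)
  key <- interaction(data$participant_id, data$day_index, drop = TRUE)
  label_cols <- intersect(names(label_schemas), names(data))
  for (con in label_cols) {
    nuniq <- tapply(data[[con]], key,
                    function(v) length(unique(v[!is.na(v)])))
    if (any(nuniq > 1, na.rm = TRUE)) {
      stop("conflicting '", con, "' labels within a participant-day",
           call. = FALSE)
    }
  }
  # rows aligned with tapply's level order
  first <- data[match(levels(key), as.character(key)), other, drop = FALSE]
  for (con in label_cols) {
    lab <- tapply(data[[con]], key, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_integer_ else as.integer(v[1])
    })
    first[[con]] <- as.integer(lab)
  }
  means <- do.call(cbind, lapply(fcols, function(col) {
    m <- tapply(data[[col]], key, function(v) mean(v, na.rm = TRUE))
    m[is.nan(m)] <- NA_real_
    as.numeric(m)
  }))
  colnames(means) <- fcols
  out <- cbind(first, as.data.frame(means))
  rownames(out) <- NULL
  wb_dataset(out, feature_schema, trait_schema, label_schemas)
}

#' Fit min-max normalization statistics on training participants
#'
#' @param train A `wb_dataset` restricted to the training participants.
#' @param columns Feature columns to normalize (default: full feature schema).
#' @return An object of class `normalization_stats` with per-feature `min`,
#'   `max` and `fitted_on` (participant ids).
#' @export
fit_minmax <- function(train, columns = schema_columns(train$feature_schema)) {
  if (n_records(train) == 0) stop("empty training set", call. = FALSE)
  x <- as.matrix(train$data[, columns, drop = FALSE])
  structure(
    list(min = apply(x, 2, min, na.rm = TRUE),
         max = apply(x, 2, max, na.rm = TRUE),
         columns = columns, fitted_on = participants(train)),
    class = "normalization_stats"
  )
}

#' Apply min-max normalization
#'
#' Maps each feature by (x - min) / (max - min) using the training extremes;
#' held-out values outside the training range are clipped to \[0, 1\];
#' constant features map to 0.
#'
#' @param d A `wb_dataset`.
#' @param stats A `normalization_stats` from [fit_minmax()].
#' @return Normalized `wb_dataset`.
#' @export
apply_minmax <- function(d, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  for (j in seq_along(stats$columns)) {
    col <- stats$columns[j]
    rng <- stats$max[j] - stats$min[j]
    v <- d$data[[col]]
    v <- if (rng > 0) (v - stats$min[j]) / rng else v * 0
    d$data[[col]] <- pmin(pmax(v, 0), 1)
  }
  d
}

#' Per-participant l2 label normalizer
#'
#' The pairwise feature loss compares embedding distances with distances
#' between l2-normalized labels. Normalization is per participant over that
#' participant's training labels (pairs are formed strictly within
#' participant, so only same-participant normalized labels are ever compared).
#'
#' @param train_labels Integer/numeric vector of one participant's training
#'   labels (non-missing).
#' @return An object of class `label_normalizer` with the l2 `norm`.
#' @export
fit_label_normalizer <- function(train_labels) {
  y <- train_labels[!is.na(train_labels)]
  if (length(y) == 0) stop("participant has no training labels", call. = FALSE)
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) stop("zero-norm label vector", call. = FALSE)
  structure(list(norm = nrm, n = length(y)), class = "label_normalizer")
}

#' Apply an l2 label normalizer
#' @param normalizer A `label_normalizer`.
#' @param y Labels to normalize.
#' @return `y / norm`.
#' @export
apply_label_normalizer <- function(normalizer, y) {
  stopifnot(inherits(normalizer, "label_normalizer"))
  y / normalizer$norm
}
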