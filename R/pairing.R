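#' Form within-participant training pairs
#'
#' Enumerates all unordered pairs of labeled samples within each participant
#' (never across participants). A pair is flagged similar when the absolute
#' raw-label difference is at most `threshold` (default 1), dissimilar
#' otherwise. Normalized labels for the pairwise feature loss come from each
#' participant's [fit_label_normalizer()] over the supplied records.
#'
#' @param d A `wb_dataset` (the training pool; must carry labels for
#'   `construct`).
#' @param construct Construct name.
#' @param threshold Integer similarity threshold on the raw label difference.
#' @return An object of class `pair_set`: list with `pairs` (data.frame with
#'   columns `participant_id`, `idx_a`, `idx_b` — row indices into `d$data` —
#'   `y_a`, `y_b`, `yhat_a`, `yhat_b`, `similar`, `weight`), `threshold`,
#'   `n_similar`, `n_dissimilar`. Weights are initialized to 1; see
#'   [compute_pair_weights()].
#' @export
form_pairs <- function(d, construct, threshold = 1L) {
  validate_construct(construct, d$label_schemas)
  stopifnot(threshold >= 0)
  y <- d$data[[construct]]
  labeled <- which(!is.na(y))
  by_pid <- split(labeled, d$data$participant_id[labeled])
  by_pid <- by_pid[lengths(by_pid) >= 2]
  if (length(by_pid) == 0) {
    stop("no participant has >= 2 labeled samples; cannot form pairs",
         call. = FALSE)
  }
  blocks <- lapply(names(by_pid), function(pid) {
    rows <- by_pid[[pid]]
    norm <- fit_label_normalizer(y[rows])
    cmb <- utils::combn(rows, 2)
    data.frame(
      participant_id = pid,
      idx_a = cmb[1, ], idx_b = cmb[2, ],
      y_a = y[cmb[1, ]], y_b = y[cmb[2, ]],
      yhat_a = apply_label_normalizer(norm, y[cmb[1, ]]),
      yhat_b = apply_label_normalizer(norm, y[cmb[2, ]]),
      stringsAsFactors = FALSE
    )
  })
  pairs <- do.call(rbind, blocks)
  pairs$similar <- abs(pairs$y_a - pairs$y_b) <= threshold
  pairs$weight <- 1
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs, threshold = as.integer(threshold),
         n_similar = sum(pairs$similar),
         n_dissimilar = sum(!pairs$similar)),
    class = "pair_set"
  )
}

#' @export
print.pair_set <- function(x, ...) {
  cat("<pair_set> ", nrow(x$pairs), " pairs (", x$n_similar, " similar, ",
      x$n_dissimilar, " dissimilar), threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Inverse-frequency class weights for pair imbalance
#'
#' Similar and dissimilar pairs are typically unbalanced; the loss is
#' reweighted so each class contributes equally: the class weight is inversely
#' proportional to its size, normalized so the mean weight over all pairs is
#' 1 (hence the total weighted pair count equals the raw pair count). If one
#' class is empty all weights stay 1, with a warning.
#'
#' @param p A `pair_set`.
#' @return The `pair_set` with its `weight` column updated.
#' @export
compute_pair_weights <- function(p) {
  stopifnot(inherits(p, "pair_set"))
  ns <- p$n_similar
  nd <- p$n_dissimilar
  if (ns == 0 || nd == 0) {
    warning("only one pair class present; weights left at 1")
    p$pairs$weight <- 1
    return(p)
  }
  total <- ns + nd
  # w_s * ns == w_d * nd and (w_s*ns + w_d*nd)/total == 1
  w_s <- total / (2 * ns)
  w_d <- total / (2 * nd)
  p$pairs$weight <- ifelse(p$pairs$similar, w_s, w_d)
  p
}
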