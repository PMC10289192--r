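#' Evaluation report container
#'
#' Holds per (variant, construct, fold, restart, fraction) Pearson scores,
#' plus metadata. Aggregates (mean/SD over restarts per variant, fraction and
#' fold) are always recomputed from the stored scores, never stored
#' redundantly; undefined scores from constant predictions are kept as `NA`
#' and excluded from aggregates with a count.
#'
#' @param scores data.frame with columns `variant`, `construct`, `fold`,
#'   `fraction`, `restart`, `pearson_r`, `n_test` (may have zero rows).
#' @param meta Named list of metadata.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(scores = NULL, meta = list()) {
  cols <- c("variant", "construct", "fold", "fraction", "restart",
            "pearson_r", "n_test")
  if (is.null(scores)) {
    scores <- data.frame(variant = character(), construct = character(),
                         fold = integer(), fraction = numeric(),
                         restart = integer(), pearson_r = numeric(),
                         n_test = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(all(cols %in% names(scores)))
  structure(list(scores = scores[, cols, drop = FALSE], meta = meta),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", nrow(x$scores), " score rows\n", sep = "")
  if (nrow(x$scores) > 0) print(aggregate_report(x))
  invisible(x)
}

#' Aggregate an evaluation report over folds and restarts
#'
#' @param report An `eval_report`.
#' @return data.frame with per variant/construct/fraction mean and SD of the
#'   stored Pearson scores (missing scores excluded, with `n_missing`
#'   counted).
#' @export
aggregate_report <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  s <- report$scores
  if (nrow(s) == 0) {
    return(data.frame(variant = character(), construct = character(),
                      fraction = numeric(), mean_r = numeric(),
                      sd_r = numeric(), n_scores = integer(),
                      n_missing = integer()))
  }
  key <- interaction(s$variant, s$construct, s$fraction, drop = TRUE)
  out <- do.call(rbind, lapply(split(s, key), function(g) {
    ok <- !is.na(g$pearson_r)
    data.frame(variant = g$variant[1], construct = g$construct[1],
               fraction = g$fraction[1],
               mean_r = mean(g$pearson_r[ok]),
               sd_r = stats::sd(g$pearson_r[ok]),
               n_scores = sum(ok), n_missing = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$variant, out$fraction), , drop = FALSE]
}

#' Mean Pearson r per restart (averaged over evaluated folds)
#'
#' The paired t-tests compare models restart-by-restart; this collapses a
#' report to one score per restart at a given fraction.
#'
#' @param report An `eval_report`.
#' @param fraction Fine-tuning fraction to select.
#' @return Numeric vector indexed by restart.
#' @export
restart_scores <- function(report, fraction) {
  s <- report$scores
  s <- s[s$fraction == fraction, , drop = FALSE]
  if (nrow(s) == 0) stop("no scores at fraction ", fraction, call. = FALSE)
  as.numeric(tapply(s$pearson_r, s$restart,
                    function(v) mean(v, na.rm = TRUE)))
}

#' Write an evaluation report to disk
#'
#' `<path>.json` holds the full report (scores + metadata, schema version
#' tag); `<path>.csv` holds the score table. The JSON round-trips losslessly
#' through [read_report()].
#'
#' @param report An `eval_report`.
#' @param path Output path without extension (or with `.json`, which is
#'   stripped).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  path <- sub("\\.json$", "", path)
  payload <- list(schema_version = "1.0",
                  meta = report$meta,
                  scores = report$scores)
  jsonlite::write_json(payload, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  utils::write.csv(report$scores, paste0(path, ".csv"), row.names = FALSE)
  invisible(paste0(path, ".json"))
}

#' Read an evaluation report written by [write_report()]
#'
#' @param path Path to the `.json` file (extension optional).
#' @return An `eval_report`.
#' @export
read_report <- function(path) {
  path <- sub("\\.json$", "", path)
  payload <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scores <- payload$scores
  if (length(scores) == 0 || is.null(nrow(scores)) || nrow(scores) == 0) {
    return(eval_report(NULL, meta = payload$meta))
  }
  scores$fold <- as.integer(scores$fold)
  scores$restart <- as.integer(scores$restart)
  scores$n_test <- as.integer(scores$n_test)
  scores$pearson_r <- as.numeric(scores$pearson_r)
  eval_report(scores, meta = payload$meta)
}
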