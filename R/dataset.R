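#' Cohort dataset container
#'
#' A `wb_dataset` wraps a wide data.frame (one row per participant-day) with
#' the schemas that describe its columns. Columns: `participant_id`,
#' `day_index`, then the 69 feature columns, the 14 trait columns and one
#' column per construct label. Missing feature values and missing labels are
#' `NA`.
#'
#' @param data data.frame with the columns described above.
#' @param feature_schema,trait_schema,label_schemas Schemas; defaults are the
#'   packaged ones.
#' @return An object of class `wb_dataset`.
#' @export
wb_dataset <- function(data,
                       feature_schema = feature_schema_default(),
                       trait_schema = trait_schema_default(),
                       label_schemas = label_schemas_default()) {
  stopifnot(is.data.frame(data))
  required <- c("participant_id", "day_index",
                schema_columns(feature_schema), schema_columns(trait_schema))
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$participant_id <- as.character(data$participant_id)
  data$day_index <- as.integer(data$day_index)
  if (anyDuplicated(data[, c("participant_id", "day_index")])) {
    stop("duplicate (participant_id, day_index) rows", call. = FALSE)
  }
  for (con in names(label_schemas)) {
    if (!con %in% names(data)) next
    sch <- label_schemas[[con]]
    y <- data[[con]]
    bad <- which(!is.na(y) & (y < sch$min_label | y > sch$max_label))
    if (length(bad) > 0) {
      stop("label '", con, "' outside schema bounds [", sch$min_label, ", ",
           sch$max_label, "] at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    data[[con]] <- as.integer(round(y))
  }
  # traits must be constant within participant
  tcols <- schema_columns(trait_schema)
  nuniq <- vapply(split(data[, tcols, drop = FALSE], data$participant_id),
                  function(df) nrow(unique(df)), integer(1))
  if (any(nuniq > 1)) {
    stop("traits vary within participant(s): ",
         paste(names(nuniq)[nuniq > 1][1:min(3, sum(nuniq > 1))],
               collapse = ", "), call. = FALSE)
  }
  structure(
    list(data = data, feature_schema = feature_schema,
         trait_schema = trait_schema, label_schemas = label_schemas),
    class = "wb_dataset"
  )
}

#' @export
print.wb_dataset <- function(x, ...) {
  cat("<wb_dataset> ", nrow(x$data), " participant-days, ",
      length(unique(x$data$participant_id)), " participants, ",
      x$feature_schema$total_count, " features, ",
      x$trait_schema$total_count, " traits\n", sep = "")
  invisible(x)
}

#' Number of records in a dataset
#' @param d A `wb_dataset`.
#' @return Integer row count.
#' @export
n_records <- function(d) nrow(d$data)

#' Participant identifiers present in a dataset
#' @param d A `wb_dataset`.
#' @return Character vector of unique participant ids, in order of appearance.
#' @export
participants <- function(d) unique(d$data$participant_id)

#' Subset a dataset by participant id
#' @param d A `wb_dataset`.
#' @param ids Character vector of participant ids to keep.
#' @return A `wb_dataset` with only the selected participants.
#' @export
subset_participants <- function(d, ids) {
  d$data <- d$data[d$data$participant_id %in% ids, , drop = FALSE]
  rownames(d$data) <- NULL
  d
}

#' Read a cohort CSV into a `wb_dataset`
#'
#' The file must be comma-separated UTF-8 with a header row; missing values
#' are empty cells. Columns not covered by the schemas are reported via a
#' message and carried along untouched; absent schema columns are an error.
#'
#' @param path Path to the CSV file.
#' @param feature_schema,trait_schema,label_schemas Schemas (defaults
#'   packaged).
#' @return A `wb_dataset`.
#' @export
load_dataset <- function(path,
                         feature_schema = feature_schema_default(),
                         trait_schema = trait_schema_default(),
                         label_schemas = label_schemas_default()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  known <- c("participant_id", "day_index",
             schema_columns(feature_schema), schema_columns(trait_schema),
             names(label_schemas))
  unknown <- setdiff(names(df), known)
  if (length(unknown) > 0) {
    message("ignoring ", length(unknown), " unknown column(s): ",
            paste(utils::head(unknown, 8), collapse = ", "))
  }
  wb_dataset(df, feature_schema, trait_schema, label_schemas)
}

#' Write a `wb_dataset` to CSV
#'
#' Inverse of [load_dataset()]: comma-separated, header row, missing values as
#' empty cells.
#'
#' @param d A `wb_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(d, path) {
  utils::write.csv(d$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the minimum-labeled-days inclusion filter
#'
#' Retains only participants with at least `min_labeled_days` records carrying
#' a non-missing label for `construct`. The study protocol this mirrors drops
#' participants with fewer than 13 labeled days, an empirically chosen
#' minimum for reliable supervised evaluation.
#'
#' @param d A `wb_dataset`.
#' @param construct Construct whose label column is counted.
#' @param min_labeled_days Minimum number of labeled days (default 13).
#' @return Filtered `wb_dataset` with attribute `n_dropped` (number of
#'   participants removed).
#' @export
filter_participants <- function(d, construct, min_labeled_days = 13L) {
  validate_construct(construct, d$label_schemas)
  stopifnot(min_labeled_days >= 1)
  labeled <- !is.na(d$data[[construct]])
  counts <- tapply(labeled, d$data$participant_id, sum)
  keep <- names(counts)[counts >= min_labeled_days]
  dropped <- length(counts) - length(keep)
  if (length(keep) == 0) {
    warning("no participant meets the ", min_labeled_days,
            "-labeled-day threshold; result is empty")
  }
  out <- subset_participants(d, keep)
  attr(out, "n_dropped") <- dropped
  out
}

feature_matrix <- function(d, columns = schema_columns(d$feature_schema)) {
  as.matrix(d$data[, columns, drop = FALSE])
}

trait_matrix_by_participant <- function(d, columns =
                                          schema_columns(d$trait_schema)) {
  ids <- participants(d)
  first_rows <- match(ids, d$data$participant_id)
  m <- as.matrix(d$data[first_rows, columns, drop = FALSE])
  rownames(m) <- ids
  m
}
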