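#' Feature, trait and label schemas
#'
#' The modeling pipeline operates on wide participant-day tables whose columns
#' are described by three schemas: the ambulatory feature schema (69 features
#' across three wearable device groups), the trait schema (14 one-time trait
#' questionnaire scores), and per-construct label schemas (daily self-report
#' ranges).
#'
#' @name schemas
NULL

#' Default ambulatory feature schema
#'
#' 69 daily ambulatory features in three device groups: 25 activity/sleep
#' measures from a wrist tracker, 29 vocal acoustic features from a wearable
#' smartphone, and 15 physiological features from a sensing garment.
#'
#' @return An object of class `feature_schema`: a list with `groups` (named
#'   list of ordered feature-name character vectors) and `total_count`.
#' @export
feature_schema_default <- function() {
  activity_sleep <- c(
    "car_upper", "car_lower", "fbar_upper", "fbar_lower",
    "par_upper", "par_lower", "oorar_upper", "oorar_lower",
    "car_minutes", "car_calories", "fbar_minutes", "fbar_calories",
    "par_minutes", "par_calories", "oorar_minutes", "oorar_calories",
    "steps", "minutes_awake", "minutes_deep_sleep", "minutes_light_sleep",
    "minutes_rem_sleep", "minutes_nonrem_sleep", "minutes_asleep",
    "minutes_in_bed", "sleep_efficiency"
  )
  acoustic <- c(
    "jitter", "jitter_delta", "shimmer", "f0_mean", "f0_contour_mean",
    "f0_envelope_mean", "hnr", "voice_prob", "signal_norm",
    "signal_norm_rasta_plp", "energy", "zero_crossing_rate", "intensity",
    "loudness", "fft_mag_250_650", "fft_mag_1000_4000",
    "rolloff_iqr_0_25", "rolloff_iqr_25_50", "rolloff_iqr_50_75",
    "rolloff_iqr_75_90", "spectral_flux", "spectral_centroid",
    "spectral_entropy", "spectral_variance", "spectral_skewness",
    "spectral_kurtosis", "spectral_slope", "spectral_sharpness",
    "spectral_harmonicity"
  )
  physiology <- c(
    "breathing_rate", "heart_rate", "garment_intensity", "avg_heart_rate",
    "accel_x", "accel_y", "accel_z", "rmssd", "total_power",
    "vlf_power", "lf_power", "hf_power", "lf_hf_ratio",
    "cadence", "steps_garment"
  )
  groups <- list(
    activity_sleep = activity_sleep,
    acoustic = acoustic,
    physiology = physiology
  )
  structure(
    list(groups = groups, total_count = length(unlist(groups))),
    class = "feature_schema"
  )
}

#' Default trait schema
#'
#' 14 one-time trait scores in three groups (3 cognitive, 8 psychological,
#' 3 health). `leakage_exclusions` lists, per daily construct, the trait
#' columns that must be dropped before the traits are used as model input:
#' trait positive/negative affect are removed when estimating daily
#' positive/negative affect so the model cannot shortcut through the trait
#' version of the target construct.
#'
#' @return An object of class `trait_schema`: list with `groups`,
#'   `total_count` and `leakage_exclusions`.
#' @export
trait_schema_default <- function() {
  groups <- list(
    cognitive = c("ocb", "fluid_intelligence", "crystallized_intelligence"),
    psychological = c(
      "extraversion", "agreeableness", "conscientiousness",
      "emotional_stability", "openness", "trait_positive_affect",
      "trait_negative_affect", "trait_anxiety"
    ),
    health = c("tobacco_use", "tobacco_quantity", "sleep_quality")
  )
  affect_traits <- c("trait_positive_affect", "trait_negative_affect")
  structure(
    list(
      groups = groups,
      total_count = length(unlist(groups)),
      leakage_exclusions = list(
        positive_affect = affect_traits,
        negative_affect = affect_traits
      )
    ),
    class = "trait_schema"
  )
}

#' Label schemas for the daily well-being constructs
#'
#' Integer self-report ranges: anxiety and stress on a 5-point scale,
#' positive affect summed over five 1-5 items (5-25), negative affect 5-24.
#'
#' @return Named list of `label_schema` objects, each with `construct`,
#'   `min_label`, `max_label`.
#' @export
label_schemas_default <- function() {
  mk <- function(construct, lo, hi) {
    structure(
      list(construct = construct, min_label = lo, max_label = hi),
      class = "label_schema"
    )
  }
  list(
    anxiety = mk("anxiety", 1L, 5L),
    stress = mk("stress", 1L, 5L),
    positive_affect = mk("positive_affect", 5L, 25L),
    negative_affect = mk("negative_affect", 5L, 24L)
  )
}

#' All construct names recognized by the default label schemas
#' @return Character vector of construct names.
#' @export
constructs <- function() names(label_schemas_default())

#' Feature names of a schema
#' @param schema A `feature_schema` or `trait_schema`.
#' @return Character vector of column names in schema order.
#' @export
schema_columns <- function(schema) as.character(unlist(schema$groups))

#' Trait columns usable for a construct after leakage exclusion
#'
#' @param trait_schema A `trait_schema`.
#' @param construct Construct name.
#' @return Character vector of trait columns with any excluded traits removed.
#' @export
trait_columns_for <- function(trait_schema, construct) {
  cols <- schema_columns(trait_schema)
  excl <- trait_schema$leakage_exclusions[[construct]]
  if (!is.null(excl)) cols <- setdiff(cols, excl)
  cols
}

validate_construct <- function(construct,
                               schemas = label_schemas_default()) {
  if (!construct %in% names(schemas)) {
    stop("unknown construct '", construct, "'; expected one of: ",
         paste(names(schemas), collapse = ", "), call. = FALSE)
  }
  invisible(construct)
}
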