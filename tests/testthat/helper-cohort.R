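# Shared fixtures: all data is generated in code at test time.

# Minimal hand-built cohort table with full schema columns; features and
# traits are filled deterministically, labels supplied per participant.
manual_cohort <- function(labels_by_pid, construct = "stress",
                          n_days = NULL) {
  fs <- feature_schema_default()
  ts <- trait_schema_default()
  rows <- lapply(names(labels_by_pid), function(pid) {
    labs <- labels_by_pid[[pid]]
    m <- length(labs)
    feat <- matrix(seq_len(m * fs$total_count) / 100, m, fs$total_count)
    colnames(feat) <- schema_columns(fs)
    tr <- matrix(rep(which(names(labels_by_pid) == pid) + 0.5,
                     m * ts$total_count), m, ts$total_count)
    colnames(tr) <- schema_columns(ts)
    df <- data.frame(participant_id = pid, day_index = seq_len(m) - 1L,
                     feat, tr, check.names = FALSE)
    for (con in constructs()) df[[con]] <- NA_integer_
    df[[construct]] <- as.integer(labs)
    df
  })
  wb_dataset(do.call(rbind, rows))
}

# Small synthetic cohort for pipeline tests.
tiny_cohort <- function(n_participants = 12, n_days = 10,
                        construct = "stress", seed = 42, ...) {
  generate_cohort(generator_config(
    n_participants = n_participants, n_days = n_days,
    construct = construct, seed = seed, ...))
}

# Adjusted Rand index, straight from the contingency-table formula; used as
# an independent oracle for cluster recovery.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Shuffle a construct's labels within each participant (breaks the
# feature-label link while preserving the pairing structure).
shuffle_labels <- function(d, construct, seed = 1) {
  withr::with_seed(seed, {
    for (pid in participants(d)) {
      rows <- which(d$data$participant_id == pid)
      d$data[[construct]][rows] <- sample(d$data[[construct]][rows])
    }
  })
  d
}
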