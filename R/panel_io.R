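#' Two-domain repeated-measures feature panel
#'
#' A `feature_panel` holds daily feature values for two device domains
#' (physical activity from a wrist accelerometer, gait from a lumbar
#' accelerometer) in long format, one row per subject-day. Rows are keyed by
#' `(subject, day)`; block membership of every feature column is known and
#' disjoint.
#'
#' @param data data.frame with columns `subject`, `day`, optionally
#'   `wear_hours`, and one column per feature.
#' @param pa_features character vector of physical-activity feature names.
#' @param gait_features character vector of gait feature names.
#' @param drop_incomplete drop rows with any missing feature value (with a
#'   message); missing values are otherwise an error.
#'
#' @return An object of class `feature_panel`: a list with elements `data`
#'   (rows sorted by subject then day), `pa_features`, `gait_features`,
#'   `has_wear` and the dimensions `n` (subjects), `N` (rows), `P`, `Q`.
#' @export
feature_panel <- function(data, pa_features, gait_features,
                          drop_incomplete = TRUE) {
  data <- as.data.frame(data)
  for (col in c("subject", "day")) {
    if (!col %in% names(data)) {
      mmj_stop(sprintf("required column '%s' is missing", col),
               "mmjive_input_error")
    }
  }
  feats <- c(pa_features, gait_features)
  if (length(pa_features) < 1L || length(gait_features) < 1L) {
    mmj_stop("each domain needs at least one feature",
             "mmjive_validation_error")
  }
  if (anyDuplicated(feats)) {
    mmj_stop("feature blocks overlap: block membership must be disjoint",
             "mmjive_validation_error")
  }
  missing_feats <- setdiff(feats, names(data))
  if (length(missing_feats)) {
    mmj_stop(sprintf("feature column(s) not in table: %s",
                     paste(missing_feats, collapse = ", ")),
             "mmjive_input_error")
  }
  data$subject <- as.character(data$subject)
  data$day <- as.integer(data$day)
  if (anyNA(data$day) || any(data$day < 1L)) {
    mmj_stop("'day' must be an integer >= 1", "mmjive_validation_error")
  }
  key <- paste(data$subject, data$day, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    mmj_stop(sprintf("duplicate (subject, day) pair: (%s)",
                     sub("\r", ", day ", dup)), "mmjive_validation_error")
  }
  vals <- as.matrix(data[, feats, drop = FALSE])
  if (!is.numeric(vals)) {
    mmj_stop("feature columns must be numeric", "mmjive_validation_error")
  }
  bad <- !is.finite(vals)
  if (any(bad)) {
    if (!drop_incomplete) {
      mmj_stop("non-finite feature values present and drop_incomplete=FALSE",
               "mmjive_validation_error")
    }
    keep <- rowSums(bad) == 0L
    message(sprintf("dropping %d row(s) with missing feature values",
                    sum(!keep)))
    data <- data[keep, , drop = FALSE]
    if (nrow(data) == 0L) {
      mmj_stop("no complete rows left after dropping missing values",
               "mmjive_validation_error")
    }
  }
  ord <- order(data$subject, data$day)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  keep_cols <- c("subject", "day",
                 intersect("wear_hours", names(data)), feats)
  data <- data[, keep_cols, drop = FALSE]
  structure(list(
    data = data,
    pa_features = pa_features,
    gait_features = gait_features,
    has_wear = "wear_hours" %in% names(data),
    n = length(unique(data$subject)),
    N = nrow(data),
    P = length(pa_features),
    Q = length(gait_features)
  ), class = "feature_panel")
}

#' @export
print.feature_panel <- function(x, ...) {
  cat(sprintf(
    "feature_panel: %d subjects, %d subject-days, P=%d PA + Q=%d gait features%s\n",
    x$n, x$N, x$P, x$Q,
    if (x$has_wear) " (wear_hours present)" else ""))
  invisible(x)
}

#' Feature matrix of a panel
#'
#' @param panel a `feature_panel`.
#' @param block `"all"`, `"pa"` or `"gait"`.
#' @return numeric matrix (rows = subject-days) of the requested block.
#' @export
panel_matrix <- function(panel, block = c("all", "pa", "gait")) {
  block <- match.arg(block)
  feats <- switch(block,
                  all = c(panel$pa_features, panel$gait_features),
                  pa = panel$pa_features,
                  gait = panel$gait_features)
  as.matrix(panel$data[, feats, drop = FALSE])
}

#' Read a two-domain feature panel from CSV
#'
#' The table must contain `subject` and `day` columns, optionally
#' `wear_hours`, and at least two feature columns, each of which must be
#' assigned to a domain by `domain_map`.
#'
#' @param path CSV file (header row, UTF-8).
#' @param domain_map either a data.frame with columns `feature` and `domain`
#'   (`"PA"` or `"gait"`), or the path to a two-column CSV of that shape.
#' @param quiet suppress the summary message.
#' @return a validated [feature_panel()].
#' @export
read_panel <- function(path, domain_map, quiet = FALSE) {
  if (!file.exists(path)) {
    mmj_stop(sprintf("input file not found: %s", path), "mmjive_input_error")
  }
  data <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is.character(domain_map) && length(domain_map) == 1L) {
    domain_map <- utils::read.csv(domain_map, stringsAsFactors = FALSE)
  }
  domain_map <- as.data.frame(domain_map)
  if (!all(c("feature", "domain") %in% names(domain_map))) {
    mmj_stop("domain_map needs columns 'feature' and 'domain'",
             "mmjive_input_error")
  }
  if (!all(domain_map$domain %in% c("PA", "gait"))) {
    mmj_stop("domain_map domains must be 'PA' or 'gait'",
             "mmjive_validation_error")
  }
  feat_cols <- setdiff(names(data), c("subject", "day", "wear_hours"))
  if (length(feat_cols) < 2L) {
    mmj_stop("need at least two feature columns", "mmjive_input_error")
  }
  unmapped <- setdiff(feat_cols, domain_map$feature)
  if (length(unmapped)) {
    mmj_stop(sprintf("feature(s) absent from domain_map: %s",
                     paste(unmapped, collapse = ", ")),
             "mmjive_validation_error")
  }
  dm <- domain_map[domain_map$feature %in% feat_cols, , drop = FALSE]
  pa <- feat_cols[feat_cols %in% dm$feature[dm$domain == "PA"]]
  gait <- feat_cols[feat_cols %in% dm$feature[dm$domain == "gait"]]
  panel <- feature_panel(data, pa_features = pa, gait_features = gait)
  if (!quiet) {
    message(sprintf("read %d subjects, %d rows, %d PA + %d gait features",
                    panel$n, panel$N, panel$P, panel$Q))
  }
  panel
}

#' Write a feature panel to CSV
#'
#' Deterministic writer (fixed column order, 12-significant-digit numbers),
#' the inverse of [read_panel()].
#'
#' @param panel a `feature_panel`.
#' @param path output CSV path.
#' @param domain_map_path optional path; if given, the feature/domain map is
#'   written there as a two-column CSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, domain_map_path = NULL) {
  write_table_csv(panel$data, path)
  if (!is.null(domain_map_path)) {
    dm <- data.frame(
      feature = c(panel$pa_features, panel$gait_features),
      domain = c(rep("PA", panel$P), rep("gait", panel$Q)),
      stringsAsFactors = FALSE)
    utils::write.csv(dm, domain_map_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Keep only valid wear days
#'
#' A valid day has at least `min_wear_hours` hours of wrist-device wear time
#' (default 10 h, the conventional compliance rule). Subjects left with no
#' valid day are dropped and reported.
#'
#' @param panel a `feature_panel` with a `wear_hours` column.
#' @param min_wear_hours threshold in hours; the rule is `>=`.
#' @return the filtered `feature_panel`, with attributes
#'   `valid_day_counts` (per-subject table) and `dropped_subjects`.
#' @export
filter_valid_days <- function(panel, min_wear_hours = 10) {
  if (!panel$has_wear) {
    mmj_stop(paste("panel has no 'wear_hours' column; skip the valid-day",
                   "filter for this input"), "mmjive_config_error")
  }
  keep <- panel$data$wear_hours >= min_wear_hours
  kept <- panel$data[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    mmj_stop("no rows satisfy the valid-day rule", "mmjive_validation_error")
  }
  dropped <- setdiff(unique(panel$data$subject), unique(kept$subject))
  out <- feature_panel(kept, panel$pa_features, panel$gait_features)
  counts <- as.data.frame(table(subject = kept$subject),
                          stringsAsFactors = FALSE)
  names(counts)[2L] <- "valid_days"
  attr(out, "valid_day_counts") <- counts
  attr(out, "dropped_subjects") <- dropped
  if (length(dropped)) {
    message(sprintf("dropped %d subject(s) with no valid day: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out
}

#' Center and scale panel features
#'
#' Column-wise z-scoring of all features. With `scope = "daily_rows"` the
#' mean and sample standard deviation are taken over all subject-days (the
#' multilevel-analysis convention). With `scope = "subject_means"` they are
#' taken over the per-subject day averages, so that the subject-means matrix
#' used by one-level analyses is exactly z-scored.
#'
#' @param panel a `feature_panel`.
#' @param scope `"daily_rows"` or `"subject_means"`.
#' @return a `scaled_panel`: the panel with transformed feature columns plus
#'   `column_means`, `column_sds` and `scaling_scope` for the inverse
#'   transform.
#' @export
scale_panel <- function(panel, scope = c("daily_rows", "subject_means")) {
  scope <- match.arg(scope)
  feats <- c(panel$pa_features, panel$gait_features)
  ref <- if (scope == "daily_rows") {
    panel_matrix(panel)
  } else {
    subject_means(panel)$values
  }
  mu <- colMeans(ref)
  sds <- apply(ref, 2L, stats::sd)
  zero <- which(sds < .Machine$double.eps^0.5)
  if (length(zero)) {
    mmj_stop(sprintf("zero-variance feature(s) in scaling scope: %s",
                     paste(feats[zero], collapse = ", ")),
             "mmjive_validation_error")
  }
  vals <- panel_matrix(panel)
  scaled <- sweep(sweep(vals, 2L, mu, `-`), 2L, sds, `/`)
  data <- panel$data
  data[, feats] <- scaled
  out <- feature_panel(data, panel$pa_features, panel$gait_features)
  out$column_means <- stats::setNames(mu, feats)
  out$column_sds <- stats::setNames(sds, feats)
  out$scaling_scope <- scope
  class(out) <- c("scaled_panel", "feature_panel")
  out
}

#' Invert panel scaling
#'
#' @param scaled a `scaled_panel` from [scale_panel()].
#' @return the `feature_panel` on the original scale.
#' @export
unscale_panel <- function(scaled) {
  if (!inherits(scaled, "scaled_panel")) {
    mmj_stop("not a scaled_panel", "mmjive_input_error")
  }
  feats <- names(scaled$column_means)
  vals <- as.matrix(scaled$data[, feats, drop = FALSE])
  orig <- sweep(sweep(vals, 2L, scaled$column_sds, `*`),
                2L, scaled$column_means, `+`)
  data <- scaled$data
  data[, feats] <- orig
  feature_panel(data, scaled$pa_features, scaled$gait_features)
}

#' Per-subject day averages
#'
#' One row per subject, the unweighted arithmetic mean over that subject's
#' days, for every feature — the input grain of the one-level analyses.
#'
#' @param panel a `feature_panel`.
#' @return a `subject_means_matrix`: list with `subject_ids`, `values`
#'   (n x (P+Q) matrix, feature-named columns), `pa_features`,
#'   `gait_features` and `n_days` per subject.
#' @export
subject_means <- function(panel) {
  vals <- panel_matrix(panel)
  g <- factor(panel$data$subject, levels = unique(panel$data$subject))
  sums <- rowsum(vals, g)
  nd <- as.vector(table(g))
  m <- sums / nd
  structure(list(
    subject_ids = levels(g),
    values = m,
    pa_features = panel$pa_features,
    gait_features = panel$gait_features,
    n_days = stats::setNames(nd, levels(g))
  ), class = "subject_means_matrix")
}

#' @export
print.subject_means_matrix <- function(x, ...) {
  cat(sprintf("subject_means_matrix: %d subjects x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# split a subject-means matrix (or any feature-named matrix) into blocks
block_split <- function(values, pa_features, gait_features) {
  list(x = values[, pa_features, drop = FALSE],
       y = values[, gait_features, drop = FALSE])
}

#' Canonical wearable feature names
#'
#' The 24 feature abbreviations (13 physical-activity, 11 gait) used in the
#' free-living wrist/lumbar accelerometry feature panels this package
#' targets; the synthetic generator uses them so reports look like real
#' ones.
#'
#' @return list with character vectors `pa` and `gait`.
#' @export
wearable_feature_names <- function() {
  list(
    pa = c("sedentary", "light", "moderate", "vigorous", "sleep_time",
           "sed_period", "light_period", "mod_period", "mean_SVMg",
           "perc95_SVMg", "max_6min", "max_15min", "max_60min"),
    gait = c("total_step_per_day", "total_bout_length", "gait_speed",
             "cadence", "stance", "swing", "stride_duration",
             "double_support", "single_limb_support", "stride_length",
             "gait_speed_95perc")
  )
}
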