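# Benchmark curation: unit harmonization, the six ordered filters with
# per-step accounting, log10 target transform, Tukey outlier removal,
# null-variance pruning, seeded 70-30 split with train-statistics
# normalization, and feature-target correlation ranking.

#' Load the uptake-unit harmonization map
#'
#' @param path YAML file with a `units` list of
#'   `canonical`/`relative`/`synonyms` entries (default: packaged map).
#' @return data.frame with columns `canonical`, `relative`, and list-column
#'   `synonyms`.
#' @export
load_unit_map <- function(path = extdata_path("config", "unit_map.yaml")) {
  y <- yaml::read_yaml(path)
  data.frame(canonical = vapply(y$units, `[[`, character(1), "canonical"),
             relative = vapply(y$units, `[[`, logical(1), "relative"),
             synonyms = I(lapply(y$units, function(u) as.character(u$synonyms))),
             stringsAsFactors = FALSE)
}

#' Standardize uptake-unit spellings
#'
#' Synonymous spellings collapse onto canonical labels; values are untouched.
#' Unmapped spellings are kept but reported in a `units_unknown` bucket.
#'
#' @param records a `cpp_records` table.
#' @param unit_map from [load_unit_map()].
#' @return list with `records` (harmonized `uptake_unit`, plus a logical
#'   `unit_relative` column) and `units_unknown` (data.frame of unmapped
#'   spellings and their counts).
#' @export
standardize_units <- function(records, unit_map = load_unit_map()) {
  lookup <- function(u) {
    l <- tolower(trimws(u))
    hit <- which(tolower(unit_map$canonical) == l |
                   vapply(unit_map$synonyms, function(s) l %in% tolower(s), logical(1)))
    if (length(hit)) hit[1] else NA_integer_
  }
  idx <- vapply(records$uptake_unit, lookup, integer(1))
  known <- !is.na(idx)
  records$uptake_unit[known] <- unit_map$canonical[idx[known]]
  records$unit_relative <- ifelse(known, unit_map$relative[idx], FALSE)
  unknown <- records$uptake_unit[!known]
  list(records = records,
       units_unknown = if (length(unknown))
         as.data.frame(table(spelling = unknown), stringsAsFactors = FALSE)
       else data.frame(spelling = character(0), Freq = integer(0)))
}

fluorescence_methods <- function() {
  c("flow cytometry", "fluorescence microscopy", "fluorescence spectroscopy",
    "FACS", "fluorimetry", "confocal microscopy (fluorescence)")
}

anomaly_fraction <- function(raw_seq, map) {
  toks <- tokenize_sequence(raw_seq)
  if (!length(toks)) return(1)
  mean(!toks %in% AA20)
}

sequence_unclear <- function(raw_seq, map) {
  toks <- tokenize_sequence(raw_seq)
  if (!length(toks)) return(TRUE)
  any(!toks %in% AA20 & !toks %in% map$token)
}

#' Apply the six benchmark-construction filters
#'
#' Ordered filters: (1) rows lacking concentration information or with
#' unclear sequences; (2) keep fluorescence-determined samples only;
#' (3) drop relative uptake units; (4) drop unusable (unparseable or
#' non-positive) concentrations; (5) drop anomaly-heavy or non-peptide
#' sequences (rule-based stand-in for a manual step: anomalous-token fraction
#' above `anomaly_frac_max`); (6) remove uptake outliers on the log10 scale
#' via [remove_outliers()].
#'
#' @param records unit-standardized `cpp_records` table (needs the
#'   `unit_relative` column from [standardize_units()]).
#' @param anomaly_map substitution map used to judge sequence clarity.
#' @param methods_keep method labels counted as fluorescence-based.
#' @param anomaly_frac_max maximum tolerated anomalous-token fraction.
#' @param outlier_rule passed to [remove_outliers()] (`multiplier`).
#' @return list with `records` (survivors, plus a `log10_uptake` column) and
#'   `report` (a `cpp_curation_report`).
#' @export
apply_benchmark_filters <- function(records, anomaly_map = load_anomaly_map(),
                                    methods_keep = fluorescence_methods(),
                                    anomaly_frac_max = 0.5,
                                    outlier_rule = list(multiplier = 1.5)) {
  steps <- c("concentration_or_sequence_missing", "fluorescence_only",
             "relative_units_excluded", "unusable_concentration",
             "anomalous_sequences_excluded", "uptake_outliers_removed")
  removed <- setNames(vector("list", length(steps)), steps)
  counts <- integer(length(steps))
  keep <- records

  drop_step <- function(df, bad) {
    list(kept = df[!bad, , drop = FALSE], ids = df$record_id[bad])
  }

  # 1: no concentration information at all, or sequence not interpretable
  no_conc <- is.na(keep$concentration_uM) &
    (is.na(keep$concentration_raw) | !nzchar(keep$concentration_raw))
  unclear <- vapply(keep$sequence, sequence_unclear, logical(1), map = anomaly_map)
  s <- drop_step(keep, no_conc | unclear)
  keep <- s$kept; removed[[1]] <- s$ids; counts[1] <- nrow(keep)

  # 2: fluorescence-determined samples only
  s <- drop_step(keep, !tolower(keep$method) %in% tolower(methods_keep))
  keep <- s$kept; removed[[2]] <- s$ids; counts[2] <- nrow(keep)

  # 3: relative uptake units cannot serve as absolute targets
  rel <- if ("unit_relative" %in% names(keep)) keep$unit_relative else
    rep(FALSE, nrow(keep))
  s <- drop_step(keep, rel)
  keep <- s$kept; removed[[3]] <- s$ids; counts[3] <- nrow(keep)

  # 4: unusable concentration values (unparseable string or non-positive)
  unusable <- is.na(keep$concentration_uM) | keep$concentration_uM <= 0
  s <- drop_step(keep, unusable)
  keep <- s$kept; removed[[4]] <- s$ids; counts[4] <- nrow(keep)

  # 5: anomaly-heavy sequences (rule-based stand-in for manual curation)
  frac <- vapply(keep$sequence, anomaly_fraction, numeric(1), map = anomaly_map)
  s <- drop_step(keep, frac > anomaly_frac_max)
  keep <- s$kept; removed[[5]] <- s$ids; counts[5] <- nrow(keep)

  # 6: log10 transform, then outlier fences
  transformable <- keep$uptake_value > 0 & !is.na(keep$uptake_value)
  log_target <- rep(NA_real_, nrow(keep))
  log_target[transformable] <- transform_target(keep$uptake_value[transformable])
  kept_idx <- which(transformable)
  out <- remove_outliers(log_target[kept_idx], rule = outlier_rule)
  final_idx <- kept_idx[out$kept]
  removed[[6]] <- keep$record_id[setdiff(seq_len(nrow(keep)), final_idx)]
  keep <- keep[final_idx, , drop = FALSE]
  keep$log10_uptake <- log_target[final_idx]
  counts[6] <- nrow(keep)

  report <- structure(list(step_names = steps, counts_after = counts,
                           removed_ids = removed, n_input = nrow(records),
                           outlier_bounds = out$bounds),
                      class = "cpp_curation_report")
  list(records = keep, report = report)
}

#' @export
print.cpp_curation_report <- function(x, ...) {
  cat("<cpp_curation_report> input rows:", x$n_input, "\n")
  for (i in seq_along(x$step_names))
    cat(sprintf("  %d. %-36s -> %d (removed %d)\n", i, x$step_names[i],
                x$counts_after[i], length(x$removed_ids[[i]])))
  invisible(x)
}

#' Export a curation report as a data.frame
#' @param report a `cpp_curation_report`.
#' @return data.frame of step, rows remaining, rows removed.
#' @export
curation_report_table <- function(report) {
  data.frame(step = report$step_names,
             rows_after = report$counts_after,
             rows_removed = vapply(report$removed_ids, length, integer(1)))
}

#' log10 transform of the uptake target
#'
#' @param uptake_value positive uptake value(s).
#' @return log10-transformed value(s).
#' @export
transform_target <- function(uptake_value) {
  if (any(is.na(uptake_value) | uptake_value <= 0))
    abort("uptake must be positive to log10-transform; exclude the row instead",
          "domain_error")
  log10(uptake_value)
}

#' Tukey-fence outlier removal
#'
#' Default rule: values outside `[Q1 - m*IQR, Q3 + m*IQR]` with `m = 1.5`,
#' applied to log10 targets. With fewer than 4 values quartiles are unstable
#' and the rule is a warned no-op; a zero IQR removes nothing.
#'
#' @param targets finite numeric values.
#' @param rule list with `multiplier`.
#' @return list with `kept` (index vector), `removed` (index vector), and
#'   `bounds` (the fences).
#' @export
remove_outliers <- function(targets, rule = list(multiplier = 1.5)) {
  if (any(!is.finite(targets))) abort("targets must be finite", "domain_error")
  n <- length(targets)
  if (n < 4) {
    if (n > 0) warning("fewer than 4 values; outlier rule skipped")
    return(list(kept = seq_len(n), removed = integer(0), bounds = c(-Inf, Inf)))
  }
  m <- rule$multiplier %||% 1.5
  q <- quantile(targets, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  bounds <- c(q[1] - m * iqr, q[2] + m * iqr)
  kept <- which(targets >= bounds[1] & targets <= bounds[2])
  list(kept = kept, removed = setdiff(seq_len(n), kept), bounds = bounds)
}

#' Remove null-variance features
#'
#' Drops columns constant over all rows; the removed-column list is retained
#' so prediction-time vectors can be pruned identically.
#'
#' @param fm a `cpp_feature_matrix`.
#' @return list with `fm` (pruned matrix) and `removed` (column names).
#' @export
remove_null_variance <- function(fm) {
  v <- apply(fm$values, 2, function(col) max(col) - min(col))
  null_cols <- colnames(fm$values)[v == 0]
  keep <- setdiff(colnames(fm$values), null_cols)
  pruned <- feature_matrix(fm$values[, keep, drop = FALSE], fm$schema,
                           fm$row_ids, fm$target, colnames_override = keep)
  list(fm = pruned, removed = null_cols)
}

#' Seeded 70-30 split with train-statistics normalization
#'
#' Train size is `floor(train_fraction * n)`. Columns are z-scored with the
#' train mean and standard deviation, applied to both subsets; zero-sd
#' columns pass through unscaled with a warning.
#'
#' @param fm a `cpp_feature_matrix` with at least 10 rows.
#' @param train_fraction train proportion (default 0.70).
#' @param seed mandatory RNG seed for the partition.
#' @return list with `train`, `test` (both `cpp_feature_matrix`), `stats`
#'   (data.frame of per-column mean/sd), and the index vectors.
#' @export
split_and_normalize <- function(fm, train_fraction = 0.7, seed) {
  n <- nrow(fm$values)
  if (n < 10) abort("need at least 10 rows to split", "domain_error")
  if (missing(seed)) abort("seed is mandatory for the split", "config_error")
  set.seed(seed)
  n_train <- floor(train_fraction * n)
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)

  mu <- colMeans(fm$values[train_idx, , drop = FALSE])
  sigma <- apply(fm$values[train_idx, , drop = FALSE], 2, sd)
  zero_sd <- sigma == 0 | is.na(sigma)
  if (any(zero_sd))
    warning(sprintf("%d zero-sd column(s) pass through unscaled", sum(zero_sd)))
  scale_block <- function(idx) {
    x <- fm$values[idx, , drop = FALSE]
    x2 <- sweep(x, 2, ifelse(zero_sd, 0, mu), "-")
    sweep(x2, 2, ifelse(zero_sd, 1, sigma), "/")
  }
  cols <- colnames(fm$values)
  mk <- function(idx) feature_matrix(scale_block(idx), fm$schema,
                                     fm$row_ids[idx],
                                     if (!is.null(fm$target)) fm$target[idx],
                                     colnames_override = cols)
  list(train = mk(train_idx), test = mk(test_idx),
       stats = data.frame(column = cols, mean = mu, sd = sigma,
                          scaled = !zero_sd, row.names = NULL),
       train_idx = train_idx, test_idx = test_idx)
}

#' Apply stored normalization statistics to a new matrix
#'
#' @param fm a `cpp_feature_matrix` whose columns match `stats$column`.
#' @param stats the `stats` element returned by [split_and_normalize()].
#' @return normalized `cpp_feature_matrix`.
#' @export
apply_normalization <- function(fm, stats) {
  if (!identical(colnames(fm$values), stats$column))
    abort("columns do not match the stored normalization statistics", "schema_error")
  x <- sweep(fm$values, 2, ifelse(stats$scaled, stats$mean, 0), "-")
  x <- sweep(x, 2, ifelse(stats$scaled, stats$sd, 1), "/")
  feature_matrix(x, fm$schema, fm$row_ids, fm$target,
                 colnames_override = colnames(fm$values))
}

#' Rank features by absolute Pearson correlation with the target
#'
#' @param fm a `cpp_feature_matrix` with a target.
#' @return data.frame of `feature`, `block`, `r`, `zero_variance`, sorted by
#'   `|r|` descending (zero-variance columns report `r = 0` and a flag).
#' @export
rank_feature_correlations <- function(fm) {
  if (is.null(fm$target)) abort("target required for correlation ranking", "domain_error")
  blocks <- schema_block_of(fm$schema)
  names(blocks) <- schema_colnames(fm$schema)
  sds <- apply(fm$values, 2, sd)
  zero <- sds == 0
  r <- numeric(ncol(fm$values))
  r[!zero] <- as.vector(cor(fm$values[, !zero, drop = FALSE], fm$target))
  out <- data.frame(feature = colnames(fm$values),
                    block = unname(blocks[colnames(fm$values)]),
                    r = r, zero_variance = zero, stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}
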