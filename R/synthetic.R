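# Synthetic CPP-like datasets with the statistical structure the pipeline
# assumes: Arg/Lys/Leu-enriched short peptides, up to two cargoes, cell lines
# with tissues, experimental conditions, and a planted linear signal on
# interpretable features (net charge, length, log-concentration, one genomics
# indicator, one cargo flag) plus Gaussian noise on the log10 uptake.

#' Default cell-line list for the generator
#' @return data.frame of `cell_line` and `tissue`.
#' @export
default_cell_lines <- function() {
  data.frame(
    cell_line = c("HeLa", "MCF7", "A549", "CHO", "CHO-K1", "HEK293T",
                  "HepG2", "Jurkat", "bEnd.3", "NIH3T3"),
    tissue = c("cervix", "breast", "lung", "ovary", "ovary", "kidney",
               "liver", "blood", "brain", "fibroblast"),
    stringsAsFactors = FALSE)
}

#' Generator specification
#'
#' Defaults emulate the benchmark's qualitative shape: lengths mostly 11-20
#' residues (range 4-100), Arg/Lys/Leu enriched and Met/Asp/Asn/Tyr depleted
#' residue usage, concentrations log-uniform on 0.1-100 uM, and stratified
#' dirty-row injection so every curation filter fires.
#'
#' @param n_records number of rows to generate.
#' @param unique_fraction fraction of rows carrying a distinct peptide; the
#'   remaining rows re-test already-drawn peptides under freshly sampled
#'   conditions, emulating benchmarks where the same CPP appears several
#'   times with different cargo/cell line/conditions.
#' @param seed RNG seed.
#' @param length_probs probabilities of the 4-10 / 11-20 / 21-30 / 31-100
#'   length strata.
#' @param residue_weights named sampling weights over the 20 residues.
#' @param anomaly_rate fraction of records given one anomalous token.
#' @param dirty_rates named fractions for the stratified dirty rows
#'   (`missing_concentration`, `non_fluorescence`, `relative_units`,
#'   `unparseable_concentration`, `anomaly_heavy`).
#' @param cell_lines data.frame of `cell_line`, `tissue`.
#' @param n_genes genomics panel width.
#' @param coefficients planted linear signal: named list with `intercept`,
#'   `net_charge`, `length`, `log_concentration`, `gene`, `cargo`,
#'   and the planted `gene_name` / `cargo_label`.
#' @param noise_sd Gaussian noise sd on the log10 target. The default is
#'   calibrated so the oracle r2 (signal variance over total variance) is
#'   0.85 under the default spec.
#' @return list of class `cpp_generator_spec`.
#' @export
generator_spec <- function(n_records = 1000L, unique_fraction = 0.51,
                           seed = 1L,
                           length_probs = c(0.25, 0.50, 0.21, 0.04),
                           residue_weights = NULL,
                           anomaly_rate = 0.08,
                           dirty_rates = c(missing_concentration = 0.04,
                                           non_fluorescence = 0.08,
                                           relative_units = 0.05,
                                           unparseable_concentration = 0.03,
                                           anomaly_heavy = 0.02),
                           cell_lines = default_cell_lines(),
                           n_genes = 735L,
                           coefficients = list(intercept = 2.0, net_charge = 0.12,
                                               length = 0.02, log_concentration = 0.50,
                                               gene = 0.80, cargo = 1.10,
                                               gene_name = "NRAS", cargo_label = "FITC"),
                           noise_sd = 0.3796) {
  if (is.null(residue_weights)) {
    residue_weights <- setNames(rep(1, 20), AA20)
    residue_weights[c("R", "K", "L")] <- c(3.0, 2.5, 2.0)
    residue_weights[c("M", "D", "N", "Y")] <- 0.4
  }
  stopifnot(n_records >= 1, noise_sd > 0, all(dirty_rates >= 0 & dirty_rates <= 1),
            anomaly_rate >= 0, anomaly_rate <= 1)
  stopifnot(unique_fraction > 0, unique_fraction <= 1)
  structure(list(n_records = as.integer(n_records),
                 unique_fraction = unique_fraction, seed = as.integer(seed),
                 length_probs = length_probs, residue_weights = residue_weights,
                 anomaly_rate = anomaly_rate, dirty_rates = dirty_rates,
                 cell_lines = cell_lines, n_genes = as.integer(n_genes),
                 coefficients = coefficients, noise_sd = noise_sd),
            class = "cpp_generator_spec")
}

sample_length <- function(n, probs) {
  stratum <- sample.int(4, n, replace = TRUE, prob = probs)
  lo <- c(4, 11, 21, 31)[stratum]
  hi <- c(10, 20, 30, 100)[stratum]
  lo + floor(runif(n) * (hi - lo + 1))
}

sample_sequence <- function(len, weights) {
  paste(sample(names(weights), len, replace = TRUE, prob = weights), collapse = "")
}

#' Generate a synthetic genomics table
#'
#' Random binary mutation matrix with per-gene mutation frequencies drawn
#' from (0, 0.3), one row per cell line, tissues attached.
#'
#' @param cell_lines data.frame of `cell_line`, `tissue`.
#' @param n_genes panel width (default 735).
#' @param seed RNG seed.
#' @return a `cpp_genomics_table`.
#' @export
generate_genomics_table <- function(cell_lines = default_cell_lines(),
                                    n_genes = 735L, seed = 1L) {
  set.seed(seed)
  genes <- default_gene_names(n_genes)
  freq <- runif(n_genes, 0.02, 0.28)
  m <- matrix(rbinom(nrow(cell_lines) * n_genes, 1,
                     rep(freq, each = nrow(cell_lines))),
              nrow = nrow(cell_lines),
              dimnames = list(vapply(cell_lines$cell_line, normalize_cell_line_name,
                                     character(1)), genes))
  genomics_table_from_matrix(m, cell_lines$tissue)
}

# genomics table for a spec, with the planted gene column pinned to a fixed
# balanced mutation pattern so the planted signal has stable variance
planted_genomics <- function(spec) {
  g <- generate_genomics_table(spec$cell_lines, spec$n_genes,
                               seed = derive_seed(spec$seed, 7))
  gene <- spec$coefficients$gene_name
  if (gene %in% colnames(g$matrix))
    g$matrix[, gene] <- rep_len(c(1, 0, 0), nrow(g$matrix))
  g
}

planted_signal <- function(seq_clean, len, conc, gene_ind, cargo_ind, co) {
  co$intercept +
    co$net_charge * vapply(seq_clean, net_charge, numeric(1), pH = 7) +
    co$length * len +
    co$log_concentration * log10(conc) +
    co$gene * gene_ind +
    co$cargo * cargo_ind
}

#' Generate a synthetic CPP dataset
#'
#' Clean records always survive the full curation pipeline; dirty rows are
#' injected at the configured rates on disjoint row sets (stratified, not
#' i.i.d.) so each filter has guaranteed test cases.
#'
#' @param spec a `cpp_generator_spec`.
#' @return list with `records` (a `cpp_records` table), `truth` (data.frame
#'   of per-record noiseless signal and realized target), `genomics` (the
#'   matched `cpp_genomics_table`), and `coefficients`.
#' @export
generate_dataset <- function(spec = generator_spec()) {
  set.seed(spec$seed)
  n <- spec$n_records
  genomics <- planted_genomics(spec)
  set.seed(derive_seed(spec$seed, 11))
  co <- spec$coefficients

  # distinct peptides, then record-level reuse under fresh conditions
  n_unique <- max(1L, round((spec$unique_fraction %||% 1) * n))
  len_u <- sample_length(n_unique, spec$length_probs)
  seqs_u <- vapply(len_u, sample_sequence, character(1),
                   weights = spec$residue_weights)

  # mild anomalies on clean peptides: one substitutable token, still accepted;
  # the planted signal is computed on the post-substitution sequence
  n_anom <- round(spec$anomaly_rate * n_unique)
  amap <- load_anomaly_map()
  obs_tokens <- amap$token[amap$observed]
  if (n_anom > 0) {
    rows <- sample.int(n_unique, n_anom)
    for (i in rows) {
      pos <- sample.int(len_u[i], 1)
      parts <- strsplit(seqs_u[i], "")[[1]]
      parts[pos] <- sample(obs_tokens, 1)
      seqs_u[i] <- paste(parts, collapse = "")
    }
  }
  clean_u <- vapply(seqs_u, function(s) substitute_anomalies(s, amap)$sequence,
                    character(1), USE.NAMES = FALSE)
  pep_idx <- sample(c(seq_len(n_unique),
                      if (n > n_unique) sample.int(n_unique, n - n_unique,
                                                   replace = TRUE)))
  len <- len_u[pep_idx]
  seqs <- seqs_u[pep_idx]
  clean_seqs <- clean_u[pep_idx]

  line_idx <- sample.int(nrow(spec$cell_lines), n, replace = TRUE)
  cell_line <- spec$cell_lines$cell_line[line_idx]
  tissue <- spec$cell_lines$tissue[line_idx]
  conc <- 10^runif(n, -1, 2)
  temp <- sample(c("37", "25", "4", "other", "unknown"), n, replace = TRUE,
                 prob = c(0.70, 0.12, 0.08, 0.02, 0.08))
  inc_avail <- runif(n) < 0.85
  inc_min <- ifelse(inc_avail, sample(c(15, 30, 60, 120, 240), n, replace = TRUE), NA)

  vocab <- load_cargo_vocab()
  cargo_w <- rep(1, nrow(vocab)); names(cargo_w) <- vocab$label
  cargo_w[co$cargo_label] <- 8
  cargo_w[c("fluorescein", "carboxyfluorescein", "rhodamine", "siRNA")] <- 4
  n_cargo <- sample(0:2, n, replace = TRUE, prob = c(0.15, 0.60, 0.25))
  cargoes <- lapply(seq_len(n), function(i)
    if (n_cargo[i] == 0) character(0)
    else sample(vocab$label, n_cargo[i], prob = cargo_w))

  norm_lines <- vapply(cell_line, normalize_cell_line_name, character(1))
  gene_ind <- genomics$matrix[norm_lines, co$gene_name]
  cargo_ind <- vapply(cargoes, function(cc) as.numeric(co$cargo_label %in% cc),
                      numeric(1))
  signal <- planted_signal(clean_seqs, len, conc, gene_ind, cargo_ind, co)
  y_log10 <- signal + rnorm(n, sd = spec$noise_sd)

  df <- data.frame(record_id = sprintf("rec%05d", seq_len(n)), sequence = seqs,
                   cell_line = cell_line, tissue = tissue,
                   concentration_uM = conc, concentration_raw = format(conc, digits = 6),
                   temperature_label = temp,
                   incubation_available = inc_avail, incubation_min = inc_min,
                   uptake_value = 10^y_log10, uptake_unit = "MFI",
                   method = "flow cytometry", stringsAsFactors = FALSE)
  df$cargoes <- cargoes

  # stratified dirty rows on disjoint index sets
  counts <- round(spec$dirty_rates * n)
  pool <- sample.int(n)
  take <- function(k) {
    k <- as.integer(k)
    if (k == 0L) return(integer(0))
    idx <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    idx
  }
  i1 <- take(counts["missing_concentration"])
  df$concentration_uM[i1] <- NA; df$concentration_raw[i1] <- ""
  i2 <- take(counts["non_fluorescence"])
  df$method[i2] <- sample(c("mass spectrometry", "HPLC", "radiolabeling"),
                          length(i2), replace = TRUE)
  i3 <- take(counts["relative_units"])
  df$uptake_unit[i3] <- sample(c("%", "fold change"), length(i3), replace = TRUE)
  i4 <- take(counts["unparseable_concentration"])
  df$concentration_uM[i4] <- NA; df$concentration_raw[i4] <- "n/a"
  i5 <- take(counts["anomaly_heavy"])
  df$sequence[i5] <- vapply(pmax(len[i5], 4), function(L)
    paste(sample(tolower(AA20), L, replace = TRUE), collapse = ""), character(1))

  truth <- data.frame(record_id = df$record_id, signal = signal,
                      log10_uptake = y_log10,
                      dirty = df$record_id %in% df$record_id[c(i1, i2, i3, i4, i5)],
                      stringsAsFactors = FALSE)
  list(records = as_cpp_records(df), truth = truth, genomics = genomics,
       coefficients = co)
}

#' Oracle r-squared of a generator specification
#'
#' Variance-ratio estimate `var(signal) / (var(signal) + noise_sd^2)` on a
#' large generated sample of the noiseless planted signal.
#'
#' @param spec a `cpp_generator_spec`.
#' @param n_eval sample size for the estimate.
#' @return r-squared in `[0, 1]`.
#' @export
oracle_r2 <- function(spec = generator_spec(), n_eval = 20000L) {
  set.seed(derive_seed(spec$seed, 99))
  co <- spec$coefficients
  len <- sample_length(n_eval, spec$length_probs)
  seqs <- vapply(len, sample_sequence, character(1), weights = spec$residue_weights)
  conc <- 10^runif(n_eval, -1, 2)
  # gene and cargo indicators at their generation-time marginal rates
  genomics <- planted_genomics(spec)
  gene_col <- genomics$matrix[, co$gene_name]
  gene_ind <- sample(gene_col, n_eval, replace = TRUE)
  vocab <- load_cargo_vocab()
  cargo_w <- rep(1, nrow(vocab)); names(cargo_w) <- vocab$label
  cargo_w[co$cargo_label] <- 8
  cargo_w[c("fluorescein", "carboxyfluorescein", "rhodamine", "siRNA")] <- 4
  n_cargo <- sample(0:2, n_eval, replace = TRUE, prob = c(0.15, 0.60, 0.25))
  cargo_ind <- vapply(seq_len(n_eval), function(i) {
    if (n_cargo[i] == 0) return(0)
    as.numeric(co$cargo_label %in% sample(vocab$label, n_cargo[i], prob = cargo_w))
  }, numeric(1))
  s <- planted_signal(seqs, len, conc, gene_ind, cargo_ind, co)
  v <- var(s)
  if (all(unlist(co[c("net_charge", "length", "log_concentration", "gene", "cargo")]) == 0))
    return(0)
  v / (v + spec$noise_sd^2)
}
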