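# Shared fixtures, all built in code.

make_record <- function(id = "r1", sequence = "GRKKRRQRRR", cargoes = list("FITC"),
                        cell_line = "HeLa", tissue = "cervix",
                        concentration_uM = 10, concentration_raw = "10",
                        temperature_label = "37",
                        incubation_available = TRUE, incubation_min = 60,
                        uptake_value = 1000, uptake_unit = "MFI",
                        method = "flow cytometry") {
  df <- data.frame(record_id = id, sequence = sequence, cell_line = cell_line,
                   tissue = tissue, concentration_uM = concentration_uM,
                   concentration_raw = concentration_raw,
                   temperature_label = temperature_label,
                   incubation_available = incubation_available,
                   incubation_min = incubation_min, uptake_value = uptake_value,
                   uptake_unit = uptake_unit, method = method,
                   stringsAsFactors = FALSE)
  df$cargoes <- cargoes
  as_cpp_records(df)
}

bind_records <- function(...) {
  as_cpp_records(do.call(rbind, lapply(list(...), as.data.frame)))
}

# 10-row dirty fixture whose per-step survivor trace is hand-derived:
# 2 missing-concentration, 3 non-fluorescence, 1 relative-unit,
# 1 unparseable-concentration, 1 anomaly-heavy, 2 clean
dirty_fixture <- function() {
  bind_records(
    make_record("clean1"),
    make_record("clean2", sequence = "KLALKLALKALKAALKLA", uptake_value = 500),
    make_record("noconc1", concentration_uM = NA, concentration_raw = ""),
    make_record("noconc2", concentration_uM = NA, concentration_raw = ""),
    make_record("nonfluo1", method = "mass spectrometry"),
    make_record("nonfluo2", method = "HPLC"),
    make_record("nonfluo3", method = "radiolabeling"),
    make_record("relunit", uptake_unit = "percent-of-control"),
    make_record("badconc", concentration_uM = NA, concentration_raw = "n/a"),
    make_record("anomheavy", sequence = "grkkrrqr"))
}

toy_genomics <- function(genes = c("NRAS", "IDH1", "TP53"),
                         lines = c("HELA", "MCF7", "A549"),
                         tissues = c("cervix", "breast", "lung"), seed = 4) {
  set.seed(seed)
  m <- matrix(rbinom(length(lines) * length(genes), 1, 0.4),
              nrow = length(lines), dimnames = list(lines, genes))
  cppuptake:::genomics_table_from_matrix(m, tissues)
}

random_sequences <- function(n, min_len = 4, max_len = 30, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(cppuptake:::AA20, sample(min_len:max_len, 1), replace = TRUE),
          collapse = ""), character(1))
}

# memoized study-scale benchmark shared by the heavier tests
.bench_cache <- new.env()
benchmark_split <- function(seed = 1, n_records = 1600) {
  key <- paste0("s", seed, "n", n_records)
  if (is.null(.bench_cache[[key]])) {
    gen <- generate_dataset(generator_spec(n_records = n_records, seed = seed))
    std <- standardize_units(gen$records)
    cur <- apply_benchmark_filters(std$records)
    fm <- suppressWarnings(assemble_features(cur$records, feature_schema(),
                                             gen$genomics,
                                             target = cur$records$log10_uptake))
    pr <- remove_null_variance(fm)
    sp <- suppressWarnings(split_and_normalize(pr$fm, seed = seed))
    .bench_cache[[key]] <- list(gen = gen, curated = cur$records, fm = fm,
                                pruned = pr$fm, split = sp)
  }
  .bench_cache[[key]]
}

# small planted-signal regression fixture for model tests
linear_fixture <- function(n = 240, p = 12, noise_sd = 0, seed = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- sprintf("f%02d", seq_len(p))
  beta <- seq(-1, 1, length.out = p)
  y <- as.numeric(x %*% beta) + rnorm(n, sd = noise_sd)
  schema <- feature_schema()
  fm <- feature_matrix(x, schema, sprintf("s%03d", seq_len(n)), target = y,
                       colnames_override = colnames(x))
  fm
}
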