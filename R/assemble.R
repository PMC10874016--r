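# Feature assembly: every record becomes one 2,908-column row (with default
# block sizes) by concatenating the whole-peptide descriptors, position
# one-hot, anomaly flags, genomics join, and experimental-condition encoders.

#' Featurize one record into a schema-ordered row
#'
#' @param record one-row slice of a `cpp_records` table.
#' @param schema a `cpp_feature_schema`.
#' @param genomics a `cpp_genomics_table`, or `NULL` for the degraded
#'   all-zeros genomics block.
#' @param anomaly_map substitution map (must match the schema's type columns).
#' @param cargo_vocab cargo vocabulary (must match the schema's cargo columns).
#' @param tissue_proxy tissue fallback config for [join_genomics()].
#' @return numeric vector of length [schema_ncol()].
#' @export
featurize_record <- function(record, schema, genomics = NULL,
                             anomaly_map = load_anomaly_map(),
                             cargo_vocab = load_cargo_vocab(),
                             tissue_proxy = list()) {
  sub <- substitute_anomalies(record$sequence, anomaly_map)
  gen <- if (is.null(genomics)) {
    c(numeric(length(schema$blocks$genomics)), 0)
  } else {
    join_genomics(record$cell_line, record$tissue, genomics,
                  tissue_proxy = tissue_proxy, quiet = TRUE)
  }
  cargoes <- record$cargoes[[1]]
  conc <- record$concentration_uM
  if (is.na(conc))
    abort(sprintf("record %s has no usable concentration", record$record_id),
          "validation_error")
  v <- c(compute_descriptors(sub$sequence),
         encode_positions(sub$sequence, schema$max_len),
         encode_anomalies(sub$annotation, anomaly_map,
                          length(schema$blocks$anomaly_position)),
         gen,
         conc,
         encode_temperature(record$temperature_label, schema$temperature_levels),
         encode_incubation(record$incubation_available, record$incubation_min),
         encode_cargo(cargoes, cargo_vocab))
  if (length(v) != schema_ncol(schema))
    abort("assembled row width does not match schema", "schema_error")
  unname(v)
}

#' Assemble the feature matrix for a record table
#'
#' @param records a `cpp_records` table (already curated: usable
#'   concentrations, sequences coverable by the anomaly map).
#' @param schema a `cpp_feature_schema`.
#' @param genomics optional `cpp_genomics_table`.
#' @param target optional numeric response vector (log10 uptake).
#' @inheritParams featurize_record
#' @return a `cpp_feature_matrix`.
#' @export
assemble_features <- function(records, schema = feature_schema(),
                              genomics = NULL, target = NULL,
                              anomaly_map = load_anomaly_map(),
                              cargo_vocab = load_cargo_vocab(),
                              tissue_proxy = list()) {
  n <- nrow(records)
  vals <- matrix(0, nrow = n, ncol = schema_ncol(schema))
  for (i in seq_len(n)) {
    vals[i, ] <- featurize_record(records[i, , drop = FALSE], schema, genomics,
                                  anomaly_map, cargo_vocab, tissue_proxy)
  }
  feature_matrix(vals, schema, records$record_id, target)
}
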