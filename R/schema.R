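# Feature schema: the ordered block layout of the assembled design matrix.
# Default block sizes: whole_peptide 31, position 2000, anomaly_position 24,
# anomaly_type 46, genomics 735, genomics_match 1, concentration 1,
# temperature 5, incubation 2, cargo 63 -- 2,908 columns in total.

#' Construct the feature schema
#'
#' @param max_len maximum peptide length for position one-hot encoding.
#' @param anomaly_map anomaly substitution map (see [load_anomaly_map()]);
#'   its observed substitution types define the anomaly-type columns.
#' @param max_anomaly_pos number of featurized anomaly positions.
#' @param gene_names character vector of genomics gene names.
#' @param temperature_levels closed temperature category set.
#' @param cargo_vocab cargo vocabulary (see [load_cargo_vocab()]).
#' @return object of class `cpp_feature_schema`: ordered named list of blocks,
#'   each a character vector of column names (already block-prefixed).
#' @export
feature_schema <- function(max_len = 100L,
                           anomaly_map = load_anomaly_map(),
                           max_anomaly_pos = 24L,
                           gene_names = default_gene_names(),
                           temperature_levels = c("4", "25", "37", "other", "unknown"),
                           cargo_vocab = load_cargo_vocab()) {
  obs_types <- anomaly_map$type[anomaly_map$observed]
  pos_cols <- as.vector(t(outer(seq_len(max_len), AA20,
                                function(i, a) sprintf("pos.%03d.%s", i, a))))
  blocks <- list(
    whole_peptide   = paste0("whole_peptide.", descriptor_names()),
    position        = pos_cols,
    anomaly_position = sprintf("anomaly.pos%02d", seq_len(max_anomaly_pos)),
    anomaly_type    = paste0("anomaly.type.", obs_types),
    genomics        = paste0("genomics.", gene_names),
    genomics_match  = "genomics.match",
    concentration   = "experimental.concentration_uM",
    temperature     = paste0("experimental.temperature.", temperature_levels),
    incubation      = c("experimental.incubation_available", "experimental.incubation_min"),
    cargo           = paste0("cargo.", cargo_vocab$label)
  )
  cols <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(cols))
    abort("feature schema column names must be unique across blocks", "schema_error")
  structure(list(blocks = blocks,
                 max_len = as.integer(max_len),
                 temperature_levels = temperature_levels),
            class = "cpp_feature_schema")
}

#' @export
print.cpp_feature_schema <- function(x, ...) {
  sizes <- vapply(x$blocks, length, integer(1))
  cat("<cpp_feature_schema> ", sum(sizes), " columns in ", length(sizes), " blocks\n", sep = "")
  for (b in names(sizes)) cat(sprintf("  %-17s %5d\n", b, sizes[[b]]))
  invisible(x)
}

#' Total column count of a schema
#' @param schema a `cpp_feature_schema`.
#' @return integer.
#' @export
schema_ncol <- function(schema) {
  length(unlist(schema$blocks, use.names = FALSE))
}

#' Column names of a schema in matrix order
#' @param schema a `cpp_feature_schema`.
#' @return character vector.
#' @export
schema_colnames <- function(schema) {
  unlist(schema$blocks, use.names = FALSE)
}

#' Block label for every column, in matrix order
#' @param schema a `cpp_feature_schema`.
#' @return character vector parallel to [schema_colnames()].
#' @export
schema_block_of <- function(schema) {
  rep(names(schema$blocks), vapply(schema$blocks, length, integer(1)))
}

# Branch routing for the forked net: the seven feature-block entry points.
forked_block_groups <- function() {
  list(experimental      = c("concentration", "temperature", "incubation"),
       cargo             = "cargo",
       sequence_anomalies = "anomaly_type",
       whole_peptide     = "whole_peptide",
       sequence_encoding = "position",
       genomics          = c("genomics", "genomics_match"),
       anomalous_position = "anomaly_position")
}

#' Construct a feature matrix container
#'
#' @param values numeric matrix, samples x features.
#' @param schema the `cpp_feature_schema` describing the columns.
#' @param row_ids record identifiers, one per row.
#' @param target optional numeric response (log10 uptake), one per row.
#' @param colnames_override internal: explicit column names when the matrix has
#'   been pruned relative to the schema.
#' @return object of class `cpp_feature_matrix`.
#' @export
feature_matrix <- function(values, schema, row_ids, target = NULL,
                           colnames_override = NULL) {
  cols <- colnames_override %||% schema_colnames(schema)
  if (ncol(values) != length(cols))
    abort(sprintf("matrix has %d columns, schema describes %d", ncol(values), length(cols)),
          "schema_error")
  if (nrow(values) != length(row_ids))
    abort("row_ids length must match row count", "schema_error")
  if (!is.null(target) && length(target) != nrow(values))
    abort("target length must match row count", "schema_error")
  if (nrow(values) > 0 && anyNA(values))
    abort("feature matrix must not contain missing values after assembly", "schema_error")
  colnames(values) <- cols
  rownames(values) <- row_ids
  structure(list(values = values, schema = schema, row_ids = row_ids, target = target),
            class = "cpp_feature_matrix")
}

#' @export
print.cpp_feature_matrix <- function(x, ...) {
  cat(sprintf("<cpp_feature_matrix> %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$target)) "" else " (+ target)"))
  invisible(x)
}

#' @export
dim.cpp_feature_matrix <- function(x) dim(x$values)
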