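# Dataset I/O: the raw CSV dialect, FASTA reading, feature-matrix export.
# Reading is lossless: uptake values/units and raw concentration strings are
# kept verbatim; all harmonization happens in the curation module.

#' Default column mapping for raw CPP dataset CSVs
#'
#' The distributed benchmark-style files do not fix header names; the mapping
#' is therefore config-driven. Each entry maps a logical field to the CSV
#' header that carries it.
#'
#' @return named list usable as the `dialect` argument of [read_cpp_dataset()].
#' @export
default_dialect <- function() {
  list(columns = list(
         record_id = "record_id", sequence = "sequence", cargoes = "cargoes",
         cell_line = "cell_line", tissue = "tissue",
         concentration = "concentration_uM", temperature = "temperature_C",
         incubation_min = "incubation_min", uptake_value = "uptake_value",
         uptake_unit = "uptake_unit", method = "method"),
       cargo_sep = ";",
       strict_concentration = TRUE)
}

#' Construct a peptide-record table
#'
#' @param df data.frame with the typed record columns.
#' @return data.frame of class `cpp_records` with a list-column `cargoes`.
#' @export
as_cpp_records <- function(df) {
  need <- c("record_id", "sequence", "cargoes", "cell_line", "tissue",
            "concentration_uM", "concentration_raw", "temperature_label",
            "incubation_available", "incubation_min", "uptake_value",
            "uptake_unit", "method")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("missing record columns: ", paste(miss, collapse = ", ")), "schema_error")
  if (!is.list(df$cargoes)) df$cargoes <- as.list(df$cargoes)
  nlab <- vapply(df$cargoes, length, integer(1))
  if (any(nlab > 2))
    abort("records allow at most two cargoes", "validation_error")
  if (any(df$incubation_available & is.na(df$incubation_min)))
    abort("incubation_min must be present when incubation_available", "validation_error")
  class(df) <- c("cpp_records", "data.frame")
  df
}

parse_temperature_label <- function(x, levels = c("4", "25", "37", "other", "unknown")) {
  x <- trimws(as.character(x))
  out <- ifelse(is.na(x) | x == "" | tolower(x) == "unknown", "unknown",
                ifelse(x %in% levels, x, "other"))
  # numeric spellings of the named temperatures collapse onto their category
  num <- suppressWarnings(as.numeric(x))
  hit <- !is.na(num) & as.character(num) %in% levels
  out[hit] <- as.character(num[hit])
  out
}

#' Read a raw CPP dataset CSV
#'
#' Rows that fail type coercion are returned in a reject list with reasons,
#' never silently dropped.
#'
#' @param path CSV file path.
#' @param dialect column mapping and options, see [default_dialect()].
#' @return list with `records` (a `cpp_records` table) and `rejects`
#'   (data.frame of `record_id`, `reason`).
#' @export
read_cpp_dataset <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) abort(paste0("cannot read ", path), "io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  cmap <- dialect$columns
  mandatory <- c("record_id", "sequence", "cell_line", "uptake_value", "uptake_unit", "method")
  for (f in mandatory) {
    if (!cmap[[f]] %in% names(raw))
      abort(sprintf("mandatory column '%s' (field %s) missing from %s", cmap[[f]], f, path),
            "schema_error")
  }
  n <- nrow(raw)
  get <- function(f) if (!is.null(cmap[[f]]) && cmap[[f]] %in% names(raw))
    raw[[cmap[[f]]]] else rep(NA_character_, n)

  conc_raw <- trimws(get("concentration"))
  conc <- suppressWarnings(as.numeric(conc_raw))
  inc_raw <- trimws(get("incubation_min"))
  inc <- parse_incubation_minutes(inc_raw)
  uptake <- suppressWarnings(as.numeric(get("uptake_value")))

  reason <- rep(NA_character_, n)
  unparseable_conc <- !is.na(conc_raw) & nzchar(conc_raw) & is.na(conc)
  if (isTRUE(dialect$strict_concentration))
    reason[unparseable_conc] <- "unparseable concentration"
  reason[is.na(uptake) & is.na(reason)] <- "unparseable uptake value"
  bad_conc <- !is.na(conc) & conc <= 0
  reason[bad_conc & is.na(reason)] <- "non-positive concentration"

  cargo_str <- get("cargoes")
  cargoes <- lapply(cargo_str, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character(0)
    else trimws(strsplit(s, dialect$cargo_sep %||% ";", fixed = TRUE)[[1]])
  })
  too_many <- vapply(cargoes, length, integer(1)) > 2
  reason[too_many & is.na(reason)] <- "more than two cargoes"

  df <- data.frame(record_id = get("record_id"), sequence = get("sequence"),
                   cell_line = get("cell_line"), tissue = get("tissue"),
                   concentration_uM = conc, concentration_raw = conc_raw,
                   temperature_label = parse_temperature_label(get("temperature")),
                   incubation_available = !is.na(inc), incubation_min = inc,
                   uptake_value = uptake, uptake_unit = get("uptake_unit"),
                   method = get("method"), stringsAsFactors = FALSE)
  df$cargoes <- cargoes
  keep <- is.na(reason)
  rejects <- data.frame(record_id = df$record_id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(records = as_cpp_records(df[keep, , drop = FALSE]), rejects = rejects)
}

# "60", "60 min", "1 h", "1.5h" -> minutes; NA when absent/unparseable
parse_incubation_minutes <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_real_, length(x))
  plain <- suppressWarnings(as.numeric(x))
  out[!is.na(plain)] <- plain[!is.na(plain)]
  hr <- grepl("^[0-9.]+\\s*h(our|r)?s?$", x)
  out[hr] <- suppressWarnings(as.numeric(sub("\\s*h.*$", "", x[hr]))) * 60
  mins <- grepl("^[0-9.]+\\s*min(ute)?s?$", x)
  out[mins] <- suppressWarnings(as.numeric(sub("\\s*min.*$", "", x[mins])))
  out[out < 0 & !is.na(out)] <- NA_real_
  out
}

#' Write a record table back to the raw CSV dialect
#'
#' Inverse of [read_cpp_dataset()] on all typed fields.
#'
#' @param records a `cpp_records` table.
#' @param path output CSV path.
#' @param dialect column mapping, see [default_dialect()].
#' @return `path`, invisibly.
#' @export
write_cpp_dataset <- function(records, path, dialect = default_dialect()) {
  cmap <- dialect$columns
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = records$record_id, b = records$sequence,
    c = vapply(records$cargoes, paste, character(1), collapse = dialect$cargo_sep %||% ";"),
    d = records$cell_line, e = records$tissue,
    f = ifelse(nzchar(records$concentration_raw) & !is.na(records$concentration_raw),
               records$concentration_raw, as.character(records$concentration_uM)),
    g = records$temperature_label,
    h = ifelse(records$incubation_available, as.character(records$incubation_min), ""),
    i = records$uptake_value, j = records$uptake_unit, k = records$method)
  names(out) <- unlist(cmap[c("record_id", "sequence", "cargoes", "cell_line", "tissue",
                              "concentration", "temperature", "incubation_min",
                              "uptake_value", "uptake_unit", "method")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read peptide sequences from FASTA
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id` and `sequence` (upper-cased, in file
#'   order).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read ", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">"))
    abort(sprintf("malformed FASTA header at line %d: record must start with '>'",
                  nonblank[1]), "parse_error")
  set <- Biostrings::readBStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(set)),
             sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a feature matrix to CSV
#'
#' Columns are block-prefixed; the first column holds row ids and, when
#' present, the target is written as a final `target` column. Round-trips
#' losslessly with [read_feature_matrix()].
#'
#' @param fm a `cpp_feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "cpp_feature_matrix"))
  dt <- data.table::as.data.table(fm$values)
  dt <- cbind(data.table::data.table(row_id = fm$row_ids), dt)
  if (!is.null(fm$target)) dt$target <- fm$target
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @param schema the schema the matrix was written under (column pruning is
#'   detected from the header).
#' @return a `cpp_feature_matrix`.
#' @export
read_feature_matrix <- function(path, schema) {
  dt <- data.table::fread(path, colClasses = list(character = "row_id"))
  has_target <- "target" %in% names(dt)
  target <- if (has_target) dt$target else NULL
  cols <- setdiff(names(dt), c("row_id", "target"))
  vals <- as.matrix(dt[, cols, with = FALSE])
  feature_matrix(vals, schema, dt$row_id, target,
                 colnames_override = if (identical(cols, schema_colnames(schema))) NULL else cols)
}
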