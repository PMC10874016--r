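# Cell-line genomics: GDSC-style gene-mutation indicators joined onto records
# by normalized cell-line name, with an exact-match flag and a tissue-proxy
# fallback.

#' Default placeholder gene list
#'
#' The curated mutation gene panel is not redistributable; this synthetic
#' 735-name stand-in keeps the full-width schema testable. Two real gene
#' symbols frequently discussed for uptake modeling (NRAS, IDH1) head the
#' list; the remainder are numbered placeholders.
#'
#' @param n_genes panel size.
#' @return character vector of gene names.
#' @export
default_gene_names <- function(n_genes = 735L) {
  named <- c("NRAS", "IDH1")
  c(named, sprintf("gene%04d", seq_len(n_genes - length(named))))
}

#' Normalize a cell-line name
#'
#' Case-folded and insensitive to hyphens, spaces, and dots, so spellings
#' like "CHO-K1" and "CHO K1" collapse to one key.
#'
#' @param name cell-line name.
#' @return normalized string.
#' @export
normalize_cell_line_name <- function(name) {
  if (length(name) == 0 || any(is.na(name)) || any(!nzchar(trimws(name))))
    abort("cell-line name must be non-empty", "validation_error")
  toupper(gsub("[-. ]", "", trimws(name)))
}

#' Load a genomics table from CSV
#'
#' @param path CSV with columns `cell_line`, `tissue`, then one 0/1 column per
#'   gene. Any recorded mutation value `> 0` is binarized to 1.
#' @param expected_genes required gene count (default 735, the GDSC-style
#'   panel width); a mismatch is an error unless `allow_other_width = TRUE`.
#' @param allow_other_width permit stand-in tables of other widths (warns).
#' @return object of class `cpp_genomics_table`: list with `cell_lines`
#'   (data.frame keyed by normalized name), `genes`, and a 0/1 `matrix`.
#' @export
load_genomics_table <- function(path, expected_genes = 735L, allow_other_width = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("cell_line", "tissue") %in% names(df)))
    abort("genomics table needs cell_line and tissue columns", "schema_error")
  genes <- setdiff(names(df), c("cell_line", "tissue"))
  if (length(genes) != expected_genes) {
    if (!allow_other_width)
      abort(sprintf("genomics table has %d gene columns, expected %d",
                    length(genes), expected_genes), "schema_error")
    warning(sprintf("genomics table width %d differs from the standard %d",
                    length(genes), expected_genes))
  }
  norm <- vapply(df$cell_line, normalize_cell_line_name, character(1))
  if (anyDuplicated(norm))
    abort("duplicate cell-line rows after name normalization", "schema_error")
  m <- as.matrix(df[, genes, drop = FALSE])
  m <- (m > 0) + 0
  rownames(m) <- norm
  structure(list(cell_lines = data.frame(name = df$cell_line, norm = norm,
                                         tissue = df$tissue, stringsAsFactors = FALSE),
                 genes = genes, matrix = m),
            class = "cpp_genomics_table")
}

genomics_table_from_matrix <- function(m, tissues) {
  structure(list(cell_lines = data.frame(name = rownames(m), norm = rownames(m),
                                         tissue = tissues, stringsAsFactors = FALSE),
                 genes = colnames(m), matrix = m),
            class = "cpp_genomics_table")
}

#' Join genomics features onto one record
#'
#' Exact-name hit returns that row with match flag 1. A miss with a known
#' tissue falls back to the configured (or alphabetically first) same-tissue
#' row with flag 0; a total miss yields all-zero indicators with flag 0 and
#' a warning.
#'
#' @param cell_line record cell-line label.
#' @param tissue optional record tissue label.
#' @param table a `cpp_genomics_table`.
#' @param tissue_proxy optional named list mapping tissue label to the proxy
#'   cell line to use on a miss.
#' @param quiet suppress the total-miss warning.
#' @return numeric vector of gene indicators plus final `match` flag
#'   (length `length(table$genes) + 1`).
#' @export
join_genomics <- function(cell_line, tissue = NA_character_, table,
                          tissue_proxy = list(), quiet = FALSE) {
  width <- length(table$genes)
  norm <- normalize_cell_line_name(cell_line)
  if (norm %in% rownames(table$matrix))
    return(c(table$matrix[norm, ], match = 1))
  if (!is.na(tissue) && nzchar(tissue)) {
    proxy <- tissue_proxy[[tissue]]
    if (is.null(proxy)) {
      cands <- sort(table$cell_lines$norm[table$cell_lines$tissue == tissue])
      proxy <- if (length(cands)) cands[1] else NULL
    } else proxy <- normalize_cell_line_name(proxy)
    if (!is.null(proxy) && proxy %in% rownames(table$matrix))
      return(c(table$matrix[proxy, ], match = 0))
  }
  if (!quiet)
    warning(sprintf("cell line '%s' not in genomics table and no tissue proxy; using zeros",
                    cell_line))
  c(setNames(numeric(width), table$genes), match = 0)
}
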