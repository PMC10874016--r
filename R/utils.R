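#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median predict quantile rbinom rnorm runif sd var setNames
#' @importFrom utils head read.csv write.csv packageVersion
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

abort <- function(msg, class, ...) {
  stop(structure(class = c(class, "cppuptake_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

extdata_path <- function(...) {
  p <- system.file("extdata", ..., package = "cppuptake")
  if (!nzchar(p)) abort(paste0("packaged data file not found: ",
                               paste(c(...), collapse = "/")), "io_error")
  p
}

#' Validate a peptide sequence against the 20 standard residues
#'
#' @param seq single character string of 1-letter codes.
#' @param allow_empty logical; error on "" unless TRUE.
#' @return invisibly, the sequence split into residues.
#' @keywords internal
check_standard_seq <- function(seq, allow_empty = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    abort("sequence must be a single character string", "validation_error")
  if (!nzchar(seq)) {
    if (allow_empty) return(invisible(character(0)))
    abort("sequence must be non-empty", "validation_error")
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% AA20)
  if (length(bad))
    abort(sprintf("non-standard residue '%s' at position %d", res[bad[1]], bad[1]),
          "validation_error")
  invisible(res)
}

# deterministic child seeds (kept < 2^31) derived from a user seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
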