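# Residue scale tables. Each single-component scale is a named numeric vector
# over the 20 standard amino acids; multi-component families (Kidera, Cruciani,
# Z-scales, MS-WHIM) are residue x component matrices. Values are transcriptions
# of the published tables shipped as plain CSV so users can audit or override.

.scale_cache <- new.env(parent = emptyenv())

scale_file <- c(
  mass            = "residue_mass_average.csv",
  kyte_doolittle  = "hydrophobicity_kyte_doolittle.csv",
  boman           = "boman_transfer.csv"
)

#' Load a packaged single-component residue scale
#'
#' @param name one of `"mass"`, `"kyte_doolittle"`, `"boman"`, or a path to a
#'   two-column CSV (`residue,value`) supplying a custom scale.
#' @return named numeric vector with one entry per standard amino acid.
#' @export
load_scale <- function(name) {
  key <- paste0("scale_", name)
  if (!is.null(.scale_cache[[key]])) return(.scale_cache[[key]])
  path <- if (name %in% names(scale_file)) {
    extdata_path("scales", scale_file[[name]])
  } else if (file.exists(name)) name else {
    abort(sprintf("unknown scale '%s'", name), "config_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  v <- setNames(as.numeric(df$value), df$residue)
  if (!all(AA20 %in% names(v)) || anyNA(v))
    abort(sprintf("scale '%s' must cover all 20 standard residues with finite values", name),
          "config_error")
  .scale_cache[[key]] <- v[AA20]
  .scale_cache[[key]]
}

#' Load a packaged multi-component residue scale set
#'
#' @param name one of `"kidera"` (10 components), `"cruciani"` (3),
#'   `"zscales"` (5), `"mswhim"` (3).
#' @return numeric matrix, residues in rows, components in columns.
#' @export
load_scale_set <- function(name) {
  key <- paste0("set_", name)
  if (!is.null(.scale_cache[[key]])) return(.scale_cache[[key]])
  files <- c(kidera = "kidera.csv", cruciani = "cruciani.csv",
             zscales = "zscales.csv", mswhim = "mswhim.csv")
  if (!name %in% names(files)) abort(sprintf("unknown scale set '%s'", name), "config_error")
  df <- read.csv(extdata_path("scales", files[[name]]), stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$residue
  if (!all(AA20 %in% rownames(m)) || anyNA(m))
    abort(sprintf("scale set '%s' incomplete", name), "config_error")
  .scale_cache[[key]] <- m[AA20, , drop = FALSE]
  .scale_cache[[key]]
}

#' Load a named pKa set for charge calculations
#'
#' Keys `nterm` and `cterm` hold the terminal pKa values; remaining keys are
#' the ionizable side chains (D, E, C, Y, H, K, R).
#'
#' @param name currently `"lehninger"`, or a path to a CSV (`group,value`).
#' @return named numeric vector of pKa values (pH units).
#' @export
load_pka_set <- function(name = "lehninger") {
  key <- paste0("pka_", name)
  if (!is.null(.scale_cache[[key]])) return(.scale_cache[[key]])
  path <- if (identical(name, "lehninger")) {
    extdata_path("scales", "pka_lehninger.csv")
  } else if (file.exists(name)) name else {
    abort(sprintf("unknown pKa set '%s'", name), "config_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  v <- setNames(as.numeric(df$value), df$group)
  need <- c("nterm", "cterm", "D", "E", "C", "Y", "H", "K", "R")
  if (!all(need %in% names(v)))
    abort("pKa set must define nterm, cterm and the 7 ionizable side chains", "config_error")
  .scale_cache[[key]] <- v
  v
}

# 20x20 dipeptide instability weights, first residue in rows
load_diwv <- function() {
  if (!is.null(.scale_cache$diwv)) return(.scale_cache$diwv)
  df <- read.csv(extdata_path("scales", "instability_diwv.csv"), stringsAsFactors = FALSE)
  m <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  m[cbind(df$first, df$second)] <- df$weight
  .scale_cache$diwv <- m
  m
}
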