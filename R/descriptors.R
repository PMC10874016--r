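# Whole-peptide physicochemical descriptors. The fixed 31-component roster is
# 10 scalar descriptors plus the Kidera (10), Cruciani (3), Z-scale (5) and
# MS-WHIM (3) family means; see the methods vignette for the rationale.

#' Molecular weight of a peptide
#'
#' Sum of average residue masses plus one water (peptide bonds release one
#' water per bond, leaving a single terminal water for the chain).
#'
#' @param seq amino-acid sequence (standard 1-letter codes).
#' @return molecular weight in Da.
#' @export
#' @examples
#' molecular_weight("AG") # 146.146
molecular_weight <- function(seq) {
  res <- check_standard_seq(seq)
  sum(load_scale("mass")[res]) + 18.0153
}

#' Net charge at a given pH
#'
#' Henderson--Hasselbalch sum over the N-terminus, C-terminus, and the
#' ionizable side chains (D, E, C, Y, H, K, R).
#'
#' @param seq amino-acid sequence.
#' @param pH pH in `[0, 14]`.
#' @param pka_set named pKa vector from [load_pka_set()].
#' @return net charge in elementary charge units.
#' @export
net_charge <- function(seq, pH = 7, pka_set = load_pka_set()) {
  res <- check_standard_seq(seq)
  if (!is.numeric(pH) || length(pH) != 1L || is.na(pH) || pH < 0 || pH > 14)
    abort("pH must be a single value in [0, 14]", "domain_error")
  pos_frac <- function(pka) 1 / (1 + 10^(pH - pka))   # protonated fraction
  neg_frac <- function(pka) 1 / (1 + 10^(pka - pH))   # deprotonated fraction
  q <- pos_frac(pka_set[["nterm"]]) - neg_frac(pka_set[["cterm"]])
  counts <- table(res)
  for (aa in c("K", "R", "H")) {
    n <- counts[aa]; if (!is.na(n)) q <- q + n * pos_frac(pka_set[[aa]])
  }
  for (aa in c("D", "E", "C", "Y")) {
    n <- counts[aa]; if (!is.na(n)) q <- q - n * neg_frac(pka_set[[aa]])
  }
  unname(q)
}

#' Isoelectric point
#'
#' pH at which the net charge vanishes, found by bisection on `[0, 14]`.
#'
#' @inheritParams net_charge
#' @param tol convergence tolerance on |net charge|.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka_set = load_pka_set(), tol = 1e-6) {
  check_standard_seq(seq)
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH; bisect until the charge vanishes
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka_set)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains:
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with X in mole percent.
#'
#' @param seq amino-acid sequence.
#' @return dimensionless index.
#' @export
aliphatic_index <- function(seq) {
  res <- check_standard_seq(seq)
  x <- 100 * c(A = mean(res == "A"), V = mean(res == "V"),
               I = mean(res == "I"), L = mean(res == "L"))
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' Instability index
#'
#' `(10 / L) * sum` of published dipeptide instability weights over consecutive
#' residue pairs.
#'
#' @param seq amino-acid sequence of length >= 2.
#' @param diwv optional 20x20 dipeptide weight matrix (first residue in rows).
#' @return dimensionless index.
#' @export
instability_index <- function(seq, diwv = load_diwv()) {
  res <- check_standard_seq(seq)
  n <- length(res)
  if (n < 2) abort("instability index requires length >= 2", "domain_error")
  (10 / n) * sum(diwv[cbind(res[-n], res[-1])])
}

#' Boman (protein-binding potential) index
#'
#' Mean per-residue solubility value; positive values indicate binding
#' potential.
#'
#' @param seq amino-acid sequence.
#' @param scale residue scale (defaults to the packaged transfer-energy scale,
#'   sign convention such that the index is the plain mean).
#' @return index in kcal/mol.
#' @export
boman_index <- function(seq, scale = load_scale("boman")) {
  res <- check_standard_seq(seq)
  mean(scale[res])
}

#' Mean hydrophobicity
#'
#' @param seq amino-acid sequence.
#' @param scale residue hydrophobicity scale (default Kyte--Doolittle).
#' @return arithmetic mean in scale units.
#' @export
hydrophobicity_mean <- function(seq, scale = load_scale("kyte_doolittle")) {
  res <- check_standard_seq(seq)
  mean(scale[res])
}

#' Hydrophobic moment
#'
#' Magnitude of the periodic projection of the hydrophobicity profile at a
#' given turn angle (100 degrees for an alpha helix, 160 for a beta strand),
#' normalized by sequence length.
#'
#' @param seq amino-acid sequence.
#' @param scale residue hydrophobicity scale.
#' @param angle_deg turn angle per residue in degrees, in (0, 360).
#' @return moment in scale units.
#' @export
hydrophobic_moment <- function(seq, scale = load_scale("kyte_doolittle"),
                               angle_deg = 100) {
  res <- check_standard_seq(seq)
  if (!(angle_deg > 0 && angle_deg < 360)) abort("angle must be in (0, 360)", "domain_error")
  h <- scale[res]
  delta <- angle_deg * pi / 180
  i <- seq_along(h) - 1
  sqrt(sum(h * sin(i * delta))^2 + sum(h * cos(i * delta))^2) / length(h)
}

#' Per-component means over the multi-component scale families
#'
#' @param seq amino-acid sequence.
#' @param set_names scale-set names in roster order.
#' @return named numeric vector (21 components for the default roster).
#' @export
scale_set_means <- function(seq, set_names = c("kidera", "cruciani", "zscales", "mswhim")) {
  res <- check_standard_seq(seq)
  out <- lapply(set_names, function(nm) {
    m <- load_scale_set(nm)
    v <- colMeans(m[res, , drop = FALSE])
    setNames(v, paste0(nm, ".", colnames(m)))
  })
  unlist(out)
}

descriptor_names <- function() {
  c("length", "molecular_weight", "net_charge", "pI", "aliphatic_index",
    "boman_index", "instability_index", "hydrophobicity_mean",
    "hydrophobic_moment_alpha", "hydrophobic_moment_beta",
    names(scale_set_means("A")))
}

#' Compute the 31-descriptor whole-peptide vector
#'
#' Fixed roster: length, molecular weight, net charge at pH 7, pI, aliphatic
#' index, Boman index, instability index, mean hydrophobicity, hydrophobic
#' moments at 100 and 160 degrees, then the Kidera (10), Cruciani (3),
#' Z-scale (5), and MS-WHIM (3) means. For length-1 sequences the instability
#' index is reported as 0 with a warning (the quantity is undefined below two
#' residues but batch assembly must not abort).
#'
#' @param seq validated amino-acid sequence (after anomaly substitution).
#' @return named numeric vector of length 31.
#' @export
compute_descriptors <- function(seq) {
  res <- check_standard_seq(seq)
  instab <- if (length(res) < 2) {
    warning("instability index undefined for length-1 sequence; reporting 0")
    0
  } else instability_index(seq)
  v <- c(length = length(res),
         molecular_weight = molecular_weight(seq),
         net_charge = net_charge(seq, 7),
         pI = isoelectric_point(seq),
         aliphatic_index = aliphatic_index(seq),
         boman_index = boman_index(seq),
         instability_index = instab,
         hydrophobicity_mean = hydrophobicity_mean(seq),
         hydrophobic_moment_alpha = hydrophobic_moment(seq, angle_deg = 100),
         hydrophobic_moment_beta = hydrophobic_moment(seq, angle_deg = 160),
         scale_set_means(seq))
  stopifnot(length(v) == 31L)
  v
}
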