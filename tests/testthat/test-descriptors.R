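test_that("molecular weight equals the residue-mass-sum oracle", {
  masses <- load_scale("mass")
  oracle <- function(s) sum(masses[strsplit(s, "")[[1]]]) + 18.0153
  expect_equal(molecular_weight("AG"), 146.146, tolerance = 0.01)
  for (s in random_sequences(25, seed = 11))
    expect_equal(molecular_weight(s), oracle(s), tolerance = 1e-9)
  # affine in repeat count
  k <- 1:5
  mw <- vapply(k, function(i) molecular_weight(strrep("A", i)), numeric(1))
  expect_equal(diff(mw), rep(masses[["A"]], 4))
  expect_error(molecular_weight(""), "non-empty")
  expect_error(molecular_weight("AXZ"), "non-standard residue")
})

test_that("net charge matches a brute-force Henderson-Hasselbalch oracle", {
  pka <- load_pka_set()
  oracle <- function(s, pH) {
    res <- strsplit(s, "")[[1]]
    q <- 1 / (1 + 10^(pH - pka[["nterm"]])) - 1 / (1 + 10^(pka[["cterm"]] - pH))
    for (r in res) {
      if (r %in% c("K", "R", "H")) q <- q + 1 / (1 + 10^(pH - pka[[r]]))
      if (r %in% c("D", "E", "C", "Y")) q <- q - 1 / (1 + 10^(pka[[r]] - pH))
    }
    q
  }
  expect_equal(net_charge("RRRR", 7), 4, tolerance = 0.05)
  expect_lt(abs(net_charge("A", 7)), 0.05)
  for (s in random_sequences(30, seed = 12))
    for (pH in c(2, 7, 11))
      expect_equal(net_charge(s, pH), oracle(s, pH), tolerance = 1e-9)
  expect_error(net_charge("AA", pH = 15), "pH")
})

test_that("net charge is non-increasing in pH", {
  phs <- seq(0, 14, by = 0.5)
  for (s in random_sequences(40, seed = 13)) {
    q <- vapply(phs, function(p) net_charge(s, p), numeric(1))
    expect_true(all(diff(q) <= 1e-12))
  }
})

test_that("isoelectric point zeroes the net charge", {
  for (s in random_sequences(40, seed = 14))
    expect_lt(abs(net_charge(s, isoelectric_point(s))), 1e-4)
  expect_gt(isoelectric_point("RRRR"), 11)
  expect_lt(isoelectric_point("DDDD"), 4)
})

test_that("aliphatic index closed forms hold", {
  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("VVVV"), 290)
  expect_equal(aliphatic_index("GGGG"), 0)
  expect_equal(aliphatic_index("AV"), 50 + 2.9 * 50)
})

test_that("instability index is the scaled dipeptide-weight sum", {
  diwv <- cppuptake:::load_diwv()
  expect_equal(instability_index("AG"), (10 / 2) * diwv["A", "G"])
  oracle <- function(s) {
    res <- strsplit(s, "")[[1]]
    (10 / length(res)) * sum(vapply(seq_len(length(res) - 1),
                                    function(i) diwv[res[i], res[i + 1]], numeric(1)))
  }
  expect_equal(instability_index("GRKW"), oracle("GRKW"), tolerance = 1e-9)
  for (s in random_sequences(10, seed = 15))
    expect_equal(instability_index(s), oracle(s), tolerance = 1e-9)
  expect_error(instability_index("A"), "length")
})

test_that("boman index is the mean residue solubility value", {
  sc <- load_scale("boman")
  expect_equal(boman_index("KKKK"), sc[["K"]])
  expect_equal(boman_index("GR"), boman_index("GRGR"))
  expect_equal(boman_index("GRK"), mean(sc[c("G", "R", "K")]))
})

test_that("mean hydrophobicity is bounded and permutation-invariant", {
  sc <- load_scale("kyte_doolittle")
  expect_equal(hydrophobicity_mean("IIII"), sc[["I"]])
  for (s in random_sequences(10, seed = 16)) {
    h <- hydrophobicity_mean(s)
    expect_gte(h, min(sc)); expect_lte(h, max(sc))
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(h, hydrophobicity_mean(rev_s))
  }
})

test_that("hydrophobic moment matches the direct trigonometric sum", {
  zero_scale <- setNames(rep(0, 20), cppuptake:::AA20)
  expect_equal(hydrophobic_moment("GRKW", scale = zero_scale), 0)
  sc <- load_scale("kyte_doolittle")
  oracle <- function(s, ang) {
    h <- sc[strsplit(s, "")[[1]]]
    d <- ang * pi / 180
    i <- seq_along(h) - 1
    sqrt(sum(h * sin(i * d))^2 + sum(h * cos(i * d))^2) / length(h)
  }
  expect_equal(hydrophobic_moment("GRKWL", angle_deg = 100),
               oracle("GRKWL", 100), tolerance = 1e-9)
  for (s in random_sequences(10, seed = 17)) {
    for (ang in c(100, 160)) {
      m <- hydrophobic_moment(s, angle_deg = ang)
      expect_equal(m, oracle(s, ang), tolerance = 1e-9)
      expect_lte(m, max(abs(sc)))
    }
  }
})

test_that("scale-set means cover 21 components and are permutation-invariant", {
  v <- scale_set_means("ACD")
  expect_length(v, 21)
  expect_equal(unname(scale_set_means("AAA")),
               unname(unlist(lapply(c("kidera", "cruciani", "zscales", "mswhim"),
                                    function(n) load_scale_set(n)["A", ]))))
  expect_equal(sort(unname(scale_set_means("KRW"))), sort(unname(scale_set_means("WKR"))))
})

test_that("the descriptor vector has 31 named finite components", {
  for (s in c("G", "GR", random_sequences(5, seed = 18))) {
    v <- if (nchar(s) < 2) suppressWarnings(compute_descriptors(s)) else compute_descriptors(s)
    expect_length(v, 31)
    expect_true(all(is.finite(v)))
  }
  expect_warning(compute_descriptors("G"), "instability")
  expect_identical(compute_descriptors("GRKKR"), compute_descriptors("GRKKR"))
})

test_that("descriptors are permutation-invariant except moments and instability", {
  s <- "GRKWLEDAYH"
  shuf <- "WGRKLEADHY"
  a <- compute_descriptors(s); b <- compute_descriptors(shuf)
  order_free <- setdiff(names(a), c("instability_index",
                                    "hydrophobic_moment_alpha",
                                    "hydrophobic_moment_beta"))
  expect_equal(a[order_free], b[order_free])
  expect_false(isTRUE(all.equal(a[["hydrophobic_moment_alpha"]],
                                b[["hydrophobic_moment_alpha"]])))
})
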