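test_that("unit spellings collapse onto canonical labels", {
  recs <- bind_records(make_record("u1", uptake_unit = "mean fluorescence intensity"),
                       make_record("u2", uptake_unit = "MFI"),
                       make_record("u3", uptake_unit = "%"),
                       make_record("u4", uptake_unit = "AU-ish"))
  out <- standardize_units(recs)
  expect_equal(out$records$uptake_unit[1:2], c("MFI", "MFI"))
  expect_equal(out$records$uptake_unit[3], "percent-of-control")
  expect_true(out$records$unit_relative[3])
  expect_equal(out$units_unknown$spelling, "AU-ish")
  # idempotence
  again <- standardize_units(out$records)
  expect_equal(again$records$uptake_unit, out$records$uptake_unit)
})

test_that("the six filters trace the hand-derived survivor counts", {
  recs <- standardize_units(dirty_fixture())$records
  cur <- apply_benchmark_filters(recs)
  expect_equal(cur$report$counts_after[1:5], c(8, 5, 4, 3, 2))
  expect_equal(nrow(cur$records), 2)
  expect_setequal(cur$records$record_id, c("clean1", "clean2"))
  # removed ids are disjoint across steps and conserve the input
  removed <- unlist(cur$report$removed_ids)
  expect_equal(anyDuplicated(removed), 0L)
  expect_setequal(c(removed, cur$records$record_id), recs$record_id)
})

test_that("all-clean and empty inputs pass through the filters unchanged", {
  clean <- standardize_units(bind_records(make_record("c1"), make_record("c2"),
                                          make_record("c3")))$records
  cur <- suppressWarnings(apply_benchmark_filters(clean))
  expect_equal(cur$report$counts_after, rep(3L, 6))
  empty <- clean[0, , drop = FALSE]
  cur0 <- apply_benchmark_filters(empty)
  expect_equal(cur0$report$counts_after, rep(0L, 6))
})

test_that("target transform is log10 on positive values only", {
  expect_equal(transform_target(1000), 3)
  expect_equal(transform_target(1), 0)
  expect_error(transform_target(0), "positive")
})

test_that("Tukey fences remove only extreme values", {
  targets <- c(seq(0, 1, by = 0.1), 100)
  out <- remove_outliers(targets)
  expect_equal(out$removed, 12L)
  expect_equal(out$kept, 1:11)
  expect_equal(remove_outliers(rep(2, 10))$removed, integer(0))
  expect_warning(out3 <- remove_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(out3$kept, 1:3)
  expect_error(remove_outliers(c(1, Inf)), "finite")
})

test_that("null-variance pruning is exact and idempotent", {
  schema <- feature_schema()
  v <- cbind(const = rep(1, 5), nearly = c(0, 0, 0, 0, 1e-9), vary = rnorm(5))
  fm <- feature_matrix(v, schema, paste0("r", 1:5), colnames_override = colnames(v))
  pr <- remove_null_variance(fm)
  expect_equal(pr$removed, "const")
  expect_equal(colnames(pr$fm$values), c("nearly", "vary"))
  pr2 <- remove_null_variance(pr$fm)
  expect_equal(pr2$removed, character(0))
})

test_that("split honors the floor convention and train-fitted normalization", {
  fm <- linear_fixture(n = 103)
  sp <- split_and_normalize(fm, seed = 5)
  expect_equal(nrow(sp$train$values), 72)  # floor(0.7 * 103)
  expect_equal(nrow(sp$test$values), 31)
  expect_true(all(abs(colMeans(sp$train$values)) < 1e-9))
  expect_true(all(abs(apply(sp$train$values, 2, sd) - 1) < 1e-9))
  # same seed -> identical partition; different seed -> different
  sp2 <- split_and_normalize(fm, seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_and_normalize(fm, seed = 6)
  expect_false(identical(sp$train_idx, sp3$train_idx))
  expect_error(split_and_normalize(linear_fixture(n = 5), seed = 1), "at least 10")
  expect_error(split_and_normalize(fm), "seed")
})

test_that("normalization inverts back to the original train values", {
  fm <- linear_fixture(n = 60)
  sp <- split_and_normalize(fm, seed = 7)
  recovered <- sweep(sweep(sp$train$values, 2, sp$stats$sd, "*"), 2,
                     sp$stats$mean, "+")
  expect_equal(unname(recovered), unname(fm$values[sp$train_idx, ]),
               tolerance = 1e-9)
  # stored stats reproduce the split's normalization on new data
  fm_test <- feature_matrix(fm$values[sp$test_idx, ], fm$schema,
                            fm$row_ids[sp$test_idx],
                            colnames_override = colnames(fm$values))
  renorm <- apply_normalization(fm_test, sp$stats)
  expect_equal(renorm$values, sp$test$values)
})

test_that("correlation ranking sorts by |r| and flags zero variance", {
  schema <- feature_schema()
  set.seed(8)
  y <- rnorm(200)
  v <- cbind(copy = y, noise = rnorm(200), flat = rep(1, 200))
  fm <- feature_matrix(v, schema, paste0("r", 1:200), target = y,
                       colnames_override = colnames(v))
  rk <- rank_feature_correlations(fm)
  expect_equal(nrow(rk), 3)
  expect_equal(rk$feature[1], "copy")
  expect_equal(rk$r[1], 1)
  expect_lt(abs(rk$r[rk$feature == "noise"]), 3 / sqrt(200))
  expect_true(rk$zero_variance[rk$feature == "flat"])
  expect_equal(rk$r[rk$feature == "flat"], 0)
})

test_that("curation accounting is conserved on random synthetic datasets", {
  for (s in 1:10) {
    gen <- generate_dataset(generator_spec(n_records = 40, seed = 300 + s))
    recs <- standardize_units(gen$records)$records
    cur <- suppressWarnings(apply_benchmark_filters(recs))
    expect_true(all(diff(c(nrow(recs), cur$report$counts_after)) <= 0))
    removed <- unlist(cur$report$removed_ids)
    expect_equal(anyDuplicated(removed), 0L)
    expect_setequal(c(removed, cur$records$record_id), recs$record_id)
  }
})
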