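test_that("forked forward pass honors shapes and zero-init analytics", {
  spec <- forked_net_spec(c(a = 4, b = 3), depth = 1, dropout = 0.5)
  blocks <- list(a = c(1, 0, 2, 1), b = c(0.5, -1, 3))
  out <- forked_forward(spec, blocks)
  expect_length(out, 1)
  expect_true(is.finite(out))
  # zero weights everywhere: output equals the (zero) output-layer bias
  expect_equal(forked_forward(spec, blocks, zero_init = TRUE), 0)
  # explicit bias on the final linear unit propagates through zero weights
  net <- cppuptake:::build_forked_net(list(a = 1:4, b = 5:7), c(a = 4, b = 3),
                                      depth = 1, zero = TRUE)
  net$trunk[[length(net$trunk)]]$b[1, 1] <- 0.7
  expect_equal(forked_forward(spec, blocks, net = net), 0.7)
  expect_error(forked_forward(spec, list(a = 1:5, b = 1:3), net = net), "width")
  expect_error(forked_forward(spec, list(zz = 1:2)), "no branch width")
})

test_that("forked parameter count matches the closed-form affine arithmetic", {
  spec <- forked_net_spec(c(a = 4, b = 3), depth = 2, dropout = 0.5)
  # branches: (2+1)*4 + (5+1)*3 = 30; concat 7 -> trunk 16 -> 16 -> 1
  # trunk: (7+1)*16 + (16+1)*16 + (16+1)*1 = 128 + 272 + 17 = 417
  expect_equal(forked_param_count(c(a = 2, b = 5), spec), 30 + 417)
  spec1 <- forked_net_spec(c(a = 2), depth = 1, dropout = 0.5)
  # branch (3+1)*2 = 8; trunk widths: max(16, floor(2/2)) = 16 -> (2+1)*16 + 17
  expect_equal(forked_param_count(c(a = 3), spec1), 8 + 48 + 17)
})

test_that("trunk widths halve geometrically with a floor of 16", {
  expect_equal(cppuptake:::trunk_widths(200, 4), c(100, 50, 25, 16))
  expect_equal(cppuptake:::trunk_widths(10, 2), c(16, 16))
})

test_that("the forked net trains with one branch per feature block group", {
  bench <- benchmark_split(1)
  # unpruned matrix keeps all seven block groups
  fm <- bench$fm
  sub <- feature_matrix(fm$values[1:60, ], fm$schema, fm$row_ids[1:60],
                        fm$target[1:60])
  cfg <- build_model("forked_net",
                     list(depth = 1, dropout = 0.3, use_dropout = FALSE,
                          learning_rate = 1e-3, epochs = 3,
                          experimental_layer_size = 6, cargo_layer_size = 8,
                          sequence_anomalies_layer_size = 6,
                          whole_peptide_layer_size = 8,
                          sequence_encoding_layer_size = 16,
                          genomics_layer_size = 16,
                          anomalous_position_layer_size = 4))
  f <- train_model(cfg, sub, seed = 5)
  expect_length(f$fit$net$branches, 7)
  expect_setequal(names(f$fit$net$branches), forked_branch_names())
  expect_length(f$fit$loss_curve, 3)
  # run-to-run reproducible with dropout disabled
  f2 <- train_model(cfg, sub, seed = 5)
  expect_identical(predict(f, sub), predict(f2, sub))
})

test_that("training reduces the loss on a planted linear signal", {
  fm <- linear_fixture(n = 200, noise_sd = 0.05)
  sp <- split_and_normalize(fm, seed = 15)
  dn <- train_model(build_model("deep_net",
                                list(depth = 1, layer_size = 32, epochs = 120,
                                     learning_rate = 1e-3, use_dropout = FALSE)),
                    sp$train, seed = 6)
  expect_lt(dn$loss_curve[length(dn$loss_curve)], dn$loss_curve[1])
  expect_gt(evaluate_model(dn, sp$train, "train")$r2, 0.8)

  bench <- benchmark_split(1)
  sub <- feature_matrix(bench$fm$values[1:80, ], bench$fm$schema,
                        bench$fm$row_ids[1:80], bench$fm$target[1:80])
  fk <- train_model(build_model("forked_net",
                                list(depth = 1, dropout = 0.3, use_dropout = FALSE,
                                     learning_rate = 1e-3, epochs = 10,
                                     sequence_encoding_layer_size = 16,
                                     genomics_layer_size = 16)),
                    sub, seed = 6)
  expect_lt(fk$loss_curve[10], fk$loss_curve[1])
})

test_that("deep net refits identically under a fixed seed", {
  fm <- linear_fixture(n = 100, noise_sd = 0.1)
  sp <- split_and_normalize(fm, seed = 16)
  cfg <- build_model("deep_net", list(depth = 1, layer_size = 16, epochs = 10,
                                      learning_rate = 1e-3, use_dropout = FALSE))
  a <- predict(train_model(cfg, sp$train, seed = 8), sp$test)
  b <- predict(train_model(cfg, sp$train, seed = 8), sp$test)
  expect_identical(a, b)
})

test_that("the binary remap restores indicator columns and nothing else", {
  x <- cbind(bin = c(rep(-0.2, 8), rep(4.8, 2)), cont = rnorm(10))
  map <- cppuptake:::fit_binary_remap(x)
  expect_equal(unname(map$cols), 1L)
  out <- cppuptake:::apply_binary_remap(map, x)
  expect_equal(sort(unique(out[, "bin"])), c(0, 1))
  expect_equal(out[, "cont"], x[, "cont"])
})
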