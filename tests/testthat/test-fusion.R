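test_that("min-max normalization follows the training-range formula", {
  b <- feature_block(matrix(c(2, 4, 6, 5, 5, 5), ncol = 2,
                            dimnames = list(c("a", "b", "c"), c("v", "const"))),
                     "raman")
  params <- minmax_fit(b)
  expect_equal(params$min, c(2, 5))
  expect_equal(params$max, c(6, 5))
  expect_equal(params$degenerate, c(FALSE, TRUE))
  scaled <- minmax_apply(b, params)
  expect_equal(unname(scaled$x[, 1]), c(0, 0.5, 1))
  expect_equal(unname(scaled$x[, 2]), c(0, 0, 0))  # degenerate rule
  expect_identical(scaled$scaling, "minmax")
  # validation values outside the training range are not clipped
  v <- feature_block(matrix(c(8, 5), ncol = 2,
                            dimnames = list("d", c("v", "const"))), "raman")
  expect_equal(unname(minmax_apply(v, params)$x[1, ]), c(1.5, 0))
  expect_error(minmax_fit(feature_block(matrix(1, 1, 1), "raman")), "two rows")
  wrong <- feature_block(matrix(0, 2, 2), "raman")
  expect_error(minmax_apply(wrong, params), "names")
})

test_that("applying fitted min-max parameters maps training columns onto [0, 1]", {
  set.seed(4)
  b <- feature_block(matrix(rnorm(60), 10, 6), "imaging")
  s <- minmax_apply(b, minmax_fit(b))
  expect_equal(unname(apply(s$x, 2, min)), rep(0, 6))
  expect_equal(unname(apply(s$x, 2, max)), rep(1, 6))
})

test_that("Pareto scaling divides centered columns by the root of their sd", {
  b <- feature_block(matrix(c(1, 2, 3), ncol = 1), "raman")
  p <- pareto_scale(b)
  expect_equal(unname(p$block$x[, 1]), c(-1, 0, 1))
  # the scaled column's variance equals the original column's sd
  set.seed(1)
  x <- matrix(rnorm(30, sd = 4), ncol = 1)
  ps <- pareto_scale(feature_block(x, "raman"))
  expect_equal(var(ps$block$x[, 1]), sd(x), tolerance = 1e-12)
  # zero-variance columns map to 0
  z <- pareto_scale(feature_block(matrix(c(7, 7), ncol = 1), "raman"))
  expect_equal(unname(z$block$x[, 1]), c(0, 0))
})

test_that("fusion concatenates Raman-first, records the boundary, and unfuses exactly", {
  set.seed(2)
  r <- feature_block(matrix(rnorm(63 * 274), 63,
                            dimnames = list(paste0("s", 1:63), NULL)), "raman")
  i <- feature_block(matrix(rnorm(63 * 120), 63,
                            dimnames = list(paste0("s", 1:63), NULL)), "imaging")
  rn <- minmax_apply(r, minmax_fit(r))
  im <- minmax_apply(i, minmax_fit(i))
  fused <- fuse_blocks(rn, im)
  expect_equal(dim(fused$x), c(63, 394))
  expect_equal(fused$boundary, 274)
  parts <- unfuse_blocks(fused)
  expect_identical(parts$raman$x, rn$x)
  expect_identical(parts$imaging$x, im$x)
  # errors: row mismatch, sample-order mismatch, un-normalized input
  expect_error(fuse_blocks(rn, block_rows_public(im, 1:60)), "rows")
  shuffled <- im
  shuffled$x <- im$x[c(2, 1, 3:63), ]
  expect_error(fuse_blocks(rn, shuffled), "order")
  expect_error(fuse_blocks(r, im), "normalized")
  # fusing with an empty block is the identity on the non-empty block
  empty <- feature_block(matrix(0, 63, 0,
                                dimnames = list(paste0("s", 1:63), NULL)),
                         "imaging", "minmax")
  expect_identical(fuse_blocks(rn, empty), rn)
})

test_that("scaling operators commute with row permutation", {
  set.seed(7)
  b <- feature_block(matrix(rnorm(50), 10, 5,
                            dimnames = list(paste0("s", 1:10), NULL)), "raman")
  perm <- sample(10)
  pb <- block_rows_public(b, perm)
  s_then_p <- minmax_apply(b, minmax_fit(b))$x[perm, ]
  p_then_s <- minmax_apply(pb, minmax_fit(pb))$x
  expect_equal(s_then_p, p_then_s, tolerance = 1e-12)
})
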