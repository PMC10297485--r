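test_that("one latent variable captures an exactly linear relation", {
  x <- matrix(1:4, ncol = 1)
  y <- 2 * (1:4)
  m <- fit_pls(x, y, ncomp = 1)
  expect_equal(as.vector(m$fitted), y, tolerance = 1e-10)
  met <- regression_metrics(y, m$fitted)
  expect_equal(met$r2, 1, tolerance = 1e-12)
})

test_that("with full-rank X and all components, PLS equals least squares", {
  set.seed(10)
  X <- matrix(rnorm(24), 8, 3)
  Y <- matrix(rnorm(16), 8, 2)
  m <- fit_pls(X, Y, ncomp = 3)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  B_ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_equal(unname(m$coefficients), unname(B_ols), tolerance = 1e-8)
})

test_that("rank-deficient X truncates the component sequence and records it", {
  set.seed(11)
  base <- matrix(rnorm(20), 10, 2)
  X <- cbind(base, base %*% matrix(c(1, 2, -1, 0.5), 2, 2))  # rank 2
  y <- rnorm(10)
  m <- fit_pls(X, y, ncomp = 5)
  expect_equal(m$ncomp, 2)
  expect_true(m$truncated)
  expect_equal(m$requested_ncomp, 5L)
})

test_that("prediction applies the stored centering deterministically", {
  set.seed(12)
  X <- matrix(rnorm(40), 10, 4)
  Y <- matrix(rnorm(20), 10, 2)
  m <- fit_pls(X, Y, ncomp = 2)
  expect_identical(predict(m, X), m$fitted)
  at_mean <- matrix(colMeans(X), nrow = 1)
  expect_equal(unname(predict(m, at_mean)), rbind(colMeans(Y)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(predict(m, X[, 1:3]), "columns")
})

test_that("successive X-scores are orthogonal and training R2 is monotone in A", {
  set.seed(13)
  X <- matrix(rnorm(120), 20, 6)
  y <- X %*% rnorm(6) + rnorm(20, sd = 0.5)
  m <- fit_pls(X, y, ncomp = 5)
  G <- crossprod(m$scores)
  expect_true(max(abs(G[upper.tri(G)])) < 1e-8 * max(diag(G)))
  r2 <- vapply(seq_len(m$ncomp), function(a) {
    pr <- predict(m, X, ncomp = a)
    1 - sum((y - pr)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("grouped cross-validation keeps groups intact and picks the minimum", {
  x <- matrix(seq(0.1, 3, length.out = 30) + 0, ncol = 1)
  y <- 2 * x[, 1]
  groups <- rep(1:10, each = 3)
  cv <- cross_validate(x, y, folds = 5, ncomp_max = 1, groups = groups)
  expect_lt(cv$rmsecv[1], 1e-8)
  expect_equal(cv$ncomp, 1)
  # rows of one group never straddle folds
  expect_true(all(tapply(cv$fold, groups, function(f) length(unique(f))) == 1))
  set.seed(14)
  X <- matrix(rnorm(200), 40, 5)
  yy <- X %*% rnorm(5) + rnorm(40)
  cv2 <- cross_validate(X, yy, folds = 4, ncomp_max = 5, seed = 3)
  expect_lte(cv2$ncomp, 5)
  expect_length(cv2$rmsecv, 5)
  expect_error(cross_validate(X, yy, folds = 50), "folds")
})

test_that("PLS-DA separates separable classes and fixes class order alphabetically", {
  X <- rbind(matrix(rnorm(20, mean = -3, sd = 0.3), 10, 2),
             matrix(rnorm(20, mean = 3, sd = 0.3), 10, 2))
  labels <- rep(c("zeta", "alpha"), each = 10)
  m <- fit_plsda(X, labels, ncomp = 1)
  expect_identical(m$classes, c("alpha", "zeta"))
  expect_identical(as.character(classify(m, X)), labels)
  # class order is invariant to input permutation
  perm <- sample(20)
  m2 <- fit_plsda(X[perm, ], labels[perm], ncomp = 1)
  expect_identical(m2$classes, m$classes)
  # the one-hot indicator construction: rows sum to one
  Y <- outer(labels, m$classes, "==") * 1
  expect_true(all(rowSums(Y) == 1))
  expect_error(fit_plsda(X, rep("one", 20), 1), "two distinct")
  expect_error(classify(fit_pls(X, rnorm(20), 1), X), "discriminant")
})

test_that("classification ties break toward the alphabetically first class", {
  # craft a degenerate response: both indicator predictions identical
  m <- structure(list(classes = c("a", "b"),
                      x_center = c(0, 0), x_scale = c(1, 1),
                      y_center = c(0.5, 0.5),
                      coefficients = matrix(0, 2, 2),
                      rotation = matrix(0, 2, 1),
                      y_loadings = matrix(0, 2, 1),
                      ncomp = 1L, method = "plsda"),
                 class = "pls_model")
  expect_identical(as.character(classify(m, matrix(0, 1, 2))), "a")
})
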