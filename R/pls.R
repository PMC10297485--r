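# NIPALS partial least squares regression and discriminant analysis with
# grouped cross-validation. X-only deflation with a Y-scores inner loop;
# the stored weights, scores and per-component explained Y-variance feed
# the VIP computation.

as_xy_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0(what, seq_len(ncol(x)))
  x
}

nipals_core <- function(X, Y, ncomp, x_center, x_scale, y_center,
                        tol = 1e-10, maxit = 500) {
  n <- nrow(X)
  p <- ncol(X)
  m <- ncol(Y)
  E <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  F0 <- sweep(Y, 2, y_center)
  norm0 <- sqrt(sum(E^2))
  if (norm0 == 0) stop("degenerate X: all variables constant")
  A <- min(ncomp, n - 1, p)
  W <- matrix(0, p, A, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, A, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, A, dimnames = list(rownames(X), NULL))
  Q <- matrix(0, m, A, dimnames = list(colnames(Y), NULL))
  ssy <- numeric(A)
  a <- 0
  while (a < A) {
    if (sqrt(sum(E^2)) < 1e-8 * norm0) break  # X residual exhausted: truncate
    u <- F0[, which.max(colSums(F0^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(E, u)
      wn <- sqrt(sum(w^2))
      if (wn == 0) break
      w <- w / wn
      tt <- as.vector(E %*% w)
      q <- as.vector(crossprod(F0, tt)) / sum(tt^2)
      u <- as.vector(F0 %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    if (wn == 0 || sum(tt^2) == 0) break
    a <- a + 1
    pa <- as.vector(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pa)
    W[, a] <- w
    P[, a] <- pa
    Tm[, a] <- tt
    Q[, a] <- q
    ssy[a] <- sum(tt^2) * sum(q^2)  # SS of Y explained by component a
  }
  if (a < 1) stop("no PLS component could be extracted")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  Q <- Q[, seq_len(a), drop = FALSE]
  ssy <- ssy[seq_len(a)]
  R <- W %*% solve(crossprod(P, W))  # X_c %*% R = T
  B <- R %*% t(Q)
  list(ncomp = a, weights = W, loadings = P, scores = Tm, y_loadings = Q,
       rotation = R, coefficients = B, ssy = ssy)
}

#' Fit a PLS regression model (NIPALS)
#'
#' Extracts up to `ncomp` latent components by the NIPALS algorithm with
#' X-only deflation. If the X residual is exhausted earlier (rank-deficient
#' X), the model truncates and records the achieved number of components.
#' Predictors are mean-centered (quantification blocks arrive already
#' min-max normalized); responses are mean-centered internally.
#'
#' @param X Predictor matrix (n x p).
#' @param Y Response matrix or vector (n x m), row-aligned with `X`.
#' @param ncomp Number of latent components requested (>= 1).
#' @param tol NIPALS inner-loop convergence tolerance.
#' @param maxit Maximum inner-loop iterations per component.
#' @return A list of class `pls_model`: `weights` (p x A), `loadings`,
#'   `scores`, `y_loadings`, `rotation`, `coefficients` (p x m), centers,
#'   scales, per-component explained Y-variance `ssy`, achieved and
#'   requested `ncomp`, `truncated` flag, training `fitted` values.
#' @export
fit_pls <- function(X, Y, ncomp, tol = 1e-10, maxit = 500) {
  X <- as_xy_matrix(X, "X")
  Y <- as_xy_matrix(Y, "Y")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 2) stop("at least two samples are required")
  if (ncomp < 1) stop("ncomp must be >= 1")
  x_center <- colMeans(X)
  x_scale <- rep(1, ncol(X))
  y_center <- colMeans(Y)
  fit <- nipals_core(X, Y, ncomp, x_center, x_scale, y_center, tol, maxit)
  model <- structure(
    c(fit, list(x_center = x_center, x_scale = x_scale, y_center = y_center,
                requested_ncomp = as.integer(ncomp),
                truncated = fit$ncomp < min(ncomp, nrow(X) - 1, ncol(X)),
                classes = NULL, method = "pls")),
    class = "pls_model")
  model$fitted <- predict(model, X)
  model
}

#' Fit a PLS-DA classification model
#'
#' The class labels are expanded into a one-hot indicator matrix (columns
#' in alphabetical class order) and regressed on Pareto-scaled predictors,
#' the scaling convention used for the saffron classification models.
#'
#' @param X Predictor matrix.
#' @param labels Class labels (character or factor), at least two distinct
#'   classes.
#' @param ncomp Number of latent components.
#' @inheritParams fit_pls
#' @return A `pls_model` with `method = "plsda"` and the alphabetical
#'   `classes` vector; predictions of the indicator columns drive
#'   [classify()].
#' @export
fit_plsda <- function(X, labels, ncomp, tol = 1e-10, maxit = 500) {
  X <- as_xy_matrix(X, "X")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("PLS-DA needs at least two distinct classes")
  Y <- outer(labels, classes, "==") * 1
  colnames(Y) <- classes
  x_center <- colMeans(X)
  s <- apply(X, 2, sd)
  x_scale <- sqrt(s)
  x_scale[s == 0] <- 1  # constant variables carry no information either way
  y_center <- colMeans(Y)
  fit <- nipals_core(X, Y, ncomp, x_center, x_scale, y_center, tol, maxit)
  model <- structure(
    c(fit, list(x_center = x_center, x_scale = x_scale, y_center = y_center,
                requested_ncomp = as.integer(ncomp),
                truncated = fit$ncomp < min(ncomp, nrow(X) - 1, ncol(X)),
                classes = classes, method = "plsda")),
    class = "pls_model")
  model$fitted <- predict(model, X)
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %s: %d component(s)%s, %d predictors, %d response(s)\n",
              x$method, x$ncomp,
              if (x$truncated) sprintf(" (truncated from %d)", x$requested_ncomp) else "",
              nrow(x$coefficients), ncol(x$coefficients)))
  invisible(x)
}

#' Predict responses from a fitted PLS model
#'
#' Applies the stored centering/scaling and regression coefficients:
#' `Yhat = (X - center)/scale %*% B + y_center`. Deterministic; a row equal
#' to the training column means predicts the training response means.
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with `p` columns.
#' @param ncomp Use only the first `ncomp` components (default: all fitted).
#' @param ... Unused.
#' @return Predicted response matrix.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_center))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$x_center))
  if (ncomp < 1 || ncomp > object$ncomp)
    stop("ncomp out of fitted range")
  B <- if (ncomp == object$ncomp) object$coefficients
       else object$rotation[, seq_len(ncomp), drop = FALSE] %*%
            t(object$y_loadings[, seq_len(ncomp), drop = FALSE])
  Xc <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  sweep(Xc %*% B, 2, object$y_center, "+")
}

#' Assign class labels from a PLS-DA model
#'
#' Argmax over the predicted indicator responses; exact ties go to the
#' alphabetically first class.
#'
#' @param model A `pls_model` fitted with [fit_plsda()].
#' @param newdata Predictor matrix.
#' @param ncomp Components to use (default: all fitted).
#' @return Factor of predicted classes with the model's class levels.
#' @export
classify <- function(model, newdata, ncomp = model$ncomp) {
  if (is.null(model$classes)) stop("model is not a discriminant (PLS-DA) model")
  resp <- predict(model, newdata, ncomp = ncomp)
  factor(model$classes[max.col(resp, ties.method = "first")],
         levels = model$classes)
}

#' Grouped K-fold cross-validation for PLS / PLS-DA
#'
#' Rows sharing a group id never straddle a fold boundary (e.g. the five
#' Raman spots of one replicate stay together), preventing leakage of
#' replicate structure into RMSECV. The RMSECV curve is computed per
#' component from the pooled out-of-fold residuals; the chosen component
#' count minimizes it (ties broken toward fewer components).
#'
#' @param X Predictor matrix.
#' @param Y Response matrix/vector, or class labels when
#'   `method = "plsda"`.
#' @param folds Number of folds (>= 2, <= number of groups).
#' @param ncomp_max Largest component count examined.
#' @param groups Optional group ids (length n); default: each row its own
#'   group.
#' @param seed Optional seed shuffling groups across folds; without it
#'   groups are dealt round-robin in sorted order.
#' @param method `"pls"` (regression) or `"plsda"` (indicator regression
#'   with Pareto scaling per fold).
#' @return A list of class `pls_cv`: `rmsecv` (per component), `ncomp`
#'   (argmin), `fold` (per-row fold id), `oof` (out-of-fold predictions,
#'   n x m x A array).
#' @export
cross_validate <- function(X, Y, folds = 7, ncomp_max = 10, groups = NULL,
                           seed = NULL, method = c("pls", "plsda")) {
  method <- match.arg(method)
  X <- as_xy_matrix(X, "X")
  n <- nrow(X)
  if (method == "plsda") {
    labels <- as.character(Y)
    classes <- sort(unique(labels))
    Ymat <- outer(labels, classes, "==") * 1
    colnames(Ymat) <- classes
  } else {
    Ymat <- as_xy_matrix(Y, "Y")
  }
  if (is.null(groups)) groups <- seq_len(n)
  groups <- as.character(groups)
  ug <- sort(unique(groups))
  if (folds < 2) stop("folds must be >= 2")
  if (folds > length(ug))
    stop("more folds than groups (", length(ug), " groups)")
  if (!is.null(seed)) {
    set.seed(seed)
    ug <- sample(ug)
  }
  fold_of_group <- rep_len(seq_len(folds), length(ug))
  names(fold_of_group) <- ug
  fold <- fold_of_group[groups]
  A_max <- ncomp_max
  oof <- NULL
  for (k in seq_len(folds)) {
    test <- which(fold == k)
    train <- which(fold != k)
    fit <- if (method == "plsda")
      fit_plsda(X[train, , drop = FALSE], labels[train], ncomp_max)
    else
      fit_pls(X[train, , drop = FALSE], Ymat[train, , drop = FALSE], ncomp_max)
    A_max <- min(A_max, fit$ncomp)
    if (is.null(oof))
      oof <- array(NA_real_, dim = c(n, ncol(Ymat), ncomp_max))
    for (a in seq_len(fit$ncomp)) {
      oof[test, , a] <- predict(fit, X[test, , drop = FALSE], ncomp = a)
    }
  }
  oof <- oof[, , seq_len(A_max), drop = FALSE]
  rmsecv <- vapply(seq_len(A_max), function(a) {
    sqrt(mean((Ymat - oof[, , a])^2))
  }, numeric(1))
  structure(list(rmsecv = rmsecv, ncomp = which.min(rmsecv),
                 fold = unname(fold), folds = folds, oof = oof,
                 method = method),
            class = "pls_cv")
}
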