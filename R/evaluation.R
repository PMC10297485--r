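# Misclassification tables, accuracy summaries, regression error metrics,
# and the stratified 210/105 train/validation split of the measurement
# design.

new_confusion_table <- function(counts) {
  members <- rowSums(counts)
  per_class <- ifelse(members > 0, 100 * diag(counts) / members, NA_real_)
  micro <- 100 * sum(diag(counts)) / sum(counts)
  macro <- mean(per_class[members > 0])
  structure(list(classes = rownames(counts), counts = counts,
                 members = members, per_class_pct = per_class,
                 micro_pct = micro, macro_pct = macro),
            class = "confusion_table")
}

#' Misclassification table with per-class, micro and macro correct rates
#'
#' Counts are tabulated true class (rows) by predicted class (columns).
#' Per-class correct rate is the diagonal count over the row's members; the
#' micro overall rate is total correct over total members; the macro
#' overall rate is the unweighted mean of the per-class rates. Both overall
#' conventions are reported because published misclassification tables mix
#' them.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Optional class list; labels outside it are an error.
#'   Defaults to the sorted union of observed labels.
#' @return A list of class `confusion_table`: `classes`, `counts`,
#'   `members`, `per_class_pct`, `micro_pct`, `macro_pct`.
#' @export
confusion_table <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop("labels outside the class list: ",
                        paste(bad, collapse = ", "))
  counts <- table(factor(truth, classes), factor(predicted, classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(classes, classes))
  new_confusion_table(counts)
}

#' Build a confusion table directly from a printed count matrix
#'
#' Useful for recomputing the summary rates of an already tabulated
#' misclassification table (rows = true classes, columns = predicted).
#'
#' @param counts Square count matrix with identical row and column names.
#' @return A `confusion_table`.
#' @export
confusion_table_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) ||
      !identical(rownames(counts), colnames(counts)))
    stop("counts must be square with matching row and column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  new_confusion_table(counts)
}

#' @export
print.confusion_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  cat("Misclassification table (true class x predicted class)\n")
  print(df)
  cat(sprintf("Overall: micro %.2f%%, macro %.2f%%\n",
              x$micro_pct, x$macro_pct))
  invisible(x)
}

#' @export
as.data.frame.confusion_table <- function(x, ...) {
  df <- data.frame(Members = x$members,
                   Correct_pct = round(x$per_class_pct, 2))
  cbind(df, as.data.frame.matrix(x$counts))
}

#' Rate of adulterated samples not predicted as pure
#'
#' The safety-critical summary of a screening table: the percentage of
#' truly adulterated samples that were *not* classified as pure saffron
#' (100% means no adulterated specimen slipped through as pure).
#'
#' @param table A [confusion_table()].
#' @param pure_class Name of the pure class (default `"pure"`).
#' @return A percentage in `[0, 100]`.
#' @export
adulterated_vs_pure_rate <- function(table, pure_class = "pure") {
  if (!pure_class %in% table$classes)
    stop("unknown pure class: ", pure_class)
  adult <- setdiff(table$classes, pure_class)
  missed <- sum(table$counts[adult, pure_class])
  total <- sum(table$members[adult])
  100 * (1 - missed / total)
}

#' Calibration, cross-validation and external prediction error metrics
#'
#' `RMSE = sqrt(mean((y - yhat)^2))` per prediction stream; `R2` is the
#' calibration (goodness-of-fit) coefficient `1 - SS_res/SS_tot` on the
#' training stream.
#'
#' @param y_train Observed training responses.
#' @param pred_train Fitted training predictions (RMSEC, R2).
#' @param pred_cv Optional cross-validated predictions of `y_train`
#'   (RMSECV).
#' @param y_external,pred_external Optional external validation pair
#'   (RMSEP); omitted when the external set is empty.
#' @return A list of class `regression_metrics` with `r2`, `rmsec`,
#'   `rmsecv`, `rmsep` (the latter two `NA` when not supplied).
#' @export
regression_metrics <- function(y_train, pred_train, pred_cv = NULL,
                               y_external = NULL, pred_external = NULL) {
  y_train <- as.numeric(y_train)
  pred_train <- as.numeric(pred_train)
  if (length(y_train) != length(pred_train))
    stop("y_train and pred_train must be aligned")
  if (var(y_train) == 0)
    stop("zero-variance observed response: R2 undefined")
  rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))
  r2 <- 1 - sum((y_train - pred_train)^2) / sum((y_train - mean(y_train))^2)
  rmsecv <- if (is.null(pred_cv)) NA_real_ else {
    if (length(pred_cv) != length(y_train))
      stop("pred_cv must align with y_train")
    rmse(y_train, as.numeric(pred_cv))
  }
  rmsep <- if (is.null(pred_external)) NA_real_ else {
    if (length(pred_external) != length(y_external))
      stop("external pair must be aligned")
    rmse(as.numeric(y_external), as.numeric(pred_external))
  }
  structure(list(r2 = r2, rmsec = rmse(y_train, pred_train),
                 rmsecv = rmsecv, rmsep = rmsep),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.3f, RMSEC = %.3f, RMSECV = %.3f, RMSEP = %.3f\n",
              x$r2, x$rmsec, x$rmsecv, x$rmsep))
  invisible(x)
}

#' Stratified train/validation split of the spectrum design
#'
#' Per class, whole (replicate, spot) groups are drawn into the training
#' partition so that every spectrum of a group stays on one side of the
#' split. Under the default design (15 groups per class, 5 spectra per
#' adulterant group, 1 per pure group) drawing 10 of 15 groups yields 50
#' training / 25 validation spectra per adulterant and 10/5 for pure
#' saffron: 210 training and 105 validation spectra in total.
#'
#' @param design The `spectra` data frame of a [generate_design()] result
#'   (or the design object itself).
#' @param seed Integer seed; the same seed always yields the same split.
#' @param train_groups Number of (replicate, spot) groups per class
#'   assigned to training (default 10 of the 15 in the standard design).
#' @return A list of class `design_split` with integer row indices `train`
#'   and `validation`.
#' @export
split_train_validation <- function(design, seed, train_groups = 10) {
  if (inherits(design, "saffron_design")) design <- design$spectra
  stopifnot(all(c("class", "replicate", "spot") %in% names(design)))
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(unique(design$class))) {
    rows <- which(design$class == cl)
    grp <- paste(design$replicate[rows], design$spot[rows], sep = "_")
    ug <- sort(unique(grp))
    if (length(ug) <= train_groups)
      stop("class ", cl, " has only ", length(ug),
           " (replicate, spot) groups; cannot fill the training quota")
    pick <- sample(ug, train_groups)
    train <- c(train, rows[grp %in% pick])
  }
  train <- sort(train)
  structure(list(train = train,
                 validation = setdiff(seq_len(nrow(design)), train),
                 seed = as.integer(seed)),
            class = "design_split")
}
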