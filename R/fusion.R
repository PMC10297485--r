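# Block preprocessing and mid-level fusion: min-max normalization fitted on
# training rows, Pareto scaling, and column-wise concatenation of the
# featured Raman and featured imaging blocks into X_fused.

#' Construct a feature block
#'
#' A sample-by-variable matrix tagged with its measurement block and
#' scaling state. Rows must carry sample ids (rownames) aligned to a shared
#' manifest; missing values are rejected.
#'
#' @param x Numeric matrix with column names (variables) and row names
#'   (sample ids).
#' @param block_id `"raman"`, `"imaging"` or `"fused"`.
#' @param scaling `"raw"`, `"minmax"` or `"pareto"`.
#' @return A list of class `feature_block` with fields `x`, `block_id`,
#'   `scaling`.
#' @export
feature_block <- function(x, block_id = c("raman", "imaging", "fused"),
                          scaling = c("raw", "minmax", "pareto")) {
  block_id <- match.arg(block_id)
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature block must not contain missing values")
  if (ncol(x) > 0 && is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  structure(list(x = x, block_id = block_id, scaling = scaling),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> %s: %d samples x %d variables (%s)\n",
              x$block_id, nrow(x$x), ncol(x$x), x$scaling))
  invisible(x)
}

#' @export
as.matrix.feature_block <- function(x, ...) x$x

#' @export
dim.feature_block <- function(x) dim(x$x)

block_rows <- function(block, idx) {
  out <- block
  out$x <- block$x[idx, , drop = FALSE]
  out
}

#' Fit per-variable min-max normalization parameters
#'
#' Column-wise minima and maxima over the (training) rows of a block.
#' Constant columns are flagged degenerate; [minmax_apply()] maps them to 0.
#'
#' @param block A [feature_block()] with at least two rows.
#' @return A data frame of class `minmax_params` with `variable`, `min`,
#'   `max`, `degenerate`.
#' @export
minmax_fit <- function(block) {
  x <- as.matrix(block)
  if (nrow(x) < 2) stop("min-max normalization needs at least two rows")
  mins <- unname(apply(x, 2, min))
  maxs <- unname(apply(x, 2, max))
  structure(data.frame(variable = colnames(x), min = mins, max = maxs,
                       degenerate = maxs == mins, row.names = NULL),
            class = c("minmax_params", "data.frame"))
}

#' Apply min-max normalization
#'
#' `x* = (x - min) / (max - min)` per variable, using training-set
#' parameters; values outside the training range are not clipped (a
#' validation value above the training max maps above 1). Degenerate
#' (constant) variables map to 0.
#'
#' @param block A [feature_block()] whose variables match `params` (same
#'   names, same order).
#' @param params A [minmax_fit()] result.
#' @return The normalized block (`scaling = "minmax"`).
#' @export
minmax_apply <- function(block, params) {
  x <- as.matrix(block)
  if (!identical(colnames(x), params$variable))
    stop("variable names of block and min-max parameters do not match")
  rng <- params$max - params$min
  rng[params$degenerate] <- 1
  out <- sweep(sweep(x, 2, params$min), 2, rng, "/")
  out[, params$degenerate] <- 0
  feature_block(out, block$block_id, "minmax")
}

#' Pareto scaling
#'
#' Per variable: `(x - mean) / sqrt(sd)`, with `sd` the sample standard
#' deviation -- intermediate between mean centering and unit-variance
#' scaling, chosen in chemometrics to damp noise without flattening strong
#' bands. Zero-variance variables map to 0.
#'
#' @param block A [feature_block()] with at least two rows.
#' @return List with the scaled `block` (`scaling = "pareto"`) and the
#'   `center` and `scale` vectors used.
#' @export
pareto_scale <- function(block) {
  x <- as.matrix(block)
  if (nrow(x) < 2) stop("Pareto scaling needs at least two rows")
  ctr <- colMeans(x)
  s <- apply(x, 2, sd)
  sc <- sqrt(s)
  deg <- s == 0
  sc[deg] <- 1
  out <- sweep(sweep(x, 2, ctr), 2, sc, "/")
  out[, deg] <- 0
  list(block = feature_block(out, block$block_id, "pareto"),
       center = ctr, scale = sc)
}

#' Fuse two normalized feature blocks (mid-level fusion)
#'
#' Column-wise concatenation, Raman variables first, with the block
#' boundary recorded so the fusion can be undone exactly. Both blocks must
#' be row-aligned (same sample ids in the same order) and already
#' normalized; fusing with an empty (zero-column) block returns the other
#' block unchanged.
#'
#' @param raman,imaging Normalized [feature_block()]s.
#' @return A `fused_block` (also a `feature_block`) with attributes
#'   `boundary` (number of Raman columns) and `provenance`.
#' @export
fuse_blocks <- function(raman, imaging) {
  if (ncol(raman$x) == 0) return(imaging)
  if (ncol(imaging$x) == 0) return(raman)
  if (nrow(raman$x) != nrow(imaging$x))
    stop("blocks have different numbers of rows")
  if (!identical(rownames(raman$x), rownames(imaging$x)))
    stop("blocks are not aligned to the same sample order")
  if (raman$scaling == "raw" || imaging$scaling == "raw")
    stop("blocks must be normalized before fusion")
  fused <- feature_block(cbind(raman$x, imaging$x), "fused", raman$scaling)
  fused$boundary <- ncol(raman$x)
  fused$provenance <- c(raman$block_id, imaging$block_id)
  class(fused) <- c("fused_block", class(fused))
  fused
}

#' Undo a fusion by slicing at the recorded block boundary
#'
#' @param fused A [fuse_blocks()] result.
#' @return List with the recovered `raman` and `imaging` blocks.
#' @export
unfuse_blocks <- function(fused) {
  if (!inherits(fused, "fused_block")) stop("not a fused block")
  b <- fused$boundary
  list(raman = feature_block(fused$x[, seq_len(b), drop = FALSE],
                             fused$provenance[1], fused$scaling),
       imaging = feature_block(fused$x[, -seq_len(b), drop = FALSE],
                               fused$provenance[2], fused$scaling))
}
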