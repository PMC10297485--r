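# Featured imaging extraction: composite the ambient/UV renderings, split
# RGB channels (red excluded), sample windowed statistics at midplane and
# ring points. Default scheme: 20 points x {green, blue} x {max, min, avg}
# = 120 variables per pattern.

#' Merge the ambient and UV renderings into one composite image
#'
#' Deterministic side-by-side merge: ambient on the left, UV on the right.
#'
#' @param ambient,uv RGB arrays (`h x w x 3`) with identical dimensions, or
#'   a single [simulate_tlc_image()] pattern passed as `ambient`.
#' @return An `h x 2w x 3` array.
#' @export
composite_image <- function(ambient, uv = NULL) {
  if (inherits(ambient, "tlc_pattern")) {
    uv <- ambient$uv
    ambient <- ambient$ambient
  }
  da <- dim(ambient)
  du <- dim(uv)
  if (length(da) != 3 || length(du) != 3 || !identical(da, du))
    stop("ambient and UV rasters must be RGB arrays of identical dimensions")
  out <- array(0, dim = c(da[1], da[2] + du[2], 3))
  out[, seq_len(da[2]), ] <- ambient
  out[, da[2] + seq_len(du[2]), ] <- uv
  out
}

#' Split an RGB image into its three channel rasters
#'
#' Lossless: recombining the channels reproduces the input. The red channel
#' carries too little pattern information on saffron TLC chips and is
#' flagged for exclusion downstream (`attr(, "excluded")`).
#'
#' @param image An `h x w x 3` array.
#' @return A named list of single-channel matrices `red`, `green`, `blue`
#'   with attribute `excluded = "red"`.
#' @export
split_channels <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("input must be a 3-channel RGB raster")
  structure(list(red = image[, , 1], green = image[, , 2], blue = image[, , 3]),
            excluded = "red")
}

#' Sampling coordinates for a TLC pattern
#'
#' Twenty points: 10 on the midplane circle (radius/2 from the center) and
#' 10 on the ring (mid-ring radius), each set equally spaced in angle
#' starting at angle 0, midplane points first. Coordinates are 0-based pixel
#' indices (`x` = column, `y` = row), rounded to the nearest pixel.
#'
#' @param geometry List with `size` (px), `center` (`c(x, y)`), `radius`
#'   (px) and `ring_width` (px).
#' @param n_midplane,n_ring Points per region.
#' @param window Window side length (px) that must fit inside the raster
#'   around every point; violations are an error.
#' @return Data frame with `region`, `index`, `x`, `y`.
#' @export
sample_points <- function(geometry, n_midplane = 10, n_ring = 10, window = 32) {
  if (geometry$radius <= 0) stop("pattern radius must be positive")
  ring_r <- geometry$radius - geometry$ring_width / 2
  one_region <- function(r, n, region) {
    theta <- 2 * pi * (seq_len(n) - 1) / n
    data.frame(region = region, index = seq_len(n),
               x = round(geometry$center[1] + r * cos(theta)),
               y = round(geometry$center[2] + r * sin(theta)))
  }
  pts <- rbind(one_region(geometry$radius / 2, n_midplane, "midplane"),
               one_region(ring_r, n_ring, "ring"))
  lo <- window_bounds(pts$x, window)
  hi <- lo + window - 1
  lo_y <- window_bounds(pts$y, window)
  hi_y <- lo_y + window - 1
  if (any(lo < 0) || any(lo_y < 0) ||
      any(hi > geometry$size - 1) || any(hi_y > geometry$size - 1))
    stop("sampling window falls outside the raster for this geometry")
  pts
}

# 0-based lower window edge; even windows biased toward the top-left
window_bounds <- function(coord, window) {
  coord - ceiling((window - 1) / 2)
}

#' Windowed channel statistics at a sampling point
#'
#' Maximum, minimum and average of all pixel values in a square window
#' centered on the point (even window sizes biased toward the top-left).
#'
#' @param raster Single-channel matrix (rows = y, columns = x).
#' @param x,y 0-based pixel coordinates of the window center.
#' @param window Window side length in pixels (default 32).
#' @return Named numeric vector `c(max, min, avg)`.
#' @export
window_stats <- function(raster, x, y, window = 32) {
  lx <- window_bounds(x, window)
  ly <- window_bounds(y, window)
  if (lx < 0 || ly < 0 ||
      lx + window > ncol(raster) || ly + window > nrow(raster))
    stop("window out of raster bounds")
  block <- raster[ly + seq_len(window), lx + seq_len(window)]
  c(max = max(block), min = min(block), avg = mean(block))
}

imaging_scheme_points <- function(geometry, n_midplane = 10, n_ring = 10,
                                  window = 32) {
  pts <- sample_points(geometry, n_midplane, n_ring, window)
  # distribute the scheme over the composite: the first half of each
  # region's points reads the ambient rendering, the second half the UV
  # rendering (shifted into the right half of the composite image)
  half_m <- n_midplane %/% 2
  half_r <- n_ring %/% 2
  pts$light <- "ambient"
  pts$light[pts$region == "midplane" & pts$index > half_m] <- "uv"
  pts$light[pts$region == "ring" & pts$index > half_r] <- "uv"
  pts$local_index <- ifelse(pts$region == "midplane",
                            (pts$index - 1) %% max(half_m, 1) + 1,
                            (pts$index - 1) %% max(half_r, 1) + 1)
  pts$x_composite <- pts$x + ifelse(pts$light == "uv", geometry$size, 0)
  pts
}

#' Extract the featured imaging vector from a TLC pattern
#'
#' Builds the ambient+UV composite, splits channels (red excluded), and
#' collects `(max, min, avg)` of a square window at each sampling point for
#' the green and blue channels. Feature order is fixed: light (ambient,
#' uv) > channel (green, blue) > region (midplane, ring) > point > statistic,
#' so the vector is the concatenation of the ambient block and the UV block.
#' Default scheme: 20 points x 2 channels x 3 statistics = 120 variables.
#'
#' @param pattern A [simulate_tlc_image()] result (or any list with
#'   `ambient`, `uv`, `geometry`).
#' @param window Window side length in pixels.
#' @param n_midplane,n_ring Sampling points per region (split evenly
#'   between the ambient and UV halves of the composite).
#' @return Named numeric vector of featured imaging variables.
#' @export
extract_imaging_features <- function(pattern, window = 32,
                                     n_midplane = 10, n_ring = 10) {
  comp <- composite_image(pattern$ambient, pattern$uv)
  chans <- split_channels(comp)
  keep <- setdiff(names(chans), attr(chans, "excluded"))
  pts <- imaging_scheme_points(pattern$geometry, n_midplane, n_ring, window)
  out <- numeric(0)
  nm <- character(0)
  for (light in c("ambient", "uv")) {
    for (channel in keep) {
      for (region in c("midplane", "ring")) {
        sel <- pts[pts$light == light & pts$region == region, , drop = FALSE]
        for (k in seq_len(nrow(sel))) {
          st <- window_stats(chans[[channel]], sel$x_composite[k], sel$y[k],
                             window)
          out <- c(out, st)
          nm <- c(nm, sprintf("%s_%s_%s_p%d_%s", light, channel, region,
                              sel$local_index[k], names(st)))
        }
      }
    }
  }
  names(out) <- nm
  out
}

#' Featured imaging matrix for a list of patterns
#'
#' @param patterns Named list of TLC patterns (e.g. `simulate_dataset()$patterns`).
#' @inheritParams extract_imaging_features
#' @return Matrix, one row per pattern.
#' @export
imaging_feature_matrix <- function(patterns, window = 32,
                                   n_midplane = 10, n_ring = 10) {
  rows <- lapply(patterns, extract_imaging_features, window = window,
                 n_midplane = n_midplane, n_ring = n_ring)
  do.call(rbind, rows)
}
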