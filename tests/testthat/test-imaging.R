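test_that("composite merge is a deterministic side-by-side concatenation", {
  a <- array(runif(100 * 100 * 3), c(100, 100, 3))
  b <- array(runif(100 * 100 * 3), c(100, 100, 3))
  comp <- composite_image(a, b)
  expect_equal(dim(comp), c(100, 200, 3))
  expect_identical(comp[, 1:100, ], a)
  expect_identical(comp[, 101:200, ], b)
  # merging an image with itself: halves identical
  self <- composite_image(a, a)
  expect_identical(self[, 1:100, ], self[, 101:200, ])
  expect_error(composite_image(a, array(0, c(50, 100, 3))), "identical dimensions")
})

test_that("channel splitting is lossless and excludes red downstream", {
  img <- array(0, c(8, 8, 3))
  img[, , 2] <- 255
  ch <- split_channels(img)
  expect_true(all(ch$green == 255) && all(ch$red == 0) && all(ch$blue == 0))
  expect_identical(attr(ch, "excluded"), "red")
  img2 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  ch2 <- split_channels(img2)
  rebuilt <- array(0, c(8, 8, 3))
  rebuilt[, , 1] <- ch2$red; rebuilt[, , 2] <- ch2$green; rebuilt[, , 3] <- ch2$blue
  expect_identical(rebuilt, img2)
  expect_error(split_channels(matrix(0, 8, 8)), "3-channel")
})

test_that("sampling points sit on the midplane and ring circles, deterministically", {
  geom <- list(size = 128, center = c(64, 64), radius = 40, ring_width = 6)
  pts <- sample_points(geom)
  expect_equal(nrow(pts), 20)
  expect_equal(sum(pts$region == "midplane"), 10)
  mid <- pts[pts$region == "midplane", ]
  d <- sqrt((mid$x - 64)^2 + (mid$y - 64)^2)
  expect_true(all(abs(d - 20) <= 0.5 + 1e-9))  # radius/2, up to pixel rounding
  expect_equal(anyDuplicated(pts[, c("x", "y")]), 0)
  expect_identical(pts, sample_points(geom))
  # a window that cannot fit inside the raster is an error
  expect_error(sample_points(list(size = 60, center = c(30, 30), radius = 28,
                                  ring_width = 4)), "outside")
})

test_that("window statistics cover constant, mixed and toy windows", {
  expect_equal(window_stats(matrix(77, 64, 64), 31, 31),
               c(max = 77, min = 77, avg = 77))
  # half 0 / half 255
  m <- rbind(matrix(0, 16, 32), matrix(255, 16, 32))
  expect_equal(window_stats(m, 16, 16),
               c(max = 255, min = 0, avg = 127.5))
  # 2x2 toy raster with the window size overridden
  toy <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] by row
  expect_equal(window_stats(toy, 1, 1, window = 2),
               c(max = 4, min = 1, avg = 2.5))
  expect_error(window_stats(toy, 1, 1, window = 32), "bounds")
  expect_true(all(diff(window_stats(matrix(runif(64^2), 64, 64), 30, 30)
                       [c("min", "avg", "max")]) >= 0))
})

test_that("the featured imaging vector has the fixed 120-variable layout", {
  cfg <- generator_config(seed = 3)
  pat <- simulate_tlc_image(sample_label("safflower", 40), cfg)
  v <- extract_imaging_features(pat)
  expect_length(v, 120)
  expect_equal(anyDuplicated(names(v)), 0)
  # ambient block first, then UV; green before blue within each light
  expect_match(names(v)[1], "^ambient_green_midplane_p1_max$")
  expect_equal(sum(grepl("^ambient_", names(v))), 60)
  expect_equal(sum(grepl("_green_", names(v))), 60)
  expect_false(any(grepl("_red_", names(v))))
  # a uniform pattern: max = min = avg at every point
  u <- extract_imaging_features(uniform_pattern(123))
  expect_true(all(u == 123))
})

test_that("features respond additively to a constant channel shift", {
  cfg <- generator_config(seed = 5)
  pat <- simulate_tlc_image(sample_label("turmeric", 60), cfg)
  v0 <- extract_imaging_features(pat)
  shifted <- pat
  shifted$ambient[, , 3] <- shifted$ambient[, , 3] + 11  # ambient blue
  v1 <- extract_imaging_features(shifted)
  blue_amb <- grepl("^ambient_blue_", names(v0))
  expect_equal(v1[blue_amb], v0[blue_amb] + 11)
  expect_equal(v1[!blue_amb], v0[!blue_amb])
})

test_that("per-pattern vectors do not depend on processing order", {
  cfg <- generator_config(seed = 9, classes = "yellow5")
  ds <- simulate_dataset(cfg)
  fwd <- imaging_feature_matrix(ds$patterns)
  rev_order <- imaging_feature_matrix(rev(ds$patterns))
  expect_identical(fwd, rev_order[rownames(fwd), ])
})
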