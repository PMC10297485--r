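test_that("the default design enumerates 315 spectrum and 63 pattern slots", {
  d <- generate_design(generator_config())
  expect_equal(nrow(d$spectra), 315)
  expect_equal(nrow(d$patterns), 63)
  # per class: 75 spectra per adulterant, 15 for pure
  expect_equal(unname(table(d$spectra$class)[SAFFRON_ADULTERANTS]),
               rep(75L, 4), ignore_attr = TRUE)
  expect_equal(sum(d$spectra$class == "pure"), 15)
  # counts do not depend on the master seed
  d2 <- generate_design(generator_config(seed = 999))
  expect_equal(dim(d2$spectra), dim(d$spectra))
  expect_false(anyDuplicated(d$spectra$sample_id) > 0)
})

test_that("a design with no adulterant classes reduces to the pure slots", {
  d <- generate_design(generator_config(classes = character(0)))
  expect_equal(nrow(d$spectra), 15)
  expect_equal(nrow(d$patterns), 3)
})

test_that("degenerate configurations are rejected", {
  expect_error(generator_config(artificial_levels = c(2, 2, 6)), "duplicate")
  expect_error(generator_config(raman_noise_sd = -1), "noise")
  expect_error(generator_config(pattern_radius = 80), "radius")
  expect_error(generator_config(classes = "paprika"), "unknown")
  expect_error(sample_label("pure", 20), "level 0")
  no_tpl <- generator_config(classes = "safflower")
  no_tpl$raman_templates$turmeric <- NULL
  expect_error(simulate_raman_spectrum(sample_label("turmeric", 20), no_tpl),
               "template")
})

test_that("noiseless spectra are exact convex template mixtures at every level", {
  cfg <- noiseless_config()
  saff <- raman_template(cfg, "saffron")
  bl <- cfg$baseline[1] + cfg$baseline[2] *
    (cfg$wavenumbers - 100) / diff(range(cfg$wavenumbers))
  for (cl in cfg$classes) {
    adult <- raman_template(cfg, cl)
    lv <- if (cl %in% ARTIFICIAL_CLASSES) cfg$artificial_levels else cfg$natural_levels
    for (level in lv) {
      sp <- simulate_raman_spectrum(sample_label(cl, level), cfg)
      f <- level / 100
      expect_equal(sp$intensities, (1 - f) * saff + f * adult + bl,
                   tolerance = 1e-12)
    }
  }
  # level 0 of any class is exactly the pure-saffron endpoint
  s0 <- simulate_raman_spectrum(sample_label("red40", 0), cfg)
  expect_equal(s0$intensities, saff + bl, tolerance = 1e-12)
  # 50% (a test-only level) is the pointwise mean of the endpoints
  s50 <- simulate_raman_spectrum(sample_label("safflower", 50), cfg)
  expect_equal(s50$intensities,
               (saff + raman_template(cfg, "safflower")) / 2 + bl,
               tolerance = 1e-12)
})

test_that("crocin-band intensity is non-increasing in spike level (noiseless)", {
  cfg <- noiseless_config()
  centers <- cfg$raman_templates$saffron$center
  idx <- match(centers, cfg$wavenumbers)
  for (cl in cfg$classes) {
    lv <- sort(if (cl %in% ARTIFICIAL_CLASSES) cfg$artificial_levels
               else cfg$natural_levels)
    prev <- simulate_raman_spectrum(sample_label(cl, 0), cfg)$intensities[idx]
    for (level in lv) {
      cur <- simulate_raman_spectrum(sample_label(cl, level), cfg)$intensities[idx]
      expect_true(all(cur <= prev + 1e-9))
      prev <- cur
    }
  }
})

test_that("simulation is bit-reproducible from (label, seed) and the master seed", {
  cfg <- generator_config(seed = 42)
  lab <- sample_label("turmeric", 40, 2, 3)
  expect_identical(simulate_raman_spectrum(lab, cfg, seed = 7)$intensities,
                   simulate_raman_spectrum(lab, cfg, seed = 7)$intensities)
  expect_identical(simulate_tlc_image(lab, cfg)$ambient,
                   simulate_tlc_image(lab, cfg)$ambient)
  # regenerating a subset matches the full dataset (per-slot seeds)
  small <- generator_config(seed = 42, classes = "red40")
  ds <- simulate_dataset(small)
  i <- 7
  sp <- ds$design$spectra[i, ]
  again <- simulate_raman_spectrum(
    sample_label(sp$class, sp$level, sp$replicate, sp$spot), small)
  expect_identical(unname(ds$raman[i, ]), unname(again$intensities))
})

test_that("TLC rendering honours colors, noise and the saturation contract", {
  cfg <- noiseless_config()
  p <- simulate_tlc_image(sample_label("pure", 0), cfg)
  ring_col <- cfg$pattern_colors$pure$ambient$ring
  # probe one pixel on the ring (angle 0): x = cx + radius - ring_width/2
  x <- round(cfg$image_center[1] + cfg$pattern_radius - cfg$ring_width / 2)
  y <- cfg$image_center[2]
  expect_equal(p$ambient[y + 1, x + 1, ], ring_col, ignore_attr = TRUE)

  # yellow 5 above the saturation threshold pegs the affected channel
  sat <- generator_config(image_noise_sd = 3)
  p8 <- simulate_tlc_image(sample_label("yellow5", 8), sat)
  ch <- match(sat$saturation$channel, c("red", "green", "blue"))
  expect_equal(unique(as.vector(p8$ambient[y + 1, x + 1, ch])),
               sat$saturation$clip)

  # with noise, different seeds give different pixel histograms
  cfgn <- generator_config(image_noise_sd = 6)
  a <- simulate_tlc_image(sample_label("pure", 0), cfgn, seed = 1)$ambient
  b <- simulate_tlc_image(sample_label("pure", 0), cfgn, seed = 2)$ambient
  expect_false(identical(a, b))
})
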