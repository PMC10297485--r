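# Synthetic measurement-design generator: Raman spectra and TLC pattern
# images with the statistical structure the downstream analysis assumes
# (linear spectral mixing, class-specific signatures, additive noise,
# channel saturation at high yellow-5 levels).

#' Adulterant classes recognised by the generator and the models
#'
#' Natural plant adulterants (safflower, turmeric) are spiked at high levels
#' (20--100% w/w); artificial colorants (red 40 / Allura red, yellow 5 /
#' tartrazine) at low levels (2--10% w/w) because of their far stronger
#' color intensity. `"pure"` denotes unadulterated saffron (level 0).
#'
#' @format Character vectors.
#' @name saffron_classes
NULL

#' @rdname saffron_classes
#' @export
SAFFRON_ADULTERANTS <- c("safflower", "turmeric", "red40", "yellow5")

#' @rdname saffron_classes
#' @export
ARTIFICIAL_CLASSES <- c("red40", "yellow5")

gaussian_peaks <- function(wavenumbers, peaks) {
  y <- numeric(length(wavenumbers))
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$amplitude[i] *
      exp(-0.5 * ((wavenumbers - peaks$center[i]) / peaks$width[i])^2)
  }
  y
}

peak_table <- function(center, width, amplitude) {
  data.frame(center = center, width = width, amplitude = amplitude)
}

default_raman_templates <- function(preset) {
  tpl <- list(
    # crocin bands; all centers fall inside the featured windows
    saffron   = peak_table(c(1020, 1165, 1210, 1285, 1536),
                           c(10, 12, 10, 11, 13),
                           c(650, 1000, 520, 430, 1250)),
    safflower = peak_table(c(1340, 1440, 1517, 1601),
                           c(12, 14, 12, 10),
                           c(380, 420, 640, 300)),
    turmeric  = peak_table(c(1183, 1250, 1601, 1630),
                           c(11, 12, 10, 11),
                           c(350, 480, 720, 880)),
    red40     = peak_table(c(1230, 1364, 1500),
                           c(10, 11, 12),
                           c(500, 450, 600)),
    yellow5   = peak_table(c(1135, 1340, 1598),
                           c(10, 12, 10),
                           c(420, 380, 560))
  )
  if (preset == "ambiguity") {
    # weak, nearly identical azo-dye signatures: at <=10% w/w both dyes look
    # spectrally almost like diluted pure saffron, and like each other
    tpl$red40   <- peak_table(c(1230, 1364, 1500), c(10, 11, 12), c(180, 160, 200))
    tpl$yellow5 <- peak_table(c(1232, 1362, 1502), c(10, 11, 12), c(175, 158, 195))
  }
  tpl
}

rgb_set <- function(amb_int, amb_ring, uv_int, uv_ring) {
  list(ambient = list(interior = amb_int, ring = amb_ring),
       uv      = list(interior = uv_int,  ring = uv_ring))
}

default_pattern_colors <- function(preset) {
  cols <- list(
    pure      = rgb_set(c(232, 178, 46), c(204, 120, 30),
                        c(45, 60, 140),  c(30, 42, 105)),
    safflower = rgb_set(c(198, 96, 60),  c(170, 70, 45),
                        c(95, 55, 55),   c(75, 45, 45)),
    turmeric  = rgb_set(c(238, 198, 40), c(215, 160, 30),
                        c(70, 165, 70),  c(55, 130, 55)),
    red40     = rgb_set(c(208, 62, 72),  c(180, 45, 60),
                        c(55, 35, 85),   c(40, 28, 70)),
    yellow5   = rgb_set(c(242, 218, 60), c(225, 190, 45),
                        c(150, 150, 65), c(120, 120, 50))
  )
  if (preset == "ambiguity") {
    # turmeric rendered almost indistinguishably from red 40 on the chip,
    # and yellow 5 pulled toward the pure-saffron hue: imaging alone then
    # confuses turmeric/red40 and pure/yellow5, as Raman disambiguates both
    cols$turmeric <- rgb_set(c(206, 64, 70), c(182, 47, 58),
                             c(57, 37, 83),  c(42, 30, 68))
    cols$yellow5  <- rgb_set(c(238, 196, 52), c(214, 140, 36),
                             c(75, 90, 120),  c(55, 65, 95))
  }
  cols
}

#' Configuration for the synthetic saffron-adulteration data generator
#'
#' Bundles the full measurement design (classes, spike levels, replicates,
#' Raman spots), the spectral and imaging emulation parameters, and the
#' master seed. The default design mirrors a 4-adulterant x 5-level x
#' 3-replicate x 5-spot study plus pure saffron: 315 spectra, 63 TLC
#' patterns.
#'
#' Two presets are provided. `"default"` gives each class a distinct Raman
#' signature and chip color. `"ambiguity"` builds in the failure modes the
#' fusion strategy exists to fix: the TLC colors of turmeric and red 40 are
#' nearly identical (imaging-only models confuse them), while the Raman
#' signatures of the two dyes are weak and nearly identical, so at their low
#' spike levels Raman-only models confuse red 40, yellow 5 and pure saffron.
#'
#' @param preset `"default"` or `"ambiguity"` (see Details).
#' @param seed Master seed; every simulated spectrum/pattern derives its own
#'   seed deterministically from it via [slot_seed()].
#' @param classes Adulterant classes in the design.
#' @param artificial_levels,natural_levels Spike levels (% w/w) for
#'   artificial colorants and natural plant adulterants.
#' @param replicates,spots Replicates per sample type and Raman collection
#'   spots per replicate.
#' @param wavenumbers Raman grid (cm^-1), strictly ascending, constant step.
#' @param raman_templates Named list of peak tables (`center`, `width`,
#'   `amplitude` columns); must contain `"saffron"` and every class in
#'   `classes`.
#' @param baseline Length-2 numeric `c(intercept, slope)`: linear baseline
#'   added to every spectrum across the grid.
#' @param raman_noise_sd Additive i.i.d. Gaussian noise sd per grid point
#'   (counts).
#' @param image_size,image_center,pattern_radius,ring_width TLC raster
#'   geometry in pixels.
#' @param pattern_colors Per-class ambient/UV interior and ring RGB colors
#'   (0--255).
#' @param background Per-light background RGB.
#' @param color_gain Named per-class multiplier on `level/100` when
#'   interpolating chip colors; artificial dyes use large gains because
#'   their tinting strength far exceeds that of plant powders. Yellow 5's
#'   gain of 100/6 makes the chip color saturate exactly at the 6%
#'   saturation threshold, so imaging carries no level information for
#'   yellow 5 above it.
#' @param image_noise_sd Additive Gaussian pixel noise sd (8-bit counts).
#' @param saturation List describing channel saturation: `class`,
#'   `threshold` (% w/w), `light`, `channel` (`"red"/"green"/"blue"`),
#'   `clip` (saturated value), `enabled`.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(preset = c("default", "ambiguity"),
                             seed = 1L,
                             classes = SAFFRON_ADULTERANTS,
                             artificial_levels = c(2, 4, 6, 8, 10),
                             natural_levels = c(20, 40, 60, 80, 100),
                             replicates = 3L,
                             spots = 5L,
                             wavenumbers = seq(100, 2200, by = 1),
                             raman_templates = NULL,
                             baseline = c(50, 30),
                             raman_noise_sd = 15,
                             image_size = 128L,
                             image_center = c(64, 64),
                             pattern_radius = 40,
                             ring_width = 6,
                             pattern_colors = NULL,
                             background = list(ambient = c(235, 235, 230),
                                               uv = c(20, 20, 30)),
                             color_gain = c(safflower = 1, turmeric = 1,
                                            red40 = 10, yellow5 = 100 / 6),
                             image_noise_sd = 6,
                             saturation = list(class = "yellow5",
                                               threshold = 6,
                                               light = "ambient",
                                               channel = "green",
                                               clip = 255,
                                               enabled = TRUE)) {
  preset <- match.arg(preset)
  if (is.null(raman_templates)) raman_templates <- default_raman_templates(preset)
  if (is.null(pattern_colors)) pattern_colors <- default_pattern_colors(preset)
  cfg <- list(preset = preset, seed = as.integer(seed), classes = classes,
              artificial_levels = artificial_levels,
              natural_levels = natural_levels,
              replicates = as.integer(replicates), spots = as.integer(spots),
              wavenumbers = wavenumbers, raman_templates = raman_templates,
              baseline = baseline, raman_noise_sd = raman_noise_sd,
              image_size = as.integer(image_size), image_center = image_center,
              pattern_radius = pattern_radius, ring_width = ring_width,
              pattern_colors = pattern_colors, background = background,
              color_gain = color_gain, image_noise_sd = image_noise_sd,
              saturation = saturation)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (anyDuplicated(cfg$classes)) stop("duplicate adulterant classes in config")
  unknown <- setdiff(cfg$classes, SAFFRON_ADULTERANTS)
  if (length(unknown)) stop("unknown adulterant class: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(cfg$artificial_levels) || anyDuplicated(cfg$natural_levels))
    stop("duplicate spike levels in config")
  if (cfg$raman_noise_sd < 0 || cfg$image_noise_sd < 0)
    stop("noise sd must be >= 0")
  steps <- diff(cfg$wavenumbers)
  if (any(steps <= 0) || diff(range(steps)) > 1e-9)
    stop("wavenumber grid must be strictly ascending with constant step")
  need <- c("saffron", cfg$classes)
  miss <- setdiff(need, names(cfg$raman_templates))
  if (length(miss)) stop("missing Raman template for: ", paste(miss, collapse = ", "))
  if (cfg$pattern_radius >= cfg$image_size / 2)
    stop("pattern radius must be smaller than half the image size")
  if (cfg$ring_width <= 0 || cfg$ring_width >= cfg$pattern_radius)
    stop("ring width must lie in (0, pattern_radius)")
  if (cfg$saturation$clip < 0 || cfg$saturation$clip > 255)
    stop("saturation clip value must be representable in an 8-bit channel")
  invisible(cfg)
}

#' Construct a validated sample label
#'
#' @param class `"pure"` or one of [SAFFRON_ADULTERANTS].
#' @param level Spike level in % w/w (0--100); must be 0 for `"pure"`.
#' @param replicate Replicate number (positive integer).
#' @param spot Raman collection spot (positive integer), or `NA` for a
#'   pattern-level label (TLC patterns have no spot).
#' @return A list of class `sample_label`.
#' @export
sample_label <- function(class, level, replicate = 1L, spot = NA_integer_) {
  if (!class %in% c("pure", SAFFRON_ADULTERANTS))
    stop("unknown class: ", class)
  if (level < 0 || level > 100) stop("spike level must lie in [0, 100]")
  if (class == "pure" && level != 0) stop("pure saffron must have level 0")
  if (replicate < 1) stop("replicate must be a positive integer")
  structure(list(class = class, level = level,
                 replicate = as.integer(replicate),
                 spot = if (is.na(spot)) NA_integer_ else as.integer(spot)),
            class = "sample_label")
}

#' Deterministic per-slot seed derived from the master seed and a label
#'
#' Hashes the label fields so any subset of the design regenerates
#' bit-identically without simulating the rest.
#'
#' @param master Master seed (integer).
#' @param label A [sample_label()].
#' @return An integer seed in `[0, 2^31)`.
#' @export
slot_seed <- function(master, label) {
  key <- paste(label$class, label$level, label$replicate,
               if (is.na(label$spot)) 0L else label$spot, sep = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147480009
  as.integer((h + (as.numeric(master) %% 2147483647) * 7919) %% 2147483647)
}

class_levels <- function(cfg, cl) {
  if (cl %in% ARTIFICIAL_CLASSES) cfg$artificial_levels else cfg$natural_levels
}

spectrum_id <- function(class, level, replicate, spot) {
  sprintf("%s_L%03d_r%d_s%d", class, level, replicate, spot)
}

pattern_id <- function(class, level, replicate) {
  sprintf("%s_L%03d_r%d", class, level, replicate)
}

#' Enumerate the experimental design
#'
#' Expands the configured classes, spike levels, replicates and Raman spots
#' into one row per spectrum slot, and collapses over spots into one row per
#' TLC pattern slot. Pure saffron contributes `replicates x spots` spectra
#' at level 0. Under the default configuration this yields 315 spectrum
#' slots and 63 pattern slots.
#'
#' @param config A [generator_config()].
#' @return A list of class `saffron_design` with data frames `spectra`
#'   (`class`, `level`, `replicate`, `spot`, `sample_id`, `pattern_id`) and
#'   `patterns` (`class`, `level`, `replicate`, `pattern_id`).
#' @export
generate_design <- function(config) {
  validate_generator_config(config)
  rows <- list()
  for (cl in config$classes) {
    g <- expand.grid(spot = seq_len(config$spots),
                     replicate = seq_len(config$replicates),
                     level = class_levels(config, cl),
                     KEEP.OUT.ATTRS = FALSE)
    g$class <- cl
    rows[[cl]] <- g
  }
  pure <- expand.grid(spot = seq_len(config$spots),
                      replicate = seq_len(config$replicates),
                      level = 0, KEEP.OUT.ATTRS = FALSE)
  pure$class <- "pure"
  rows[["pure"]] <- pure
  spectra <- do.call(rbind, rows)
  spectra <- spectra[, c("class", "level", "replicate", "spot")]
  rownames(spectra) <- NULL
  if (anyDuplicated(spectra))
    stop("duplicate (class, level, replicate, spot) tuples in design")
  spectra$sample_id <- spectrum_id(spectra$class, spectra$level,
                                   spectra$replicate, spectra$spot)
  spectra$pattern_id <- pattern_id(spectra$class, spectra$level,
                                   spectra$replicate)
  patterns <- unique(spectra[, c("class", "level", "replicate", "pattern_id")])
  rownames(patterns) <- NULL
  structure(list(spectra = spectra, patterns = patterns),
            class = "saffron_design")
}

#' @export
print.saffron_design <- function(x, ...) {
  cat("Saffron adulteration design:",
      nrow(x$spectra), "spectrum slots,",
      nrow(x$patterns), "TLC pattern slots\n")
  print(table(x$spectra$class))
  invisible(x)
}

raman_baseline <- function(config) {
  w <- config$wavenumbers
  config$baseline[1] + config$baseline[2] * (w - min(w)) / diff(range(w))
}

#' Evaluate a pure-component Raman template on the configured grid
#'
#' @param config A [generator_config()].
#' @param class `"saffron"` or an adulterant class with a template.
#' @return Numeric vector of template intensities (no baseline, no noise).
#' @export
raman_template <- function(config, class) {
  tpl <- config$raman_templates[[class]]
  if (is.null(tpl)) stop("no Raman template for class: ", class)
  gaussian_peaks(config$wavenumbers, tpl)
}

#' Simulate one Raman spectrum
#'
#' The intensity model is a linear (convex) mixture of the pure-saffron and
#' adulterant templates, weighted by the spike level, plus a linear baseline
#' and additive i.i.d. Gaussian noise:
#' `(1 - level/100) * saffron + (level/100) * adulterant + baseline + noise`.
#' Identical `(label, seed)` pairs give bit-identical spectra.
#'
#' @param label A [sample_label()].
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to [slot_seed()] of the master seed
#'   and the label.
#' @return A list of class `raman_spectrum` with `wavenumbers`,
#'   `intensities` (non-negative) and `label`.
#' @export
simulate_raman_spectrum <- function(label, config, seed = NULL) {
  stopifnot(inherits(label, "sample_label"))
  validate_generator_config(config)
  if (is.null(seed)) seed <- slot_seed(config$seed, label)
  saff <- raman_template(config, "saffron")
  f <- label$level / 100
  adult <- if (label$class == "pure") 0 else raman_template(config, label$class)
  set.seed(seed)
  noise <- if (config$raman_noise_sd > 0)
    rnorm(length(saff), sd = config$raman_noise_sd) else 0
  intens <- (1 - f) * saff + f * adult + raman_baseline(config) + noise
  structure(list(wavenumbers = config$wavenumbers,
                 intensities = pmax(intens, 0),
                 label = label),
            class = "raman_spectrum")
}

render_pattern_raster <- function(config, label, light) {
  size <- config$image_size
  cx <- config$image_center[1]
  cy <- config$image_center[2]
  # 0-based pixel coordinates, x = column, y = row
  xs <- matrix(rep(0:(size - 1), each = size), nrow = size)   # column index
  ys <- matrix(rep(0:(size - 1), times = size), nrow = size)  # row index
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  interior <- d < (config$pattern_radius - config$ring_width)
  ring <- d >= (config$pattern_radius - config$ring_width) &
    d <= config$pattern_radius
  pure_col <- config$pattern_colors[["pure"]][[light]]
  if (label$class == "pure") {
    f <- 0
    class_col <- pure_col
  } else {
    gain <- config$color_gain[[label$class]]
    f <- min(1, label$level / 100 * gain)
    class_col <- config$pattern_colors[[label$class]][[light]]
  }
  bg <- config$background[[light]]
  arr <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    m <- matrix(bg[ch], size, size)
    m[interior] <- (1 - f) * pure_col$interior[ch] + f * class_col$interior[ch]
    m[ring] <- (1 - f) * pure_col$ring[ch] + f * class_col$ring[ch]
    arr[, , ch] <- m
  }
  if (config$image_noise_sd > 0)
    arr <- arr + array(rnorm(length(arr), sd = config$image_noise_sd), dim = dim(arr))
  sat <- config$saturation
  if (isTRUE(sat$enabled) && label$class == sat$class &&
      label$level >= sat$threshold && light == sat$light) {
    ch <- match(sat$channel, c("red", "green", "blue"))
    m <- arr[, , ch]
    m[interior | ring] <- sat$clip
    arr[, , ch] <- m
  }
  arr[arr < 0] <- 0
  arr[arr > 255] <- 255
  arr
}

#' Simulate one TLC pattern image pair
#'
#' Renders the dried sample droplet as a filled circle with a darker outer
#' ring on a plate background, under ambient and 365 nm UV illumination.
#' Per-channel colors interpolate between the pure-saffron color and the
#' adulterant's color as the spike level rises (dye classes use an amplified
#' effective level, see [generator_config()]), with additive Gaussian pixel
#' noise. When saturation is enabled, yellow 5 at or above the threshold
#' level clips the configured channel at the clip value over the whole
#' pattern, emulating color saturation on the chip.
#'
#' @inheritParams simulate_raman_spectrum
#' @return A list of class `tlc_pattern` with 8-bit-range numeric arrays
#'   `ambient` and `uv` (`size x size x 3`), the `geometry` (size, center,
#'   radius, ring width) and the `label`.
#' @export
simulate_tlc_image <- function(label, config, seed = NULL) {
  stopifnot(inherits(label, "sample_label"))
  validate_generator_config(config)
  if (is.null(seed)) seed <- slot_seed(config$seed, label)
  set.seed(seed)
  ambient <- render_pattern_raster(config, label, "ambient")
  uv <- render_pattern_raster(config, label, "uv")
  structure(list(ambient = ambient, uv = uv,
                 geometry = list(size = config$image_size,
                                 center = config$image_center,
                                 radius = config$pattern_radius,
                                 ring_width = config$ring_width),
                 label = label),
            class = "tlc_pattern")
}

#' Simulate the full dataset for a configured design
#'
#' @param config A [generator_config()].
#' @return A list of class `saffron_dataset`: the `design`, a `raman`
#'   intensity matrix (spectrum slots x wavenumbers, rownames = sample ids,
#'   colnames = wavenumbers) and `patterns`, a named list of
#'   [simulate_tlc_image()] results keyed by pattern id.
#' @export
simulate_dataset <- function(config) {
  design <- generate_design(config)
  sp <- design$spectra
  raman <- matrix(0, nrow(sp), length(config$wavenumbers),
                  dimnames = list(sp$sample_id, config$wavenumbers))
  for (i in seq_len(nrow(sp))) {
    lab <- sample_label(sp$class[i], sp$level[i], sp$replicate[i], sp$spot[i])
    raman[i, ] <- simulate_raman_spectrum(lab, config)$intensities
  }
  pt <- design$patterns
  patterns <- vector("list", nrow(pt))
  names(patterns) <- pt$pattern_id
  for (i in seq_len(nrow(pt))) {
    lab <- sample_label(pt$class[i], pt$level[i], pt$replicate[i])
    patterns[[i]] <- simulate_tlc_image(lab, config)
  }
  structure(list(design = design, raman = raman, patterns = patterns),
            class = "saffron_dataset")
}
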