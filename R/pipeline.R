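# End-to-end experiments: simulate -> featurize -> normalize/fuse ->
# classify / quantify -> evaluate, with a shared train/validation split and
# full determinism from the master seed.

#' Configuration for an end-to-end fusion experiment
#'
#' @param generator A [generator_config()].
#' @param windows A [band_windows()] object for the featured Raman block.
#' @param cv_folds Folds of the grouped cross-validation.
#' @param ncomp_max Largest PLS component count examined by CV.
#' @param window_px Imaging window side length (px).
#' @param seed Seed for the split and CV fold shuffling (defaults to the
#'   generator's master seed).
#' @param out_dir Optional directory; when set, tables, metrics and a run
#'   manifest are written there.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              windows = band_windows(),
                              cv_folds = 7, ncomp_max = 8, window_px = 32,
                              seed = generator$seed, out_dir = NULL) {
  validate_generator_config(generator)
  structure(list(generator = generator, windows = windows,
                 cv_folds = cv_folds, ncomp_max = ncomp_max,
                 window_px = window_px, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

# Simulate and featurize both modalities at spectrum granularity: the five
# Raman spots of a replicate share that replicate's single TLC pattern, the
# only join preserving 315 spectra against 63 patterns.
build_feature_blocks <- function(config) {
  ds <- simulate_dataset(config$generator)
  raman_feat <- extract_raman_bands(ds$raman, config$windows)
  imaging_pat <- imaging_feature_matrix(ds$patterns, window = config$window_px)
  imaging_spec <- imaging_pat[ds$design$spectra$pattern_id, , drop = FALSE]
  rownames(imaging_spec) <- ds$design$spectra$sample_id
  list(dataset = ds,
       raman = feature_block(raman_feat, "raman"),
       imaging = feature_block(imaging_spec, "imaging"),
       imaging_patterns = imaging_pat)
}

# Min-max parameters are fitted on the training rows only and applied to
# every row, so validation metrics see no information from the held-out set.
normalize_block <- function(block, train_idx) {
  params <- minmax_fit(block_rows(block, train_idx))
  list(block = minmax_apply(block, params), params = params)
}

cv_groups <- function(design_rows) {
  interaction(design_rows$class, design_rows$level, design_rows$replicate,
              drop = TRUE)
}

#' Run the three-block classification experiment
#'
#' Simulates the configured design, extracts featured Raman and featured
#' imaging blocks, min-max normalizes each on the training partition, forms
#' the fused block, and fits one PLS-DA model per block (imaging-only,
#' Raman-only, fused) on the identical train/validation split. Component
#' counts are chosen per block by grouped cross-validation. Returns train
#' and validation misclassification tables for all three blocks.
#'
#' @param config An [experiment_config()].
#' @return A list of class `classification_experiment`: `tables` (per
#'   block: `train`, `validation` confusion tables), `ncomp` (chosen per
#'   block), `split`, `accuracy` (summary data frame), `models`.
#' @export
run_classification_experiment <- function(config) {
  fb <- build_feature_blocks(config)
  design <- fb$dataset$design$spectra
  split <- split_train_validation(design, seed = config$seed)
  labels <- design$class
  norm_raman <- normalize_block(fb$raman, split$train)
  norm_imaging <- normalize_block(fb$imaging, split$train)
  blocks <- list(imaging = norm_imaging$block,
                 raman = norm_raman$block,
                 fused = fuse_blocks(norm_raman$block, norm_imaging$block))
  groups <- cv_groups(design[split$train, ])
  tables <- list()
  models <- list()
  ncomp <- integer(0)
  for (bn in names(blocks)) {
    Xtr <- as.matrix(blocks[[bn]])[split$train, , drop = FALSE]
    Xva <- as.matrix(blocks[[bn]])[split$validation, , drop = FALSE]
    cv <- cross_validate(Xtr, labels[split$train], folds = config$cv_folds,
                         ncomp_max = config$ncomp_max, groups = groups,
                         seed = config$seed, method = "plsda")
    model <- fit_plsda(Xtr, labels[split$train], cv$ncomp)
    tables[[bn]] <- list(
      train = confusion_table(labels[split$train], classify(model, Xtr)),
      validation = confusion_table(labels[split$validation],
                                   classify(model, Xva),
                                   classes = model$classes))
    models[[bn]] <- model
    ncomp[bn] <- model$ncomp
  }
  accuracy <- do.call(rbind, lapply(names(tables), function(bn) {
    data.frame(block = bn,
               partition = c("train", "validation"),
               micro_pct = c(tables[[bn]]$train$micro_pct,
                             tables[[bn]]$validation$micro_pct),
               macro_pct = c(tables[[bn]]$train$macro_pct,
                             tables[[bn]]$validation$macro_pct))
  }))
  result <- structure(list(tables = tables, ncomp = ncomp, split = split,
                           accuracy = accuracy, models = models,
                           config = config),
                      class = "classification_experiment")
  if (!is.null(config$out_dir)) write_classification_outputs(result)
  result
}

#' @export
print.classification_experiment <- function(x, ...) {
  cat("Three-block PLS-DA classification experiment\n")
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}

#' Run the three-block quantification experiment
#'
#' One PLS regression per (adulterant, block): predictors are the featured
#' block rows of that adulterant's samples plus pure saffron (the level-0
#' calibration point), the response is the spike level (% w/w). Natural
#' and artificial adulterants are never pooled into one regression, since
#' their level ranges differ by an order of magnitude. Training rows come
#' from the shared classification split; RMSEP uses the adulterant's 25
#' external validation spectra.
#'
#' @param config An [experiment_config()].
#' @return A list of class `quantification_experiment` with `metrics` (data
#'   frame: adulterant, block, ncomp, r2, rmsec, rmsecv, rmsep) and
#'   `config`.
#' @export
run_quantification_experiment <- function(config) {
  fb <- build_feature_blocks(config)
  design <- fb$dataset$design$spectra
  split <- split_train_validation(design, seed = config$seed)
  rows <- list()
  for (adult in config$generator$classes) {
    tr <- intersect(split$train, which(design$class %in% c(adult, "pure")))
    ex <- intersect(split$validation, which(design$class == adult))
    nr <- normalize_block(block_rows(fb$raman, c(tr, ex)),
                          seq_along(tr))
    ni <- normalize_block(block_rows(fb$imaging, c(tr, ex)),
                          seq_along(tr))
    blocks <- list(imaging = ni$block, raman = nr$block,
                   fused = fuse_blocks(nr$block, ni$block))
    y_tr <- design$level[tr]
    y_ex <- design$level[ex]
    groups <- interaction(design$level[tr], design$replicate[tr], drop = TRUE)
    for (bn in names(blocks)) {
      X <- as.matrix(blocks[[bn]])
      Xtr <- X[seq_along(tr), , drop = FALSE]
      Xex <- X[length(tr) + seq_along(ex), , drop = FALSE]
      cv <- cross_validate(Xtr, y_tr, folds = config$cv_folds,
                           ncomp_max = config$ncomp_max, groups = groups,
                           seed = config$seed, method = "pls")
      model <- fit_pls(Xtr, y_tr, cv$ncomp)
      met <- regression_metrics(y_tr, model$fitted,
                                pred_cv = cv$oof[, 1, cv$ncomp],
                                y_external = y_ex,
                                pred_external = predict(model, Xex))
      rows[[paste(adult, bn)]] <- data.frame(
        adulterant = adult, block = bn, ncomp = model$ncomp,
        r2 = met$r2, rmsec = met$rmsec, rmsecv = met$rmsecv,
        rmsep = met$rmsep)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  result <- structure(list(metrics = metrics, split = split, config = config),
                      class = "quantification_experiment")
  if (!is.null(config$out_dir)) write_quantification_outputs(result)
  result
}

#' @export
print.quantification_experiment <- function(x, ...) {
  cat("Three-block PLS quantification experiment\n")
  print(quantification_table(x), row.names = FALSE)
  invisible(x)
}

#' Reshape quantification metrics into the conventional wide layout
#'
#' One row per adulterant; R2 / RMSEP / RMSECV columns grouped by block
#' (imaging, Raman, fused).
#'
#' @param experiment A [run_quantification_experiment()] result (or its
#'   `metrics` data frame).
#' @return A wide data frame.
#' @export
quantification_table <- function(experiment) {
  m <- if (is.data.frame(experiment)) experiment else experiment$metrics
  out <- data.frame(adulterant = unique(m$adulterant))
  for (bn in unique(m$block)) {
    sub <- m[m$block == bn, ]
    sub <- sub[match(out$adulterant, sub$adulterant), ]
    out[[paste0(bn, "_r2")]] <- round(sub$r2, 3)
    out[[paste0(bn, "_rmsep")]] <- round(sub$rmsep, 2)
    out[[paste0(bn, "_rmsecv")]] <- round(sub$rmsecv, 2)
  }
  out
}
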