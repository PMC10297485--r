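# Plain-text interchange: CSV feature/spectra tables, PNG pattern images,
# YAML configs and run manifests, JSON metrics.

#' Write a wide spectra CSV (rows = samples, columns = wavenumbers)
#'
#' @param raman Intensity matrix with wavenumber column names and sample-id
#'   row names (e.g. `simulate_dataset()$raman`).
#' @param path Output file.
#' @export
write_spectra_csv <- function(raman, path) {
  df <- data.frame(sample_id = rownames(raman), raman, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a TLC pattern as a pair of PNG files
#'
#' @param pattern A [simulate_tlc_image()] result.
#' @param dir Output directory.
#' @param stem File stem; files are `<stem>_ambient.png` and
#'   `<stem>_uv.png`.
#' @return The two file paths, invisibly.
#' @export
write_pattern_png <- function(pattern, dir, stem = "pattern") {
  paths <- file.path(dir, paste0(stem, c("_ambient.png", "_uv.png")))
  png::writePNG(pattern$ambient / 255, paths[1])
  png::writePNG(pattern$uv / 255, paths[2])
  invisible(paths)
}

#' Read a PNG image back into the 8-bit-range array convention
#'
#' @param path PNG file.
#' @return An `h x w x 3` array with values in 0--255.
#' @export
read_pattern_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3 && dim(arr)[3] == 4)
    arr <- arr[, , 1:3]
  arr * 255
}

#' Write the design manifest as CSV
#'
#' @param design A [generate_design()] result.
#' @param path Output file.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design$spectra, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path YAML file.
#' @export
write_generator_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$raman_templates <- lapply(raw$raman_templates, as.data.frame)
  raw$color_gain <- unlist(raw$color_gain)
  cfg <- structure(raw, class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Write a confusion table as CSV in the conventional layout
#'
#' Rows are true classes with `Members` and `Correct_pct` columns followed
#' by one column per predicted class; a final `Total` row carries the micro
#' overall rate.
#'
#' @param table A [confusion_table()].
#' @param path Output file.
#' @export
write_confusion_csv <- function(table, path) {
  df <- as.data.frame(table)
  total <- data.frame(Members = sum(table$members),
                      Correct_pct = round(table$micro_pct, 2),
                      as.data.frame.matrix(t(colSums(table$counts))))
  rownames(total) <- "Total"
  out <- rbind(df, total)
  out <- cbind(class = rownames(out), out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

write_classification_outputs <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- result$config$out_dir
  for (bn in names(result$tables)) {
    write_confusion_csv(result$tables[[bn]]$train,
                        file.path(od, paste0("confusion_", bn, "_train.csv")))
    write_confusion_csv(result$tables[[bn]]$validation,
                        file.path(od, paste0("confusion_", bn, "_validation.csv")))
  }
  utils::write.csv(result$accuracy, file.path(od, "accuracy_summary.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(seed = result$config$seed,
                        preset = result$config$generator$preset,
                        chosen_ncomp = as.list(result$ncomp),
                        n_train = length(result$split$train),
                        n_validation = length(result$split$validation)),
                   file.path(od, "classification_manifest.yaml"))
  invisible(od)
}

write_quantification_outputs <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- result$config$out_dir
  utils::write.csv(result$metrics, file.path(od, "quantification_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(quantification_table(result),
                   file.path(od, "quantification_table.csv"), row.names = FALSE)
  jsonlite::write_json(result$metrics,
                       file.path(od, "quantification_metrics.json"),
                       dataframe = "rows", digits = NA)
  yaml::write_yaml(list(seed = result$config$seed,
                        preset = result$config$generator$preset),
                   file.path(od, "quantification_manifest.yaml"))
  invisible(od)
}

#' Bundled example misclassification count tables
#'
#' Four count matrices for a five-class saffron adulteration screen
#' (training tables for the imaging-only, Raman-only and fused blocks, and
#' an external-validation table for the fused block), shipped as plain CSV
#' under `inst/extdata`. Used in the documentation and tests to demonstrate
#' the accuracy summaries.
#'
#' @param which One of `"training_imaging"`, `"training_raman"`,
#'   `"training_fused"`, `"validation_fused"`.
#' @return A square integer count matrix (true x predicted).
#' @export
example_confusion_counts <- function(which = c("training_imaging",
                                               "training_raman",
                                               "training_fused",
                                               "validation_fused")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("confusion_", which, ".csv"),
                      package = "saffusion", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
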