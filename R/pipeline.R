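#' Load and validate an image manifest
#'
#' The manifest is a CSV with the exact header `path,label,split`, one row
#' per image; labels must be exactly `benign`/`malignant` and splits
#' `train`/`test` (case-sensitive). Errors name the offending row.
#'
#' @param path manifest file path.
#' @param check_paths also require every referenced image file to exist
#'   (relative to the manifest's directory).
#' @return A tibble `path`, `label`, `split`, row order preserved.
#' @export
load_manifest <- function(path, check_paths = FALSE) {
  if (!file.exists(path)) stop_data(paste0("manifest not found: ", path))
  lines <- readLines(path)
  if (!length(lines) || trimws(lines[1]) != "path,label,split") {
    stop_data("manifest must start with the exact header 'path,label,split'")
  }
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad_len <- which(lengths(parts) != 3L)
  if (length(bad_len)) {
    stop_data(paste0("manifest row(s) without 3 fields: ", paste(bad_len + 1L, collapse = ", ")))
  }
  m <- do.call(rbind, parts)
  df <- tibble::tibble(path = m[, 1], label = m[, 2], split = m[, 3])
  bad_lab <- which(!df$label %in% c("benign", "malignant"))
  if (length(bad_lab)) {
    stop_data(paste0("invalid label at manifest row(s): ",
                     paste(bad_lab + 1L, collapse = ", "),
                     " (labels are case-sensitive 'benign'/'malignant')"))
  }
  bad_split <- which(!df$split %in% c("train", "test"))
  if (length(bad_split)) {
    stop_data(paste0("invalid split at manifest row(s): ", paste(bad_split + 1L, collapse = ", ")))
  }
  dup <- df$path[duplicated(df$path)]
  if (length(dup)) {
    stop_data(paste0("duplicate path(s) in manifest: ", paste(unique(dup), collapse = ", ")))
  }
  if (check_paths) {
    full <- file.path(dirname(path), df$path)
    missing <- df$path[!file.exists(full)]
    if (length(missing)) {
      stop_data(paste0("missing image file(s): ", paste(missing, collapse = ", ")))
    }
  }
  df
}

#' Read a dataset (manifest plus images) from disk
#'
#' @param manifest_path path to a manifest CSV; image paths are resolved
#'   relative to its directory.
#' @return A dataset tibble with an `image` list-column.
#' @export
read_dataset <- function(manifest_path) {
  mf <- load_manifest(manifest_path, check_paths = TRUE)
  base <- dirname(manifest_path)
  mf$image <- lapply(file.path(base, mf$path), read_gray_png)
  class(mf) <- c("us_dataset", class(mf))
  mf
}

#' Assemble a full run configuration
#'
#' One nested, serializable configuration driving [run_pipeline()]. Either
#' a `synth` block (the dataset is generated) or a `manifest` path (it is
#' read from disk) must be present. Unknown keys are rejected.
#'
#' @param config a named list (or path to a YAML file with the same
#'   structure). Recognized top-level keys: `seed`, `out_dir`, `synth`
#'   (`n_benign`, `n_malignant`, `train_fraction`, `image_size`),
#'   `manifest`, `enhance`, `features`, `gan`, `fusion`, `augment`.
#' @return A validated `run_config` list with config objects in place.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  allowed <- c("seed", "out_dir", "synth", "manifest", "enhance", "features",
               "gan", "fusion", "augment")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop_config(paste0("unknown run-config key(s): ", paste(unknown, collapse = ", ")))
  }
  seed <- as.integer(config$seed %||% 1L)
  synth <- config$synth
  if (is.null(synth) && is.null(config$manifest)) {
    stop_config("run config needs either a 'synth' block or a 'manifest' path")
  }
  gan_args <- config$gan %||% list()
  gan_args$seed <- derive_seed(seed, "gan")
  fus_args <- config$fusion %||% list()
  fus_args$seed <- derive_seed(seed, "cv")
  structure(list(
    seed = seed,
    out_dir = config$out_dir,
    synth = synth,
    manifest = config$manifest,
    enhance = do.call(enhancement_config, config$enhance %||% list()),
    features = do.call(feature_extraction_config, config$features %||% list()),
    gan = do.call(gan_train_config, gan_args),
    fusion = do.call(fusion_config, fus_args),
    augment = config$augment
  ), class = "run_config")
}

#' Run the end-to-end pipeline
#'
#' Builds (or reads) the dataset, then runs stratified cross-validation in
#' which each fold applies the enhancement policy, optional augmentation,
#' classical feature extraction with a fold-fitted vocabulary, GAN training
#' and deep-feature extraction, per-block standardization and fusion, and
#' classifier training — all on the fold's training portion only — and
#' evaluates on the held-out portion. Writes `report.json` (config digest,
#' per-fold and pooled confusion counts and metrics) plus a provenance
#' record to `out_dir` when given. Identical configuration and seed
#' reproduce the report byte for byte on a single-threaded CPU.
#'
#' @param config a [run_config()] (or the list/path it accepts).
#' @return The `metrics_report`, invisibly carrying attribute
#'   `report_path` when a report was written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dataset <- if (!is.null(config$synth)) {
    s <- config$synth
    generate_dataset(
      n_benign = s$n_benign %||% 100L,
      n_malignant = s$n_malignant %||% 100L,
      train_fraction = s$train_fraction %||% 0.6,
      preset_overrides = s$preset_overrides,
      seed = derive_seed(config$seed, "synth"),
      image_size = s$image_size %||% 128L
    )
  } else {
    read_dataset(config$manifest)
  }
  report <- cross_validate(dataset, config$fusion, config$features,
                           config$enhance, config$gan, config$augment)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(config$out_dir, "report.json")
    write_report_json(report, config, path)
    attr(report, "report_path") <- path
  }
  invisible(report)
}

# Digest of the scientific configuration: output location is bookkeeping,
# not configuration, so two runs differing only in out_dir hash identically.
config_digest <- function(config) {
  plain <- rapply(unclass(config), function(x) x, how = "list")
  plain$out_dir <- NULL
  digest::digest(plain, algo = "sha256")
}

write_report_json <- function(report, config, path) {
  payload <- list(
    config_digest = config_digest(config),
    seed = config$seed,
    per_fold = report$per_fold,
    pooled = report$pooled,
    provenance = list(
      package = "thyrocad",
      package_version = as.character(utils::packageVersion("thyrocad")),
      arms = report$config$conventional %||% "main",
      folds = nrow(report$per_fold)
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
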