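#' Default pipeline configuration
#'
#' All tunable parameters of the two processing stages, as a nested list
#' that can be overridden wholesale or per field via [read_config()].
#'
#' @return Nested list with entries `fold_threshold`
#'   (see [fold_threshold_config()]), `blood_mask` (see [color_mask()]),
#'   `dbscan` (see [dbscan_config()]), `otsu_levels`, `kmeans`
#'   (see [kmeans_config()]) and `stats` (defaults for [compare_groups()]).
#' @export
default_config <- function() {
  list(
    fold_threshold = list(n_bins = 101L, smoothing_window = 5L,
                          prominence_fraction = 0.25),
    blood_mask = list(center = c(35, 45, 25), radius = 18),
    dbscan = list(R = 3, MinPxs = 9),
    otsu_levels = 256L,
    kmeans = list(k = 3L, n_restarts = 10L, max_iter = 300L, tol = 1e-4,
                  seed = NULL),
    stats = list(m = 10000L, statistic = "mean_difference",
                 tail = "two_tailed", ci_level = 0.95)
  )
}

#' Read a configuration file (JSON or YAML)
#'
#' Values present in the file override the matching entries of
#' [default_config()]; everything else keeps its default.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the 'yaml' package is required to read YAML configs")
      }
      yaml::read_yaml(path)
    },
    stop("unsupported config format: ", ext)
  )
  utils::modifyList(default_config(), user)
}

#' Read an 8-bit RGB image
#'
#' Reads PNG (always) or TIFF (if the `tiff` package is installed) into the
#' `H x W x 3` integer array in \[0, 255\] used by the pipeline. Grayscale
#' images are replicated across channels; an alpha channel is dropped.
#'
#' @param path Image file path.
#' @return `H x W x 3` integer array.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF images")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  arr <- array(as.integer(round(raw * 255)), dim = dim(raw))
  arr
}

#' Write an RGB array or a binary mask as PNG
#'
#' @param img `H x W x 3` array in \[0, 255\], or a logical matrix (written
#'   as a black/white image with foreground white).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (is.logical(img)) {
    png::writePNG(img * 1, path)
  } else {
    png::writePNG(img / 255, path)
  }
  invisible(path)
}

#' Process one stained-section image end to end
#'
#' Runs the pre-processing stage (defect removal, contrast enhancement, wall
#' delimitation) and the feature-extraction stage (color clustering and area
#' quantification) on a single image, returning one sample record. The
#' image's clustering seed is derived deterministically from the global seed
#' and the sample id, so batch composition never changes per-sample results.
#'
#' @param path Image file path, or an `H x W x 3` RGB array in \[0, 255\].
#' @param sample_id Sample identifier (defaults to the file name).
#' @param group Optional group label carried into the record.
#' @param config Pipeline configuration, see [default_config()].
#' @param seed Global integer seed.
#' @param save_intermediates If `TRUE`, write the contrast-enhanced image,
#'   wall mask and component masks to `out_dir`.
#' @param out_dir Directory for intermediates.
#' @return One-row data frame (the sample record): `sample_id`, `group`,
#'   `path`, `A_SMF`, `A_ECM`, `A_TOT`, `ratio_SMF`, `ratio_ECM`, `fold_t`,
#'   `otsu_t`, `seed`, `config_hash`, `version`.
#' @export
process_image <- function(path, sample_id = NULL, group = NA_character_,
                          config = default_config(), seed = 1L,
                          save_intermediates = FALSE, out_dir = ".") {
  if (is.character(path)) {
    img <- read_rgb_image(path)
    if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
    src <- path
  } else {
    img <- path
    if (is.null(sample_id)) sample_id <- "sample"
    src <- NA_character_
  }
  img_seed <- derive_seed(seed, sample_id)
  pre <- preprocess_image(img, config)
  seg <- segment_image(pre$enhanced, pre$wall, config, seed = img_seed)
  q <- seg$quant

  if (isTRUE(save_intermediates)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_image_png(lab_to_rgb(pre$enhanced),
                    file.path(out_dir, paste0(sample_id, "_enhanced.png")))
    write_image_png(unclass(pre$wall$mask) == TRUE,
                    file.path(out_dir, paste0(sample_id, "_wall.png")))
    write_image_png(seg$component_masks$SMF,
                    file.path(out_dir, paste0(sample_id, "_smf.png")))
    write_image_png(seg$component_masks$ECM,
                    file.path(out_dir, paste0(sample_id, "_ecm.png")))
  }

  data.frame(
    sample_id = sample_id, group = group, path = src,
    A_SMF = q$A_SMF, A_ECM = q$A_ECM, A_TOT = q$A_TOT,
    ratio_SMF = q$ratio_SMF, ratio_ECM = q$ratio_ECM,
    fold_t = pre$fold_t, otsu_t = pre$otsu_t,
    seed = img_seed, config_hash = config_hash(config),
    version = as.character(utils::packageVersion("vesselquant")),
    stringsAsFactors = FALSE
  )
}

#' Run a full study: batch quantification plus group statistics
#'
#' Processes every image listed in a manifest (columns `sample_id`, `group`,
#' `path`), collects the per-sample records, and compares groups with
#' pairwise permutation tests on the normalized component areas. Per-image
#' failures are recorded and the batch continues.
#'
#' @param manifest Data frame or CSV path with columns `sample_id`, `group`,
#'   `path`.
#' @param config Pipeline configuration.
#' @param seed Global seed (drives both clustering and resampling).
#' @param m Resamplings per pairwise permutation test.
#' @param n_workers Parallel workers for the permutation tests.
#' @param out_dir If non-`NULL`, write `records.csv`, `report.csv` and a
#'   JSON report there.
#' @param save_intermediates Forwarded to [process_image()].
#' @return List with `records` (per-sample data frame), `report` (pairwise
#'   p-value data frame, or `NULL` with a warning if fewer than two groups
#'   succeeded) and `errors` (named character vector of per-image failures).
#' @export
run_study <- function(manifest, config = default_config(), seed = 1L,
                      m = NULL, n_workers = 1L, out_dir = NULL,
                      save_intermediates = FALSE) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "group", "path") %in% names(manifest)))
  if (nrow(manifest) == 0) stop("empty manifest")
  if (is.null(m)) m <- config$stats$m

  records <- list()
  errors <- character(0)
  for (i in seq_len(nrow(manifest))) {
    rec <- tryCatch(
      process_image(manifest$path[i], sample_id = manifest$sample_id[i],
                    group = manifest$group[i], config = config, seed = seed,
                    save_intermediates = save_intermediates,
                    out_dir = if (is.null(out_dir)) "." else out_dir),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      errors[manifest$sample_id[i]] <- conditionMessage(rec)
      vq_log("sample %s failed: %s", manifest$sample_id[i],
             conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (length(records) == 0) stop("no image processed successfully")
  records <- do.call(rbind, records)
  records <- records[order(records$sample_id), , drop = FALSE]
  rownames(records) <- NULL

  report <- NULL
  if (length(unique(records$group[!is.na(records$group)])) >= 2) {
    report <- compare_groups(records, m = m,
                             statistic = config$stats$statistic,
                             tail = config$stats$tail, seed = seed,
                             n_workers = n_workers,
                             ci_level = config$stats$ci_level)
  } else {
    warning("fewer than two groups; statistics skipped")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    if (!is.null(report)) {
      utils::write.csv(report, file.path(out_dir, "report.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(seed = seed, m = m, config_hash = config_hash(config),
             report = report),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  list(records = records, report = report, errors = errors)
}
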