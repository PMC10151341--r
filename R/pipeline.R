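#' Full pipeline configuration
#'
#' Bundles the stage configurations and the master seed; serializable to a
#' single YAML document with [write_pipeline_config()].
#'
#' @param preprocess A [preprocess_config()].
#' @param imf An [imf_config()].
#' @param nipple A [nipple_config()].
#' @param clahe A [clahe_config()].
#' @param training A [training_config()].
#' @param eval An [eval_config()].
#' @param seed Master seed for the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            imf = imf_config(), nipple = nipple_config(),
                            clahe = clahe_config(), training = training_config(),
                            eval = eval_config(), seed = 1L) {
  stopifnot(inherits(preprocess, "preprocess_config"), inherits(imf, "imf_config"),
            inherits(nipple, "nipple_config"), inherits(clahe, "clahe_config"),
            inherits(training, "training_config"), inherits(eval, "eval_config"))
  structure(list(preprocess = preprocess, imf = imf, nipple = nipple,
                 clahe = clahe, training = training, eval = eval,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Quarter-scale pipeline configuration
#'
#' Convenience configuration matched to the default phantom geometry
#' (1024 x 682 images, 64-pixel ROIs): the working scale for tests and
#' examples.
#'
#' @param seed Master seed.
#' @param ... Overrides forwarded to [pipeline_config()].
#' @export
pipeline_config_quarter <- function(seed = 1L, ...) {
  pipeline_config(
    preprocess = preprocess_config(resize_cols = 682L, resize_rows = 1024L),
    imf = imf_config(roi_size = 64L),
    nipple = nipple_config(roi_size = 64L),
    seed = seed, ...)
}

strip_config <- function(x) {
  x <- unclass(x)
  lapply(x, function(v) if (is.list(v)) strip_config(v) else v)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a validated [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(strip_config(cfg), path)
  invisible(path)
}

call_config <- function(fn, stored) {
  args <- stored[intersect(names(stored), names(formals(fn)))]
  do.call(fn, args)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    preprocess = call_config(preprocess_config, raw$preprocess %||% list()),
    imf = call_config(imf_config, raw$imf %||% list()),
    nipple = call_config(nipple_config, raw$nipple %||% list()),
    clahe = call_config(clahe_config, raw$clahe %||% list()),
    training = call_config(training_config, raw$training %||% list()),
    eval = call_config(eval_config, raw$eval %||% list()),
    seed = raw$seed %||% 1L
  )
}

read_labels_file <- function(path) {
  lb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "imf_label", "nipple_label")
  if (!all(need %in% names(lb))) {
    abort(sprintf("labels file must have columns %s", paste(need, collapse = ", ")),
          class = "mammoqc_io_error")
  }
  lb$imf_label <- label_code(lb$imf_label)
  lb$nipple_label <- label_code(lb$nipple_label)
  lb
}

#' Run the end-to-end positioning-quality workflow
#'
#' Reads every PNG in `image_dir`, standardizes it, detects the
#' inframammary-fold and nipple regions, CLAHE-enhances the patches, and
#' cross-validates a classifier per part against the labels in
#' `labels_file` (CSV with columns `image_id`, `imf_label`, `nipple_label`;
#' labels as 1/2/3 or poor/average/excellent; `image_id` may be the file
#' name with or without extension). Images without a label are skipped with
#' a warning; failed nipple detections are excluded from that part's
#' cross-validation with a logged count. The run is reproducible from the
#' configuration seed.
#'
#' @param image_dir Directory of PNG mammograms.
#' @param labels_file Path to the labels CSV.
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory; when given, enhanced patches
#'   (8-bit PNG), per-image JSON sidecars, the metric report and a manifest
#'   (config, seed, input and patch MD5 hashes) are written there.
#' @return A list of class `pipeline_run`: `detections` (per-image tibble),
#'   `cv` (list with `imf` and `nipple` [cross_validate()] results),
#'   `skipped`, `n_nonconverged_imf`, `n_failed_nipple`, `manifest`.
#' @export
run_pipeline <- function(image_dir, labels_file, cfg = pipeline_config_quarter(),
                         out_dir = NULL) {
  files <- sort(list.files(image_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) {
    abort(sprintf("no PNG images found in %s", image_dir), class = "mammoqc_io_error")
  }
  labels <- read_labels_file(labels_file)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "patches"), recursive = TRUE, showWarnings = FALSE)
  }

  det_rows <- list(); patches <- list(imf = list(), nipple = list())
  patch_labels <- list(imf = integer(), nipple = integer())
  skipped <- character(); n_nonconv <- 0L; n_failed_nipple <- 0L
  patch_files <- character()

  for (f in files) {
    id <- sub("\\.png$", "", basename(f))
    hit <- which(labels$image_id %in% c(id, basename(f)))
    if (length(hit) == 0L) {
      warn(sprintf("no label for image %s; skipped", id))
      skipped <- c(skipped, id)
      next
    }
    lab <- labels[hit[1], ]
    img <- standardize(read_mammogram(f), cfg$preprocess)

    imf_det <- withCallingHandlers(
      detect_imf(img, cfg$imf),
      mammoqc_nonconvergence = function(w) {
        n_nonconv <<- n_nonconv + 1L
        message(sprintf("[imf] %s: %s", id, conditionMessage(w)))
        rlang::cnd_muffle(w)
      })
    imf_patch <- enhance_clahe(imf_det$patch, cfg$clahe)
    patches$imf[[length(patches$imf) + 1L]] <- imf_patch
    patch_labels$imf <- c(patch_labels$imf, lab$imf_label)

    nip_det <- tryCatch(detect_nipple(img, cfg$nipple), error = function(e) {
      n_failed_nipple <<- n_failed_nipple + 1L
      message(sprintf("[nipple] %s: detection failed: %s", id, conditionMessage(e)))
      NULL
    })
    if (!is.null(nip_det)) {
      nip_patch <- enhance_clahe(nip_det$patch, cfg$clahe)
      patches$nipple[[length(patches$nipple) + 1L]] <- nip_patch
      patch_labels$nipple <- c(patch_labels$nipple, lab$nipple_label)
    }

    row <- dplyr::bind_cols(tibble::tibble(image_id = id), tidy(imf_det))
    if (!is.null(nip_det)) {
      nt <- tidy(nip_det)
      names(nt) <- paste0("nipple_", names(nt))
      row <- dplyr::bind_cols(row, nt)
    }
    det_rows[[length(det_rows) + 1L]] <- row

    if (!is.null(out_dir)) {
      pf <- file.path(out_dir, "patches", sprintf("%s_imf.png", id))
      write_image_png(imf_patch, pf)
      patch_files <- c(patch_files, pf)
      sidecar <- list(image_id = id, imf = tidy(imf_det))
      if (!is.null(nip_det)) {
        pf2 <- file.path(out_dir, "patches", sprintf("%s_nipple.png", id))
        write_image_png(nip_patch, pf2)
        patch_files <- c(patch_files, pf2)
        sidecar$nipple <- tidy(nip_det)
      }
      jsonlite::write_json(sidecar, file.path(out_dir, "patches", sprintf("%s.json", id)),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if (length(det_rows) == 0L) {
    abort("no usable images (all skipped for missing labels)", class = "mammoqc_io_error")
  }

  cv <- list()
  for (part in c("imf", "nipple")) {
    dat <- tibble::tibble(patch = patches[[part]], label = patch_labels[[part]])
    tcfg <- cfg$training; tcfg$seed <- cfg$seed
    ecfg <- cfg$eval; ecfg$seed <- cfg$seed
    cv[[part]] <- cross_validate(dat, ecfg, tcfg)
  }

  manifest <- list(
    package = as.character(utils::packageVersion("mammoqc")),
    seed = cfg$seed,
    config = strip_config(cfg),
    inputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    n_images = length(det_rows), n_skipped = length(skipped),
    n_nonconverged_imf = n_nonconv, n_failed_nipple = n_failed_nipple
  )
  if (!is.null(out_dir)) {
    manifest$patches <- lapply(sort(patch_files), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
    report <- list(
      confusion = lapply(cv, function(r) unclass(r$confusion)),
      metrics = lapply(cv, function(r) as.list(glance(r)))
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(detections = dplyr::bind_rows(det_rows), cv = cv, skipped = skipped,
         n_nonconverged_imf = n_nonconv, n_failed_nipple = n_failed_nipple,
         manifest = manifest),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d image(s), %d skipped, %d non-converged IMF, %d failed nipple\n",
              x$manifest$n_images, x$manifest$n_skipped,
              x$n_nonconverged_imf, x$n_failed_nipple))
  for (part in names(x$cv)) {
    cat(sprintf("-- %s --\n", part)); print(x$cv[[part]])
  }
  invisible(x)
}
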