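#' Read and write PET images as NIfTI-1
#'
#' NIfTI-1 is the canonical on-disk image format: float32 voxels, spacings in
#' mm in the header, values in kBq/ml. Reading recovers the voxel array,
#' spacing and origin; the description field records the units.
#'
#' @param img A [pet_image()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_pet_image`: a [pet_image()]; `write_pet_image`: `path`,
#'   invisibly.
#' @export
write_pet_image <- function(img, path) {
  n <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(n) <- img$spacing
  RNifti::writeNifti(n, path, datatype = "float")
  meta <- img$meta
  meta$origin <- img$origin
  meta$units <- "kBq/ml"
  jsonlite::write_json(sanitize_meta(meta), paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

sanitize_meta <- function(m) {
  lapply(m, function(x) {
    if (inherits(x, c("fill_spec", "recon_config", "scanner_profile", "isotope_spec"))) {
      sanitize_meta(unclass(x))
    } else if (is.list(x)) sanitize_meta(x) else x
  })
}

#' @rdname write_pet_image
#' @export
read_pet_image <- function(path) {
  if (!file.exists(path)) stop_nemaiq("format", "file not found: %s", path)
  n <- tryCatch(RNifti::readNifti(path),
                error = function(e) stop_nemaiq("format", "cannot read %s: %s",
                                                path, conditionMessage(e)))
  if (length(dim(n)) != 3) stop_nemaiq("format", "%s is not a 3D volume", path)
  sp <- RNifti::pixdim(n)[1:3]
  meta <- list()
  origin <- NULL
  side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$origin)) origin <- as.numeric(meta$origin)
  }
  pet_image(array(as.numeric(n), dim(n)), sp, origin = origin, meta = meta)
}

#' Serialise phantom, fill and reconstruction to a YAML block
#'
#' Writes (and reads back) a YAML description with keys `spheres`, `body`,
#' `lung_insert`, `fill` and `recon`, so a phantom study is fully described
#' by one small text file.
#'
#' @param spec A [nema_phantom()].
#' @param fill Optional [fill_spec()].
#' @param recon Optional [recon_config()].
#' @param path YAML file path.
#' @return `write_phantom_config`: `path`, invisibly. `read_phantom_config`:
#'   list with `spec`, `fill` (or `NULL`), `recon` (or `NULL`).
#' @export
write_phantom_config <- function(spec, path, fill = NULL, recon = NULL) {
  blk <- list(
    spheres = lapply(seq_len(nrow(spec$spheres)), function(i) {
      s <- spec$spheres[i, ]
      list(diameter = s$diameter, centre = c(s$cx, s$cy, s$cz))
    }),
    body = list(half_axes = spec$body$half_axes, length = spec$body$length),
    lung_insert = list(radius = spec$lung$radius, length = spec$lung$length)
  )
  if (!is.null(fill)) {
    blk$fill <- list(sphere = fill$sphere, background = fill$background,
                     fill_time = fill$fill_time, scan_time = fill$scan_time,
                     isotope = list(name = fill$isotope$name,
                                    half_life = fill$isotope$half_life,
                                    mean_positron_range = fill$isotope$mean_positron_range),
                     residual_factor = fill$residual_factor)
  }
  if (!is.null(recon)) {
    blk$recon <- list(family = recon$family, gaussian_fwhm = recon$gaussian_fwhm,
                      beta = recon$beta, label = recon$label)
  }
  yaml::write_yaml(blk, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  blk <- yaml::read_yaml(path)
  spheres <- do.call(rbind, lapply(blk$spheres, function(s) {
    data.frame(diameter = s$diameter, cx = s$centre[1], cy = s$centre[2],
               cz = s$centre[3])
  }))
  spec <- structure(list(spheres = spheres[order(-spheres$diameter), ],
                         body = list(half_axes = unlist(blk$body$half_axes),
                                     length = blk$body$length),
                         lung = list(radius = blk$lung_insert$radius,
                                     length = blk$lung_insert$length)),
                    class = "nema_phantom")
  rownames(spec$spheres) <- NULL
  fill <- NULL
  if (!is.null(blk$fill)) {
    iso <- isotope_spec(blk$fill$isotope$name, blk$fill$isotope$half_life,
                        blk$fill$isotope$mean_positron_range)
    fill <- fill_spec(blk$fill$sphere, blk$fill$background, blk$fill$fill_time,
                      blk$fill$scan_time, iso, blk$fill$residual_factor)
  }
  recon <- NULL
  if (!is.null(blk$recon)) {
    recon <- recon_config(blk$recon$family,
                          gaussian_fwhm = blk$recon$gaussian_fwhm,
                          beta = blk$recon$beta, label = blk$recon$label)
  }
  list(spec = spec, fill = fill, recon = recon)
}

#' Read a run configuration
#'
#' YAML configuration for [run_experiment()]. Recognised blocks: `experiment`
#' (`optimise`, `multicentre`, `clinical` or `contrast_sweep`), `seed`,
#' `fill` (`sphere`, `background`), `scanner` (passed to
#' [scanner_profile()]), `recon_grid` (`beta`, `fwhm`), plus per-experiment
#' options (`n_scanners`, `bias_sd`, `ratios`, `n_lesions`). Missing fields
#' fall back to the defaults of the corresponding constructors.
#'
#' @param path YAML file path.
#' @return Named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment) ||
      !cfg$experiment %in% c("optimise", "multicentre", "clinical", "contrast_sweep")) {
    stop_nemaiq("invalid_config", "experiment must be one of optimise, multicentre, clinical, contrast_sweep")
  }
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (cfg$seed != as.integer(cfg$seed)) stop_nemaiq("invalid_config", "seed must be an integer")
  # YAML sequences of mixed int/real arrive as lists; flatten numeric grids
  for (blk in c("recon_grid")) {
    if (!is.null(cfg[[blk]])) cfg[[blk]] <- lapply(cfg[[blk]], function(x) as.numeric(unlist(x)))
  }
  if (!is.null(cfg$ratios)) cfg$ratios <- as.numeric(unlist(cfg$ratios))
  structure(cfg, class = "run_config")
}

cfg_fill <- function(cfg) {
  f <- cfg$fill
  fill_spec(f$sphere %||% 19.9, f$background %||% 2.4)
}

cfg_scanner <- function(cfg) {
  s <- cfg$scanner
  do.call(scanner_profile, modifyList(
    list(), s[intersect(names(s), names(formals(scanner_profile)))] %||% list()))
}

fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
}

write_report_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run a full experiment from a configuration
#'
#' Chains simulation, segmentation, metric extraction and the downstream
#' stage of the chosen experiment, writing CSV/JSON reports and a manifest
#' into `out_dir`. Rerunning with an identical configuration and seed
#' reproduces every output byte for byte.
#'
#' Experiments:
#' \describe{
#'   \item{optimise}{one scanner, PSF filter-width grid and BPL beta grid;
#'     writes `iq_results.csv` and `ptv_results.csv`.}
#'   \item{multicentre}{simulated scanner ensemble; writes `iq_results.csv`,
#'     `limits.csv` and `compliance.json`.}
#'   \item{clinical}{synthetic lesion cohort, Bland-Altman of every BPL
#'     reconstruction against the PSF reference; writes `lesions.csv` and
#'     `ba_report.json`.}
#'   \item{contrast_sweep}{sphere-to-background ratio sweep; writes
#'     `contrast_sweep.csv` recording per-sphere segmentation success.}
#' }
#'
#' @param config A `run_config` from [read_run_config()], or a path to a
#'   YAML file, or a named list in the same shape.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly; stage results in the
#'   `results` attribute.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) config$seed <- 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- nema_phantom()
  fill <- cfg_fill(config)
  scanner <- cfg_scanner(config)
  seed <- as.integer(config$seed)
  files <- list(); results <- list()

  if (config$experiment == "optimise") {
    ws <- config$recon_grid$fwhm %||% c(2, 4, 5, 6.4)
    betas <- config$recon_grid$beta %||% seq(200, 1200, by = 200)
    recons <- c(lapply(ws, function(w) recon_config("psf", gaussian_fwhm = w)),
                lapply(betas, function(b) recon_config("bpl", beta = b)))
    iq_rows <- list(); ptv_rows <- list()
    base <- resolution_blur(rasterize_phantom(spec, fill, scanner$voxel_spacing),
                            fill$isotope, scanner$psf_fwhm)
    for (rc in recons) {
      img <- simulate_acquisition(spec, fill, scanner, rc, seed = seed, base = base)
      iq <- analyse_iq(img, spec, fill)
      iq_rows[[rc$label]] <- as.data.frame(iq)
      masks <- segment_spheres(img, spec)
      for (m in masks) {
        pr <- tryCatch(extract_profiles(img, m), nemaiq_error = function(e) NULL)
        pv <- if (is.null(pr)) NULL else mean_ptv(pr)
        ptv_rows[[length(ptv_rows) + 1]] <- data.frame(
          label = rc$label, diameter = m$diameter,
          shape = if (is.null(pv)) "profiles_unavailable" else pv$shape,
          ptv_mean = if (is.null(pv) || !pv$measurable) NA_real_ else pv$mean,
          ptv_sd = if (is.null(pv) || !pv$measurable) NA_real_ else pv$sd)
      }
    }
    files$iq_results <- write_report_csv(do.call(rbind, c(iq_rows, make.row.names = FALSE)),
                                         file.path(out_dir, "iq_results.csv"))
    files$ptv_results <- write_report_csv(do.call(rbind, ptv_rows),
                                          file.path(out_dir, "ptv_results.csv"))
    results$iq <- iq_rows; results$ptv <- ptv_rows
  } else if (config$experiment == "multicentre") {
    n <- config$n_scanners %||% 6
    ens <- simulate_ensemble(n, spec, fill, scanner,
                             jitter = list(bias_sd = config$bias_sd %||% 0.03),
                             seed = seed)
    iqs <- lapply(ens$images, function(im) analyse_iq(im, spec, fill, battery = FALSE))
    summ <- aggregate_iq(iqs)
    lims <- derive_limits(summ)
    comp <- check_compliance(iqs[[1]], lims)
    files$iq_results <- write_report_csv(
      do.call(rbind, c(lapply(iqs, as.data.frame), make.row.names = FALSE)),
      file.path(out_dir, "iq_results.csv"))
    files$limits <- write_report_csv(as.data.frame(lims), file.path(out_dir, "limits.csv"))
    jsonlite::write_json(comp, file.path(out_dir, "compliance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files$compliance <- file.path(out_dir, "compliance.json")
    results$summary <- summ; results$limits <- lims; results$compliance <- comp
  } else if (config$experiment == "clinical") {
    lesions <- generate_synthetic_lesions(n_lesions = config$n_lesions %||% 24,
                                          seed = seed)
    ba <- compare_to_reference(lesions)
    files$lesions <- write_report_csv(lesions, file.path(out_dir, "lesions.csv"))
    rep <- lapply(ba, function(x) list(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                                       loa = x$loa, n_outside = x$n_outside, p = x$p))
    jsonlite::write_json(rep, file.path(out_dir, "ba_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files$ba_report <- file.path(out_dir, "ba_report.json")
    results$bland_altman <- ba
  } else { # contrast_sweep
    ratios <- config$ratios %||% c(2, 5, 8, 10, 15)
    rows <- list()
    for (rt in ratios) {
      f <- fill_spec(fill$background * rt, fill$background)
      img <- simulate_acquisition(spec, f, scanner,
                                  recon_config("conventional", 6.4), seed = seed)
      for (i in seq_len(nrow(spec$spheres))) {
        ok <- tryCatch({segment_sphere(img, spec, i); TRUE},
                       nemaiq_segmentation_failure = function(e) FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          ratio = rt, diameter = spec$spheres$diameter[i], segmented = ok)
      }
    }
    files$contrast_sweep <- write_report_csv(do.call(rbind, rows),
                                             file.path(out_dir, "contrast_sweep.csv"))
    results$sweep <- do.call(rbind, rows)
  }

  manifest <- list(experiment = config$experiment, seed = seed,
                   package_version = as.character(utils::packageVersion("nemaiq")),
                   config = unclass(config),
                   outputs = vapply(files, basename, character(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$manifest <- file.path(out_dir, "manifest.json")
  attr(files, "results") <- results
  invisible(files)
}
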