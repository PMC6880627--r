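#' Default study configuration
#'
#' Every constant of the phantom study, priors, sampler and baseline
#' fitter, with defaults equal to the published protocol values
#' (SNR 15, dt 0.012/0.017 min, T 3 min, 4000-step chains with 1000
#' burn-in, 100-start NLLS with the standard physiological bounds, 20
#' Monte-Carlo realisations).
#'
#' @return Nested named list; see [load_config()] for the file format.
#' @export
default_config <- function() {
  list(
    phantom = list(conditions = c("rest", "stress", "stress_defect"),
                   dt_stress = 0.012, dt_rest = 0.017, duration = 3,
                   snr = 15, tau0 = 0, hct = 0.45),
    priors = list(fb_var = 0.1, ps_var = 0.1, vp_max = 0.3, ve_max = 0.4,
                  sigma2_shape = 0.001, sigma2_scale = 0.001,
                  spatial_rate = 5, spatial_norm = 1,
                  alpha_b_support = c(0.001, 7),
                  alpha_ps_support = c(0.001, 5),
                  nonhier_fb_mean = 3.5, nonhier_ps_mean = 1.0,
                  nonhier_var = 0.2),
    sampler = list(steps = 4000L, burn_in = 1000L, chains = 1L,
                   tune_interval = 50L),
    nlls = list(n_starts = 100L, tol = 1e-8, max_iter = 1000L,
                lower = c(fb = 0.001, vp = 0.001, ve = 0.001, ps = 0.001),
                upper = c(fb = 6.0, vp = 0.3, ve = 0.4, ps = 4.0)),
    evaluation = list(n_realisations = 20L,
                      methods = c("bayes", "nlls1", "nlls100")),
    seed = 1L,
    out_dir = ".")
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.list(user[[nm]]))
      stop("configuration key ", here, " must be a mapping", call. = FALSE)
    defaults[[nm]] <- if (is.list(defaults[[nm]]))
      merge_config(defaults[[nm]], user[[nm]], here)
    else user[[nm]]
  }
  defaults
}

#' Load (or save) a study configuration from YAML
#'
#' Unspecified fields take the published-protocol defaults of
#' [default_config()]; unknown keys raise an error so typos cannot pass
#' silently. Basic cross-field validity (positive `dt`, `steps > burn_in`,
#' bounds ordered) is enforced.
#'
#' @param path YAML file path (for `load_config`, may be `NULL` for pure
#'   defaults).
#' @return The resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- merge_config(cfg, user)
  }
  # YAML mappings and sequences come back as lists; restore the canonical
  # vector forms (and bound names, which YAML sequences drop)
  for (f in c("lower", "upper")) {
    v <- unlist(cfg$nlls[[f]])
    if (is.null(names(v))) names(v) <- c("fb", "vp", "ve", "ps")
    cfg$nlls[[f]] <- v
  }
  for (f in c("alpha_b_support", "alpha_ps_support"))
    cfg$priors[[f]] <- unname(unlist(cfg$priors[[f]]))
  cfg$phantom$conditions <- unname(unlist(cfg$phantom$conditions))
  cfg$evaluation$methods <- unname(unlist(cfg$evaluation$methods))
  cfg$sampler$steps <- as.integer(cfg$sampler$steps)
  cfg$sampler$burn_in <- as.integer(cfg$sampler$burn_in)
  if (cfg$sampler$steps <= cfg$sampler$burn_in)
    stop("sampler.steps must exceed sampler.burn_in", call. = FALSE)
  if (cfg$phantom$snr <= 0) stop("phantom.snr must be positive", call. = FALSE)
  if (cfg$phantom$dt_stress <= 0 || cfg$phantom$dt_rest <= 0)
    stop("phantom sampling intervals must be positive", call. = FALSE)
  lo <- unlist(cfg$nlls$lower); hi <- unlist(cfg$nlls$upper)
  if (any(lo >= hi)) stop("nlls.lower must be below nlls.upper", call. = FALSE)
  cfg
}

#' @param cfg Configuration list.
#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the resolved configuration, seeds and package version beside a
#' run's outputs so the run can be reproduced exactly.
#'
#' @param cfg Resolved configuration list.
#' @param path Output JSON path.
#' @param extra Optional named list of additional fields (e.g. seeds
#'   actually consumed).
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  manifest <- c(list(package = "perfusr",
                     version = as.character(utils::packageVersion("perfusr")),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     config = cfg), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read or write a dynamic image series
#'
#' Series are stored as NIfTI volumes with axis order `(t, y, x)` recorded
#' in a JSON sidecar (`<stem>.json`); masks as separate binary NIfTI
#' volumes (`<stem>_mask.nii.gz`). The sidecar's declared axis order is
#' checked on read and a mismatch is an error, never a silent
#' transposition. All values are promoted to double precision internally.
#'
#' @param path NIfTI path of the series (the mask and sidecar paths are
#'   derived from it).
#' @return `read_series` returns a list with `noisy` (the `(t, y, x)`
#'   array), `mask`, `times`, `dt` and any extra fields stored in the
#'   sidecar (`tau0`, `hct`).
#' @export
read_series <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  sidecar <- paste0(stem, ".json")
  mask_path <- paste0(stem, "_mask.nii.gz")
  if (!file.exists(sidecar))
    stop("missing sidecar ", sidecar, " (expected axis-order metadata)",
         call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$axis_order, c("t", "y", "x")))
    stop("series at ", path, " declares axis order ",
         paste(meta$axis_order, collapse = ","),
         "; expected t,y,x - re-export the series rather than transposing",
         call. = FALSE)
  if (!file.exists(mask_path))
    stop("missing mask volume ", mask_path,
         " (write one with write_series(), a binary (y, x) NIfTI)",
         call. = FALSE)
  arr <- array(as.double(RNifti::readNifti(path)),
               dim = dim(RNifti::readNifti(path)))
  mask <- matrix(as.double(RNifti::readNifti(mask_path)) > 0.5,
                 nrow = dim(arr)[2L])
  dt <- meta$dt
  list(noisy = arr, mask = mask, dt = dt,
       times = seq(0, by = dt, length.out = dim(arr)[1L]),
       tau0 = meta$tau0 %||% 0, hct = meta$hct %||% 0.45)
}

#' @param series List with `noisy` (or `clean`) array, `mask`, `dt` and
#'   optional `tau0`, `hct` -- e.g. a [simulate_series()] result.
#' @rdname read_series
#' @export
write_series <- function(series, path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  arr <- series$noisy %||% series$clean
  mask <- series$mask %||% series$truth$mask
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  RNifti::writeNifti(RNifti::asNifti(mask * 1), paste0(stem, "_mask.nii.gz"))
  jsonlite::write_json(list(axis_order = c("t", "y", "x"), dt = series$dt,
                            tau0 = series$tau0 %||% 0,
                            hct = series$hct %||% 0.45),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write parameter maps
#'
#' Writes each map both as a NIfTI volume (`<dir>/<name>.nii.gz`) and
#' together as one long-format CSV (`<dir>/maps.csv` with columns
#' `parameter, row, col, value`).
#'
#' @param maps Named list of numeric matrices.
#' @param dir Output directory (created if needed).
#' @export
write_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (nm in names(maps)) {
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]]),
                       file.path(dir, paste0(nm, ".nii.gz")))
    m <- maps[[nm]]
    rows[[nm]] <- data.frame(parameter = nm, row = c(row(m)), col = c(col(m)),
                             value = c(m))
  }
  write.csv(do.call(rbind, rows), file.path(dir, "maps.csv"),
            row.names = FALSE)
  invisible(dir)
}
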