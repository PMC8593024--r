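#' Synthesize a dynamic PET-like activity series from a seeding run
#'
#' Forward model for already-reconstructed dynamic PET frames of
#' radiolabeled cells in the bioreactor: per 5-min frame, voxel activity is
#' (deposited + suspended cells) x activity per cell x the physical decay
#' factor of fluorine-18, plus a circulating free-tracer background in
#' open voxels during the perfusion phase; adherent-cell activity leaks
#' slowly during washout (single-exponential efflux); the image is blurred
#' with an isotropic Gaussian PSF and optionally Poisson-resampled.
#' Scanner physics (attenuation, randoms, dead time, reconstruction) is
#' not modeled.
#'
#' @param seeding_result a `seeding_result` with frame snapshots.
#' @param domain the matching `simulation_domain`.
#' @param activity_per_cell_Bq label activity per cell at t = 0, Bq;
#'   `NULL` (default) derives it as the 1 MBq label offer per 2e5 cells
#'   (5 Bq/cell) times `uptake_fraction`.
#' @param uptake_fraction fraction of the offered label taken up per cell
#'   (free model parameter, default 0.05).
#' @param free_tracer_fraction circulating unbound-tracer background as a
#'   fraction of the suspension's cell-bound activity concentration.
#' @param leak_per_min washout-phase efflux rate of adherent-cell
#'   activity, 1/min (small; produces the observed slow decline to a
#'   plateau).
#' @param psf_mm Gaussian point-spread-function sigma, mm (0 disables).
#' @param noise `"none"` or `"poisson"`.
#' @param counts_per_MBq Poisson count scale (events per MBq per voxel per
#'   frame) when `noise = "poisson"`.
#' @param seed RNG seed for the noise model.
#' @return An `activity_series` object: list of 3-D frame arrays (MBq per
#'   voxel), frame timing, decay metadata.
#' @export
synthesize_pet <- function(seeding_result, domain,
                           activity_per_cell_Bq = NULL,
                           uptake_fraction = 0.05,
                           free_tracer_fraction = 0.1,
                           leak_per_min = 0.004,
                           psf_mm = 0.8, noise = c("none", "poisson"),
                           counts_per_MBq = 1e4, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(activity_per_cell_Bq)) {
    activity_per_cell_Bq <- (1e6 / 2e5) * uptake_fraction
  }
  stopifnot(inherits(seeding_result, "seeding_result"),
            activity_per_cell_Bq >= 0, free_tracer_fraction >= 0,
            psf_mm >= 0, leak_per_min >= 0)
  frames <- seeding_result$frames
  frames <- frames[!vapply(frames, is.null, logical(1))]
  if (!length(frames)) abort("seeding result carries no frame snapshots")
  h <- seeding_result$voxel_mm
  dm <- dim(domain$labels)
  half_life <- perfuseed_constants$f18_half_life_min
  lambda <- log(2) / half_life
  a_cell_MBq <- activity_per_cell_Bq * 1e-6
  w <- seeding_result$particle_weight_cells
  conc_cells_mm3 <- seeding_result$suspension$concentration_cells_ml * 1e-3
  T_seed <- seeding_result$protocol$seeding_duration_min
  opn <- open_mask(domain)

  out <- with_seed(seed, lapply(frames, function(fr) {
    t_min <- fr$t_min
    decay <- exp(-lambda * t_min)
    leak <- if (t_min > T_seed) exp(-leak_per_min * (t_min - T_seed)) else 1
    act <- (fr$deposited * leak + fr$suspended) * w * a_cell_MBq * decay
    if (t_min <= T_seed && free_tracer_fraction > 0) {
      bg <- free_tracer_fraction * conc_cells_mm3 * h^3 * a_cell_MBq * decay
      act[opn] <- act[opn] + bg
    }
    if (psf_mm > 0) {
      act <- gaussian_smooth3(act, sigma = psf_mm / h)
      act[act < 0] <- 0
    }
    if (noise == "poisson") {
      sc <- counts_per_MBq
      act <- array(stats::rpois(length(act), act * sc) / sc, dim(act))
    }
    act
  }))

  structure(list(
    frames = out,
    t_min = vapply(frames, `[[`, numeric(1), "t_min"),
    frame_min = seeding_result$protocol$frame_min,
    t0 = 0,
    decay_corrected = FALSE,
    isotope_half_life_min = half_life,
    psf_mm = psf_mm, noise_model = noise,
    voxel_mm = h
  ), class = "activity_series")
}

#' Construct an activity series from raw frame arrays
#'
#' Low-level constructor, useful for synthetic test inputs.
#'
#' @param frames list of 3-D arrays, MBq per voxel.
#' @param t_min frame times (min), same length.
#' @param frame_min frame duration, min.
#' @param voxel_mm voxel size, mm.
#' @param decay_corrected logical flag.
#' @return An `activity_series`.
#' @export
activity_series <- function(frames, t_min, frame_min = 5, voxel_mm = 0.5,
                            decay_corrected = FALSE) {
  stopifnot(length(frames) == length(t_min))
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    abort("activities must be nonnegative")
  }
  structure(list(frames = frames, t_min = t_min, frame_min = frame_min,
                 t0 = 0, decay_corrected = decay_corrected,
                 isotope_half_life_min = perfuseed_constants$f18_half_life_min,
                 psf_mm = 0, noise_model = "none", voxel_mm = voxel_mm),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf(
    "<activity_series> %d frames x %s voxels, %g-min framing, %sdecay-corrected\n",
    length(x$frames), paste(dim(x$frames[[1]]), collapse = " x "),
    x$frame_min, if (x$decay_corrected) "" else "not "))
  invisible(x)
}

#' Correct an activity series for physical decay
#'
#' Scales frame k by \eqn{\exp(+\lambda t_k)} with
#' \eqn{\lambda = \ln 2 / T_{1/2}} (fluorine-18, 109.77 min). Refuses to
#' correct twice. [decay_uncorrect()] inverts the operation.
#'
#' @param series an `activity_series`.
#' @return the corrected series, `decay_corrected` flag set.
#' @export
decay_correct <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  if (series$decay_corrected) abort("series is already decay-corrected")
  lambda <- log(2) / series$isotope_half_life_min
  series$frames <- Map(function(f, t) f * exp(lambda * t), series$frames,
                       series$t_min)
  series$decay_corrected <- TRUE
  series
}

#' @rdname decay_correct
#' @export
decay_uncorrect <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  if (!series$decay_corrected) abort("series is not decay-corrected")
  lambda <- log(2) / series$isotope_half_life_min
  series$frames <- Map(function(f, t) f * exp(-lambda * t), series$frames,
                       series$t_min)
  series$decay_corrected <- FALSE
  series
}

# ROI masks: whole scaffold bounding box, axial thirds, outflow tract
roi_masks <- function(domain) {
  dm <- dim(domain$labels)
  zr <- domain$scaffold_z; xr <- domain$scaffold_x; yr <- domain$scaffold_y
  box <- function(z1, z2) {
    m <- array(FALSE, dm)
    m[xr[1]:xr[2], yr[1]:yr[2], z1:z2] <- TRUE
    m
  }
  cuts <- floor(seq(zr[1] - 1, zr[2], length.out = 4))
  outfl <- array(FALSE, dm)
  if (zr[2] + 1L <= dm[3]) outfl[, , (zr[2] + 1L):dm[3]] <- TRUE
  list(
    whole  = box(zr[1], zr[2]),
    upper  = box(cuts[1] + 1L, cuts[2]),
    middle = box(cuts[2] + 1L, cuts[3]),
    lower  = box(cuts[3] + 1L, cuts[4]),
    outflow = outfl
  )
}

#' ROI time-activity curves
#'
#' Sums each frame over the standard regions of interest: the whole
#' scaffold bounding box, its upper (inlet-proximal), middle and lower
#' axial thirds, and the outflow tract (everything downstream of the
#' scaffold, tracking sedimentation outside the block).
#'
#' @param series an `activity_series` on the domain grid.
#' @param domain the matching `simulation_domain`.
#' @return A `roi_table` tibble: `frame`, `t_min`, and MBq columns
#'   `whole`, `upper`, `middle`, `lower`, `outflow`.
#' @export
roi_timecourses <- function(series, domain) {
  stopifnot(inherits(series, "activity_series"))
  if (!identical(dim(series$frames[[1]]), dim(domain$labels))) {
    abort("activity series and domain grids do not match")
  }
  rois <- roi_masks(domain)
  rows <- purrr::imap(series$frames, function(f, k) {
    sums <- vapply(rois, function(m) sum(f[m]), numeric(1))
    tibble::tibble(frame = k, t_min = series$t_min[k],
                   whole = sums[["whole"]], upper = sums[["upper"]],
                   middle = sums[["middle"]], lower = sums[["lower"]],
                   outflow = sums[["outflow"]])
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("roi_table", class(out)))
}

#' Enrichment and homogeneity time courses
#'
#' Per frame: total scaffold activity (enrichment, MBq) and the axial
#' Hoover coefficient of the frame's scaffold activity distribution. The
#' 60-min values are the headline readouts used to compare bioreactor
#' configurations.
#'
#' @param series an `activity_series` (decay-corrected or not; the
#'   homogeneity readout defaults to decay-corrected input by convention).
#' @param domain the matching `simulation_domain`.
#' @param planes optional `plane_set` passed to
#'   [axial_distribution_hoover()].
#' @return tibble: `frame`, `t_min`, `enrichment_MBq`, `hoover`.
#' @export
enrichment_and_hoover_timecourse <- function(series, domain, planes = NULL) {
  rois <- roi_masks(domain)
  rows <- purrr::imap(series$frames, function(f, k) {
    hv <- tryCatch(axial_distribution_hoover(f, domain, planes),
                   error = function(e) NA_real_)
    tibble::tibble(frame = k, t_min = series$t_min[k],
                   enrichment_MBq = sum(f[rois$whole]), hoover = hv)
  })
  dplyr::bind_rows(rows)
}

#' Save / load an activity series as 4-D NIfTI
#'
#' @param series an `activity_series`.
#' @param path `.nii` or `.nii.gz` path; a JSON sidecar (same path with
#'   `.json` appended) stores frame timing and decay metadata.
#' @return `save_activity_series` returns `path` invisibly.
#' @export
save_activity_series <- function(series, path) {
  dm <- dim(series$frames[[1]])
  arr <- array(unlist(series$frames), c(dm, length(series$frames)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(series$voxel_mm, 3), series$frame_min * 60)
  RNifti::writeNifti(img, path)
  meta <- list(t_min = series$t_min, frame_min = series$frame_min,
               decay_corrected = series$decay_corrected,
               isotope_half_life_min = series$isotope_half_life_min,
               psf_mm = series$psf_mm, noise_model = series$noise_model,
               voxel_mm = series$voxel_mm)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_activity_series
#' @export
load_activity_series <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) abort("expected a 4-D activity image")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(seq_len(dim(arr)[4]), function(k) arr[, , , k])
  s <- activity_series(frames, meta$t_min, meta$frame_min, meta$voxel_mm,
                       meta$decay_corrected)
  s$psf_mm <- meta$psf_mm; s$noise_model <- meta$noise_model
  s
}
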