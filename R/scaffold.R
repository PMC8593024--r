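#' @importFrom stats rnorm quantile fft sd median cor setNames
#' @importFrom rlang abort warn
NULL

# voxel occupancy codes
SOLID <- 0L
FLUID <- 1L

new_scaffold_volume <- function(occupancy, voxel_mm, pore_scale_mm = NA_real_,
                                seed = NA_integer_, provenance = "synthetic") {
  storage.mode(occupancy) <- "integer"
  stopifnot(length(dim(occupancy)) == 3)
  vol <- structure(
    list(
      occupancy     = occupancy,
      voxel_mm      = voxel_mm,
      dims_mm       = dim(occupancy) * voxel_mm,
      porosity      = mean(occupancy == FLUID),
      pore_scale_mm = pore_scale_mm,
      seed          = seed,
      provenance    = provenance
    ),
    class = "scaffold_volume"
  )
  vol
}

#' @export
print.scaffold_volume <- function(x, ...) {
  cat(sprintf(
    "<scaffold_volume> %d x %d x %d voxels @ %.4g mm (%s)\n  dims %.3g x %.3g x %.3g mm, porosity %.4f, pore scale %.3g mm\n",
    dim(x$occupancy)[1], dim(x$occupancy)[2], dim(x$occupancy)[3],
    x$voxel_mm, x$provenance,
    x$dims_mm[1], x$dims_mm[2], x$dims_mm[3], x$porosity, x$pore_scale_mm
  ))
  invisible(x)
}

# periodic separable Gaussian smoothing via FFT; sigma in voxels
gaussian_smooth3 <- function(x, sigma) {
  d <- dim(x)
  kern1 <- function(n) {
    pos <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-pos^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1]), kern1(d[2])), kern1(d[3]))
  dim(K) <- d
  Re(fft(fft(x) * fft(K), inverse = TRUE)) / prod(d)
}

# vectorized BFS over a logical 3-D mask with 6-neighbour (face) adjacency;
# returns logical array of voxels reachable from `seeds` (linear indices)
flood3d <- function(mask, seeds) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  reach <- logical(length(mask))
  seeds <- seeds[mask[seeds]]
  reach[seeds] <- TRUE
  frontier <- seeds
  # precompute index coordinates lazily via arithmetic
  while (length(frontier)) {
    i0 <- frontier - 1L
    ix <- i0 %% nx
    iy <- (i0 %/% nx) %% ny
    iz <- i0 %/% (nx * ny)
    nbrs <- c(
      frontier[ix > 0L] - 1L,
      frontier[ix < nx - 1L] + 1L,
      frontier[iy > 0L] - nx,
      frontier[iy < ny - 1L] + nx,
      frontier[iz > 0L] - nx * ny,
      frontier[iz < nz - 1L] + nx * ny
    )
    nbrs <- unique(nbrs)
    nbrs <- nbrs[mask[nbrs] & !reach[nbrs]]
    reach[nbrs] <- TRUE
    frontier <- nbrs
  }
  dim(reach) <- d
  reach
}

# does the fluid phase connect the two z-end slices (face adjacency)?
percolates_z <- function(fluid_mask) {
  d <- dim(fluid_mask)
  bottom <- which(as.vector(slice.index(fluid_mask, 3) == 1) & as.vector(fluid_mask))
  if (!length(bottom)) return(FALSE)
  reach <- flood3d(fluid_mask, bottom)
  any(reach[, , d[3]])
}

#' Generate a synthetic porous scaffold volume
#'
#' Produces a voxelized two-phase (solid/fluid) volume emulating a
#' macro-porous bone-substitute block: a seeded Gaussian white-noise field
#' is smoothed with a Gaussian kernel whose width is set by the target
#' pore scale, thresholded at the porosity quantile (top fraction of the
#' field becomes fluid), and repaired for percolation along the
#' longitudinal (z) axis by stepwise threshold relaxation.
#'
#' Defaults correspond to a 10 x 10 x 20 mm cancellous-bone block with
#' 69% porosity and a ~0.1 mm macropore scale, represented at a coarse,
#' desk-resolvable surrogate pore scale of 0.5 mm.
#'
#' @param dims_mm numeric length-3, physical extent in mm.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param target_porosity target fluid volume fraction in (0, 1).
#' @param pore_scale_mm target correlation length of the fluid phase, mm;
#'   must be at least `2 * voxel_mm`.
#' @param seed integer RNG seed; same seed and parameters give a
#'   bit-identical volume.
#' @return A `scaffold_volume` object.
#' @export
generate_scaffold <- function(dims_mm = c(10, 10, 20), voxel_mm = 0.25,
                              target_porosity = 0.69, pore_scale_mm = 0.5,
                              seed = 1L) {
  stopifnot(length(dims_mm) == 3, all(dims_mm > 0), voxel_mm > 0)
  if (!(target_porosity > 0 && target_porosity < 1)) {
    abort("`target_porosity` must lie strictly between 0 and 1.")
  }
  if (pore_scale_mm < 2 * voxel_mm) {
    abort("`pore_scale_mm` must be at least 2 * voxel_mm (resolvable pores).")
  }
  d <- pmax(1L, as.integer(round(dims_mm / voxel_mm)))
  n <- prod(d)
  field <- with_seed(seed, {
    noise <- array(rnorm(n), d)
    gaussian_smooth3(noise, sigma = pore_scale_mm / (2 * voxel_mm))
  })
  ord <- order(field, decreasing = TRUE)   # fluid = highest-field voxels
  k <- max(1L, min(n, as.integer(round(target_porosity * n))))
  occ_for_k <- function(k) {
    occ <- array(SOLID, d)
    occ[ord[seq_len(k)]] <- FLUID
    occ
  }
  occ <- occ_for_k(k)
  step <- max(1L, as.integer(round(0.0025 * n)))
  while (!percolates_z(occ == FLUID)) {
    k2 <- min(n, k + step)
    if (k2 == k || (k2 / n - target_porosity) > 0.02) {
      abort(sprintf(
        "porosity drift exceeds 0.02 during percolation repair (achieved porosity %.4f, target %.4f)",
        k / n, target_porosity
      ))
    }
    k <- k2
    occ <- occ_for_k(k)
  }
  new_scaffold_volume(occ, voxel_mm, pore_scale_mm, as.integer(seed), "synthetic")
}

#' Measure the porosity (fluid volume fraction) of a volume
#'
#' @param vol a `scaffold_volume`.
#' @return fraction of FLUID voxels, in \[0, 1\].
#' @export
measure_porosity <- function(vol) {
  stopifnot(inherits(vol, "scaffold_volume"))
  mean(vol$occupancy == FLUID)
}

#' Save / load a scaffold volume
#'
#' Two on-disk representations are supported: NIfTI (`.nii` / `.nii.gz`,
#' isotropic spacing carried in the header) and a plain-text JSON format
#' (all metadata plus the occupancy array; used for small fixtures).
#' A round trip reproduces occupancy, spacing and dims bit-exactly.
#'
#' @param vol a `scaffold_volume`.
#' @param path output file; extension selects the format when
#'   `format = "auto"` (`.json` vs `.nii`/`.nii.gz`).
#' @param format one of `"auto"`, `"nifti"`, `"json"`.
#' @return `save_volume` returns `path` invisibly; `load_volume` returns a
#'   `scaffold_volume`.
#' @export
save_volume <- function(vol, path, format = c("auto", "nifti", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "scaffold_volume"))
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "nifti"
  if (format == "json") {
    obj <- list(
      container = "perfuseed_scaffold_volume",
      shape = dim(vol$occupancy),
      voxel_mm = vol$voxel_mm,
      pore_scale_mm = vol$pore_scale_mm,
      seed = vol$seed,
      provenance = vol$provenance,
      labels = list(SOLID = SOLID, FLUID = FLUID),
      occupancy = as.integer(vol$occupancy)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    img <- RNifti::asNifti(vol$occupancy * 1L)
    RNifti::pixdim(img) <- rep(vol$voxel_mm, 3)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' @rdname save_volume
#' @export
load_volume <- function(path, format = c("auto", "nifti", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "nifti"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$container, "perfuseed_scaffold_volume")) {
      abort("not a perfuseed scaffold volume JSON file")
    }
    occ <- array(as.integer(obj$occupancy), dim = obj$shape)
    vol <- new_scaffold_volume(occ, obj$voxel_mm,
                               obj$pore_scale_mm %||% NA_real_,
                               obj$seed %||% NA_integer_,
                               obj$provenance %||% "imported")
    return(vol)
  }
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (max(pd) - min(pd) > 1e-6 * max(pd)) {
    abort(sprintf("non-isotropic voxel spacing in %s: %s", path,
                  paste(signif(pd, 6), collapse = " x ")))
  }
  arr <- as.array(img)
  if (length(dim(arr)) != 3) abort("expected a 3-D volume")
  occ <- array(as.integer(arr != 0), dim = dim(arr))
  new_scaffold_volume(occ, pd[1], provenance = "imported")
}
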