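#' Hoover (Robin-Hood) inequality index
#'
#' Half the L1 distance between the shares of a nonnegative quantity and
#' reference (population/volume) shares: with quantities \eqn{v_i} and
#' weights \eqn{w_i},
#' \deqn{H = \tfrac12 \sum_i \left| \frac{v_i w_i}{\sum_j v_j w_j} -
#'   \frac{w_i}{\sum_j w_j} \right|.}
#' 0 means a perfectly even distribution; values approaching 1 mean the
#' whole quantity is concentrated in a vanishing share of the reference
#' mass. With equal weights and one loaded bin out of n, the index equals
#' 1 - 1/n.
#'
#' @param values nonnegative quantities, not all zero.
#' @param weights positive reference weights, same length (default equal).
#' @return a scalar in \[0, 1\].
#' @export
hoover_index <- function(values, weights = NULL) {
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("`values` must be finite and nonnegative")
  }
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values) || any(weights <= 0)) {
    abort("`weights` must be positive and match `values` in length")
  }
  tot <- sum(values * weights)
  if (tot <= 0) abort("Hoover index is undefined for all-zero values")
  sum(abs(values * weights / tot - weights / sum(weights))) / 2
}

#' Evaluation plane set along the flow axis
#'
#' @param positions_mm strictly increasing, uniformly spaced plane
#'   coordinates (voxel-center z positions), mm.
#' @param spacing_mm plane spacing, mm.
#' @param axis flow axis (always 3 = z here).
#' @return A `plane_set` (tibble of plane index and position with
#'   attributes `spacing_mm`, `axis`, `count`).
#' @export
plane_set <- function(positions_mm, spacing_mm, axis = 3L) {
  stopifnot(length(positions_mm) >= 1, all(diff(positions_mm) > 0))
  if (length(positions_mm) > 1) {
    stopifnot(max(abs(diff(positions_mm) - spacing_mm)) < 1e-6)
  }
  out <- tibble::tibble(plane = seq_along(positions_mm), position_mm = positions_mm)
  structure(out, spacing_mm = spacing_mm, axis = axis,
            count = length(positions_mm),
            class = c("plane_set", class(out)))
}

#' Default cross-sectional evaluation planes
#'
#' 24 planes at a constant 1 mm spacing, perpendicular to the flow axis,
#' centered on the scaffold so the 23 mm span covers the scaffold block
#' plus 1.5 mm of each adjacent connector. Positions snap to voxel-center
#' coordinates (the spacing is rounded to a whole number of voxels).
#'
#' @param domain a `simulation_domain`.
#' @param count number of planes (default 24).
#' @param spacing_mm plane spacing (default 1 mm).
#' @return A `plane_set`.
#' @export
default_planes <- function(domain, count = 24L, spacing_mm = 1) {
  h <- domain$voxel_mm
  step <- max(1L, as.integer(round(spacing_mm / h)))
  spacing <- step * h
  span_vox <- step * (count - 1L)
  mid <- mean(domain$scaffold_z)                     # voxel index, may be x.5
  z0 <- as.integer(round(mid - span_vox / 2))
  zs <- z0 + step * (0:(count - 1L))
  nz <- dim(domain$labels)[3]
  if (z0 < 2L || max(zs) > nz - 1L) {
    abort(sprintf(
      "domain (%.3g mm of fluid span) is shorter than the %d-plane span of %.3g mm",
      (nz - 2L) * h, count, span_vox * h))
  }
  plane_set((zs - 0.5) * h, spacing_mm = spacing, axis = 3L)
}

# z voxel indices of a plane set
plane_slices <- function(domain, planes) {
  as.integer(round(planes$position_mm / domain$voxel_mm + 0.5))
}

#' Within-plane flow homogeneity (mean Hoover coefficient)
#'
#' For each evaluation plane, the Hoover index of the velocity-magnitude
#' distribution over the plane's open (non-wall, non-solid) voxels with
#' equal weights; their arithmetic mean is the mean Hoover coefficient
#' used to rank bioreactor designs (lower = more homogeneous flow).
#'
#' @param flow a `flow_field` from [solve_flow()].
#' @param domain the matching `simulation_domain`.
#' @param planes a `plane_set`, `NULL` to use every scaffold voxel plane,
#'   or a number: margin in mm of adjacent connector to include on each
#'   side of the scaffold (the connector sweeps use 1 mm so every length
#'   is scored on the same support, including the near-face connector flow
#'   where the geometries differ most).
#' @return A `hoover_result`: tibble with one row per retained plane
#'   (`plane`, `position_mm`, `n_voxels`, `hoover`) and attributes `mean`
#'   and `excluded` (planes without fluid voxels).
#' @export
flow_homogeneity <- function(flow, domain, planes = NULL) {
  vm <- velocity_magnitude(flow)
  if (is.null(planes) || is.numeric(planes)) {
    m_vox <- if (is.null(planes)) 0L else
      as.integer(round(planes / domain$voxel_mm))
    z1 <- max(2L, domain$scaffold_z[1] - m_vox)
    z2 <- min(dim(domain$labels)[3] - 1L, domain$scaffold_z[2] + m_vox)
    zs <- seq(z1, z2)
    pos <- (zs - 0.5) * domain$voxel_mm
  } else {
    zs <- plane_slices(domain, planes)
    pos <- planes$position_mm
  }
  opn <- open_mask(domain)
  rows <- lapply(seq_along(zs), function(k) {
    m <- opn[, , zs[k]]
    v <- vm[, , zs[k]][m]
    if (!length(v) || sum(v) <= 0) {
      return(tibble::tibble(plane = k, position_mm = pos[k],
                            n_voxels = length(v), hoover = NA_real_))
    }
    tibble::tibble(plane = k, position_mm = pos[k], n_voxels = length(v),
                   hoover = hoover_index(v))
  })
  out <- dplyr::bind_rows(rows)
  excluded <- out$plane[is.na(out$hoover)]
  kept <- out[!is.na(out$hoover), ]
  structure(kept, mean = mean(kept$hoover), excluded = excluded,
            class = c("hoover_result", class(kept)))
}

#' @export
print.hoover_result <- function(x, ...) {
  cat(sprintf("<hoover_result> %d planes, mean Hoover = %.4f\n",
              nrow(x), attr(x, "mean")))
  NextMethod()
}

#' Mean Hoover coefficient of a flow-homogeneity result
#' @param x a `hoover_result`.
#' @return scalar mean over planes.
#' @export
mean_hoover <- function(x) attr(x, "mean")

#' Axial distribution homogeneity of a deposited quantity
#'
#' Hoover index *across* planes of the per-plane integrated quantity
#' (deposited cells or activity) within the scaffold, weighted by the
#' per-plane scaffold fluid volume. This is the single-number homogeneity
#' readout used for cell/activity distributions (distinct from the
#' within-plane flow application above; the two share the index but not
#' the partition).
#'
#' @param density_field nonnegative 3-D array on the domain grid
#'   (quantity per voxel).
#' @param domain a `simulation_domain`.
#' @param planes optional `plane_set`; default bins are the scaffold's
#'   voxel planes.
#' @return scalar Hoover index in \[0, 1\].
#' @export
axial_distribution_hoover <- function(density_field, domain, planes = NULL) {
  stopifnot(identical(dim(density_field), dim(domain$labels)))
  if (any(density_field < 0)) abort("density must be nonnegative")
  zr <- domain$scaffold_z
  if (is.null(planes)) {
    zs <- seq(zr[1], zr[2]); half <- 0L
  } else {
    zs <- plane_slices(domain, planes)
    step <- max(1L, as.integer(round(attr(planes, "spacing_mm") / domain$voxel_mm)))
    half <- step %/% 2L
  }
  scaff <- domain$labels == DOMAIN_LABELS[["SCAFFOLD_FLUID"]]
  fluid_vol <- if (domain$resolved) scaff * 1.0 else {
    ifelse(scaff, ifelse(is.na(domain$porosity_field), 0, domain$porosity_field), 0)
  }
  qty <- wgt <- numeric(0)
  for (z in zs) {
    zz <- max(zr[1], z - half):min(zr[2], z + half)
    zz <- zz[zz >= 1 & zz <= dim(density_field)[3]]
    if (!length(zz) || z < zr[1] || z > zr[2]) next
    s <- scaff[, , zz, drop = FALSE]
    qty <- c(qty, sum(density_field[, , zz, drop = FALSE][s]))
    wgt <- c(wgt, sum(fluid_vol[, , zz, drop = FALSE]))
  }
  keep <- wgt > 0
  if (!any(keep) || sum(qty[keep]) <= 0) {
    abort("no deposited quantity inside the scaffold; axial Hoover undefined")
  }
  hoover_index(qty[keep], wgt[keep])
}
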