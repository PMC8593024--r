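#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flow-homogeneity result
#'
#' @param x a `hoover_result`.
#' @param ... unused.
#' @return tibble with one row per plane: `plane`, `position_mm`,
#'   `n_voxels`, `hoover`.
#' @export
tidy.hoover_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("plane", "position_mm", "n_voxels", "hoover")])
}

#' @rdname tidy.hoover_result
#' @export
glance.hoover_result <- function(x, ...) {
  tibble::tibble(mean_hoover = attr(x, "mean"), n_planes = nrow(x),
                 n_excluded = length(attr(x, "excluded")))
}

#' One-row summary of a solved flow field
#'
#' @param x a `flow_field`.
#' @param ... unused.
#' @return tibble: flow rate, peak speed, solver iterations and residuals.
#' @export
glance.flow_field <- function(x, ...) {
  tibble::tibble(
    inlet_flow_ml_min = x$inlet_flow_ml_min,
    max_speed_mm_s = max(velocity_magnitude(x)),
    max_shear_s1 = max(shear_rate_field(x)),
    iterations = x$residuals$iterations %||% NA_integer_,
    rel_residual = x$residuals$rel_residual %||% NA_real_,
    max_divergence_s1 = x$residuals$max_div %||% NA_real_
  )
}

#' Tidy a seeding result
#'
#' @param x a `seeding_result`.
#' @param ... unused.
#' @return the per-frame retention series as a tibble.
#' @export
tidy.seeding_result <- function(x, ...) x$retention_series

#' @rdname tidy.seeding_result
#' @export
glance.seeding_result <- function(x, ...) {
  l <- as.list(x$ledger)
  tibble::tibble(
    mode = x$protocol$mode, rate_ml_min = x$protocol$rate_ml_min,
    concentration_cells_ml = x$suspension$concentration_cells_ml,
    injected = l$injected, deposited = l$deposited,
    in_domain = l$in_domain, outflowed = l$outflowed,
    efficiency = x$efficiency, seed = x$seed
  )
}

#' Tidy a sweep report
#'
#' @param x a `sweep_report`.
#' @param ... unused.
#' @return the per-run result tibble (tidy) or the per-condition summary
#'   (glance).
#' @export
tidy.sweep_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.sweep_report
#' @export
glance.sweep_report <- function(x, ...) sweep_summary(x)

#' Tidy a scaffold volume
#'
#' @param x a `scaffold_volume`.
#' @param ... unused.
#' @return one-row tibble of geometry and porosity metadata.
#' @export
glance.scaffold_volume <- function(x, ...) {
  tibble::tibble(
    nx = dim(x$occupancy)[1], ny = dim(x$occupancy)[2], nz = dim(x$occupancy)[3],
    voxel_mm = x$voxel_mm, porosity = x$porosity,
    pore_scale_mm = x$pore_scale_mm, seed = x$seed, provenance = x$provenance
  )
}
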