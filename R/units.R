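#' Unit constants and conversions
#'
#' Internal unit system: lengths in mm, time in s, dynamic viscosity in
#' mPa.s (equal to Pa.s x 1e-3), pressure in Pa, flow rate supplied in
#' ml/min and converted once here. 1 ml/min = 1000 mm^3 / 60 s.
#'
#' @format A named list with elements `mm3s_per_ml_min` (16.6667),
#'   `f18_half_life_min` (109.77, physical half-life of fluorine-18,
#'   standard nuclide constant) and `gravity_mm_s2` (9810).
#' @export
perfuseed_constants <- list(
  mm3s_per_ml_min  = 1000 / 60,
  f18_half_life_min = 109.77,
  gravity_mm_s2    = 9.80665e3
)

#' Convert a flow rate from ml/min to mm^3/s
#' @param ml_min flow rate in ml/min.
#' @return flow rate in mm^3/s.
#' @export
ml_min_to_mm3_s <- function(ml_min) ml_min * perfuseed_constants$mm3s_per_ml_min

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
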