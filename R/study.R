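#' Printed reference values from the original design study
#'
#' The published summary numbers used as worked-example inputs and as the
#' reference for direction-of-effect checks: mean Hoover coefficients of
#' the connector-length sweep (six lengths, cylindrical and conical), the
#' diameter study (D = 1 vs 10 mm), the maximum scaffold shear rates, the
#' reported seeding-efficiency operating points and correlations, and the
#' imaging-readout summaries. These are transcribed inputs, not outputs of
#' this package.
#'
#' @return A list with elements `table1` (tibble: `length_mm`,
#'   `cylindrical`, `conical`), `diameter_study`, `shear_study`,
#'   `efficiency`, `correlations`, `imaging`.
#' @export
design_fixtures <- function() {
  list(
    table1 = tibble::tibble(
      length_mm   = c(1, 2, 3, 4, 5, 10),
      cylindrical = c(0.6073, 0.5208, 0.4911, 0.4665, 0.4594, 0.4441),
      conical     = c(0.5571, 0.4915, 0.4542, 0.4075, 0.4238, 0.4301)
    ),
    diameter_study = c(hoover_d1_mm = 0.6205, hoover_d10_mm = 0.4441),
    shear_study = c(shear_d1_s1 = 49, shear_d10_s1 = 18),
    efficiency = list(
      optimum = 0.80, optimum_concentration_cells_ml = 0.4e6,
      at_0.5e6_cells_ml = 0.70, at_1e6_cells_ml = 0.60,
      rate_low_ml_min = 0.90, rate_high_ml_min = 0.05,
      concentration_range_cells_ml = c(0.06e6, 1.22e6),
      rate_grid_ml_min = c(0.25, 0.5, 1.0, 2.0)
    ),
    correlations = c(concentration = -0.7726, rate = -0.9018),
    imaging = list(
      enrichment_MBq = c(type1_enc_minus = 0.75, type2_enc_minus = 0.71,
                         type1_enc_plus = 0.80, type2_enc_plus = 1.05),
      hoover_oscillating = 0.24, hoover_oscillating_sd = 0.02
    )
  )
}

#' Percent change relative to a reference
#'
#' `100 * (reference - value) / reference`: the percent reduction achieved
#' by `value` relative to `reference` (negative if `value` exceeds it).
#'
#' @param reference nonzero reference value.
#' @param value new value.
#' @return percent change.
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) abort("reference must be nonzero")
  100 * (reference - value) / reference
}

#' Pearson correlation
#'
#' Standard Pearson r via [stats::cor.test()]. Note: the original report
#' labels signed r values as "R^2"; both `r` and `r_squared` are returned
#' to keep the two readings apart.
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return tibble: `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Pearson correlation undefined for zero-variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value, n = length(x))
}

#' Welch two-sample t test
#'
#' @param a,b numeric vectors, length >= 2 each.
#' @return tibble: `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  tt <- stats::t.test(a, b)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

new_sweep_report <- function(results, summary, kind) {
  structure(results, summary = summary, kind = kind,
            class = c("sweep_report", class(results)))
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("<sweep_report: %s>\n", attr(x, "kind")))
  print(attr(x, "summary"))
  invisible(x)
}

#' Sweep summary of a report
#' @param report a `sweep_report`.
#' @return the per-condition summary tibble.
#' @export
sweep_summary <- function(report) attr(report, "summary")

#' Connector-geometry sweep
#'
#' Solves the homogenized flow problem for every combination of connector
#' shape, length and diameter over an ensemble of synthetic scaffold
#' seeds, scoring each configuration by the mean Hoover coefficient over
#' scaffold cross-sections and the maximum scaffold shear rate.
#'
#' @param scaffold_seeds integer seeds of the scaffold ensemble.
#' @param shapes connector shapes to test.
#' @param lengths_mm connector lengths, mm.
#' @param diameters_mm cylinder diameter / conical base diameter, mm.
#' @param voxel_mm flow-grid voxel size (default 0.5 mm).
#' @param inlet_flow_ml_min flow rate (default 1, the simulation
#'   condition).
#' @param scaffold_args extra arguments to [generate_scaffold()].
#' @param props `fluid_props`.
#' @return A `sweep_report` tibble: one row per (shape, length, diameter,
#'   seed) with `mean_hoover` and `max_shear_s1`; summary attribute
#'   averages over seeds.
#' @export
connector_sweep <- function(scaffold_seeds = 1:5,
                            shapes = c("cylindrical", "conical"),
                            lengths_mm = c(1, 2, 3, 4, 5, 10),
                            diameters_mm = 10,
                            voxel_mm = 0.5, inlet_flow_ml_min = 1,
                            scaffold_args = list(), props = fluid_props()) {
  grid <- tidyr::expand_grid(shape = shapes, length_mm = lengths_mm,
                             diameter_mm = diameters_mm)
  chamber_mm <- scaffold_args$dims_mm %||% c(10, 10, 20)
  rows <- list()
  for (s in scaffold_seeds) {
    sc <- do.call(generate_scaffold, c(list(seed = s), scaffold_args))
    for (i in seq_len(nrow(grid))) {
      cfg <- study_config(grid$shape[i], grid$length_mm[i], grid$diameter_mm[i],
                          chamber_mm = chamber_mm)
      row <- tibble::tibble(shape = grid$shape[i], length_mm = grid$length_mm[i],
                            diameter_mm = grid$diameter_mm[i], seed = s,
                            mean_hoover = NA_real_, max_shear_s1 = NA_real_,
                            error = NA_character_)
      res <- tryCatch({
        dom <- build_domain(sc, cfg, voxel_mm = voxel_mm)
        fl <- solve_flow(dom, props, inlet_flow_ml_min, mode = "homogenized")
        list(h = mean_hoover(flow_homogeneity(fl, dom, planes = 1)),
             g = max_shear_in_scaffold(fl, dom))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$mean_hoover <- res$h
        row$max_shear_s1 <- res$g
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$shape, .data$length_mm, .data$diameter_mm) |>
    dplyr::summarise(
      sd_hoover = sd(.data$mean_hoover),
      mean_hoover = mean(.data$mean_hoover),
      max_shear_s1 = mean(.data$max_shear_s1),
      n_seeds = dplyr::n(), .groups = "drop") |>
    dplyr::relocate("sd_hoover", .after = "mean_hoover") |>
    dplyr::arrange(.data$mean_hoover)
  new_sweep_report(results, summary, "connector_geometry")
}

#' Seeding-efficiency sweep over concentrations or flow rates
#'
#' Simulates seeding at each condition over an ensemble of seeds and
#' reports the Pearson correlation between efficiency and the swept
#' variable. The flow field is solved once and rescaled per rate (Stokes
#' linearity).
#'
#' @param concentrations_cells_ml cell concentrations to sweep (with
#'   `rate_ml_min` fixed), or `NULL`.
#' @param rates_ml_min flow rates to sweep (with concentration fixed), or
#'   `NULL`. Exactly one of the two sweeps must be given.
#' @param fixed_concentration_cells_ml concentration for the rate sweep.
#' @param fixed_rate_ml_min rate for the concentration sweep.
#' @param params `deposition_params` (calibrated).
#' @param seeds simulation seeds per condition.
#' @param flow,domain optional pre-solved reference flow and domain
#'   (type 2 enc+ by default, built on demand).
#' @param mode perfusion mode for the sweep (default unidirectional).
#' @param ... passed to [simulate_seeding()].
#' @return A `sweep_report` tibble with per-run efficiencies; the summary
#'   holds per-condition means and the correlation is in
#'   `attr(, "correlation")`.
#' @export
efficiency_sweep <- function(concentrations_cells_ml = NULL,
                             rates_ml_min = NULL,
                             fixed_concentration_cells_ml = 0.4e6,
                             fixed_rate_ml_min = 0.5,
                             params = deposition_params(), seeds = 1:10,
                             flow = NULL, domain = NULL,
                             mode = "unidirectional", ...) {
  if (is.null(concentrations_cells_ml) == is.null(rates_ml_min)) {
    abort("supply exactly one of `concentrations_cells_ml` or `rates_ml_min`")
  }
  if (is.null(domain)) {
    sc <- generate_scaffold(seed = 1L)
    domain <- build_domain(sc, preset("type2", encasement = TRUE), voxel_mm = 0.5)
  }
  if (is.null(flow)) flow <- solve_flow(domain, inlet_flow_ml_min = 1)
  sweep_var <- if (is.null(rates_ml_min)) "concentration_cells_ml" else "rate_ml_min"
  values <- if (is.null(rates_ml_min)) concentrations_cells_ml else rates_ml_min
  if (!length(values)) abort("empty sweep grid")
  rows <- list()
  for (v in values) {
    conc <- if (sweep_var == "concentration_cells_ml") v else fixed_concentration_cells_ml
    rate <- if (sweep_var == "rate_ml_min") v else fixed_rate_ml_min
    prot <- perfusion_protocol(mode, rate_ml_min = rate)
    susp <- cell_suspension(conc)
    for (s in seeds) {
      sr <- simulate_seeding(flow, domain, prot, susp, params, seed = s, ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        concentration_cells_ml = conc, rate_ml_min = rate, seed = s,
        efficiency = sr$efficiency)
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(sweep_var))) |>
    dplyr::summarise(mean_efficiency = mean(.data$efficiency),
                     sd_efficiency = sd(.data$efficiency),
                     n_seeds = dplyr::n(), .groups = "drop")
  corr <- if (sd(results[[sweep_var]]) > 0 && sd(results$efficiency) > 0) {
    r <- stats::cor(results[[sweep_var]], results$efficiency)
    p <- if (nrow(results) >= 3) {
      stats::cor.test(results[[sweep_var]], results$efficiency)$p.value
    } else NA_real_
    tibble::tibble(r = r, r_squared = r^2, p_value = p, n = nrow(results))
  } else {
    # degenerate (constant) input: correlation undefined
    tibble::tibble(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                   n = nrow(results))
  }
  rep <- new_sweep_report(results, summary, paste0("efficiency_", sweep_var))
  attr(rep, "correlation") <- corr
  rep
}

#' Compare the six studied bioreactor configurations
#'
#' Builds and runs the full pipeline (domain, flow, seeding, PET
#' synthesis) for the studied configurations: type 1 and 2 without
#' encasement, types 1-3 with encasement, and type 2 with encasement and
#' oscillating perfusion. Reports 60-min enrichment, the 60-min axial
#' Hoover coefficient and the seeding efficiency per seed, with Welch
#' t comparisons of enrichment between encased and non-encased variants.
#'
#' @param seeds simulation seeds per configuration.
#' @param rate_ml_min perfusion rate (default 0.5).
#' @param concentration_cells_ml cell concentration (default 0.4e6).
#' @param params `deposition_params`.
#' @param voxel_mm flow-grid voxel size.
#' @param scaffold_seed seed of the shared synthetic scaffold.
#' @param pet_noise `"none"` or `"poisson"`.
#' @param configs optional named list of `reactor_config`s with a logical
#'   `oscillating` attribute; defaults to the six studied presets.
#' @param ... passed to [simulate_seeding()].
#' @return A `sweep_report` tibble (one row per config x seed) with a
#'   per-config summary and `attr(, "tests")` (Welch t results).
#' @export
configuration_comparison <- function(seeds = 1:5, rate_ml_min = 0.5,
                                     concentration_cells_ml = 0.4e6,
                                     params = deposition_params(),
                                     voxel_mm = 0.5, scaffold_seed = 1L,
                                     pet_noise = "none", configs = NULL, ...) {
  if (is.null(configs)) {
    configs <- list(
      `type1_enc-` = preset("type1", encasement = FALSE),
      `type2_enc-` = preset("type2", encasement = FALSE),
      `type1_enc+` = preset("type1", encasement = TRUE),
      `type2_enc+` = preset("type2", encasement = TRUE),
      `type3_enc+` = preset("type3", encasement = TRUE),
      `type2_enc+_osc` = preset("type2", encasement = TRUE)
    )
    osc <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  } else {
    osc <- vapply(configs, function(cf) isTRUE(attr(cf, "oscillating")),
                  logical(1))
  }
  sc <- generate_scaffold(seed = scaffold_seed)
  rows <- list()
  for (ci in seq_along(configs)) {
    cfg_name <- names(configs)[ci]
    res <- tryCatch({
      dom <- build_domain(sc, configs[[ci]], voxel_mm = voxel_mm)
      fl <- solve_flow(dom, inlet_flow_ml_min = 1)
      prot <- perfusion_protocol(if (osc[ci]) "oscillating" else "unidirectional",
                                 rate_ml_min = rate_ml_min)
      susp <- cell_suspension(concentration_cells_ml)
      lapply(seeds, function(s) {
        sr <- simulate_seeding(fl, dom, prot, susp, params, seed = s, ...)
        pet <- synthesize_pet(sr, dom, noise = pet_noise, seed = s)
        tc <- enrichment_and_hoover_timecourse(decay_correct(pet), dom)
        at60 <- tc[which.min(abs(tc$t_min - 60)), ]
        tibble::tibble(config = cfg_name, seed = s,
                       efficiency = sr$efficiency,
                       enrichment_MBq = at60$enrichment_MBq,
                       hoover_60min = at60$hoover)
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        config = cfg_name, seed = NA_integer_, efficiency = NA_real_,
        enrichment_MBq = NA_real_, hoover_60min = NA_real_,
        error = conditionMessage(res))
    } else {
      rows <- c(rows, res)
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::filter(!is.na(.data$seed)) |>
    dplyr::group_by(.data$config) |>
    dplyr::summarise(efficiency = mean(.data$efficiency),
                     enrichment_MBq = mean(.data$enrichment_MBq),
                     hoover_60min = mean(.data$hoover_60min),
                     n_seeds = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$hoover_60min)
  tests <- list()
  for (pair in list(c("type1_enc+", "type1_enc-"), c("type2_enc+", "type2_enc-"))) {
    a <- results$enrichment_MBq[results$config == pair[1]]
    b <- results$enrichment_MBq[results$config == pair[2]]
    if (length(a) >= 2 && length(b) >= 2) {
      tests[[paste(pair, collapse = "_vs_")]] <- welch_t(a, b)
    }
  }
  rep <- new_sweep_report(results, summary, "configuration_comparison")
  attr(rep, "tests") <- tests
  rep
}
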