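# small fixtures built in code, shared across test files

# a scaffold_volume from an explicit occupancy array
mk_volume <- function(occ, voxel_mm = 0.5) {
  perfuseed:::new_scaffold_volume(occ, voxel_mm)
}

# open rectangular duct domain (no scaffold; interior is CHAMBER_FLUID,
# full-face ports): the analytic duct-flow oracle geometry
mk_duct_domain <- function(nx = 10, ny = 10, nz = 20, h = 0.5) {
  L <- perfuseed:::DOMAIN_LABELS
  lab <- array(L[["WALL"]], c(nx, ny, nz))
  lab[2:(nx - 1), 2:(ny - 1), 2:(nz - 1)] <- L[["CHAMBER_FLUID"]]
  lab[2:(nx - 1), 2:(ny - 1), 1] <- L[["INLET_PORT"]]
  lab[2:(nx - 1), 2:(ny - 1), nz] <- L[["OUTLET_PORT"]]
  structure(list(
    labels = lab, voxel_mm = h, flow_axis = 3L,
    scaffold_z = c(2L, nz - 1L), scaffold_x = c(2L, nx - 1L),
    scaffold_y = c(2L, ny - 1L),
    porosity_field = array(NA_real_, c(nx, ny, nz)), resolved = TRUE,
    pore_scale_mm = 0.5, scaffold_porosity = 1,
    config = list(type_label = "duct", encasement = TRUE),
    provenance = list()
  ), class = "simulation_domain")
}

# duct with the interior marked as (homogenized) scaffold fluid
mk_porous_duct_domain <- function(nx = 10, ny = 10, nz = 20, h = 0.5,
                                  porosity = 0.69) {
  d <- mk_duct_domain(nx, ny, nz, h)
  L <- perfuseed:::DOMAIN_LABELS
  interior <- d$labels == L[["CHAMBER_FLUID"]]
  d$labels[interior] <- L[["SCAFFOLD_FLUID"]]
  d$porosity_field[interior] <- porosity
  d$resolved <- FALSE
  d$scaffold_porosity <- porosity
  d
}

# analytic fully developed rectangular-duct axial velocity (series
# solution), evaluated on a grid of cell centers across an a x a section
duct_profile_analytic <- function(a, y, z, n_terms = 80) {
  s <- 0
  for (n in seq(1, n_terms, 2)) {
    s <- s + (1 / n^3) *
      (1 - cosh(n * pi * (y - a / 2) / a) / cosh(n * pi / 2)) *
      sin(n * pi * z / a)
  }
  s
}

# independent Hoover oracle: direct share-difference computation
hoover_brute <- function(v, w = rep(1, length(v))) {
  q <- v * w / sum(v * w)
  p <- w / sum(w)
  sum(abs(q - p)) / 2
}

# small deterministic seeding run on a compact chamber (fast)
mk_small_seeding <- function(seed = 1L, mode = "unidirectional",
                             adhesion = 0.125, rate = 0.5,
                             conc = 0.4e6, n_particles = 300,
                             seeding_min = 10, washout_min = 5) {
  env <- test_cache()
  key <- "small_flow"
  if (is.null(env[[key]])) {
    sc <- generate_scaffold(c(5, 5, 10), 0.25, 0.69, 0.5, seed = 5L)
    cfg <- study_config("conical", length_mm = 4, diameter_mm = 5,
                        chamber_mm = c(5, 5, 10))
    dom <- build_domain(sc, cfg, voxel_mm = 0.5)
    fl <- solve_flow(dom, inlet_flow_ml_min = 1)
    env[[key]] <- list(dom = dom, fl = fl)
  }
  dom <- env[[key]]$dom; fl <- env[[key]]$fl
  prot <- perfusion_protocol(mode, rate_ml_min = rate,
                             seeding_duration_min = seeding_min,
                             washout_duration_min = washout_min,
                             switch_at_min = seeding_min / 2)
  sr <- simulate_seeding(fl, dom, prot, cell_suspension(conc),
                         deposition_params(adhesion_prob = adhesion),
                         seed = seed, n_particles = n_particles)
  list(domain = dom, flow = fl, result = sr)
}

# session-level cache shared across test files (expensive objects built once)
test_cache <- local({
  env <- new.env(parent = emptyenv())
  function() env
})
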