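# shared, lazily built study objects for the acceptance-level tests; each
# is computed once per test run under fixed seeds

studies_reference <- function() {
  env <- test_cache()
  if (is.null(env$ref)) {
    sc <- generate_scaffold(seed = 1L)
    dom <- build_domain(sc, preset("type2", encasement = TRUE), voxel_mm = 0.5)
    fl <- solve_flow(dom, inlet_flow_ml_min = 1, mode = "homogenized")
    env$ref <- list(domain = dom, flow = fl)
  }
  env$ref
}

# memoized seeding run on the reference type2 enc+ system
ref_run <- function(mode, rate, conc, seed, params = deposition_params()) {
  env <- test_cache()
  if (is.null(env$runs)) env$runs <- new.env(parent = emptyenv())
  key <- sprintf("%s_%g_%g_%d_%g", mode, rate, conc, seed, params$adhesion_prob)
  if (is.null(env$runs[[key]])) {
    ref <- studies_reference()
    prot <- perfusion_protocol(mode, rate_ml_min = rate)
    env$runs[[key]] <- simulate_seeding(ref$flow, ref$domain, prot,
                                        cell_suspension(conc), params,
                                        seed = seed)
  }
  env$runs[[key]]
}

studies_connector <- function() {
  env <- test_cache()
  if (is.null(env$connector)) {
    main <- connector_sweep(scaffold_seeds = 1:5)
    d1 <- connector_sweep(scaffold_seeds = 1:5, shapes = "cylindrical",
                          lengths_mm = 10, diameters_mm = 1)
    env$connector <- list(main = main, d1 = d1)
  }
  env$connector
}

studies_configs <- function() {
  env <- test_cache()
  if (is.null(env$configs)) {
    env$configs <- configuration_comparison(seeds = 1:3)
  }
  env$configs
}
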