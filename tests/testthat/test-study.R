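test_that("percent_change reproduces the worked-example arithmetic", {
  # printed design-study values: mean Hoover 0.6205 -> 0.4441, shear 49 -> 18
  expect_equal(percent_change(0.6205, 0.4441), 28.4287, tolerance = 1e-4)
  expect_equal(percent_change(49, 18), 63.2653, tolerance = 1e-4)
  expect_identical(percent_change(3.7, 3.7), 0)
  expect_error(percent_change(0, 1), "nonzero")
})

test_that("reference fixtures carry the printed digits", {
  fx <- design_fixtures()
  t1 <- fx$table1
  expect_identical(t1$length_mm, c(1, 2, 3, 4, 5, 10))
  expect_identical(t1$cylindrical[1], 0.6073)
  expect_identical(t1$conical[4], 0.4075)
  expect_identical(min(c(t1$cylindrical, t1$conical)), 0.4075)
  expect_identical(t1$length_mm[which.min(t1$conical)], 4)
  expect_identical(unname(fx$diameter_study), c(0.6205, 0.4441))
  expect_identical(unname(fx$shear_study), c(49, 18))
  expect_identical(unname(fx$correlations), c(-0.7726, -0.9018))
})

test_that("pearson_r matches hand-computed covariance arithmetic", {
  # x = 1:4, y = (2,1,4,3): centered cross products sum to 3, sds sqrt(5/3)
  out <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(out$r, 0.6, tolerance = 1e-12)
  expect_equal(out$r_squared, 0.36, tolerance = 1e-12)
  expect_identical(out$n, 4L)
  # perfectly linear increasing pairs
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$r, 1, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero-variance")
})

test_that("welch_t is near-null for equal distributions and flags separation", {
  set.seed(51)
  a <- rnorm(200); b <- rnorm(200)
  nt <- welch_t(a, b)
  expect_gt(nt$p_value, 0.01)
  st <- welch_t(rnorm(50, 5), rnorm(50, 0))
  expect_lt(st$p_value, 1e-6)
})

test_that("a single-configuration sweep equals the direct solver call", {
  args <- list(dims_mm = c(5, 5, 10), voxel_mm = 0.25, pore_scale_mm = 0.5)
  rep1 <- connector_sweep(scaffold_seeds = 5L, shapes = "conical",
                          lengths_mm = 4, diameters_mm = 5,
                          scaffold_args = args)
  sc <- do.call(generate_scaffold, c(list(seed = 5L), args))
  cfg <- study_config("conical", 4, 5, chamber_mm = c(5, 5, 10))
  dom <- build_domain(sc, cfg, voxel_mm = 0.5)
  fl <- solve_flow(dom, inlet_flow_ml_min = 1)
  expect_equal(rep1$mean_hoover,
               mean_hoover(flow_homogeneity(fl, dom, planes = 1)),
               tolerance = 1e-9)
  expect_equal(rep1$max_shear_s1, max_shear_in_scaffold(fl, dom),
               tolerance = 1e-9)

  # repeating the sweep with the same seed reproduces it exactly
  rep2 <- connector_sweep(scaffold_seeds = 5L, shapes = "conical",
                          lengths_mm = 4, diameters_mm = 5,
                          scaffold_args = args)
  expect_identical(rep1$mean_hoover, rep2$mean_hoover)
})

test_that("a two-point efficiency grid gives a closed-form correlation of +-1", {
  run <- mk_small_seeding(seed = 1)          # warms the shared small domain
  rep <- efficiency_sweep(rates_ml_min = c(0.25, 2), seeds = 1L,
                          flow = run$flow, domain = run$domain,
                          n_particles = 200)
  corr <- attr(rep, "correlation")
  expect_equal(abs(corr$r), 1, tolerance = 1e-12)
  expect_identical(sign(corr$r), -1)         # slower perfusion captures more
  expect_error(efficiency_sweep(rates_ml_min = numeric(0), seeds = 1L,
                                flow = run$flow, domain = run$domain),
               "empty")
})

test_that("tidiers and plots expose the result objects", {
  run <- mk_small_seeding(seed = 2)
  g <- glance(run$result)
  expect_identical(g$injected, 300L)
  expect_identical(g$injected, g$deposited + g$in_domain + g$outflowed)
  td <- tidy(run$result)
  expect_true(all(c("frame", "t_min", "retained_particles") %in% names(td)))
  hr <- flow_homogeneity(run$flow, run$domain)
  expect_s3_class(autoplot(hr), "ggplot")
  expect_identical(glance(hr)$mean_hoover, mean_hoover(hr))
  expect_s3_class(plot_retention(run$result), "ggplot")
  expect_s3_class(plot_flow_slice(run$flow), "ggplot")
  gf <- glance(run$flow)
  expect_lt(gf$rel_residual, 1e-7)
})
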