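test_that("presets reproduce the three chamber types", {
  p1 <- preset("type1", encasement = FALSE)
  expect_identical(p1$inlet$shape, "cylindrical")
  expect_equal(p1$inlet$diameter_mm, 1)
  expect_identical(p1$orientation, "lengthwise")
  expect_false(p1$encasement)
  expect_gt(p1$gap_mm, 0)

  p3 <- preset("type3", encasement = TRUE)
  expect_identical(p3$inlet$shape, "conical")
  expect_equal(p3$inlet$length_mm, 15)
  expect_equal(p3$inlet$width_mm, 25)
  expect_identical(p3$orientation, "transverse")

  expect_identical(preset("type2"), preset("type2"))
  expect_error(preset("type9"))
})

test_that("configuration invariants are enforced", {
  expect_error(connector_spec("conical", 5, 10, width_mm = 3), "width")
  c1 <- connector_spec("cylindrical", 1, 15)
  expect_error(reactor_config(c(10, 10, 20), c1, c1, encasement = FALSE,
                              gap_mm = 0), "positive gap")
  expect_error(reactor_config(c(10, 10, 20), c1, c1, encasement = TRUE,
                              gap_mm = 0.5), "enc\\+")
})

test_that("type2 enc+ domain has no bypass and the expected inlet patch area", {
  env <- test_cache()
  if (is.null(env$type2_domain)) {
    sc <- generate_scaffold(seed = 42)
    env$type2_domain <- build_domain(sc, preset("type2"), voxel_mm = 0.5)
  }
  dom <- env$type2_domain
  L <- perfuseed:::DOMAIN_LABELS
  expect_identical(sum(dom$labels == L[["BYPASS_GAP"]]), 0L)
  h <- dom$voxel_mm
  n_port <- sum(dom$labels[, , 1] == L[["INLET_PORT"]])
  analytic <- pi * (1.6 / 2)^2
  # voxelized circle area agrees within one perimeter voxel layer
  expect_lt(abs(n_port * h^2 - analytic), pi * 1.6 * h)
})

test_that("a 10 mm cylindrical connector matches brute-force point-in-cylinder voxelization", {
  sc <- generate_scaffold(seed = 3)
  cfg <- study_config("cylindrical", length_mm = 2, diameter_mm = 10)
  dom <- build_domain(sc, cfg, voxel_mm = 0.5)
  L <- perfuseed:::DOMAIN_LABELS
  lab <- dom$labels
  d <- dim(lab)
  h <- dom$voxel_mm
  cx <- d[1] * h / 2; cy <- d[2] * h / 2
  z_conn <- 2L                                 # a connector slice
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    inside <- i >= 2 && i <= d[1] - 1 && j >= 2 && j <= d[2] - 1
    in_circle <- ((i - 0.5) * h - cx)^2 + ((j - 0.5) * h - cy)^2 <= 25
    expected <- if (inside && in_circle) L[["CONNECTOR"]] else L[["WALL"]]
    expect_identical(lab[i, j, z_conn], expected)
  }
})

test_that("ports connect through open voxels; encasement controls the path", {
  sc <- generate_scaffold(c(5, 5, 10), 0.25, 0.69, 0.5, seed = 5)
  cfg_enc <- study_config("conical", length_mm = 4, diameter_mm = 5,
                          chamber_mm = c(5, 5, 10))
  dom_enc <- build_domain(sc, cfg_enc, voxel_mm = 0.5)
  expect_true(ports_connected(dom_enc))
  # enc+: no route that avoids the scaffold
  expect_false(ports_connected(dom_enc, through = c("CONNECTOR", "CHAMBER_FLUID",
                                                    "BYPASS_GAP")))

  cfg2 <- preset("type2", encasement = FALSE)
  sc2 <- generate_scaffold(seed = 6)
  dom_loose <- build_domain(sc2, cfg2, voxel_mm = 0.5)
  expect_true(ports_connected(dom_loose))
  # enc-: a pure bypass route exists
  expect_true(ports_connected(dom_loose, through = c("CONNECTOR", "CHAMBER_FLUID",
                                                     "BYPASS_GAP")))
  L <- perfuseed:::DOMAIN_LABELS
  expect_gt(sum(dom_loose$labels == L[["BYPASS_GAP"]]), 0)
})

test_that("transverse orientation preserves the scaffold fluid volume", {
  sc <- generate_scaffold(seed = 9)
  dom_l <- build_domain(sc, preset("type2"), voxel_mm = 0.25)
  dom_t <- build_domain(sc, preset("type3"), voxel_mm = 0.25)
  L <- perfuseed:::DOMAIN_LABELS
  expect_identical(sum(dom_l$labels == L[["SCAFFOLD_FLUID"]]),
                   sum(dom_t$labels == L[["SCAFFOLD_FLUID"]]))
})

test_that("impossible geometry is rejected", {
  sc <- generate_scaffold(c(5, 5, 10), 0.25, 0.69, 0.5, seed = 5)
  too_wide <- study_config("cylindrical", length_mm = 2, diameter_mm = 12,
                           chamber_mm = c(5, 5, 10))
  expect_error(build_domain(sc, too_wide, voxel_mm = 0.5), "wider")
  mismatch <- preset("type2")                  # 10 x 10 x 20 chamber
  expect_error(build_domain(sc, mismatch, voxel_mm = 0.5), "chamber")
})

test_that("reactor configurations round-trip through JSON", {
  for (cfg in list(preset("type1", encasement = FALSE),
                   preset("type3", encasement = TRUE),
                   study_config("cylindrical", 4, 10))) {
    path <- tempfile(fileext = ".json")
    save_config(cfg, path)
    expect_identical(load_config(path), cfg)
    unlink(path)
  }
})
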