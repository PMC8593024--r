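test_that("hoover_index matches its analytic anchor points", {
  expect_identical(hoover_index(rep(3.2, 10)), 0)
  # all mass in one of four equal-weight bins: 1 - 1/4
  expect_equal(hoover_index(c(0, 0, 7, 0)), 0.75, tolerance = 1e-12)
  # frozen from the direct share-difference computation: shares of
  # (1,2,3,6)/12 vs 1/4 each -> half L1 distance = 0.25
  expect_equal(hoover_index(c(1, 2, 3, 6)), 0.25, tolerance = 1e-12)
})

test_that("hoover_index rejects undefined input", {
  expect_error(hoover_index(c(0, 0, 0)), "all-zero")
  expect_error(hoover_index(c(1, -1, 2)), "nonnegative")
  expect_error(hoover_index(c(1, 2), weights = c(1, -1)), "weights")
  expect_error(hoover_index(c(1, 2), weights = c(1, 1, 1)), "weights")
})

test_that("hoover_index agrees with the brute-force oracle on random input", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    v <- stats::rexp(n)
    w <- stats::runif(n, 0.2, 3)
    expect_equal(hoover_index(v), hoover_brute(v), tolerance = 1e-12)
    expect_equal(hoover_index(v, w), hoover_brute(v, w), tolerance = 1e-12)
  }
})

test_that("hoover_index is scale and permutation invariant, bounded", {
  set.seed(12)
  for (i in 1:20) {
    v <- stats::rexp(6)
    expect_equal(hoover_index(3.7 * v), hoover_index(v), tolerance = 1e-12)
    expect_equal(hoover_index(sample(v)), hoover_index(v), tolerance = 1e-12)
    h <- hoover_index(v)
    expect_gte(h, 0)
    expect_lte(h, 1 - 1 / 6 + 1e-12)
  }
  # extremes attained exactly
  one_hot <- c(1, rep(0, 7))
  expect_equal(hoover_index(one_hot), 1 - 1 / 8, tolerance = 1e-12)
})

test_that("merging two equal-share bins never increases the index", {
  set.seed(13)
  for (i in 1:20) {
    v <- stats::rexp(6)
    h0 <- hoover_index(v)
    # merged bin carries the combined mass spread over twice the weight
    merged <- c((v[1] + v[2]) / 2, v[3:6])
    w <- c(2, rep(1, 4))
    expect_lte(hoover_index(merged, w), h0 + 1e-12)
  }
})

test_that("default planes are 24 at 1 mm on voxel centers", {
  env <- test_cache()
  if (is.null(env$type2_domain)) {
    sc <- generate_scaffold(seed = 42)
    env$type2_domain <- build_domain(sc, preset("type2"), voxel_mm = 0.5)
  }
  dom <- env$type2_domain
  pl <- default_planes(dom)
  expect_identical(attr(pl, "count"), 24L)
  expect_equal(attr(pl, "spacing_mm"), 1)
  expect_equal(unique(round(diff(pl$position_mm), 9)), 1)
  # snap check: positions sit on voxel centers of the 0.5 mm grid
  idx <- pl$position_mm / dom$voxel_mm + 0.5
  expect_equal(idx, round(idx), tolerance = 1e-9)

  pl12 <- default_planes(dom, count = 12L, spacing_mm = 2)
  expect_identical(nrow(pl12), 12L)
  expect_equal(unique(round(diff(pl12$position_mm), 9)), 2)
})

test_that("default planes fail on domains shorter than their span", {
  sc <- generate_scaffold(c(5, 5, 10), 0.25, 0.69, 0.5, seed = 1)
  cfg <- study_config("cylindrical", length_mm = 1, diameter_mm = 5,
                      chamber_mm = c(5, 5, 10))
  dom <- build_domain(sc, cfg, voxel_mm = 0.5)
  expect_error(default_planes(dom), "shorter")
})

test_that("flow homogeneity reduces to the scalar index and is 0 for plug flow", {
  dom <- mk_duct_domain(4, 4, 6, h = 0.5)
  dm <- dim(dom$labels)
  w <- array(0, dm)
  w[2:3, 2:3, ] <- 1                       # uniform over open voxels
  fl <- flow_field(array(0, dm), array(0, dm), w, voxel_mm = 0.5)
  hr <- flow_homogeneity(fl, dom)
  expect_equal(mean_hoover(hr), 0, tolerance = 1e-12)

  # single plane with velocities (1,1,1,5) reduces to hoover_index
  w2 <- array(0, dm)
  w2[2:3, 2:3, 3] <- c(1, 1, 1, 5)
  fl2 <- flow_field(array(0, dm), array(0, dm), w2, voxel_mm = 0.5)
  pl <- plane_set(positions_mm = (3 - 0.5) * 0.5, spacing_mm = 0.5)
  hr2 <- flow_homogeneity(fl2, dom, pl)
  expect_equal(hr2$hoover, hoover_index(c(1, 1, 1, 5)), tolerance = 1e-12)
})

test_that("axial distribution hoover: uniform density scores 0, concentrated matches the plane-sum oracle", {
  dom <- mk_porous_duct_domain(6, 6, 14, h = 0.5)
  dm <- dim(dom$labels)
  scaff <- dom$labels == perfuseed:::DOMAIN_LABELS[["SCAFFOLD_FLUID"]]
  unif <- array(0, dm); unif[scaff] <- 1
  expect_equal(axial_distribution_hoover(unif, dom), 0, tolerance = 1e-12)

  top <- array(0, dm)
  zr <- dom$scaffold_z
  third <- zr[1]:(zr[1] + 3)
  for (z in third) top[, , z][scaff[, , z]] <- 2.5
  # independent plane-sum oracle
  zs <- zr[1]:zr[2]
  qty <- vapply(zs, function(z) sum(top[, , z][scaff[, , z]]), numeric(1))
  wgt <- vapply(zs, function(z) sum(scaff[, , z]) * dom$porosity_field[2, 2, z],
                numeric(1))
  expect_equal(axial_distribution_hoover(top, dom),
               hoover_brute(qty, wgt), tolerance = 1e-12)

  expect_error(axial_distribution_hoover(array(0, dm), dom), "axial Hoover")
})
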