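test_that("duct flow reproduces the analytic rectangular-duct profile within 2%", {
  dom <- mk_duct_domain(18, 18, 66, h = 0.5)
  fl <- solve_flow(dom, inlet_flow_ml_min = 1, mode = "resolved")
  zmid <- 33L
  wsl <- fl$w[2:17, 2:17, zmid]
  ratio <- max(wsl) / mean(wsl)
  a <- 8                                        # 16 cells x 0.5 mm
  yc <- (1:16 - 0.5) * 0.5
  an <- outer(yc, yc, function(y, z) {
    mapply(function(yy, zz) duct_profile_analytic(a, yy, zz), y, z)
  })
  ratio_an <- max(an) / mean(an)
  expect_lt(abs(ratio - ratio_an) / ratio_an, 0.02)
})

test_that("mass is conserved through every cross-section", {
  env <- test_cache()
  if (is.null(env$type2_flow)) {
    if (is.null(env$type2_domain)) {
      sc <- generate_scaffold(seed = 42)
      env$type2_domain <- build_domain(sc, preset("type2"), voxel_mm = 0.5)
    }
    env$type2_flow <- solve_flow(env$type2_domain, inlet_flow_ml_min = 1)
  }
  fl <- env$type2_flow
  Q <- ml_min_to_mm3_s(1)
  nz <- dim(fl$w)[3]
  fluxes <- vapply(seq(2, nz, by = 7), function(z) plane_flux(fl, z), numeric(1))
  expect_true(all(abs(fluxes - Q) / Q < 0.01))
  expect_lt(fl$residuals$max_div, 1e-6)
})

test_that("the homogenized porous duct carries plug-like flow with plane mean Q/A", {
  dom <- mk_porous_duct_domain(12, 12, 24, h = 0.5)
  fl <- solve_flow(dom, inlet_flow_ml_min = 1, mode = "homogenized")
  Q <- ml_min_to_mm3_s(1)
  A <- 10 * 10 * 0.5^2                          # open cross-section, mm^2
  for (z in c(6L, 12L, 18L)) {
    wbar <- mean(fl$w[2:11, 2:11, z])
    expect_lt(abs(wbar - Q / A) / (Q / A), 0.01)
  }
  # plug-like: within-plane spread is small relative to the mean
  hr <- flow_homogeneity(fl, dom)
  expect_lt(mean_hoover(hr), 0.05)
})

test_that("the field is linear in the flow rate", {
  dom <- mk_porous_duct_domain(8, 8, 16, h = 0.5)
  f1 <- solve_flow(dom, inlet_flow_ml_min = 1)
  f2 <- solve_flow(dom, inlet_flow_ml_min = 2)
  sc <- max(abs(f1$w))
  expect_lt(max(abs(f2$u - 2 * f1$u), abs(f2$v - 2 * f1$v),
                abs(f2$w - 2 * f1$w)) / (2 * sc), 1e-6)
})

test_that("reversing inlet and outlet roles negates the field (Stokes reversibility)", {
  dom <- mk_porous_duct_domain(8, 8, 16, h = 0.5)
  fwd <- solve_flow(dom, inlet_flow_ml_min = 1, direction = "forward")
  rev <- solve_flow(dom, inlet_flow_ml_min = 1, direction = "reverse")
  sc <- max(abs(fwd$w))
  expect_lt(max(abs(rev$u + fwd$u), abs(rev$v + fwd$v), abs(rev$w + fwd$w)) / sc,
            1e-6)
  # reverse_flow gives the same thing without a solve
  neg <- reverse_flow(fwd)
  expect_equal(neg$w, rev$w, tolerance = 1e-6)
})

test_that("a mirror-symmetric domain yields a mirror-symmetric field", {
  # uniform (all-fluid) scaffold: the domain and drag are left-right symmetric
  sc <- mk_volume(array(1L, c(20, 20, 40)), voxel_mm = 0.25)
  cfg <- study_config("conical", length_mm = 4, diameter_mm = 5,
                      chamber_mm = c(5, 5, 10))
  dom <- build_domain(sc, cfg, voxel_mm = 0.5)
  fl <- solve_flow(dom, inlet_flow_ml_min = 1)
  wm <- fl$w
  flipped <- wm[rev(seq_len(dim(wm)[1])), , ]
  expect_lt(max(abs(wm - flipped)) / max(abs(wm)), 1e-4)
})

test_that("shear rate matches analytic fields and the finite-difference oracle", {
  dm <- c(6, 6, 6)
  unif <- flow_field(array(2, dm), array(-1, dm), array(0.5, dm), voxel_mm = 0.5)
  expect_equal(max(shear_rate_field(unif)), 0, tolerance = 1e-12)

  # planar Couette u_x = k y -> shear = k everywhere (including boundaries)
  k <- 3
  y <- array(rep((1:6 - 0.5) * 0.5, each = 6), dm)
  couette <- flow_field(k * y, array(0, dm), array(0, dm), voxel_mm = 0.5)
  expect_equal(range(shear_rate_field(couette)), c(k, k), tolerance = 1e-9)

  # random small field vs an independent per-voxel gradient-tensor oracle
  set.seed(21)
  u <- array(rnorm(prod(dm), sd = 0.1), dm)
  v <- array(rnorm(prod(dm), sd = 0.1), dm)
  w <- array(rnorm(prod(dm), sd = 0.1), dm)
  h <- 0.5
  fl <- flow_field(u, v, w, voxel_mm = h)
  gam <- shear_rate_field(fl)
  num_grad <- function(f, idx, d) {
    i <- idx
    n <- dm[d]
    ip <- i; ip[d] <- min(i[d] + 1, n)
    im <- i; im[d] <- max(i[d] - 1, 1)
    (f[ip[1], ip[2], ip[3]] - f[im[1], im[2], im[3]]) / ((ip[d] - im[d]) * h)
  }
  flds <- list(u, v, w)
  for (trial in 1:12) {
    idx <- c(sample(6, 1), sample(6, 1), sample(6, 1))
    G <- matrix(0, 3, 3)
    for (ci in 1:3) for (dj in 1:3) G[ci, dj] <- num_grad(flds[[ci]], idx, dj)
    D <- (G + t(G)) / 2
    expect_equal(gam[idx[1], idx[2], idx[3]], sqrt(2 * sum(D^2)),
                 tolerance = 1e-9)
  }
})

test_that("max shear in scaffold behaves at the analytic anchors", {
  dom <- mk_porous_duct_domain(6, 6, 12, h = 0.5)
  dm <- dim(dom$labels)
  zero <- flow_field(array(0, dm), array(0, dm), array(0, dm), voxel_mm = 0.5)
  expect_identical(max_shear_in_scaffold(zero, dom), 0)
  k <- 3
  y <- array(rep(rep((seq_len(dm[2]) - 0.5) * 0.5, each = dm[1]), dm[3]), dm)
  couette <- flow_field(k * y, array(0, dm), array(0, dm), voxel_mm = 0.5)
  expect_equal(max_shear_in_scaffold(couette, dom), k, tolerance = 1e-9)
})

test_that("disconnected ports are refused", {
  dom <- mk_duct_domain(8, 8, 16, h = 0.5)
  L <- perfuseed:::DOMAIN_LABELS
  dom$labels[, , 8] <- L[["WALL"]]              # plug the duct
  expect_error(solve_flow(dom), "not connected")
})
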