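# minimal hand-built seeding result for forward-model oracles
mk_fake_seeding <- function(dm, frames, voxel_mm = 0.5,
                            conc = 0.4e6, weight = 1000) {
  structure(list(
    frames = frames,
    particle_weight_cells = weight,
    suspension = cell_suspension(conc),
    protocol = perfusion_protocol("unidirectional", rate_ml_min = 0.5),
    voxel_mm = voxel_mm
  ), class = c("seeding_result"))
}

test_that("a static point source halves over one half-life", {
  dm <- c(4, 4, 6)
  dom <- mk_duct_domain(4, 4, 6, h = 0.5)
  dep <- array(0, dm); dep[2, 2, 3] <- 5
  frames <- list(
    list(deposited = dep, suspended = array(0, dm), t_min = 0),
    list(deposited = dep, suspended = array(0, dm), t_min = 109.77)
  )
  sr <- mk_fake_seeding(dm, frames)
  # seeding phase ends at 60 min; disable the washout leak to isolate decay
  pet <- synthesize_pet(sr, dom, free_tracer_fraction = 0, psf_mm = 0,
                        leak_per_min = 0, noise = "none")
  expect_equal(sum(pet$frames[[2]]), sum(pet$frames[[1]]) / 2, tolerance = 1e-9)
})

test_that("zero cells and zero background give an all-zero series", {
  dm <- c(4, 4, 6)
  dom <- mk_duct_domain(4, 4, 6, h = 0.5)
  z <- array(0, dm)
  frames <- list(list(deposited = z, suspended = z, t_min = 5))
  pet <- synthesize_pet(mk_fake_seeding(dm, frames), dom,
                        free_tracer_fraction = 0, psf_mm = 0.8)
  expect_identical(sum(abs(pet$frames[[1]])), 0)
})

test_that("frame totals match the brute-force per-voxel summation oracle", {
  set.seed(31)
  dm <- c(5, 5, 8)
  dom <- mk_duct_domain(5, 5, 8, h = 0.5)
  dep <- array(rpois(prod(dm), 2), dm)
  sus <- array(rpois(prod(dm), 1), dm)
  t_min <- 25
  frames <- list(list(deposited = dep, suspended = sus, t_min = t_min))
  w <- 1000
  sr <- mk_fake_seeding(dm, frames, weight = w)
  a_cell_Bq <- 5 * 0.05
  pet <- synthesize_pet(sr, dom, free_tracer_fraction = 0, psf_mm = 0,
                        noise = "none")
  lambda <- log(2) / 109.77
  expected <- sum((dep + sus)) * w * a_cell_Bq * 1e-6 * exp(-lambda * t_min)
  expect_equal(sum(pet$frames[[1]]), expected, tolerance = 1e-9)
  # PSF blur redistributes but conserves total activity
  pet_psf <- synthesize_pet(sr, dom, free_tracer_fraction = 0, psf_mm = 0.8,
                            noise = "none")
  expect_equal(sum(pet_psf$frames[[1]]), expected, tolerance = 1e-6)
})

test_that("decay correction flattens a decaying static source and round-trips", {
  dm <- c(3, 3, 3)
  lambda <- log(2) / 109.77
  t <- c(0, 20, 40, 80)
  frames <- lapply(t, function(tt) array(exp(-lambda * tt), dm))
  s <- activity_series(frames, t_min = t, voxel_mm = 0.5)
  cor <- decay_correct(s)
  totals <- vapply(cor$frames, sum, numeric(1))
  expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-6)
  expect_error(decay_correct(cor), "already")
  back <- decay_uncorrect(cor)
  expect_equal(back$frames, s$frames, tolerance = 1e-12)
  expect_error(decay_uncorrect(back), "not decay-corrected")
  # correction factor at exactly one half-life is 2
  s2 <- activity_series(list(array(1, dm)), t_min = 109.77, voxel_mm = 0.5)
  expect_equal(sum(decay_correct(s2)$frames[[1]]) / sum(s2$frames[[1]]),
               2, tolerance = 1e-12)
})

test_that("ROI time courses partition the scaffold into consistent thirds", {
  # 12 scaffold slices -> exact thirds of 4 slices each
  dom <- mk_porous_duct_domain(6, 6, 14, h = 0.5)
  dm <- dim(dom$labels)
  scaff <- dom$labels == perfuseed:::DOMAIN_LABELS[["SCAFFOLD_FLUID"]]
  unif <- array(0, dm); unif[scaff] <- 0.01
  s <- activity_series(list(unif), t_min = 60, voxel_mm = 0.5)
  tab <- roi_timecourses(s, dom)
  expect_equal(tab$upper, tab$whole / 3, tolerance = 1e-12)
  expect_equal(tab$middle, tab$whole / 3, tolerance = 1e-12)
  expect_equal(tab$lower, tab$whole / 3, tolerance = 1e-12)
  expect_equal(tab$upper + tab$middle + tab$lower, tab$whole, tolerance = 1e-12)

  # all activity downstream of the scaffold: whole ~ 0, outflow > 0
  below <- array(0, dm); below[3, 3, dm[3]] <- 1
  s2 <- activity_series(list(below), t_min = 60, voxel_mm = 0.5)
  tab2 <- roi_timecourses(s2, dom)
  expect_identical(tab2$whole, 0)
  expect_gt(tab2$outflow, 0)
})

test_that("thirds still sum to the whole within 2% under PSF blur", {
  run <- mk_small_seeding(seed = 9)
  pet <- synthesize_pet(run$result, run$domain, psf_mm = 0.8, noise = "none",
                        seed = 1)
  tab <- roi_timecourses(pet, run$domain)
  late <- tab[tab$whole > 0, ]
  expect_true(all(abs(late$upper + late$middle + late$lower - late$whole) /
                    late$whole < 0.02))
})

test_that("enrichment rises during seeding and homogeneity is defined per frame", {
  run <- mk_small_seeding(seed = 10)
  pet <- synthesize_pet(run$result, run$domain, noise = "none", seed = 1)
  tc <- enrichment_and_hoover_timecourse(decay_correct(pet), run$domain)
  seed_phase <- tc[tc$t_min <= run$result$protocol$seeding_duration_min, ]
  expect_gt(seed_phase$enrichment_MBq[nrow(seed_phase)],
            seed_phase$enrichment_MBq[1])
  expect_true(all(tc$hoover[!is.na(tc$hoover)] >= 0 &
                  tc$hoover[!is.na(tc$hoover)] <= 1))
  # constant uniform frames give Hoover 0 at every frame
  dom <- mk_porous_duct_domain(6, 6, 14, h = 0.5)
  dm <- dim(dom$labels)
  scaff <- dom$labels == perfuseed:::DOMAIN_LABELS[["SCAFFOLD_FLUID"]]
  unif <- array(0, dm); unif[scaff] <- 1
  s <- activity_series(list(unif, unif), t_min = c(5, 10), voxel_mm = 0.5)
  tc2 <- enrichment_and_hoover_timecourse(s, dom)
  expect_equal(tc2$hoover, c(0, 0), tolerance = 1e-12)
})

test_that("4-D activity series round-trip through NIfTI with sidecar", {
  dm <- c(4, 4, 6)
  set.seed(41)
  frames <- lapply(1:3, function(k) array(runif(prod(dm)), dm))
  s <- activity_series(frames, t_min = c(5, 10, 15), voxel_mm = 0.5)
  path <- tempfile(fileext = ".nii.gz")
  save_activity_series(s, path)
  back <- load_activity_series(path)
  expect_equal(back$frames, s$frames, tolerance = 1e-6)
  expect_equal(back$t_min, s$t_min)
  expect_identical(back$decay_corrected, FALSE)
  unlink(c(path, paste0(path, ".json")))
})

test_that("poisson noise is seeded and mean-preserving at high counts", {
  dm <- c(4, 4, 6)
  dom <- mk_duct_domain(4, 4, 6, h = 0.5)
  dep <- array(100, dm)
  frames <- list(list(deposited = dep, suspended = array(0, dm), t_min = 5))
  sr <- mk_fake_seeding(dm, frames, weight = 1000)
  p1 <- synthesize_pet(sr, dom, free_tracer_fraction = 0, psf_mm = 0,
                       noise = "poisson", counts_per_MBq = 1e6, seed = 5)
  p2 <- synthesize_pet(sr, dom, free_tracer_fraction = 0, psf_mm = 0,
                       noise = "poisson", counts_per_MBq = 1e6, seed = 5)
  expect_identical(p1$frames, p2$frames)
  p0 <- synthesize_pet(sr, dom, free_tracer_fraction = 0, psf_mm = 0,
                       noise = "none")
  expect_lt(abs(sum(p1$frames[[1]]) - sum(p0$frames[[1]])) / sum(p0$frames[[1]]),
            0.01)
})
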