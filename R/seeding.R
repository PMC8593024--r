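#' Perfusion protocol
#'
#' Seeding protocols used in the studies: 60 min of cell-suspension
#' perfusion followed by a 40 min washout with cell-free buffer, reported
#' in 5-min frames. Oscillating mode reverses the flow direction either
#' once at 30 min (the imaging protocol; default) or every 5 min (the
#' microscopy protocol; set `switch_every_min = 5`).
#'
#' @param mode `"unidirectional"` or `"oscillating"`.
#' @param rate_ml_min perfusion rate, ml/min.
#' @param switch_at_min reversal times (min) for oscillating mode.
#' @param switch_every_min alternative: reverse every this many minutes.
#' @param seeding_duration_min cell perfusion duration (default 60).
#' @param washout_duration_min washout duration (default 40).
#' @param frame_min reporting frame length (default 5).
#' @return A `perfusion_protocol`.
#' @export
perfusion_protocol <- function(mode = c("unidirectional", "oscillating"),
                               rate_ml_min = 0.5,
                               switch_at_min = 30, switch_every_min = NULL,
                               seeding_duration_min = 60,
                               washout_duration_min = 40, frame_min = 5) {
  mode <- match.arg(mode)
  stopifnot(rate_ml_min > 0, seeding_duration_min > 0,
            washout_duration_min >= 0, frame_min > 0)
  schedule <- numeric(0)
  if (mode == "oscillating") {
    schedule <- if (!is.null(switch_every_min)) {
      seq(switch_every_min, seeding_duration_min - 1e-9, by = switch_every_min)
    } else sort(switch_at_min)
    if (any(schedule <= 0 | schedule >= seeding_duration_min)) {
      abort("reversal times must fall inside the seeding window")
    }
  }
  structure(list(mode = mode, rate_ml_min = rate_ml_min,
                 switch_schedule = schedule,
                 seeding_duration_min = seeding_duration_min,
                 washout_duration_min = washout_duration_min,
                 frame_min = frame_min),
            class = "perfusion_protocol")
}

#' Cell suspension properties
#'
#' @param concentration_cells_ml cell concentration, cells/ml (study range
#'   0.06e6 to 1.22e6; reference operating point 0.4e6).
#' @param cell_diameter_um cell diameter, um (default 15, a typical
#'   adipose-derived stem cell scale).
#' @param cell_density_kg_m3 cell density (default 1050).
#' @param props carrier `fluid_props`.
#' @return A `cell_suspension`.
#' @export
cell_suspension <- function(concentration_cells_ml = 0.4e6,
                            cell_diameter_um = 15,
                            cell_density_kg_m3 = 1050,
                            props = fluid_props()) {
  stopifnot(concentration_cells_ml >= 0, cell_diameter_um > 0)
  structure(list(concentration_cells_ml = concentration_cells_ml,
                 cell_diameter_um = cell_diameter_um,
                 cell_density_kg_m3 = cell_density_kg_m3, props = props),
            class = "cell_suspension")
}

#' Stokes settling velocity of a suspended cell
#'
#' \eqn{v_s = \Delta\rho\, g\, d^2 / (18 \mu)}, positive along the forward
#' flow axis (+z, top-to-bottom perfusion).
#'
#' @param suspension a `cell_suspension`.
#' @return settling speed in mm/s.
#' @export
settling_velocity <- function(suspension) {
  drho <- suspension$cell_density_kg_m3 - suspension$props$density_kg_m3   # kg/m^3
  d <- suspension$cell_diameter_um * 1e-6                                  # m
  mu <- suspension$props$viscosity_mPas * 1e-3                             # Pa s
  (drho * 9.80665 * d^2 / (18 * mu)) * 1e3                                 # mm/s
}

#' Deposition (adhesion) model parameters
#'
#' The free parameters of the cell capture model: particles in voxels with
#' available solid surface adhere with hazard rate
#' `adhesion_prob * v_dep * S_v` where `S_v` is the local surface area per
#' volume, `v_dep` the deposition velocity (settling plus a diffusive
#' term), modulated multiplicatively by shear
#' (`max(0, 1 - shear/threshold)`) and by remaining surface capacity.
#' These are model parameters, not measured values; `adhesion_prob` is
#' calibrated to the 80% reference seeding efficiency at 0.4e6 cells/ml
#' and 0.5 ml/min (see [calibrate_deposition()]); the shipped default is
#' the result of that calibration.
#'
#' @param adhesion_prob sticking efficiency per surface encounter, \[0, 1\].
#' @param shear_detach_threshold_s1 shear rate (1/s) above which adhesion
#'   is fully suppressed; scaling is linear below it.
#' @param surface_capacity_cells_mm2 saturation surface density, cells/mm^2.
#' @param diffusion_mm2_s random-walk (dispersion) coefficient, mm^2/s.
#' @param settling include gravitational settling.
#' @return A `deposition_params`.
#' @export
deposition_params <- function(adhesion_prob = 0.15,
                              shear_detach_threshold_s1 = 50,
                              surface_capacity_cells_mm2 = 3000,
                              diffusion_mm2_s = 5e-3,
                              settling = TRUE) {
  stopifnot(adhesion_prob >= 0, adhesion_prob <= 1,
            shear_detach_threshold_s1 > 0, surface_capacity_cells_mm2 > 0,
            diffusion_mm2_s >= 0)
  structure(list(adhesion_prob = adhesion_prob,
                 shear_detach_threshold_s1 = shear_detach_threshold_s1,
                 surface_capacity_cells_mm2 = surface_capacity_cells_mm2,
                 diffusion_mm2_s = diffusion_mm2_s, settling = settling),
            class = "deposition_params")
}

# solid surface area per voxel (mm^2): homogenized scaffold voxels carry
# 6(1-phi)/d_pore per unit volume; resolved voxels and open voxels count
# solid/wall-adjacent faces
surface_area_field <- function(domain) {
  lab <- domain$labels
  h <- domain$voxel_mm
  solid <- !open_mask(domain)
  nfaces <- array(0, dim(lab))
  for (d in 1:3) {
    nfaces <- nfaces + shift3(solid * 1, d, 1L, fill = 1) +
                       shift3(solid * 1, d, -1L, fill = 1)
  }
  area <- nfaces * h^2
  area[solid] <- 0
  scaff <- lab == DOMAIN_LABELS[["SCAFFOLD_FLUID"]]
  if (!domain$resolved) {
    phi <- domain$porosity_field
    sv <- 6 * (1 - phi) / (domain_pore_scale(domain))   # 1/mm
    area[scaff] <- sv[scaff] * h^3
  }
  area
}

# trilinear interpolation of a cell-centered field at positions (n x 3), mm
trilinear <- function(field, pos, h) {
  trilinear3(list(field), pos, h)[[1]]
}

# shared-weight trilinear interpolation of several fields at once
trilinear3 <- function(fields, pos, h) {
  dm <- dim(fields[[1]])
  n <- nrow(pos)
  cidx <- pos / h + 0.5                          # continuous voxel index
  i0 <- pmin(pmax(floor(cidx), 1), rep(dm, each = n) - 1)
  fr <- pmin(pmax(cidx - i0, 0), 1)
  out <- rep(list(numeric(n)), length(fields))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
           (if (dy) fr[, 2] else 1 - fr[, 2]) *
           (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- (i0[, 1] + dx) + dm[1] * (i0[, 2] + dy - 1) + dm[1] * dm[2] * (i0[, 3] + dz - 1)
    for (f in seq_along(fields)) out[[f]] <- out[[f]] + wgt * fields[[f]][lin]
  }
  out
}

# voxel linear index of positions
pos_to_voxel <- function(pos, dm, h) {
  ii <- pmin(pmax(ceiling(pos / h), 1), rep(dm, each = nrow(pos)))
  ii[, 1] + dm[1] * (ii[, 2] - 1) + dm[1] * dm[2] * (ii[, 3] - 1)
}

#' Simulate cell seeding and washout in a solved flow field
#'
#' Lagrangian particle simulation of cell transport, adhesion and washout.
#' Representative particles (each standing for an equal number of real
#' cells) are injected at the inlet at rate c x Q over the seeding phase,
#' advected by the interpolated velocity field (interstitial velocity
#' inside the homogenized scaffold), displaced by gravitational settling
#' and an isotropic random walk, and captured on solid surface with the
#' hazard model of [deposition_params()]. Oscillating protocols swap the
#' active field at the scheduled reversal times (the reverse field is the
#' negated forward field by Stokes reversibility). The washout phase
#' injects no particles. The particle ledger is conserved exactly:
#' injected = deposited + in_domain + outflowed.
#'
#' @param flow_forward solved forward `flow_field`.
#' @param domain the matching `simulation_domain`.
#' @param protocol a `perfusion_protocol`; its `rate_ml_min` rescales the
#'   flow field linearly if it differs from the solved rate.
#' @param suspension a `cell_suspension`.
#' @param params a `deposition_params`.
#' @param seed integer RNG seed (same seed, same result).
#' @param n_particles number of representative particles injected over the
#'   seeding phase (default 1500).
#' @param dt_s base time step, s (default 2; automatically sub-stepped so
#'   no particle moves more than one voxel per sub-step).
#' @param flow_reverse optional solved reverse field (defaults to the
#'   negated forward field).
#' @return A `seeding_result`: deposited-cell voxel field, integer particle
#'   ledger, per-frame retention series and frame snapshots, seeding
#'   efficiency (scaffold-deposited / injected), and per-region counts.
#' @export
simulate_seeding <- function(flow_forward, domain, protocol, suspension,
                             params = deposition_params(), seed = 1L,
                             n_particles = 1500, dt_s = 2,
                             flow_reverse = NULL) {
  stopifnot(inherits(flow_forward, "flow_field"),
            inherits(domain, "simulation_domain"),
            inherits(protocol, "perfusion_protocol"),
            inherits(suspension, "cell_suspension"),
            inherits(params, "deposition_params"))
  if (!identical(dim(flow_forward$u), dim(domain$labels))) {
    abort("flow field and domain grids do not match")
  }
  h <- domain$voxel_mm
  dm <- dim(domain$labels)
  scale <- protocol$rate_ml_min / abs(flow_forward$inlet_flow_ml_min)
  fwd <- list(u = flow_forward$u * scale, v = flow_forward$v * scale,
              w = flow_forward$w * scale)
  rev <- if (is.null(flow_reverse)) {
    lapply(fwd, function(x) -x)
  } else {
    s2 <- protocol$rate_ml_min / abs(flow_reverse$inlet_flow_ml_min)
    list(u = flow_reverse$u * s2, v = flow_reverse$v * s2, w = flow_reverse$w * s2)
  }

  # interstitial correction inside the homogenized scaffold
  phi_eff <- array(1, dm)
  scaffm <- domain$labels == DOMAIN_LABELS[["SCAFFOLD_FLUID"]]
  scaff_lin <- which(scaffm)
  if (!domain$resolved) {
    pf <- domain$porosity_field
    phi_eff[scaffm] <- pmax(pf[scaffm], 0.05)
  }
  for (nm in names(fwd)) { fwd[[nm]] <- fwd[[nm]] / phi_eff; rev[[nm]] <- rev[[nm]] / phi_eff }

  area <- surface_area_field(domain)
  shear <- shear_rate_field(
    flow_field(fwd$u * phi_eff, fwd$v * phi_eff, fwd$w * phi_eff, h))
  shear_fac <- pmax(0, 1 - shear / params$shear_detach_threshold_s1)
  # surface capacity is tracked per z-slice of the scaffold (a deposition
  # front filling downstream), per voxel elsewhere; representative-particle
  # granularity is much coarser than a single voxel's surface
  zslice <- as.integer(slice.index(domain$labels, 3))
  slice_capacity <- vapply(seq_len(dm[3]), function(z) {
    sum(area[, , z][scaffm[, , z]])
  }, numeric(1)) * params$surface_capacity_cells_mm2        # cells per slice
  wall_capacity <- vapply(seq_len(dm[3]), function(z) {
    sum(area[, , z][!scaffm[, , z]])
  }, numeric(1)) * params$surface_capacity_cells_mm2        # non-scaffold walls
  vdep <- (if (params$settling) abs(settling_velocity(suspension)) else 0) +
    params$diffusion_mm2_s / (max(domain_pore_scale(domain), h) / 2)
  hazard0 <- params$adhesion_prob * vdep * area / h^3        # 1/s
  open <- open_mask(domain)
  blocked <- !open

  Q <- ml_min_to_mm3_s(protocol$rate_ml_min)
  T_seed <- protocol$seeding_duration_min * 60
  T_total <- T_seed + protocol$washout_duration_min * 60
  frame_s <- protocol$frame_min * 60
  n_frames <- ceiling(T_total / frame_s)
  cells_total <- suspension$concentration_cells_ml * protocol$rate_ml_min *
    protocol$seeding_duration_min
  weight <- cells_total / n_particles                        # real cells/particle

  port_xyz_in  <- arrayInd(label_idx(domain, "INLET_PORT"), dm)
  port_xyz_out <- arrayInd(label_idx(domain, "OUTLET_PORT"), dm)
  out_port <- array(FALSE, dm)
  out_port[label_idx(domain, "OUTLET_PORT")] <- TRUE
  out_port[label_idx(domain, "INLET_PORT")] <- TRUE          # exit in reverse phase
  vs <- if (params$settling) settling_velocity(suspension) else 0

  switch_s <- protocol$switch_schedule * 60
  deposited <- array(0L, dm)                                 # particles per voxel
  slice_dep <- integer(dm[3])                                # scaffold particles per slice
  wall_dep <- integer(dm[3])                                 # wall particles per slice
  pos <- matrix(numeric(0), 0, 3)
  n_inj <- 0L; n_out <- 0L
  inj_acc <- 0
  retention <- integer(n_frames)
  frames <- vector("list", n_frames)
  dt_min <- 1e-3

  with_seed(seed, {
    nstep <- ceiling(T_total / dt_s)
    for (step in seq_len(nstep)) {
      t0 <- (step - 1) * dt_s
      t1 <- min(step * dt_s, T_total)
      dt <- t1 - t0
      n_rev <- sum(switch_s <= t0)
      fld <- if (n_rev %% 2 == 0) fwd else rev
      # injection during seeding, from the active upstream port
      if (t0 < T_seed) {
        inj_acc <- inj_acc + n_particles * dt / T_seed
        k <- floor(inj_acc)
        if (k >= 1) {
          inj_acc <- inj_acc - k
          forward_phase <- n_rev %% 2 == 0
          pxy <- if (forward_phase) port_xyz_in else port_xyz_out
          pick <- sample.int(nrow(pxy), k, replace = TRUE)
          newp <- (pxy[pick, , drop = FALSE] - matrix(runif(3 * k), k, 3)) * h
          # first interior layer inside the active upstream connector
          newp[, 3] <- if (forward_phase) (2 - runif(k)) * h
                       else (dm[3] - 1 - runif(k)) * h
          pos <- rbind(pos, newp)
          n_inj <- n_inj + k
        }
      }
      if (nrow(pos)) {
        # advect with per-particle sub-stepping (<= 1 voxel per move)
        remaining <- rep(dt, nrow(pos))
        guard <- 0L
        while (any(remaining > 0)) {
          guard <- guard + 1L
          act <- which(remaining > 0)
          p <- pos[act, , drop = FALSE]
          vel3 <- trilinear3(list(fld$u, fld$v, fld$w), p, h)
          vel <- cbind(vel3[[1]], vel3[[2]], vel3[[3]])
          vel[, 3] <- vel[, 3] + vs
          spd <- sqrt(rowSums(vel^2))
          dts <- pmin(remaining[act], 0.9 * h / pmax(spd, 1e-9))
          dts <- pmax(dts, pmin(remaining[act], dt_min))
          if (guard > 200L) abort("particle sub-stepping below the minimum time step")
          newp <- p + vel * dts
          if (params$diffusion_mm2_s > 0) {
            newp <- newp + matrix(rnorm(length(newp),
                                        sd = sqrt(2 * params$diffusion_mm2_s * dts)),
                                  ncol = 3)
          }
          # reject moves into walls/solid
          vox_new <- pos_to_voxel(newp, dm, h)
          bad <- blocked[vox_new]
          newp[bad, ] <- p[bad, , drop = FALSE]
          pos[act, ] <- newp
          remaining[act] <- remaining[act] - dts
        }
        # outflow through either port layer
        vox <- pos_to_voxel(pos, dm, h)
        gone <- out_port[vox]
        if (any(gone)) {
          n_out <- n_out + sum(gone)
          pos <- pos[!gone, , drop = FALSE]
          vox <- vox[!gone]
        }
        # adhesion: capture hazard, then acceptance by remaining capacity
        # (a representative particle can carry more cells than one voxel's
        # capacity; accepting with probability remaining/weight keeps the
        # deposited cell count unbiased)
        if (nrow(pos)) {
          lam <- hazard0[vox] * shear_fac[vox]
          in_scaff <- scaffm[vox]
          zz <- zslice[vox]
          rem <- ifelse(in_scaff,
                        slice_capacity[zz] - slice_dep[zz] * weight,
                        wall_capacity[zz] - wall_dep[zz] * weight)
          capfac <- pmin(1, pmax(0, rem) / weight)
          pcap <- -expm1(-lam * dt) * capfac
          hit <- runif(length(pcap)) < pcap
          if (any(hit)) {
            tab <- table(vox[hit])
            ii <- as.integer(names(tab))
            deposited[ii] <- deposited[ii] + as.integer(tab)
            tz <- table(zz[hit & in_scaff])
            iz <- as.integer(names(tz))
            slice_dep[iz] <- slice_dep[iz] + as.integer(tz)
            tw <- table(zz[hit & !in_scaff])
            iw <- as.integer(names(tw))
            wall_dep[iw] <- wall_dep[iw] + as.integer(tw)
            pos <- pos[!hit, , drop = FALSE]
          }
        }
      }
      # frame bookkeeping: record each frame once, as soon as it completes
      fidx <- floor(t1 / frame_s + 1e-9)
      if (t1 >= T_total) fidx <- n_frames
      if (fidx >= 1 && fidx <= n_frames && is.null(frames[[fidx]])) {
        retention[fidx] <- nrow(pos) + sum(deposited)
        susp <- array(0, dm)
        if (nrow(pos)) {
          vox <- pos_to_voxel(pos, dm, h)
          tb <- table(vox)
          susp[as.integer(names(tb))] <- as.numeric(tb)
        }
        frames[[fidx]] <- list(deposited = deposited * 1.0, suspended = susp,
                               t_min = fidx * protocol$frame_min)
      }
    }
  })

  scaff_dep <- sum(deposited[scaffm])
  zr <- domain$scaffold_z
  thirds <- floor(seq(zr[1] - 1, zr[2], length.out = 4))
  region_count <- function(zlo, zhi) {
    m <- array(FALSE, dm); m[, , (zlo + 1L):zhi] <- TRUE
    sum(deposited[m & scaffm])
  }
  per_region <- tibble::tibble(
    region = c("inflow_tract", "upper", "middle", "lower", "outflow_tract"),
    particles = c(
      sum(deposited[, , 1:(zr[1] - 1L)]),
      region_count(thirds[1], thirds[2]),
      region_count(thirds[2], thirds[3]),
      region_count(thirds[3], thirds[4]),
      sum(deposited[, , (zr[2] + 1L):dm[3]])
    )
  )
  per_region$cells <- per_region$particles * weight

  structure(list(
    deposited_cells = deposited * weight,
    deposited_particles = deposited,
    ledger = c(injected = as.integer(n_inj), deposited = as.integer(sum(deposited)),
               in_domain = as.integer(nrow(pos)), outflowed = as.integer(n_out)),
    retention_series = tibble::tibble(
      frame = seq_len(n_frames),
      t_min = seq_len(n_frames) * protocol$frame_min,
      retained_particles = retention,
      retained_cells = retention * weight
    ),
    frames = frames,
    efficiency = if (n_inj > 0) scaff_dep / n_inj else 0,
    per_region = per_region,
    particle_weight_cells = weight,
    protocol = protocol, suspension = suspension, params = params,
    seed = as.integer(seed), voxel_mm = h
  ), class = "seeding_result")
}

#' @export
print.seeding_result <- function(x, ...) {
  l <- x$ledger
  cat(sprintf(
    "<seeding_result> %s, %.3g ml/min: injected %d, deposited %d, in domain %d, outflowed %d particles\n  seeding efficiency (scaffold) = %.3f\n",
    x$protocol$mode, x$protocol$rate_ml_min,
    l[["injected"]], l[["deposited"]], l[["in_domain"]], l[["outflowed"]],
    x$efficiency))
  invisible(x)
}

#' Seeding efficiency from cell counts
#'
#' Experimental definition: cells retained in the scaffold relative to the
#' cells deployed, from counts recovered in the outflow, the washout and
#' the cleaning solution:
#' `(inflow - outflow - washout - cleaning) / inflow`.
#'
#' @param inflow_cells cells deployed (> 0).
#' @param outflow_cells,washout_cells,cleaning_cells recovered counts.
#' @return fraction in \[0, 1\] (clipped with a warning if negative).
#' @export
efficiency_from_counts <- function(inflow_cells, outflow_cells,
                                   washout_cells, cleaning_cells) {
  stopifnot(all(c(outflow_cells, washout_cells, cleaning_cells) >= 0))
  if (inflow_cells <= 0) abort("inflow cell count must be positive")
  eff <- (inflow_cells - outflow_cells - washout_cells - cleaning_cells) / inflow_cells
  if (eff < 0) {
    warn(sprintf("recovered cells exceed inflow (efficiency %.3f); clipping to 0", eff))
    eff <- 0
  }
  min(eff, 1)
}

#' Calibrate the adhesion probability to a target seeding efficiency
#'
#' Coarse grid over `adhesion_prob` followed by bisection, evaluating the
#' ensemble-mean simulated efficiency at the reference operating point
#' (0.4e6 cells/ml, 0.5 ml/min, type 2 chamber with encasement,
#' unidirectional perfusion) or any supplied reference condition.
#'
#' @param target_efficiency target in \[0, 1\].
#' @param flow,domain solved reference flow field and domain (type 2 enc+
#'   at 0.5 ml/min when following the study design).
#' @param protocol,suspension reference protocol and suspension.
#' @param params template `deposition_params`; only `adhesion_prob` is
#'   searched.
#' @param seeds seeds of the calibration ensemble.
#' @param tol_pp acceptable deviation, percentage points (default 5).
#' @param grid initial adhesion-probability grid.
#' @param ... passed on to [simulate_seeding()].
#' @return A `deposition_params` with the calibrated `adhesion_prob`.
#' @export
calibrate_deposition <- function(target_efficiency, flow, domain,
                                 protocol = perfusion_protocol("unidirectional",
                                                               rate_ml_min = 0.5),
                                 suspension = cell_suspension(0.4e6),
                                 params = deposition_params(),
                                 seeds = 1:3, tol_pp = 5,
                                 grid = c(0.05, 0.15, 0.35, 0.65, 1), ...) {
  stopifnot(target_efficiency >= 0, target_efficiency <= 1)
  if (target_efficiency == 0) {
    params$adhesion_prob <- 0
    return(params)
  }
  eval_eff <- function(p) {
    pp <- params; pp$adhesion_prob <- p
    mean(vapply(seeds, function(s) {
      simulate_seeding(flow, domain, protocol, suspension, pp, seed = s, ...)$efficiency
    }, numeric(1)))
  }
  effs <- vapply(grid, eval_eff, numeric(1))
  if (max(effs) + tol_pp / 100 < target_efficiency) {
    abort(sprintf("target efficiency %.2f unreachable (max %.2f at adhesion_prob %.2f)",
                  target_efficiency, max(effs), grid[which.max(effs)]))
  }
  k <- which.min(abs(effs - target_efficiency))
  lo <- if (k > 1) grid[k - 1] else 0
  hi <- if (k < length(grid)) grid[k + 1] else grid[k]
  best_p <- grid[k]; best_e <- effs[k]
  for (i in 1:6) {
    if (abs(best_e - target_efficiency) <= tol_pp / 100 / 2) break
    mid <- (lo + hi) / 2
    e <- eval_eff(mid)
    if (abs(e - target_efficiency) < abs(best_e - target_efficiency)) {
      best_p <- mid; best_e <- e
    }
    if (e < target_efficiency) lo <- mid else hi <- mid
  }
  params$adhesion_prob <- best_p
  params
}
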