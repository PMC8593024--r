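#' Fluid properties of the perfusate
#'
#' Defaults are the rheometer-measured values for a cell suspension at
#' 1e6 cells/ml and 37 C: dynamic viscosity 1.176 mPa s, density
#' 1004 kg/m^3.
#'
#' @param viscosity_mPas dynamic viscosity, mPa s.
#' @param density_kg_m3 density, kg/m^3.
#' @return A `fluid_props` object.
#' @export
fluid_props <- function(viscosity_mPas = 1.176, density_kg_m3 = 1004) {
  stopifnot(viscosity_mPas > 0, density_kg_m3 > 0)
  structure(list(viscosity_mPas = viscosity_mPas, density_kg_m3 = density_kg_m3),
            class = "fluid_props")
}

#' Kozeny-Carman permeability
#'
#' \eqn{k = \phi^3 d^2 / (C (1-\phi)^2)} with the classic granular
#' constant C = 180 and d the pore/grain scale.
#'
#' @param porosity fluid volume fraction in (0, 1).
#' @param pore_scale_mm characteristic pore scale, mm.
#' @param constant Kozeny-Carman constant (default 180).
#' @return permeability in mm^2.
#' @export
kozeny_carman <- function(porosity, pore_scale_mm, constant = 180) {
  phi <- pmin(pmax(porosity, 0.02), 0.98)
  phi^3 * pore_scale_mm^2 / (constant * (1 - phi)^2)
}

# construct a flow_field container from cell-centered fields (also used to
# build synthetic fields in tests)
#' Construct a flow field from cell-centered velocity arrays
#'
#' Mainly useful for constructing synthetic fields; [solve_flow()] returns
#' the same container with face velocities and pressure attached.
#'
#' @param u,v,w cell-centered velocity components, mm/s (3-D arrays).
#' @param voxel_mm voxel edge length, mm.
#' @param pressure optional pressure array, Pa.
#' @param inlet_flow_ml_min prescribed flow rate, ml/min.
#' @param ... further fields stored as-is (face arrays, residuals, mode).
#' @return A `flow_field`.
#' @export
flow_field <- function(u, v, w, voxel_mm, pressure = NULL,
                       inlet_flow_ml_min = NA_real_, ...) {
  stopifnot(identical(dim(u), dim(v)), identical(dim(u), dim(w)))
  structure(list(u = u, v = v, w = w, p = pressure, voxel_mm = voxel_mm,
                 inlet_flow_ml_min = inlet_flow_ml_min, ...),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  vm <- velocity_magnitude(x)
  cat(sprintf("<flow_field> %s cells @ %.3g mm, Q = %.3g ml/min, max |u| = %.4g mm/s\n",
              paste(dim(x$u), collapse = " x "), x$voxel_mm,
              x$inlet_flow_ml_min, max(vm)))
  if (!is.null(x$residuals)) {
    cat(sprintf("  schur-cg: %d iterations, rel. residual %.2e, max |div| %.2e 1/s\n",
                x$residuals$iterations, x$residuals$rel_residual, x$residuals$max_div))
  }
  invisible(x)
}

#' Cell-centered velocity magnitude
#' @param flow a `flow_field`.
#' @return 3-D array of |u| in mm/s.
#' @export
velocity_magnitude <- function(flow) sqrt(flow$u^2 + flow$v^2 + flow$w^2)

# face activity/known-value layout for one component
face_layout <- function(open, d) {
  dm <- dim(open)
  fdim <- dm; fdim[d] <- fdim[d] + 1L
  act <- array(FALSE, fdim)
  idx_lo <- idx_hi <- as.list(rep(TRUE, 3))
  nL <- dm[d]
  iface <- 2:nL                      # interior face positions along d
  argL <- argR <- argF <- as.list(rep(TRUE, 3))
  argL[[d]] <- 1:(nL - 1); argR[[d]] <- 2:nL; argF[[d]] <- iface
  both <- do.call(`[`, c(list(open), argL, drop = FALSE)) &
          do.call(`[`, c(list(open), argR, drop = FALSE))
  act <- do.call(`[<-`, c(list(act), argF, list(both)))
  act
}

# shift an array by +1/-1 along axis d, padding with `fill`
shift3 <- function(x, d, by, fill = 0) {
  dm <- dim(x)
  out <- array(fill, dm)
  src <- dst <- as.list(rep(TRUE, 3))
  n <- dm[d]
  if (by == 1L) { src[[d]] <- 1:(n - 1); dst[[d]] <- 2:n }
  else          { src[[d]] <- 2:n;       dst[[d]] <- 1:(n - 1) }
  do.call(`[<-`, c(list(out), dst,
                   list(do.call(`[`, c(list(x), src, drop = FALSE)))))
}

#' Solve steady Stokes-Brinkman flow through a reactor domain
#'
#' Creeping (inertia-free) incompressible flow on a marker-and-cell
#' staggered voxel grid: open regions obey Stokes flow; scaffold voxels
#' carry an isotropic Brinkman drag \eqn{\mu/k} with Kozeny-Carman
#' permeability from the local porosity field (`mode = "homogenized"`), or
#' are treated as exact no-slip obstacles where the domain resolves the
#' pore structure (`mode = "resolved"`). Boundary conditions follow the
#' study protocol: uniform normal velocity Q/A over the inlet port, outlet
#' at zero reference pressure (uniform outflow velocity with the pressure
#' re-referenced to the outlet-plane mean), no slip on all walls.
#'
#' The discrete saddle-point system is solved by conjugate gradients on
#' the pressure Schur complement with sparse Cholesky factorizations of
#' the per-component momentum blocks and a diagonal (SIMPLE-type)
#' preconditioner. At creeping-flow Reynolds numbers the solution is
#' linear in Q and exactly reversible.
#'
#' @param domain a `simulation_domain`.
#' @param props a `fluid_props`.
#' @param inlet_flow_ml_min prescribed inlet flow rate, ml/min (> 0).
#' @param mode `"homogenized"` or `"resolved"`. Resolved mode requires a
#'   domain built at the scaffold's native voxel size.
#' @param direction `"forward"` (inlet -> outlet, +z) or `"reverse"`
#'   (roles swapped; by Stokes linearity this equals the negated forward
#'   field).
#' @param tol relative residual tolerance of the Schur CG (default 1e-8).
#' @param max_iter CG iteration budget.
#' @return A `flow_field` with cell-centered `u`, `v`, `w` (mm/s),
#'   pressure `p` (Pa, outlet-referenced), face velocities, shear-rate
#'   field accessor via [shear_rate_field()], and a `residuals` record.
#' @export
solve_flow <- function(domain, props = fluid_props(), inlet_flow_ml_min = 1,
                       mode = c("homogenized", "resolved"),
                       direction = c("forward", "reverse"),
                       tol = 1e-8, max_iter = 800) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  stopifnot(inherits(domain, "simulation_domain"), inlet_flow_ml_min > 0)
  if (mode == "resolved" && !domain$resolved) {
    abort("resolved mode requires a domain at the scaffold's native voxel size")
  }
  lab <- domain$labels
  dm <- dim(lab)
  h <- domain$voxel_mm
  mu <- props$viscosity_mPas * 1e-3      # Pa s
  open <- open_mask(domain)
  if (mode == "homogenized" && !domain$resolved) {
    # nothing extra: scaffold voxels are open with porosity field
  }
  if (!any(lab == DOMAIN_LABELS[["INLET_PORT"]]) ||
      !any(lab == DOMAIN_LABELS[["OUTLET_PORT"]])) {
    abort("domain has no inlet/outlet port voxels")
  }
  if (!ports_connected(domain)) abort("inlet and outlet ports are not connected")

  Q <- ml_min_to_mm3_s(inlet_flow_ml_min)      # mm^3/s
  sgn <- if (direction == "forward") 1 else -1
  port_in  <- lab[, , 1] == DOMAIN_LABELS[["INLET_PORT"]]
  port_out <- lab[, , dm[3]] == DOMAIN_LABELS[["OUTLET_PORT"]]
  u_in  <- sgn * Q / (sum(port_in) * h^2)
  u_out <- sgn * Q / (sum(port_out) * h^2)

  # cell drag (Pa s / mm^2)
  drag <- array(0, dm)
  if (mode == "homogenized") {
    scaff <- lab == DOMAIN_LABELS[["SCAFFOLD_FLUID"]]
    phi <- domain$porosity_field
    phi[is.na(phi)] <- 1
    k <- kozeny_carman(phi, domain_pore_scale(domain))
    drag[scaff] <- mu / k[scaff]
  }

  ncell <- sum(open)
  cell_id <- array(0L, dm)
  cell_id[open] <- seq_len(ncell)

  comp <- vector("list", 3)
  nface_tot <- 0L
  for (d in 1:3) {
    act <- face_layout(open, d)
    fdim <- dim(act)
    known <- array(0, fdim)
    if (d == 3L) {
      k1 <- known[, , 1]; k1[port_in] <- u_in; known[, , 1] <- k1
      k2 <- known[, , fdim[3]]; k2[port_out] <- u_out; known[, , fdim[3]] <- k2
    }
    fid <- array(0L, fdim)
    nf <- sum(act)
    fid[act] <- seq_len(nf) + nface_tot
    nface_tot <- nface_tot + nf
    comp[[d]] <- list(act = act, known = known, fid = fid, fdim = fdim, nf = nf)
  }

  mu_h2 <- mu / h^2
  tri_i <- tri_j <- vector("list", 3)
  tri_x <- vector("list", 3)
  rhs_u <- numeric(nface_tot)
  Gi <- Gj <- Gx <- vector("list", 3)
  gp <- numeric(ncell)                      # continuity RHS from known faces

  for (d in 1:3) {
    cc <- comp[[d]]
    act <- cc$act; fdim <- cc$fdim
    fidx <- which(act)
    n <- length(fidx)
    row <- cc$fid[act] - (cc$fid[act][1] - 1L)  # local 1..n (fids are contiguous)
    diag_v <- numeric(n)
    off_i <- off_j <- integer(0); off_x <- numeric(0)
    # face drag: mean of adjacent cells
    argL <- argR <- as.list(rep(TRUE, 3))
    nL <- dm[d]
    argL[[d]] <- 1:(nL - 1); argR[[d]] <- 2:nL
    dr_face <- array(0, fdim)
    interior <- as.list(rep(TRUE, 3)); interior[[d]] <- 2:nL
    dr_face <- do.call(`[<-`, c(list(dr_face), interior, list(
      (do.call(`[`, c(list(drag), argL, drop = FALSE)) +
       do.call(`[`, c(list(drag), argR, drop = FALSE))) / 2)))
    diag_v <- diag_v + dr_face[act]

    for (dn in 1:3) {
      for (by in c(-1L, 1L)) {
        nb_fid <- shift3(cc$fid, dn, -by, fill = 0L)   # fid of neighbor at +by
        nb_known <- shift3(cc$known, dn, -by, fill = 0)
        nb_act <- nb_fid > 0L
        v_act <- nb_act[act]
        v_fid <- nb_fid[act]
        v_kn <- nb_known[act]
        # active neighbor: off-diagonal coupling
        sel <- v_act
        off_i <- c(off_i, which(sel))
        off_j <- c(off_j, v_fid[sel] - (cc$fid[act][1] - 1L))
        off_x <- c(off_x, rep(-mu_h2, sum(sel)))
        diag_v[sel] <- diag_v[sel] + mu_h2
        # inactive neighbor
        if (dn == d) {       # longitudinal: Dirichlet value at full spacing
          diag_v[!sel] <- diag_v[!sel] + mu_h2
          rhs_here <- mu_h2 * v_kn
          rhs_here[sel] <- 0
        } else {             # tangential: wall at half spacing, mirror ghost
          diag_v[!sel] <- diag_v[!sel] + 2 * mu_h2
          rhs_here <- 2 * mu_h2 * v_kn
          rhs_here[sel] <- 0
        }
        base <- cc$fid[act]
        rhs_u[base] <- rhs_u[base] + rhs_here
      }
    }
    tri_i[[d]] <- c(seq_len(n), off_i)
    tri_j[[d]] <- c(seq_len(n), off_j)
    tri_x[[d]] <- c(diag_v, off_x)

    # gradient operator entries and continuity knowns for this component
    cl_f <- array(0L, fdim); ch_f <- array(0L, fdim)
    argF <- as.list(rep(TRUE, 3)); argF[[d]] <- 2:nL
    argLc <- as.list(rep(TRUE, 3)); argLc[[d]] <- 1:(nL - 1)
    argRc <- as.list(rep(TRUE, 3)); argRc[[d]] <- 2:nL
    cl_f <- do.call(`[<-`, c(list(cl_f), argF,
      list(do.call(`[`, c(list(cell_id), argLc, drop = FALSE)))))
    ch_f <- do.call(`[<-`, c(list(ch_f), argF,
      list(do.call(`[`, c(list(cell_id), argRc, drop = FALSE)))))
    # end-cap boundary faces: single adjacent cell
    aB <- as.list(rep(TRUE, 3)); aB[[d]] <- 1L
    aC <- as.list(rep(TRUE, 3)); aC[[d]] <- 1L
    ch_f <- do.call(`[<-`, c(list(ch_f), aB,
      list(do.call(`[`, c(list(cell_id), aC, drop = FALSE)))))
    aB[[d]] <- nL + 1L; aC[[d]] <- nL
    cl_f <- do.call(`[<-`, c(list(cl_f), aB,
      list(do.call(`[`, c(list(cell_id), aC, drop = FALSE)))))
    fL <- cl_f[act]; fH <- ch_f[act]
    base <- cc$fid[act]
    Gi[[d]] <- c(base, base)
    Gj[[d]] <- c(fH, fL)
    Gx[[d]] <- c(rep(1 / h, length(base)), rep(-1 / h, length(base)))
    # known faces adjacent to open cells contribute to continuity RHS
    kn_mask <- !act & cc$known != 0
    if (any(kn_mask)) {
      kn_idx <- which(kn_mask)
      kH <- ch_f[kn_idx]; kL <- cl_f[kn_idx]; kv <- cc$known[kn_idx]
      sel <- kH > 0L   # known face below/left of cell kH: contributes +v/h
      gp[kH[sel]] <- gp[kH[sel]] - kv[sel] / h
      sel <- kL > 0L
      gp[kL[sel]] <- gp[kL[sel]] + kv[sel] / h
    }
  }

  # assemble per-component momentum blocks and factor
  offs <- c(0L, cumsum(vapply(comp, function(z) z$nf, integer(1))))
  Afac <- vector("list", 3)
  for (d in 1:3) {
    n <- comp[[d]]$nf
    A <- Matrix::sparseMatrix(i = tri_i[[d]], j = tri_j[[d]], x = tri_x[[d]],
                              dims = c(n, n))
    A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
    Afac[[d]] <- Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
  }
  Gmat <- Matrix::sparseMatrix(i = unlist(Gi), j = unlist(Gj), x = unlist(Gx),
                               dims = c(nface_tot, ncell))
  Ainv <- function(x) {
    out <- numeric(nface_tot)
    for (d in 1:3) {
      rng <- (offs[d] + 1L):offs[d + 1L]
      out[rng] <- as.numeric(Matrix::solve(Afac[[d]], x[rng]))
    }
    out
  }
  Sapply <- function(p) as.numeric(Matrix::crossprod(Gmat, Ainv(as.numeric(Gmat %*% p))))

  # Jacobi-type Schur preconditioner: diag(S) ~ sum_f G^2 / diag(A)
  diagA <- numeric(nface_tot)
  for (d in 1:3) {
    n <- comp[[d]]$nf
    diagA[(offs[d] + 1L):offs[d + 1L]] <- tri_x[[d]][seq_len(n)]
  }
  Sdiag <- as.numeric(Matrix::crossprod(Gmat^2, 1 / diagA))
  Sdiag[Sdiag <= 0] <- mean(Sdiag[Sdiag > 0])

  rhs_p <- as.numeric(Matrix::crossprod(Gmat, Ainv(rhs_u))) - gp
  rhs_p <- rhs_p - mean(rhs_p)
  pvec <- numeric(ncell)
  r <- rhs_p
  z <- r / Sdiag; z <- z - mean(z)
  dvec <- z
  rz <- sum(r * z)
  nrm0 <- sqrt(sum(rhs_p^2))
  it <- 0L; rel <- 1
  if (nrm0 > 0) {
    for (it in seq_len(max_iter)) {
      Sd <- Sapply(dvec)
      alpha <- rz / sum(dvec * Sd)
      pvec <- pvec + alpha * dvec
      r <- r - alpha * Sd
      rel <- sqrt(sum(r^2)) / nrm0
      if (rel <= tol) break
      z <- r / Sdiag; z <- z - mean(z)
      rz_new <- sum(r * z)
      dvec <- z + (rz_new / rz) * dvec
      rz <- rz_new
    }
  } else rel <- 0
  if (rel > sqrt(tol)) {
    abort(sprintf(
      "flow solver failed to converge: relative residual %.2e after %d iterations",
      rel, it))
  }
  uvec <- Ainv(rhs_u - as.numeric(Gmat %*% pvec))

  # scatter back to face arrays (known values included)
  faces <- vector("list", 3)
  for (d in 1:3) {
    cc <- comp[[d]]
    fa <- cc$known
    fa[cc$act] <- uvec[(offs[d] + 1L):offs[d + 1L]]
    faces[[d]] <- fa
  }
  # cell-centered velocities
  avg_faces <- function(fa, d) {
    nL <- dm[d]
    a1 <- a2 <- as.list(rep(TRUE, 3))
    a1[[d]] <- 1:nL; a2[[d]] <- 2:(nL + 1L)
    (do.call(`[`, c(list(fa), a1, drop = FALSE)) +
     do.call(`[`, c(list(fa), a2, drop = FALSE))) / 2
  }
  u <- array(avg_faces(faces[[1]], 1), dm)
  v <- array(avg_faces(faces[[2]], 2), dm)
  w <- array(avg_faces(faces[[3]], 3), dm)

  # divergence check (1/s)
  divg <- array(0, dm)
  for (d in 1:3) {
    nL <- dm[d]
    a1 <- a2 <- as.list(rep(TRUE, 3))
    a1[[d]] <- 1:nL; a2[[d]] <- 2:(nL + 1L)
    divg <- divg + (do.call(`[`, c(list(faces[[d]]), a2, drop = FALSE)) -
                    do.call(`[`, c(list(faces[[d]]), a1, drop = FALSE))) / h
  }
  max_div <- max(abs(divg[open]))

  parr <- array(NA_real_, dm)
  parr[open] <- pvec
  out_cells <- lab == DOMAIN_LABELS[["OUTLET_PORT"]]
  parr <- parr - mean(parr[out_cells], na.rm = TRUE)

  flow_field(u, v, w, voxel_mm = h, pressure = parr,
             inlet_flow_ml_min = sgn * inlet_flow_ml_min,
             uf = faces[[1]], vf = faces[[2]], wf = faces[[3]],
             mode = mode, direction = direction, props = props,
             residuals = list(iterations = it, rel_residual = rel,
                              max_div = max_div))
}

#' Negate a flow field (Stokes reversibility)
#'
#' For creeping flow the field with inlet and outlet roles swapped is
#' exactly the negation of the forward field.
#'
#' @param flow a `flow_field`.
#' @return the negated `flow_field`.
#' @export
reverse_flow <- function(flow) {
  for (f in c("u", "v", "w", "uf", "vf", "wf")) {
    if (!is.null(flow[[f]])) flow[[f]] <- -flow[[f]]
  }
  flow$inlet_flow_ml_min <- -flow$inlet_flow_ml_min
  flow$direction <- if (identical(flow$direction, "forward")) "reverse" else "forward"
  flow
}

#' Volumetric flux through a cross-sectional plane
#'
#' @param flow a solved `flow_field` (face velocities present).
#' @param z_index z cell layer; flux is through that layer's lower face.
#' @return flux in mm^3/s (positive toward +z).
#' @export
plane_flux <- function(flow, z_index) {
  stopifnot(!is.null(flow$wf))
  sum(flow$wf[, , z_index]) * flow$voxel_mm^2
}

# gradient of a 3-D array along axis d: central differences, one-sided at
# the two boundary layers
grad3 <- function(x, d, h) {
  dm <- dim(x)
  n <- dm[d]
  out <- (shift3(x, d, -1L) - shift3(x, d, 1L)) / (2 * h)
  a_first <- a_second <- a_last <- a_prev <- as.list(rep(TRUE, 3))
  a_first[[d]] <- 1L; a_second[[d]] <- 2L; a_last[[d]] <- n; a_prev[[d]] <- n - 1L
  one_sided <- (do.call(`[`, c(list(x), a_second, drop = FALSE)) -
                do.call(`[`, c(list(x), a_first, drop = FALSE))) / h
  out <- do.call(`[<-`, c(list(out), a_first, list(one_sided)))
  one_sided <- (do.call(`[`, c(list(x), a_last, drop = FALSE)) -
                do.call(`[`, c(list(x), a_prev, drop = FALSE))) / h
  out <- do.call(`[<-`, c(list(out), a_last, list(one_sided)))
  out
}

#' Shear-rate magnitude field
#'
#' \eqn{\dot\gamma = \sqrt{2\, D\!:\!D}} with
#' \eqn{D = (\nabla u + \nabla u^T)/2} the rate-of-strain tensor, from
#' central differences on the cell-centered velocity (one-sided at
#' boundaries). Units 1/s.
#'
#' @param flow a `flow_field`.
#' @return 3-D array of shear rate, 1/s.
#' @export
shear_rate_field <- function(flow) {
  h <- flow$voxel_mm
  g <- list()
  for (ci in 1:3) {
    fld <- flow[[c("u", "v", "w")[ci]]]
    for (dj in 1:3) g[[paste0(ci, dj)]] <- grad3(fld, dj, h)
  }
  dd <- 0
  for (ci in 1:3) for (dj in 1:3) {
    Dij <- (g[[paste0(ci, dj)]] + g[[paste0(dj, ci)]]) / 2
    dd <- dd + Dij^2
  }
  sqrt(2 * dd)
}

#' Maximum shear rate inside the scaffold
#'
#' @param flow a solved `flow_field`.
#' @param domain the matching `simulation_domain`.
#' @return maximum of the shear-rate field over `SCAFFOLD_FLUID` voxels, 1/s.
#' @export
max_shear_in_scaffold <- function(flow, domain) {
  m <- domain$labels == DOMAIN_LABELS[["SCAFFOLD_FLUID"]]
  if (!any(m)) abort("domain has no scaffold fluid voxels")
  max(shear_rate_field(flow)[m])
}
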