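# region label codes for SimulationDomain voxel grids
DOMAIN_LABELS <- c(
  WALL = 0L, INLET_PORT = 1L, CONNECTOR = 2L, SCAFFOLD_FLUID = 3L,
  SCAFFOLD_SOLID = 4L, BYPASS_GAP = 5L, OUTLET_PORT = 6L, CHAMBER_FLUID = 7L
)
OPEN_LABELS <- DOMAIN_LABELS[c("INLET_PORT", "CONNECTOR", "SCAFFOLD_FLUID",
                               "BYPASS_GAP", "OUTLET_PORT", "CHAMBER_FLUID")]

#' Connector (inlet/outlet nozzle) specification
#'
#' Describes a perfusion-chamber connector: a straight cylindrical bore of
#' diameter `diameter_mm`, or a conical diffuser expanding linearly
#' (frustum) from a throat of `diameter_mm` at the port to a base of
#' `width_mm` at the scaffold face. A diffuser spreads the inflow over the
#' whole scaffold face instead of injecting a narrow jet.
#'
#' @param shape `"cylindrical"` or `"conical"`.
#' @param diameter_mm connector bore, mm: the cylinder diameter, or the
#'   cone's throat diameter at the port.
#' @param length_mm axial connector length, mm.
#' @param width_mm conical only: base width at the scaffold face, mm; must
#'   be at least `diameter_mm`.
#' @param bore_mm diameter of the tubing opening feeding the connector at
#'   its port end, mm; defaults to `min(diameter_mm, 1.6)` (a typical
#'   flow-tubing bore). The perfusate enters the connector body as a jet
#'   through this opening, which is what makes connector length and shape
#'   matter for flow homogeneity.
#' @return A `connector_spec` object.
#' @export
connector_spec <- function(shape = c("cylindrical", "conical"),
                           diameter_mm, length_mm, width_mm = NULL,
                           bore_mm = NULL) {
  shape <- match.arg(shape)
  stopifnot(diameter_mm > 0, length_mm > 0)
  if (shape == "conical") {
    if (is.null(width_mm)) abort("conical connectors require `width_mm`")
    if (width_mm < diameter_mm) abort("conical base width must be >= throat diameter")
  } else {
    width_mm <- diameter_mm
  }
  bore_mm <- bore_mm %||% min(diameter_mm, 1.6)
  if (bore_mm > diameter_mm + 1e-9) abort("bore_mm cannot exceed the connector diameter")
  structure(list(shape = shape, diameter_mm = diameter_mm,
                 length_mm = length_mm, width_mm = width_mm,
                 bore_mm = bore_mm),
            class = "connector_spec")
}

#' Reactor configuration
#'
#' Bundles chamber dimensions, inlet/outlet connectors, lateral encasement
#' state and scaffold orientation. With encasement (`encasement = TRUE`,
#' "enc+") the chamber is a press-fit, form-locking sleeve around the
#' scaffold so all flow crosses it; without (`enc-`) a uniform annular
#' bypass gap of `gap_mm` separates the scaffold's lateral faces from the
#' chamber walls and the connector span is an open plenum.
#'
#' @param chamber_mm numeric length-3 (width, depth, height/flow-span) of
#'   the scaffold chamber interior, mm.
#' @param inlet,outlet `connector_spec` objects.
#' @param encasement logical; `TRUE` = enc+, `FALSE` = enc-.
#' @param gap_mm annular bypass width when `encasement = FALSE`; must be
#'   positive exactly when encasement is off.
#' @param orientation `"lengthwise"` (flow along the scaffold's long axis)
#'   or `"transverse"` (flow across the 10 mm dimension).
#' @param type_label free-text preset label.
#' @return A `reactor_config` object.
#' @export
reactor_config <- function(chamber_mm, inlet, outlet, encasement = TRUE,
                           gap_mm = 0, orientation = c("lengthwise", "transverse"),
                           type_label = "custom") {
  orientation <- match.arg(orientation)
  stopifnot(inherits(inlet, "connector_spec"), inherits(outlet, "connector_spec"),
            length(chamber_mm) == 3, all(chamber_mm > 0))
  if (encasement && gap_mm != 0) abort("enc+ (press-fit) implies gap_mm = 0")
  if (!encasement && gap_mm <= 0) abort("enc- (loose fit) requires a positive gap_mm")
  structure(list(chamber_mm = chamber_mm, inlet = inlet, outlet = outlet,
                 encasement = encasement, gap_mm = gap_mm,
                 orientation = orientation, type_label = type_label),
            class = "reactor_config")
}

#' Bioreactor type presets
#'
#' The three manufactured chamber types: type 1 has 1 mm cylindrical
#' inflow/outflow bores; type 2 a conical diffuser 15 mm long x 15 mm wide
#' at the base; type 3 a conical diffuser 15 mm long x 25 mm wide with the
#' scaffold perfused transversally to its long axis. Diffuser throat
#' diameter defaults to a 1.6 mm tubing bore (not part of the published
#' dimensions; configurable).
#'
#' @param type_label `"type1"`, `"type2"` or `"type3"`.
#' @param encasement logical, enc+ (`TRUE`) or enc- (`FALSE`).
#' @param gap_mm bypass gap width for enc-, mm (default 0.5).
#' @param throat_mm diffuser throat diameter, mm.
#' @return A `reactor_config`.
#' @export
preset <- function(type_label = c("type1", "type2", "type3"),
                   encasement = TRUE, gap_mm = 0.5, throat_mm = 1.6) {
  type_label <- match.arg(type_label)
  gap <- if (encasement) 0 else gap_mm
  switch(type_label,
    type1 = reactor_config(
      chamber_mm = c(10, 10, 20),
      inlet  = connector_spec("cylindrical", 1, 15),
      outlet = connector_spec("cylindrical", 1, 15),
      encasement = encasement, gap_mm = gap,
      orientation = "lengthwise", type_label = "type1"),
    type2 = reactor_config(
      chamber_mm = c(10, 10, 20),
      inlet  = connector_spec("conical", throat_mm, 15, width_mm = 15),
      outlet = connector_spec("conical", throat_mm, 15, width_mm = 15),
      encasement = encasement, gap_mm = gap,
      orientation = "lengthwise", type_label = "type2"),
    type3 = reactor_config(
      chamber_mm = c(10, 20, 10),
      inlet  = connector_spec("conical", throat_mm, 15, width_mm = 25),
      outlet = connector_spec("conical", throat_mm, 15, width_mm = 25),
      encasement = encasement, gap_mm = gap,
      orientation = "transverse", type_label = "type3")
  )
}

#' In-silico connector-study configuration
#'
#' Reactor configuration used in the connector-geometry simulations: a
#' form-fit (enc+) chamber around the 10 x 10 x 20 mm scaffold, perfused
#' lengthwise, with equal inlet and outlet connectors. Cylindrical
#' connectors have diameter `diameter_mm` (1 or 10 mm in the study);
#' conical connectors expand from `throat_mm` to a base diameter of
#' `diameter_mm` (10 mm).
#'
#' @param shape connector shape, `"cylindrical"` or `"conical"`.
#' @param length_mm connector length, mm (study range 1 to 10).
#' @param diameter_mm cylinder diameter / conical base diameter, mm.
#' @param throat_mm conical throat diameter, mm.
#' @param chamber_mm chamber dimensions, mm (the scaffold's footprint).
#' @return A `reactor_config`.
#' @export
study_config <- function(shape = c("cylindrical", "conical"), length_mm,
                         diameter_mm = 10, throat_mm = 1.6,
                         chamber_mm = c(10, 10, 20)) {
  shape <- match.arg(shape)
  conn <- if (shape == "cylindrical") {
    connector_spec("cylindrical", diameter_mm, length_mm)
  } else {
    connector_spec("conical", min(throat_mm, diameter_mm), length_mm,
                   width_mm = diameter_mm)
  }
  reactor_config(chamber_mm = chamber_mm, inlet = conn, outlet = conn,
                 encasement = TRUE, gap_mm = 0, orientation = "lengthwise",
                 type_label = sprintf("%s_L%g_D%g", shape, length_mm, diameter_mm))
}

# voxels of a cross-sectional opening: centers within `radius` of the
# interior center (Euclidean for circular bores, Chebyshev for the
# square-based diffuser frustums), clipped to the interior box; falls back
# to the nearest voxel(s) so a port is never empty
disc_mask <- function(nx, ny, voxel, radius, interior, square = FALSE) {
  cx <- nx * voxel / 2
  cy <- ny * voxel / 2
  xc <- (seq_len(nx) - 0.5) * voxel
  yc <- (seq_len(ny) - 0.5) * voxel
  d2 <- if (square) {
    outer(abs(xc - cx), abs(yc - cy), pmax)^2
  } else {
    outer((xc - cx)^2, (yc - cy)^2, `+`)
  }
  m <- d2 <= radius^2 & interior
  if (!any(m)) {
    d2i <- ifelse(interior, d2, Inf)
    m <- d2i <= min(d2i) + 1e-12
  }
  m
}

#' Build the full reactor simulation domain
#'
#' Voxelizes chamber, connectors, scaffold (optionally resampled to a
#' coarser flow grid), bypass gap and walls into a labeled domain. The
#' flow axis is z; the origin sits at the inlet port plane; world
#' coordinates refer to voxel centers. When `voxel_mm` is coarser than the
#' scaffold's native resolution, scaffold occupancy is block-averaged into
#' a per-voxel porosity field (used by the homogenized flow mode) and all
#' scaffold voxels are labeled `SCAFFOLD_FLUID`.
#'
#' @param scaffold a `scaffold_volume`.
#' @param config a `reactor_config`.
#' @param voxel_mm domain voxel size, mm; defaults to the scaffold's. Must
#'   be an integer multiple of the scaffold voxel size.
#' @return A `simulation_domain` object: integer label array (see
#'   `DOMAIN_LABELS`), voxel size, flow axis, scaffold slice range and
#'   per-voxel scaffold porosity field.
#' @export
build_domain <- function(scaffold, config, voxel_mm = NULL) {
  stopifnot(inherits(scaffold, "scaffold_volume"), inherits(config, "reactor_config"))
  h <- voxel_mm %||% scaffold$voxel_mm
  f <- h / scaffold$voxel_mm
  if (abs(f - round(f)) > 1e-8 || f < 1) {
    abort("domain voxel_mm must be a positive integer multiple of the scaffold voxel size")
  }
  f <- as.integer(round(f))

  occ <- scaffold$occupancy
  if (config$orientation == "transverse") occ <- aperm(occ, c(2, 3, 1))
  sdim_mm <- dim(occ) * scaffold$voxel_mm
  if (any(abs(sdim_mm - config$chamber_mm) > scaffold$voxel_mm + 1e-9)) {
    abort(sprintf(
      "scaffold (%s mm after orientation) does not fit the chamber (%s mm)",
      paste(signif(sdim_mm, 4), collapse = " x "),
      paste(signif(config$chamber_mm, 4), collapse = " x ")))
  }

  # scaffold voxel counts on the domain grid
  sd_vox <- as.integer(dim(occ) %/% f)
  occ <- occ[seq_len(sd_vox[1] * f), seq_len(sd_vox[2] * f), seq_len(sd_vox[3] * f),
             drop = FALSE]
  resolved <- f == 1L
  if (resolved) {
    por_field <- occ * 1.0
    scaff_lab <- ifelse(occ == FLUID, DOMAIN_LABELS[["SCAFFOLD_FLUID"]],
                        DOMAIN_LABELS[["SCAFFOLD_SOLID"]])
  } else {
    por_field <- block_mean3(occ * 1.0, f)
    scaff_lab <- array(DOMAIN_LABELS[["SCAFFOLD_FLUID"]], sd_vox)
  }

  g_vox <- if (config$encasement) 0L else as.integer(round(config$gap_mm / h))
  if (!config$encasement && g_vox < 1L) {
    abort("enc- gap_mm is below one domain voxel; increase gap_mm or refine voxel_mm")
  }
  nLin  <- max(1L, as.integer(round(config$inlet$length_mm / h)))
  nLout <- max(1L, as.integer(round(config$outlet$length_mm / h)))
  cross <- sd_vox[1:2] + 2L * g_vox          # interior cross-section, voxels
  nx <- cross[1] + 2L; ny <- cross[2] + 2L   # + wall shell
  nz <- nLin + sd_vox[3] + nLout + 2L        # + end caps
  lab <- array(DOMAIN_LABELS[["WALL"]], c(nx, ny, nz))

  interior <- matrix(FALSE, nx, ny)
  interior[2:(nx - 1L), 2:(ny - 1L)] <- TRUE
  face_diag <- sqrt(sum((cross * h)^2))
  for (side in c("inlet", "outlet")) {
    conn <- config[[side]]
    if (conn$diameter_mm > min(cross * h) + h + 1e-9) {
      abort(sprintf("%s connector throat (%g mm) is wider than the chamber face",
                    side, conn$diameter_mm))
    }
    L <- if (side == "inlet") nLin else nLout
    zs <- if (side == "inlet") 1L + seq_len(L) else 1L + nLin + sd_vox[3] + seq_len(L)
    # distance from the scaffold face, voxel centers
    s_face <- if (side == "inlet") (rev(seq_len(L)) - 0.5) * h else (seq_len(L) - 0.5) * h
    r_throat <- conn$diameter_mm / 2
    # diffusers are square-based frustums matching the square chamber face
    # (a circular cone base would starve the face corners)
    conical <- conn$shape == "conical"
    r_base <- min(conn$width_mm / 2, if (conical) max(cross * h) / 2 else face_diag / 2)
    for (k in seq_along(zs)) {
      r <- if (conn$shape == "cylindrical") r_throat else {
        r_throat + (r_base - r_throat) * (1 - s_face[k] / conn$length_mm)
      }
      m <- disc_mask(nx, ny, h, r, interior, square = conical)
      sl <- lab[, , zs[k]]
      sl[m] <- DOMAIN_LABELS[["CONNECTOR"]]
      if (!config$encasement) sl[interior & !m] <- DOMAIN_LABELS[["CHAMBER_FLUID"]]
      lab[, , zs[k]] <- sl
    }
    # port patch on the end cap: the tubing bore opening
    zp <- if (side == "inlet") 1L else nz
    m <- disc_mask(nx, ny, h, conn$bore_mm / 2, interior)
    sl <- lab[, , zp]
    sl[m] <- DOMAIN_LABELS[[if (side == "inlet") "INLET_PORT" else "OUTLET_PORT"]]
    lab[, , zp] <- sl
  }

  sx <- 1L + g_vox + seq_len(sd_vox[1])
  sy <- 1L + g_vox + seq_len(sd_vox[2])
  sz <- 1L + nLin + seq_len(sd_vox[3])
  lab[sx, sy, sz] <- scaff_lab
  if (!config$encasement) {
    ring <- array(TRUE, c(cross[1], cross[2]))
    ring[g_vox + seq_len(sd_vox[1]), g_vox + seq_len(sd_vox[2])] <- FALSE
    for (z in sz) {
      sl <- lab[, , z]
      sl[2:(nx - 1L), 2:(ny - 1L)][ring] <- DOMAIN_LABELS[["BYPASS_GAP"]]
      lab[, , z] <- sl
    }
  }
  pf <- array(NA_real_, dim(lab))
  pf[sx, sy, sz] <- por_field

  structure(list(
    labels = lab, voxel_mm = h, flow_axis = 3L,
    scaffold_z = range(sz), scaffold_x = range(sx), scaffold_y = range(sy),
    porosity_field = pf, resolved = resolved,
    pore_scale_mm = scaffold$pore_scale_mm,
    scaffold_porosity = scaffold$porosity,
    config = config,
    provenance = list(scaffold_seed = scaffold$seed, type_label = config$type_label)
  ), class = "simulation_domain")
}

#' @export
print.simulation_domain <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = DOMAIN_LABELS, labels = names(DOMAIN_LABELS)))
  cat(sprintf("<simulation_domain> %d x %d x %d @ %.3g mm (%s, %s)\n",
              d[1], d[2], d[3], x$voxel_mm, x$config$type_label,
              if (x$config$encasement) "enc+" else "enc-"))
  cat("  ", paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# mean over f^3 blocks of a 3-D array whose dims are multiples of f
block_mean3 <- function(x, f) {
  d <- dim(x) %/% f
  dim(x) <- c(f, d[1], f, d[2], f, d[3])
  out <- apply(x, c(2, 4, 6), mean)
  array(out, d)
}

# linear indices of voxels with a given label
label_idx <- function(domain, label) which(domain$labels == DOMAIN_LABELS[[label]])

# pore scale with a sane fallback for volumes lacking the metadata
domain_pore_scale <- function(domain) {
  ps <- domain$pore_scale_mm
  if (is.null(ps) || is.na(ps)) 0.5 else ps
}

# logical mask of voxels open to flow
open_mask <- function(domain) array(domain$labels %in% OPEN_LABELS, dim(domain$labels))

#' Check that both ports are connected through open voxels
#'
#' Breadth-first search (6-neighbour adjacency) from the inlet port
#' through non-wall, non-solid voxels.
#'
#' @param domain a `simulation_domain`.
#' @param through optional label names restricting the traversable set
#'   (ports are always traversable).
#' @return `TRUE` if the outlet port is reachable from the inlet port.
#' @export
ports_connected <- function(domain, through = NULL) {
  mask <- open_mask(domain)
  if (!is.null(through)) {
    keep <- DOMAIN_LABELS[c("INLET_PORT", "OUTLET_PORT", through)]
    mask <- array(domain$labels %in% keep, dim(domain$labels))
  }
  reach <- flood3d(mask, label_idx(domain, "INLET_PORT"))
  any(reach[label_idx(domain, "OUTLET_PORT")])
}

#' Save / load a reactor configuration as JSON
#'
#' Flat key-value serialization of a `reactor_config` (connectors
#' inlined with `inlet_` / `outlet_` prefixes).
#'
#' @param config a `reactor_config`.
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   a `reactor_config` value-identical to the saved one.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "reactor_config"))
  flat <- list(container = "perfuseed_reactor_config",
               chamber_mm = config$chamber_mm,
               encasement = config$encasement, gap_mm = config$gap_mm,
               orientation = config$orientation, type_label = config$type_label)
  for (side in c("inlet", "outlet")) {
    for (f in names(config[[side]])) {
      flat[[paste0(side, "_", f)]] <- config[[side]][[f]]
    }
  }
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$container, "perfuseed_reactor_config")) {
    abort("not a perfuseed reactor config file")
  }
  conn <- function(side) {
    connector_spec(x[[paste0(side, "_shape")]],
                   diameter_mm = as.numeric(x[[paste0(side, "_diameter_mm")]]),
                   length_mm = as.numeric(x[[paste0(side, "_length_mm")]]),
                   width_mm = as.numeric(x[[paste0(side, "_width_mm")]]),
                   bore_mm = as.numeric(x[[paste0(side, "_bore_mm")]]))
  }
  reactor_config(chamber_mm = as.numeric(x$chamber_mm), inlet = conn("inlet"),
                 outlet = conn("outlet"), encasement = x$encasement,
                 gap_mm = as.numeric(x$gap_mm), orientation = x$orientation,
                 type_label = x$type_label)
}
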