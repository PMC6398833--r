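#' Parametric 2D vein geometry
#'
#' Dimensions of the modeled vein segment: a thin wall, a symmetric bileaflet
#' valve and sinus pockets, in cm. Defaults are the bovine-saphenous reference
#' dimensions used throughout the package. The leaflet base sits
#' `valve_offset` from the distal (inlet) end; the sinus bulge is a smooth
#' half-cosine of height `h_s` over length `d_s` starting at the leaflet base.
#'
#' @param L0 wall length (cm).
#' @param d0 luminal diameter (cm).
#' @param t0 wall thickness (cm).
#' @param d_v valve (leaflet) longitudinal depth (cm).
#' @param h_v valve radial height (cm): radial level of the leaflet belly.
#' @param t_v valve thickness (cm).
#' @param u_g0 initial tip-to-tip gap (cm).
#' @param d_s sinus longitudinal depth (cm).
#' @param h_s sinus bulged height (cm).
#' @param t_sinus sinus thickness (cm).
#' @param valve_offset distance of the leaflet base from the distal end (cm).
#' @return object of class `vein_geometry`.
#' @export
vein_geometry <- function(L0 = 2.50, d0 = 0.691, t0 = 0.040,
                          d_v = 0.573, h_v = 0.310, t_v = 0.020,
                          u_g0 = 0.018, d_s = 0.922, h_s = 0.050,
                          t_sinus = 0.030, valve_offset = 0.8) {
  g <- list(L0 = L0, d0 = d0, t0 = t0, d_v = d_v, h_v = h_v, t_v = t_v,
            u_g0 = u_g0, d_s = d_s, h_s = h_s, t_sinus = t_sinus,
            valve_offset = valve_offset)
  for (nm in setdiff(names(g), "h_s"))
    if (!is.finite(g[[nm]]) || g[[nm]] <= 0)
      stop("parameter error: ", nm, " must be positive")
  if (h_s < 0) stop("parameter error: h_s must be >= 0")
  if (u_g0 >= d0) stop("parameter error: u_g0 must be smaller than d0")
  if (2 * h_v + u_g0 > d0 + 2 * h_s)
    stop("parameter error: h_v too large for the lumen (2*h_v + u_g0 > d0 + 2*h_s)")
  if (valve_offset >= L0) stop("parameter error: valve_offset must be < L0")
  class(g) <- "vein_geometry"
  g
}

# sinus bulge profile: smooth half-cosine bump of height h_s over [x_h, x_h+d_s]
sinus_bump <- function(x, geom) {
  xi <- (x - geom$valve_offset) / geom$d_s
  b <- numeric(length(x))
  inside <- xi > 0 & xi < 1
  b[inside] <- sin(pi * xi[inside])^2
  b
}

# local band thickness: wall thickness blended to the sinus thickness with the
# same window as the bulge
band_thickness <- function(x, geom) {
  b <- sinus_bump(x, geom)
  geom$t0 * (1 - b) + geom$t_sinus * b
}

# quadratic Bezier leaflet midline for one side (side = +1 upper / -1 lower),
# resampled to ~equal arc length; y relative to the vessel axis. The midline
# tip sits at (u_g0 + tv)/2 from the axis so that the flow-side SURFACE tips
# are separated by exactly u_g0 across the centerline.
leaflet_midline <- function(geom, side, n = 400L, tv = geom$t_v) {
  H <- c(geom$valve_offset, side * geom$d0 / 2)
  Tt <- c(geom$valve_offset + geom$d_v, side * (geom$u_g0 + tv) / 2)
  C <- c(geom$valve_offset + 0.35 * geom$d_v, side * (geom$d0 / 2 - geom$h_v))
  u <- seq(0, 1, length.out = n)
  px <- (1 - u)^2 * H[1] + 2 * u * (1 - u) * C[1] + u^2 * Tt[1]
  py <- (1 - u)^2 * H[2] + 2 * u * (1 - u) * C[2] + u^2 * Tt[2]
  arc <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  list(x = px, y = py, arc = arc, length = arc[n])
}

#' Closed part outlines of the vein model
#'
#' Generates closed, non-self-intersecting outlines (polylines, first point
#' not repeated) for the two wall strips, the two sinus pockets and the two
#' leaflets, in the fluid-domain frame (vessel axis at `y = axis_y`). The
#' geometry is exactly mirror symmetric about the axis.
#'
#' @param geom a [vein_geometry()].
#' @param axis_y y coordinate of the vessel axis (cm).
#' @param n sampling density along curves.
#' @return named list of outline matrices (k x 2), class `vein_outlines`.
#' @export
build_vein_geometry <- function(geom, axis_y = 1.071 / 2, n = 200L) {
  stopifnot(inherits(geom, "vein_geometry"))
  xs <- seq(0, geom$L0, length.out = n)
  band_outline <- function(side) {
    yin <- axis_y + side * (geom$d0 / 2 + geom$h_s * sinus_bump(xs, geom))
    yout <- yin + side * band_thickness(xs, geom)
    rbind(cbind(xs, yin), cbind(rev(xs), rev(yout)))
  }
  sinus_outline <- function(side) {
    xs2 <- seq(geom$valve_offset, geom$valve_offset + geom$d_s, length.out = n)
    yin <- axis_y + side * (geom$d0 / 2 + geom$h_s * sinus_bump(xs2, geom))
    yout <- yin + side * band_thickness(xs2, geom)
    rbind(cbind(xs2, yin), cbind(rev(xs2), rev(yout)))
  }
  leaflet_outline <- function(side) {
    ml <- leaflet_midline(geom, side, n)
    tx <- c(diff(ml$x), 0); ty <- c(diff(ml$y), 0)
    tx[n] <- tx[n - 1]; ty[n] <- ty[n - 1]
    tl <- sqrt(tx^2 + ty^2)
    # normal pointing toward the axis for the upper leaflet
    nx <- ty / tl * side; ny <- -tx / tl * side
    h <- geom$t_v / 2
    rbind(cbind(ml$x + h * nx, (axis_y + ml$y) + h * ny),
          cbind(rev(ml$x - h * nx), rev((axis_y + ml$y) - h * ny)))
  }
  out <- list(wall_upper = band_outline(+1), wall_lower = band_outline(-1),
              sinus_upper = sinus_outline(+1), sinus_lower = sinus_outline(-1),
              leaflet_1 = leaflet_outline(+1), leaflet_2 = leaflet_outline(-1))
  attr(out, "axis_y") <- axis_y
  class(out) <- "vein_outlines"
  out
}

#' Lesion case material and thickness factors
#'
#' The five cases: Normal; CFV / CAV (both leaflets fibrotic / atrophic);
#' IFV / IAV (leaflet 1 fibrotic / atrophic, leaflet 2 healthy). Fibrosis
#' stiffens the exponential coefficient C0 tenfold and thickens the leaflet by
#' 25%; atrophy softens C0 tenfold at unchanged thickness.
#'
#' @param case_id one of "Normal", "CFV", "CAV", "IFV", "IAV"
#'   (case-insensitive).
#' @param c0_healthy healthy valve C0 (kPa).
#' @return list with `case_id`, `c0_leaflet` (kPa, length 2),
#'   `thickness_factor` (length 2), class `lesion_case`.
#' @export
configure_lesion <- function(case_id = "Normal", c0_healthy = 417) {
  id <- toupper(case_id)
  if (id == "NORMAL") id <- "Normal"
  states <- switch(id,
    "Normal" = c("healthy", "healthy"),
    "CFV" = c("fibrotic", "fibrotic"),
    "CAV" = c("atrophic", "atrophic"),
    "IFV" = c("fibrotic", "healthy"),
    "IAV" = c("atrophic", "healthy"),
    stop("unknown lesion case: ", case_id,
         " (expected Normal, CFV, CAV, IFV or IAV)"))
  c0 <- ifelse(states == "fibrotic", 10 * c0_healthy,
               ifelse(states == "atrophic", c0_healthy / 10, c0_healthy))
  tf <- ifelse(states == "fibrotic", 1.25, 1.0)
  structure(list(case_id = id, leaflet_state = states,
                 c0_leaflet = c0, thickness_factor = tf),
            class = "lesion_case")
}

#' Pulsed-wave loading protocol
#'
#' The transvalvular driving gradient is `delta_p_max * pulse_waveform(t)`.
#' The maximum gradient composes the hydrostatic column over the segment with
#' the muscular pump: `delta_p_max = rho_f g L0 + p_pump`. Each 1 s cycle
#' starts with a 0.05 s relaxation window (waveform 0) after which a single
#' smooth sin^2 pulse of duration `pulse_duration` rises to 1 and returns to
#' 0; the remainder of the cycle is unloaded so that tissue recoil can reverse
#' the flow and close the valve.
#'
#' @param delta_p_max_mmhg peak pressure gradient (mm Hg).
#' @param cycle_period cycle length (s); 60 cycles/min gives 1 s.
#' @param relax_duration initial relaxation window (s).
#' @param pulse_duration active pulse length (s).
#' @param rho_f blood density (g/cm^3), for the hydrostatic decomposition.
#' @param L0 segment length (cm).
#' @param gravity_handling "folded-into-pressure" (default) or
#'   "explicit-body-force".
#' @return list of class `loading_protocol`; pressures stored in dyn/cm^2.
#' @export
loading_protocol <- function(delta_p_max_mmhg = 4.0, cycle_period = 1.0,
                             relax_duration = 0.05, pulse_duration = 0.5,
                             rho_f = 1.08, L0 = 2.5,
                             gravity_handling = c("folded-into-pressure",
                                                  "explicit-body-force")) {
  gravity_handling <- match.arg(gravity_handling)
  stopifnot(relax_duration < cycle_period,
            relax_duration + pulse_duration <= cycle_period)
  g <- 981  # cm/s^2
  dp <- mmhg_to_cgs(delta_p_max_mmhg)
  structure(list(delta_p_max = dp,
                 p_hydrostatic = rho_f * g * L0,
                 p_pump = dp - rho_f * g * L0,
                 cycle_period = cycle_period,
                 relax_duration = relax_duration,
                 pulse_duration = pulse_duration,
                 gravity_handling = gravity_handling),
            class = "loading_protocol")
}

#' Dimensionless pulsed-wave function
#'
#' 0 during the relaxation window at the start of each cycle, a single smooth
#' sin^2 pulse with maximum 1 during the active window, and 0 for the rest of
#' the cycle. Periodic with `cycle_period`.
#'
#' @param t time(s) in s, `t >= 0`; vectorized.
#' @param protocol a [loading_protocol()].
#' @return waveform value(s) in `[0, 1]`.
#' @export
pulse_waveform <- function(t, protocol) {
  tc <- t %% protocol$cycle_period
  w <- numeric(length(t))
  act <- tc >= protocol$relax_duration &
    tc <= protocol$relax_duration + protocol$pulse_duration
  w[act] <- sin(pi * (tc[act] - protocol$relax_duration) /
                  protocol$pulse_duration)^2
  w
}

#' Structured Eulerian fluid grid
#'
#' Uniform quadrilateral grid over the rectangular fluid domain. The cell
#' counts are the ceilings of the side lengths over `h`; the actual spacings
#' divide the domain exactly.
#'
#' @param domain numeric length-2: domain size (cm), default the 2.5 x 1.071
#'   cm^2 box the vein is immersed in.
#' @param h target cell size (cm).
#' @return a `quad_mesh` with attributes `nx`, `ny`, `hx`, `hy`; boundary tags
#'   (inlet x = 0, outlet x = Lx, lateral y = 0 and y = Ly) are available via
#'   [fluid_boundary_nodes()].
#' @export
build_fluid_grid <- function(domain = c(2.5, 1.071), h = 0.008) {
  stopifnot(h > 0, length(domain) == 2L, all(domain > 0))
  nx <- as.integer(ceiling(domain[1] / h - 1e-9))
  ny <- as.integer(ceiling(domain[2] / h - 1e-9))
  hx <- domain[1] / nx; hy <- domain[2] / ny
  m <- mesh_block(function(s, t) s * domain[1], function(s, t) t * domain[2],
                  nx, ny, part = "fluid")
  attr(m, "nx") <- nx; attr(m, "ny") <- ny
  attr(m, "hx") <- hx; attr(m, "hy") <- hy
  attr(m, "domain") <- domain
  m
}

#' Boundary node sets of a structured fluid grid
#'
#' @param grid a grid from [build_fluid_grid()].
#' @return list of integer node-id vectors: `inlet`, `outlet`, `lateral`.
#' @export
fluid_boundary_nodes <- function(grid) {
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  list(inlet = nid(1L, 1:(ny + 1L)),
       outlet = nid(nx + 1L, 1:(ny + 1L)),
       lateral = c(nid(1:(nx + 1L), 1L), nid(1:(nx + 1L), ny + 1L)))
}

# structured-edge tag records for a block mesh (local node ids)
block_side_edges <- function(ns, nt, side) {
  nid <- function(i, j) (j - 1L) * (ns + 1L) + i
  switch(side,
         t0 = data.frame(n1 = nid(1:ns, 1L), n2 = nid(2:(ns + 1L), 1L)),
         t1 = data.frame(n1 = nid(1:ns, nt + 1L), n2 = nid(2:(ns + 1L), nt + 1L)),
         s0 = data.frame(n1 = nid(1L, 1:nt), n2 = nid(1L, 2:(nt + 1L))),
         s1 = data.frame(n1 = nid(ns + 1L, 1:nt), n2 = nid(ns + 1L, 2:(nt + 1L))))
}

#' Mesh the vein solid
#'
#' Builds the full quadrilateral solid mesh: two wall/sinus bands (upper and
#' lower) and two leaflets, each a structured block with longitudinal spacing
#' close to `target_size` and four through-thickness layers at the reference
#' size 0.008 cm (scaled with `target_size`, minimum two layers in the
#' leaflets). The bands and leaflets are independent bodies; leaflet base
#' nodes rest on the wall inner surface and are clamped by the solver.
#'
#' @param geom a [vein_geometry()].
#' @param target_size mean mesh size (cm).
#' @param lesion a [configure_lesion()] case (thickness factors re-mesh the
#'   leaflets geometrically).
#' @param axis_y y of the vessel axis in the fluid frame.
#' @param leaflet_refine extra refinement factor applied to the leaflet
#'   blocks (their root bending controls the valve kinematics).
#' @return object of class `vein_mesh`: a list with the merged `mesh`,
#'   per-element component tags, boundary-edge tags, tip/hinge node ids,
#'   clamped node ids, and per-component minimum thickness.
#' @export
mesh_solid <- function(geom, target_size = 0.008,
                       lesion = configure_lesion("Normal"),
                       axis_y = 1.071 / 2, leaflet_refine = 1) {
  stopifnot(inherits(geom, "vein_geometry"), target_size > 0)
  h <- target_size
  layers_ref <- 4L
  band_layers <- max(2L, as.integer(round(layers_ref * 0.008 / h)))
  leaf_layers <- max(2L, as.integer(round(layers_ref * leaflet_refine * 0.008 / h)))
  ns_band <- max(4L, as.integer(round(geom$L0 / h)))

  pieces <- list(); comps <- character(0); tags <- list()
  add_piece <- function(m, comp, tagdf) {
    pieces[[length(pieces) + 1L]] <<- m
    comps <<- c(comps, comp)
    tags[[length(tags) + 1L]] <<- tagdf
  }

  for (side in c(+1, -1)) {
    fy_in <- function(s) axis_y + side * (geom$d0 / 2 + geom$h_s * sinus_bump(s * geom$L0, geom))
    fx <- function(s, t) s * geom$L0
    fy <- function(s, t) fy_in(s) + t * side * band_thickness(s * geom$L0, geom)
    mb <- mesh_block(fx, fy, ns_band, band_layers,
                     part = "wall")
    # re-tag sinus elements by bump at element centers
    ec_x <- rowMeans(matrix(mb$nodes[mb$elems, 1L], ncol = 4L))
    mb$part[sinus_bump(ec_x, geom) > 1e-8] <- "sinus"
    comp <- if (side > 0) "band_upper" else "band_lower"
    e_in <- block_side_edges(ns_band, band_layers, "t0")
    mid_x <- (mb$nodes[e_in$n1, 1L] + mb$nodes[e_in$n2, 1L]) / 2
    e_in$tag <- ifelse(sinus_bump(mid_x, geom) > 1e-8, "sinus_inner", "lumen_wall")
    e_out <- block_side_edges(ns_band, band_layers, "t1"); e_out$tag <- "wall_outer"
    e_l <- block_side_edges(ns_band, band_layers, "s0"); e_l$tag <- "wall_end"
    e_r <- block_side_edges(ns_band, band_layers, "s1"); e_r$tag <- "wall_end"
    add_piece(mb, comp, rbind(e_in, e_out, e_l, e_r))
  }

  for (k in 1:2) {
    side <- if (k == 1L) +1 else -1
    tv <- geom$t_v * lesion$thickness_factor[k]
    ml <- leaflet_midline(geom, side, tv = tv)
    ns_leaf <- max(4L, as.integer(round(leaflet_refine * ml$length / h)))
    sfrac <- ml$arc / ml$length
    mx <- stats::approxfun(sfrac, ml$x); my <- stats::approxfun(sfrac, ml$y)
    eps <- 1e-5
    fx <- function(s, t) {
      s <- pmin(pmax(s, 0), 1)
      tx <- (mx(pmin(s + eps, 1)) - mx(pmax(s - eps, 0)))
      ty <- (my(pmin(s + eps, 1)) - my(pmax(s - eps, 0)))
      tl <- sqrt(tx^2 + ty^2)
      nxv <- ty / tl * side  # toward the axis at t = 0 .. away at t = 1
      mx(s) + (t - 0.5) * tv * (-nxv)
    }
    fy <- function(s, t) {
      s <- pmin(pmax(s, 0), 1)
      tx <- (mx(pmin(s + eps, 1)) - mx(pmax(s - eps, 0)))
      ty <- (my(pmin(s + eps, 1)) - my(pmax(s - eps, 0)))
      tl <- sqrt(tx^2 + ty^2)
      nyv <- -tx / tl * side
      axis_y + my(s) + (t - 0.5) * tv * (-nyv)
    }
    # t = 0 face is the axis-facing (flow) surface, t = 1 the sinus side
    mlf <- mesh_block(fx, fy, ns_leaf, leaf_layers,
                      part = paste0("valve_leaflet_", k))
    e_up <- block_side_edges(ns_leaf, leaf_layers, "t0"); e_up$tag <- "leaflet_surface_upper"
    e_lo <- block_side_edges(ns_leaf, leaf_layers, "t1"); e_lo$tag <- "leaflet_surface_lower"
    e_b <- block_side_edges(ns_leaf, leaf_layers, "s0"); e_b$tag <- "leaflet_base"
    e_t <- block_side_edges(ns_leaf, leaf_layers, "s1"); e_t$tag <- "leaflet_tip"
    add_piece(mlf, paste0("leaflet_", k), rbind(e_up, e_lo, e_b, e_t))
  }

  merged <- mesh_merge(pieces)
  nm <- attr(merged, "node_maps")
  edge_tags <- do.call(rbind, Map(function(df, map, comp) {
    data.frame(n1 = map[df$n1], n2 = map[df$n2], tag = df$tag, comp = comp)
  }, tags, nm, comps))
  comp_of_elem <- rep(comps, vapply(pieces, function(m) nrow(m$elems), 1L))

  # reorient tagged edges to the counter-clockwise boundary orientation of
  # their component, so outward normals derived from (n1 -> n2) are correct
  ccw_keys <- character(0)
  for (cn in unique(comp_of_elem)) {
    sub <- merged; keep <- comp_of_elem == cn
    sub$elems <- sub$elems[keep, , drop = FALSE]; sub$part <- sub$part[keep]
    be <- mesh_boundary_edges(sub)
    ccw_keys <- c(ccw_keys, paste(be$n1, be$n2))
  }
  rev_sel <- paste(edge_tags$n2, edge_tags$n1) %in% ccw_keys &
    !(paste(edge_tags$n1, edge_tags$n2) %in% ccw_keys)
  if (any(rev_sel)) {
    tmp <- edge_tags$n1[rev_sel]
    edge_tags$n1[rev_sel] <- edge_tags$n2[rev_sel]
    edge_tags$n2[rev_sel] <- tmp
  }

  if (any(mesh_min_corner_jacobian(merged) <= 0))
    stop("mesh error: non-positive Jacobian in generated solid mesh")

  # special nodes
  find_node <- function(xy) {
    d2 <- (merged$nodes[, 1] - xy[1])^2 + (merged$nodes[, 2] - xy[2])^2
    which.min(d2)
  }
  tip1 <- find_node(c(geom$valve_offset + geom$d_v, axis_y + geom$u_g0 / 2))
  tip2 <- find_node(c(geom$valve_offset + geom$d_v, axis_y - geom$u_g0 / 2))
  hinge1 <- find_node(c(geom$valve_offset, axis_y + geom$d0 / 2))
  hinge2 <- find_node(c(geom$valve_offset, axis_y - geom$d0 / 2))

  # constrained nodes: band ends clamped; each leaflet clamped over its base
  # edge at its resting position on the wall inner surface (the anatomical
  # attachment line, which also supplies the root restoring moment)
  base_nodes <- unique(c(edge_tags$n1[edge_tags$tag == "leaflet_base"],
                         edge_tags$n2[edge_tags$tag == "leaflet_base"]))
  fixed <- unique(c(
    which(abs(merged$nodes[, 1]) < 1e-9 | abs(merged$nodes[, 1] - geom$L0) < 1e-9),
    base_nodes))

  comp_thickness <- c(band_upper = min(geom$t0, geom$t_sinus),
                      band_lower = min(geom$t0, geom$t_sinus),
                      leaflet_1 = geom$t_v * lesion$thickness_factor[1],
                      leaflet_2 = geom$t_v * lesion$thickness_factor[2])

  structure(list(mesh = merged, comp = comp_of_elem, edge_tags = edge_tags,
                 tips = c(tip1, tip2), hinges = c(hinge1, hinge2),
                 fixed_nodes = fixed, comp_thickness = comp_thickness,
                 geom = geom, lesion = lesion, axis_y = axis_y,
                 target_size = h),
            class = "vein_mesh")
}

#' @export
print.vein_mesh <- function(x, ...) {
  cat("vein_mesh (", x$lesion$case_id, "), target size ", x$target_size,
      " cm\n", sep = "")
  print(x$mesh)
  invisible(x)
}

#' Per-part element counts of a vein mesh
#' @param vm a `vein_mesh`.
#' @return named integer vector over part tags (wall, sinus, leaflets).
#' @export
vein_mesh_counts <- function(vm) {
  tb <- table(vm$mesh$part)
  c(wall = sum(tb[grepl("wall", names(tb))]),
    valve = sum(tb[grepl("valve_leaflet", names(tb))]),
    sinus = sum(tb[grepl("sinus", names(tb))]))
}
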