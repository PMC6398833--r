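#' Geometric orifice width
#'
#' Transverse distance between the two leaflet tip nodes in the current
#' configuration.
#'
#' @param coords current solid coordinates (n x 2).
#' @param tips integer length-2 tip node ids.
#' @return l_GOA (cm).
#' @export
orifice_width <- function(coords, tips) {
  if (length(tips) != 2L || any(is.na(tips)))
    stop("configuration error: leaflet tip nodes not tagged")
  abs(coords[tips[1], 2] - coords[tips[2], 2])
}

#' Geometric orifice area
#'
#' Elliptical orifice `A = pi (d0 + 2 h_s') l_GOA / 4` with the deformed
#' sinus bulge `h_s'` setting the long axis.
#'
#' @param l_goa orifice width (cm).
#' @param d0 luminal diameter (cm).
#' @param h_s_current deformed sinus bulge height (cm).
#' @return area (cm^2).
#' @export
orifice_area <- function(l_goa, d0, h_s_current) {
  stopifnot(all(l_goa >= 0), d0 > 0, all(h_s_current >= 0))
  pi * (d0 + 2 * h_s_current) * l_goa / 4
}

#' Current sinus bulge height
#'
#' Maximum outward excursion of the sinus inner surface beyond the luminal
#' radius, in the current configuration.
#'
#' @param vm a `vein_mesh`.
#' @param coords current solid coordinates.
#' @return h_s' (cm), >= 0.
#' @export
current_sinus_bulge <- function(vm, coords) {
  et <- vm$edge_tags
  sn <- unique(c(et$n1[et$tag == "sinus_inner"], et$n2[et$tag == "sinus_inner"]))
  if (!length(sn)) return(0)
  max(0, max(abs(coords[sn, 2] - vm$axis_y) - vm$geom$d0 / 2))
}

#' Volumetric flow rate through a transverse segment
#'
#' Line integral of the axial velocity over the segment, scaled to the
#' elliptical lumen: `Q = pi * long_axis * int v dy / 4`.
#'
#' @param fmodel a [fluid_model()].
#' @param state a [fluid_state()].
#' @param x_station axial position of the segment (cm).
#' @param y_range numeric length-2 transverse extent (cm).
#' @param long_axis elliptical long axis (cm), e.g. `d0 + 2 h_s'`.
#' @param npts quadrature points.
#' @return Q (cm^3/s).
#' @export
flow_rate <- function(fmodel, state, x_station, y_range, long_axis,
                      npts = 41L) {
  if (diff(y_range) <= 0) return(0)
  ys <- seq(y_range[1], y_range[2], length.out = npts)
  u <- fluid_interp(fmodel, state, rep(x_station, npts), ys, "u")
  integ <- sum((u[-1] + u[-npts]) / 2) * (ys[2] - ys[1])
  pi * long_axis * integ / 4
}

#' Forward/reverse venous volumes and critical time
#'
#' Trapezoidal time integrals of the positive and negative parts of `Q(t)`
#' over the cycle, and the first positive-to-negative zero crossing as a
#' percentage of the cycle.
#'
#' @param t time grid (s).
#' @param Q flow-rate samples (cm^3/s).
#' @param cycle_period cycle length (s).
#' @return list: `forward` (cm^3), `reverse` (cm^3, <= 0), `critical_time`
#'   (percent of cycle; 100 with attribute `no_crossing` when the flow never
#'   reverses).
#' @export
venous_volumes <- function(t, Q, cycle_period = max(t)) {
  stopifnot(length(t) == length(Q), length(t) >= 2L)
  dt <- diff(t)
  qp <- pmax(Q, 0); qm <- pmin(Q, 0)
  fwd <- sum((qp[-1] + qp[-length(qp)]) / 2 * dt)
  rev <- sum((qm[-1] + qm[-length(qm)]) / 2 * dt)
  # forward-to-reverse transition: first downward zero crossing after the
  # flow-rate peak (start-up jitter around zero is not a reversal)
  ipk <- which.max(Q)
  cross <- which(Q[-length(Q)] > 0 & Q[-1] <= 0)
  cross <- cross[cross >= ipk]
  if (length(cross)) {
    i <- cross[1]
    tc <- t[i] + (t[i + 1] - t[i]) * Q[i] / (Q[i] - Q[i + 1])
    crit <- 100 * tc / cycle_period
    no_cross <- FALSE
  } else {
    crit <- 100; no_cross <- TRUE
  }
  out <- list(forward = fwd, reverse = rev, critical_time = crit)
  attr(out, "no_crossing") <- no_cross
  out
}

#' Fluid wall shear stress along a curve
#'
#' One-sided recovery into the real fluid: the tangential velocity is
#' sampled at offsets `h` and `2h` along the outward normal and
#' differentiated with the second-order one-sided stencil anchored at the
#' wall velocity (exact for a parabolic profile).
#'
#' @param fmodel a [fluid_model()].
#' @param state a [fluid_state()].
#' @param px,py curve points (cm).
#' @param nx,ny outward unit normals (into the fluid).
#' @param wall_u,wall_v wall velocity at the points (default 0).
#' @param offset sampling offset (cm), default one grid cell.
#' @return FWSS values (dyn/cm^2), signed along the tangent
#'   `t = (-ny, nx)`.
#' @export
wall_shear_stress_fluid <- function(fmodel, state, px, py, nx, ny,
                                    wall_u = 0, wall_v = 0, offset = NULL) {
  if (is.null(offset)) offset <- min(fmodel$hx, fmodel$hy)
  tx <- -ny; ty <- nx
  vt0 <- wall_u * tx + wall_v * ty
  u1 <- fluid_interp(fmodel, state, px + offset * nx, py + offset * ny, "u")
  v1 <- fluid_interp(fmodel, state, px + offset * nx, py + offset * ny, "v")
  u2 <- fluid_interp(fmodel, state, px + 2 * offset * nx, py + 2 * offset * ny, "u")
  v2 <- fluid_interp(fmodel, state, px + 2 * offset * nx, py + 2 * offset * ny, "v")
  vt1 <- u1 * tx + v1 * ty; vt2 <- u2 * tx + v2 * ty
  mu <- state$mu[1]
  mu * (-3 * vt0 + 4 * vt1 - vt2) / (2 * offset)
}

#' Solid wall shear stress on a boundary edge set
#'
#' Surface traction `t = sigma n` from the element Cauchy stress
#' (extrapolated from the 2x2 Gauss points to the edge midpoint), decomposed
#' into its tangential magnitude `|t - (t.n) n|`.
#'
#' @param model a [solid_model()].
#' @param d displacement vector.
#' @param edges data.frame `n1`, `n2`, `elem` (from
#'   [mesh_boundary_edges()]).
#' @param coords current coordinates (for normals).
#' @return SWSS per edge (dyn/cm^2).
#' @export
wall_shear_stress_solid <- function(model, d, edges, coords) {
  st <- solid_element_stress(model, d)
  el <- model$mesh$elems
  out <- numeric(nrow(edges))
  locs <- list(`12` = c(0, -1), `23` = c(1, 0), `34` = c(0, 1), `41` = c(-1, 0))
  x1 <- coords[edges$n1, 1]; y1 <- coords[edges$n1, 2]
  x2 <- coords[edges$n2, 1]; y2 <- coords[edges$n2, 2]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  nxv <- (y2 - y1) / len; nyv <- -(x2 - x1) / len
  for (k in seq_len(nrow(edges))) {
    e <- edges$elem[k]
    conn <- el[e, ]
    i1 <- match(edges$n1[k], conn); i2 <- match(edges$n2[k], conn)
    key <- paste0(min(i1, i2), max(i1, i2))
    if (key == "14") key <- "41"
    loc <- locs[[key]]
    if (is.null(loc)) loc <- c(0, 0)
    s11 <- gauss_extrapolate(st$gauss[e, , 1, drop = TRUE], loc[1], loc[2])
    s22 <- gauss_extrapolate(st$gauss[e, , 2, drop = TRUE], loc[1], loc[2])
    s12 <- gauss_extrapolate(st$gauss[e, , 3, drop = TRUE], loc[1], loc[2])
    tx <- s11 * nxv[k] + s12 * nyv[k]
    ty <- s12 * nxv[k] + s22 * nyv[k]
    tn <- tx * nxv[k] + ty * nyv[k]
    out[k] <- sqrt((tx - tn * nxv[k])^2 + (ty - tn * nyv[k])^2)
  }
  out
}

#' Mechanical cost at the leaflet base
#'
#' Ratio of solid to fluid wall shear stress evaluated at the moment of
#' minimum FWSS inside the supplied (closing-closed) window.
#'
#' @param t time grid (s).
#' @param swss,fwss shear-stress series at the leaflet base / backside.
#' @param window numeric length-2 time window (s).
#' @return list `cost`, `t_selected`; `cost` is `Inf` with attribute
#'   `unbounded` when the selected FWSS is zero.
#' @export
mechanical_cost <- function(t, swss, fwss, window = range(t)) {
  sel <- which(t >= window[1] & t <= window[2])
  if (!length(sel)) stop("empty selection window")
  i <- sel[which.min(abs(fwss[sel]))]
  if (abs(fwss[i]) < .Machine$double.eps) {
    out <- list(cost = Inf, t_selected = t[i])
    attr(out, "unbounded") <- TRUE
    return(out)
  }
  list(cost = abs(swss[i]) / abs(fwss[i]), t_selected = t[i])
}

#' Leaflet rotation angle
#'
#' Signed angle (degrees) between the current and reference hinge-to-tip
#' chords; invariant to stretching along the chord.
#'
#' @param coords_ref,coords_cur reference/current coordinates.
#' @param hinge,tip node ids.
#' @return angle in degrees (positive counter-clockwise).
#' @export
leaflet_rotation <- function(coords_ref, coords_cur, hinge, tip) {
  a <- coords_ref[tip, ] - coords_ref[hinge, ]
  b <- coords_cur[tip, ] - coords_cur[hinge, ]
  atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2]) * 180 / pi
}

#' Segment the valve cycle into its four phases
#'
#' Opening: from the end of the relaxation window until the orifice first
#' reaches 95% of its maximum; equilibrium: while above 95% of maximum;
#' closing: from the last time above 95% until the orifice falls to the
#' closure threshold; closed: from closure onward. A valve that never
#' reaches closure yields an empty closed phase and the incompetence flag.
#'
#' @param t time grid (s).
#' @param l_goa orifice width series (cm).
#' @param relax_end end of the relaxation window (s).
#' @param closure_threshold orifice width counted as closed (cm).
#' @return data.frame `phase`, `t_start`, `t_end`; attributes `incompetent`
#'   (logical) and `l_max`.
#' @export
phase_segmentation <- function(t, l_goa, relax_end = 0.05,
                               closure_threshold) {
  stopifnot(length(t) == length(l_goa))
  lmax <- max(l_goa)
  if (diff(range(l_goa)) < 1e-12)
    stop("degenerate segmentation: constant orifice width")
  hi <- which(l_goa >= 0.95 * lmax & t >= relax_end)
  if (!length(hi)) stop("degenerate segmentation: no equilibrium plateau")
  t_open_end <- t[hi[1]]
  t_eq_end <- t[hi[length(hi)]]
  after <- which(t > t_eq_end & l_goa <= closure_threshold)
  if (length(after)) {
    t_close_end <- t[after[1]]
    incom <- FALSE
  } else {
    t_close_end <- t[length(t)]
    incom <- TRUE
  }
  ph <- data.frame(
    phase = c("opening", "equilibrium", "closing", "closed"),
    t_start = c(relax_end, t_open_end, t_eq_end, t_close_end),
    t_end = c(t_open_end, t_eq_end, t_close_end,
              if (incom) t_close_end else t[length(t)]))
  attr(ph, "incompetent") <- incom
  attr(ph, "l_max") <- lmax
  ph
}
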