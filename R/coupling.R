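#' Point-in-polygon test (crossing number)
#'
#' @param px,py point coordinates (vectors).
#' @param polyx,poly_y closed polygon vertex coordinates (first vertex not
#'   repeated).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, polyx, poly_y) {
  n <- length(polyx)
  x1 <- polyx; y1 <- poly_y
  x2 <- polyx[c(2:n, 1L)]; y2 <- poly_y[c(2:n, 1L)]
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    cond <- (y1[k] > py) != (y2[k] > py)
    if (any(cond)) {
      xin <- (x2[k] - x1[k]) * (py[cond] - y1[k]) / (y2[k] - y1[k]) + x1[k]
      inside[cond] <- xor(inside[cond], px[cond] < xin)
    }
  }
  inside
}

# minimum distance from points to a polyline segment set; returns list with
# dist, seg (index), tpar (parameter along segment)
.points_seg_dist <- function(px, py, x1, y1, x2, y2) {
  P <- length(px); S <- length(x1)
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- pmax(dx^2 + dy^2, 1e-30)
  best <- rep(Inf, P); bseg <- integer(P); bt <- numeric(P)
  for (s in seq_len(S)) {
    t <- ((px - x1[s]) * dx[s] + (py - y1[s]) * dy[s]) / L2[s]
    t <- pmin(pmax(t, 0), 1)
    d2 <- (px - (x1[s] + t * dx[s]))^2 + (py - (y1[s] + t * dy[s]))^2
    upd <- d2 < best
    best[upd] <- d2[upd]; bseg[upd] <- s; bt[upd] <- t[upd]
  }
  list(dist = sqrt(best), seg = bseg, tpar = bt)
}

#' Coupling cache for an immersed vein
#'
#' Precomputes, per solid component (upper/lower wall-sinus band, each
#' leaflet), the boundary-edge list and the boundary loops used for
#' classification, together with the classification dilation: components
#' thinner than the fluid cell are inflated to an effective half-thickness of
#' `0.75 h` so that a covered-node layer always exists (the dilation vanishes
#' once the grid resolves the thickness).
#'
#' @param vm a `vein_mesh`.
#' @param fmodel a [fluid_model()].
#' @return object of class `fsi_coupling`.
#' @export
fsi_coupling <- function(vm, fmodel) {
  ratio <- fmodel$h / vm$target_size
  if (ratio < 0.5 || ratio > 2.0)
    warning("fluid/solid mesh size ratio ", signif(ratio, 3),
            " outside the supported band [0.5, 2.0]", call. = FALSE)
  comps <- unique(vm$comp)
  cdata <- list()
  for (cn in comps) {
    eidx <- which(vm$comp == cn)
    sub <- vm$mesh; sub$elems <- sub$elems[eidx, , drop = FALSE]
    sub$part <- sub$part[eidx]
    edges <- mesh_boundary_edges(sub)
    loops <- mesh_boundary_loops(edges)
    thick <- vm$comp_thickness[[cn]]
    # effective half-thickness of at least ~1.05 h: the covered-node band is
    # then at least two grid rows wide, which makes the immersed member
    # watertight for the bilinear flux (a single Dirichlet row is porous)
    dil <- max(0, 1.05 * fmodel$h - thick / 2)
    cdata[[cn]] <- list(name = cn, elems = eidx, edges = edges,
                        loops = loops, thickness = thick, dilate = dil)
  }
  structure(list(comps = cdata, vm = vm, mesh_ratio = ratio),
            class = "fsi_coupling")
}

#' Classify Eulerian nodes against the immersed solid
#'
#' Nodes covered by (or within the dilation band of) any solid component are
#' ghost when they have a grid-edge neighbor that is real, inactive
#' otherwise; all remaining nodes are real.
#'
#' @param coup an [fsi_coupling()].
#' @param fmodel a [fluid_model()].
#' @param coords current solid node coordinates (n_s x 2).
#' @return list with `activity` (integer labels per fluid node: 1 real,
#'   2 ghost, 3 inactive), `cover_comp` (covering component name index,
#'   0 when real) and `elem_covered` (logical per grid cell: cell centre
#'   covered, hence the cell is excluded from the fluid equations so thin
#'   members block the flux even where the covered-node band is one node
#'   wide).
#' @export
classify_fluid_nodes <- function(coup, fmodel, coords) {
  nd <- fmodel$grid$nodes
  el <- fmodel$grid$elems
  ec <- cbind(rowMeans(matrix(nd[el, 1L], ncol = 4L)),
              rowMeans(matrix(nd[el, 2L], ncol = 4L)))
  nfl <- nrow(nd)
  covered <- logical(nfl); cover <- integer(nfl)
  ecov <- logical(nrow(el))
  mark <- function(px, py, done, cd) {
    lxl <- cd$lx; lyl <- cd$ly
    mar <- cd$dilate + 1e-10
    cand <- which(px >= min(lxl) - mar & px <= max(lxl) + mar &
                  py >= min(lyl) - mar & py <= max(lyl) + mar & !done)
    if (!length(cand)) return(integer(0))
    isin <- point_in_polygon(px[cand], py[cand], lxl, lyl)
    if (cd$dilate > 0) {
      n <- length(lxl)
      x2 <- lxl[c(2:n, 1L)]; y2 <- lyl[c(2:n, 1L)]
      dd <- .points_seg_dist(px[cand], py[cand], lxl, lyl, x2, y2)
      isin <- isin | dd$dist <= cd$dilate
    }
    cand[isin]
  }
  for (ci in seq_along(coup$comps)) {
    cd <- coup$comps[[ci]]
    for (lp in cd$loops) {
      cdl <- list(lx = coords[lp, 1L], ly = coords[lp, 2L],
                  dilate = cd$dilate)
      hit <- mark(nd[, 1], nd[, 2], covered, cdl)
      covered[hit] <- TRUE; cover[hit] <- ci
      # cell deactivation uses the undilated geometry: with the two-row
      # covered-node band the (ghost,ghost) faces already seal the member,
      # and a dilated cell cover would disconnect the ghost band from the
      # active fluid (losing the moving-wall condition)
      cdl$dilate <- 0
      ecov[mark(ec[, 1], ec[, 2], ecov, cdl)] <- TRUE
    }
  }
  act <- rep(ACT_REAL, nfl)
  if (any(covered)) {
    nx <- fmodel$nx; ny <- fmodel$ny
    covm <- matrix(covered, nx + 1L, ny + 1L)
    neigh_real <- matrix(FALSE, nx + 1L, ny + 1L)
    realm <- !covm
    neigh_real[-1, ] <- neigh_real[-1, ] | realm[-(nx + 1L), ]
    neigh_real[-(nx + 1L), ] <- neigh_real[-(nx + 1L), ] | realm[-1, ]
    neigh_real[, -1] <- neigh_real[, -1] | realm[, -(ny + 1L)]
    neigh_real[, -(ny + 1L)] <- neigh_real[, -(ny + 1L)] | realm[, -1]
    ghost <- covered & as.vector(neigh_real)
    act[covered] <- ACT_INACTIVE
    act[ghost] <- ACT_GHOST
  }
  list(activity = act, cover_comp = cover, elem_covered = ecov)
}

#' Interface map from ghost nodes to the solid boundary
#'
#' For each ghost node finds the nearest point on the boundary of the
#' component that covers it (nearest over all components when the cover is a
#' dilation band).
#'
#' @param coup an [fsi_coupling()].
#' @param fmodel a [fluid_model()].
#' @param coords current solid coordinates.
#' @param cls classification from [classify_fluid_nodes()].
#' @return data.frame: `node` (fluid id), `comp`, `n1`, `n2` (solid edge
#'   node ids), `tpar`, `elem` (parent solid element), `dist`.
#' @export
interface_map <- function(coup, fmodel, coords, cls) {
  gnodes <- which(cls$activity == ACT_GHOST)
  if (!length(gnodes))
    return(data.frame(node = integer(0), comp = integer(0), n1 = integer(0),
                      n2 = integer(0), tpar = numeric(0), elem = integer(0),
                      dist = numeric(0)))
  nd <- fmodel$grid$nodes
  out <- vector("list", length(coup$comps))
  assigned <- rep(Inf, length(gnodes))
  res <- data.frame(node = gnodes, comp = 0L, n1 = 0L, n2 = 0L,
                    tpar = 0, elem = 0L, dist = Inf)
  for (ci in seq_along(coup$comps)) {
    cd <- coup$comps[[ci]]
    sel <- which(cls$cover_comp[gnodes] == ci)
    if (!length(sel)) next
    e <- cd$edges
    dd <- .points_seg_dist(nd[gnodes[sel], 1], nd[gnodes[sel], 2],
                           coords[e$n1, 1], coords[e$n1, 2],
                           coords[e$n2, 1], coords[e$n2, 2])
    res$comp[sel] <- ci
    res$n1[sel] <- e$n1[dd$seg]; res$n2[sel] <- e$n2[dd$seg]
    res$tpar[sel] <- dd$tpar; res$elem[sel] <- e$elem[dd$seg]
    res$dist[sel] <- dd$dist
  }
  res
}

#' Interpolate solid velocity to ghost nodes
#'
#' The ghost node receives the solid boundary velocity at the nearest
#' boundary point extrapolated by the boundary-element velocity gradient:
#' `v_b = v(B') + grad v |_(B') l_(B'b)`. The gradient is evaluated from the
#' parent element's bilinear field in the current configuration (exact for
#' rigid translation and rotation); degenerate elements fall back to the
#' zeroth-order value.
#'
#' @param map an [interface_map()].
#' @param fmodel a [fluid_model()].
#' @param coords current solid coordinates (n_s x 2).
#' @param vel solid nodal velocity (n_s x 2).
#' @param elems solid element connectivity (for the gradient).
#' @return data.frame `node`, `u`, `v`.
#' @export
velocity_solid_to_fluid <- function(map, fmodel, coords, vel, elems) {
  if (!nrow(map)) return(data.frame(node = integer(0), u = numeric(0),
                                    v = numeric(0)))
  nd <- fmodel$grid$nodes
  t <- map$tpar
  bx <- (1 - t) * coords[map$n1, 1] + t * coords[map$n2, 1]
  by <- (1 - t) * coords[map$n1, 2] + t * coords[map$n2, 2]
  vbx <- (1 - t) * vel[map$n1, 1] + t * vel[map$n2, 1]
  vby <- (1 - t) * vel[map$n1, 2] + t * vel[map$n2, 2]
  # parent-element velocity gradient at the element centre (current config)
  el <- elems[map$elem, , drop = FALSE]
  xe <- matrix(coords[el, 1L], ncol = 4L); ye <- matrix(coords[el, 2L], ncol = 4L)
  ue <- matrix(vel[el, 1L], ncol = 4L); ve <- matrix(vel[el, 2L], ncol = 4L)
  dNdxi <- c(-1, 1, 1, -1) / 4; dNdeta <- c(-1, -1, 1, 1) / 4
  dxdxi <- xe %*% dNdxi; dxdeta <- xe %*% dNdeta
  dydxi <- ye %*% dNdxi; dydeta <- ye %*% dNdeta
  detJ <- as.vector(dxdxi * dydeta - dxdeta * dydxi)
  ok <- abs(detJ) > 1e-20
  inv <- ifelse(ok, 1 / detJ, 0)
  dudx <- (as.vector(ue %*% dNdxi) * as.vector(dydeta) -
             as.vector(ue %*% dNdeta) * as.vector(dydxi)) * inv
  dudy <- (-as.vector(ue %*% dNdxi) * as.vector(dxdeta) +
             as.vector(ue %*% dNdeta) * as.vector(dxdxi)) * inv
  dvdx <- (as.vector(ve %*% dNdxi) * as.vector(dydeta) -
             as.vector(ve %*% dNdeta) * as.vector(dydxi)) * inv
  dvdy <- (-as.vector(ve %*% dNdxi) * as.vector(dxdeta) +
             as.vector(ve %*% dNdeta) * as.vector(dxdxi)) * inv
  lx <- nd[map$node, 1] - bx; ly <- nd[map$node, 2] - by
  data.frame(node = map$node,
             u = vbx + dudx * lx + dudy * ly,
             v = vby + dvdx * lx + dvdy * ly)
}

#' Bilinear interpolation of fluid fields at arbitrary points
#'
#' @param fmodel a [fluid_model()].
#' @param state a [fluid_state()].
#' @param px,py sample coordinates (clamped into the domain).
#' @param field "p", "u" or "v".
#' @return numeric vector of interpolated values.
#' @export
fluid_interp <- function(fmodel, state, px, py, field = "p") {
  nx <- fmodel$nx; ny <- fmodel$ny; hx <- fmodel$hx; hy <- fmodel$hy
  px <- pmin(pmax(px, 0), nx * hx - 1e-12)
  py <- pmin(pmax(py, 0), ny * hy - 1e-12)
  i <- pmin(pmax(floor(px / hx), 0), nx - 1)
  j <- pmin(pmax(floor(py / hy), 0), ny - 1)
  a <- px / hx - i; b <- py / hy - j
  nid <- function(ii, jj) (jj) * (nx + 1L) + ii + 1L
  f <- switch(field, p = state$p, u = state$v[, 1], v = state$v[, 2])
  f[nid(i, j)] * (1 - a) * (1 - b) + f[nid(i + 1, j)] * a * (1 - b) +
    f[nid(i + 1, j + 1)] * a * b + f[nid(i, j + 1)] * (1 - a) * b
}

#' Fluid pressure traction on the solid boundary
#'
#' Interpolates the fluid pressure to each solid boundary node bilinearly
#' from its host fluid cell and integrates `-p n` consistently over the
#' boundary edges (viscous shear is omitted: the no-slip condition is
#' carried by the velocity interpolation). With `offset > 0` the pressure is
#' sampled at `x + offset * n` along the outward node normal, one-sided into
#' the fluid; `offset = 0` samples at the node itself.
#'
#' @param coup an [fsi_coupling()].
#' @param fmodel a [fluid_model()].
#' @param state a [fluid_state()].
#' @param coords current solid coordinates.
#' @param offset sampling offset (cm).
#' @param fallback_pressure optional function `(px, py, nx, ny)` returning a
#'   pressure for sample points whose host cell is not fully resolved (some
#'   corner covered by the solid); used as a subgrid model where thin members
#'   pinch the grid off (e.g. the sealed tip gap of a nearly closed valve).
#' @param smooth_passes boundary-wise 1-2-1 smoothing passes applied to the
#'   sampled nodal pressures (mollifies grid-scale sampling noise that would
#'   otherwise excite node-scale flutter of light immersed members).
#' @return list: `force` (2 n_s nodal force vector, dyn per unit width),
#'   `pressure` (per boundary node).
#' @export
traction_fluid_to_solid <- function(coup, fmodel, state, coords, offset = 0,
                                    fallback_pressure = NULL,
                                    smooth_passes = 0L) {
  ns <- nrow(coords)
  force <- numeric(2L * ns)
  pnode <- rep(NA_real_, ns)
  for (cd in coup$comps) {
    for (lp in cd$loops) {
      m <- length(lp)
      lx <- coords[lp, 1]; ly <- coords[lp, 2]
      nxt <- c(2:m, 1L); prv <- c(m, 1:(m - 1L))
      # outward node normal: mean of the adjacent CCW edge normals
      ex <- lx[nxt] - lx; ey <- ly[nxt] - ly
      el <- sqrt(ex^2 + ey^2)
      enx <- ey / el; eny <- -ex / el         # edge outward normals
      nnx <- enx + enx[prv]; nny <- eny + eny[prv]
      nl <- pmax(sqrt(nnx^2 + nny^2), 1e-12)
      nnx <- nnx / nl; nny <- nny / nl
      px <- lx + offset * nnx; py <- ly + offset * nny
      p <- fluid_interp(fmodel, state, px, py, "p")
      if (!is.null(fallback_pressure)) {
        res <- fluid_sample_resolved(fmodel, state$activity, px, py)
        if (any(!res))
          p[!res] <- fallback_pressure(px[!res], py[!res], nnx[!res], nny[!res])
      }
      for (pass in seq_len(smooth_passes))
        p <- 0.25 * p[prv] + 0.5 * p + 0.25 * p[nxt]
      pnode[lp] <- p
      # consistent linear-edge integration of -p n over the CCW edges
      pa <- p; pb <- p[nxt]
      fa <- -(2 * pa + pb) / 6 * el
      fb <- -(pa + 2 * pb) / 6 * el
      idx <- c(2L * (lp - 1L) + 1L, 2L * lp,
               2L * (lp[nxt] - 1L) + 1L, 2L * lp[nxt])
      val <- c(fa * enx, fa * eny, fb * enx, fb * eny)
      agg <- rowsum(val, idx)
      ii <- as.integer(rownames(agg))
      force[ii] <- force[ii] + agg[, 1]
    }
  }
  list(force = force, pressure = pnode)
}

#' Are sample points inside fully resolved (all-real) cells?
#'
#' @param fmodel a [fluid_model()].
#' @param activity integer activity labels per fluid node.
#' @param px,py sample coordinates.
#' @return logical vector.
#' @export
fluid_sample_resolved <- function(fmodel, activity, px, py) {
  nx <- fmodel$nx; ny <- fmodel$ny; hx <- fmodel$hx; hy <- fmodel$hy
  i <- pmin(pmax(floor(px / hx), 0), nx - 1)
  j <- pmin(pmax(floor(py / hy), 0), ny - 1)
  nid <- function(ii, jj) (jj) * (nx + 1L) + ii + 1L
  activity[nid(i, j)] == ACT_REAL & activity[nid(i + 1, j)] == ACT_REAL &
    activity[nid(i, j + 1)] == ACT_REAL & activity[nid(i + 1, j + 1)] == ACT_REAL
}

#' Bilinear interpolation weights of a point in its host cell
#'
#' Exposes the interpolation used for the fluid-to-solid transfer: weights
#' `alpha`, `beta` and the four corner node ids of the host cell.
#'
#' @param fmodel a [fluid_model()].
#' @param px,py point coordinates.
#' @return data.frame `alpha`, `beta`, `n_a`, `n_b`, `n_c`, `n_e` (corner ids
#'   counter-clockwise from the upper-right, matching
#'   `p = a*b p_a + b(1-a) p_b + (1-a)(1-b) p_c + a(1-b) p_e`).
#' @export
bilinear_weights <- function(fmodel, px, py) {
  nx <- fmodel$nx; ny <- fmodel$ny; hx <- fmodel$hx; hy <- fmodel$hy
  i <- pmin(pmax(floor(px / hx), 0), nx - 1)
  j <- pmin(pmax(floor(py / hy), 0), ny - 1)
  a <- px / hx - i; b <- py / hy - j
  nid <- function(ii, jj) (jj) * (nx + 1L) + ii + 1L
  data.frame(alpha = a, beta = b,
             n_a = nid(i + 1, j + 1), n_b = nid(i, j + 1),
             n_c = nid(i, j), n_e = nid(i + 1, j))
}
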