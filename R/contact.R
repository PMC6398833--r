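#' Adhesive contact parameters
#'
#' 12-6 Lennard-Jones inter-body potential with positive well depth
#' `epsilon` and equilibrium distance `r0` (twice the initial leaflet gap by
#' default). The closed-form integral of `phi(r) r` drives a panel-pair
#' force that is strongly repulsive below the zero crossing
#' `r0 * 5^(-1/6) ~ 0.765 r0` and weakly adhesive beyond it; separations
#' below `0.4 r0` are treated as the hard-repulsion band. Forces beyond
#' `cutoff` (default `3 r0`) are dropped.
#'
#' @param epsilon well-depth magnitude (calibrated force scale; see
#'   [calibrate_contact_epsilon()]).
#' @param r0 equilibrium distance (cm).
#' @param beta_i,beta_j dimensionless surface densities.
#' @param cutoff interaction cutoff (cm).
#' @param candidate_margin extra margin for candidate search (cm).
#' @param force_ceiling per-panel force magnitude that triggers a time-step
#'   warning.
#' @return list of class `contact_params`.
#' @export
contact_params <- function(epsilon = 1, r0 = 0.036, beta_i = 1, beta_j = 1,
                           cutoff = 3 * r0, candidate_margin = r0,
                           force_ceiling = Inf) {
  stopifnot(r0 > 0, cutoff >= 2 * r0, beta_i > 0, beta_j > 0, epsilon > 0)
  structure(list(epsilon = epsilon, r0 = r0, beta_i = beta_i,
                 beta_j = beta_j, cutoff = cutoff,
                 candidate_margin = candidate_margin,
                 force_ceiling = force_ceiling),
            class = "contact_params")
}

#' Lennard-Jones 12-6 potential
#'
#' `phi(r) = epsilon ((r0/r)^12 - 2 (r0/r)^6)`: minimum `-epsilon` at
#' `r = r0`, zero at `r0 2^(-1/6)`, vanishing at range.
#'
#' @param r distance(s), > 0.
#' @param params a [contact_params()].
#' @return potential value(s).
#' @export
lj_potential <- function(r, params) {
  if (any(r <= 0)) stop("domain error: r must be positive")
  s6 <- (params$r0 / r)^6
  params$epsilon * (s6^2 - 2 * s6)
}

#' Closed-form tail integral of the potential
#'
#' `I(s) = int_s^Inf phi(r) r dr = epsilon (r0^12/(10 s^10) - r0^6/(2 s^4))`;
#' positive (repulsive) below `s = r0 5^(-1/6)`, negative (adhesive) beyond.
#'
#' @param s lower integration bound (cm), > 0.
#' @param params a [contact_params()].
#' @return integral value(s).
#' @export
lj_force_integral <- function(s, params) {
  if (any(s <= 0)) stop("penetration error: nonpositive surface separation")
  params$epsilon * (params$r0^12 / (10 * s^10) - params$r0^6 / (2 * s^4))
}

#' Surface panels of a boundary edge set
#'
#' @param coords current solid coordinates.
#' @param edges data.frame `n1`, `n2` (counter-clockwise boundary edges).
#' @param beta dimensionless density.
#' @return data.frame of class `surface_panels`: midpoints `bx`, `by`,
#'   outward normals `nx`, `ny`, lengths `da`, endpoint ids, `beta`.
#' @export
surface_panels <- function(coords, edges, beta = 1) {
  x1 <- coords[edges$n1, 1]; y1 <- coords[edges$n1, 2]
  x2 <- coords[edges$n2, 1]; y2 <- coords[edges$n2, 2]
  da <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  out <- data.frame(bx = (x1 + x2) / 2, by = (y1 + y2) / 2,
                    nx = (y2 - y1) / da, ny = -(x2 - x1) / da,
                    da = da, n1 = edges$n1, n2 = edges$n2, beta = beta)
  class(out) <- c("surface_panels", "data.frame")
  out
}

#' Candidate panel pairs within the cutoff
#'
#' Pairs of panels from two distinct surfaces with midpoint distance below
#' `cutoff + candidate_margin` that face each other (each midpoint on the
#' outward side of the other panel).
#'
#' @param panels_i,panels_j [surface_panels()] of the two bodies.
#' @param params a [contact_params()].
#' @return data.frame `i`, `j` of panel row indices.
#' @export
detect_candidates <- function(panels_i, panels_j, params) {
  rc <- params$cutoff + params$candidate_margin
  dx <- outer(panels_i$bx, panels_j$bx, "-")
  dy <- outer(panels_i$by, panels_j$by, "-")
  d2 <- dx^2 + dy^2
  near <- d2 < rc^2
  # facing filters: i is on the outward side of j and vice versa
  fj <- (dx * rep(panels_j$nx, each = nrow(panels_i)) +
           dy * rep(panels_j$ny, each = nrow(panels_i))) > 0
  fi <- (-dx * panels_i$nx - dy * panels_i$ny) > 0
  idx <- which(near & fj & fi, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

#' Force on one panel from another
#'
#' `F_i = beta_i beta_j n_j da_i dalpha I(s)`, where `s` is the distance
#' from the midpoint of panel i to panel j, `dalpha` the angle subtended by
#' panel j at that midpoint, and `I(s)` the closed-form tail integral
#' ([lj_force_integral()]); the direction is along the source panel's
#' outward normal `n_j` (repulsion pushes the receiver away from the source
#' body).
#'
#' @param panel_i,panel_j single-row [surface_panels()] entries.
#' @param params a [contact_params()].
#' @return force vector (length 2) on panel i per unit out-of-plane width.
#' @export
panel_pair_force <- function(panel_i, panel_j, params) {
  # distance from B_i to the source segment
  hx <- panel_j$da / 2
  p1x <- panel_j$bx - hx * (-panel_j$ny); p1y <- panel_j$by - hx * panel_j$nx
  p2x <- panel_j$bx + hx * (-panel_j$ny); p2y <- panel_j$by + hx * panel_j$nx
  dd <- .points_seg_dist(panel_i$bx, panel_i$by, p1x, p1y, p2x, p2y)
  s <- dd$dist
  if (s <= 0) stop("penetration error: panel midpoint on the source panel")
  e1x <- p1x - panel_i$bx; e1y <- p1y - panel_i$by
  e2x <- p2x - panel_i$bx; e2y <- p2y - panel_i$by
  dalpha <- abs(atan2(e1x * e2y - e1y * e2x, e1x * e2x + e1y * e2y))
  if (s >= params$cutoff) return(c(0, 0))
  Iv <- lj_force_integral(s, params)
  params$beta_i * params$beta_j * panel_i$da * dalpha * Iv *
    c(panel_j$nx, panel_j$ny)
}

# vectorized pair forces; pairs is the candidate data.frame
.pair_forces <- function(panels_i, panels_j, pairs, params) {
  if (!nrow(pairs)) return(cbind(fx = numeric(0), fy = numeric(0), s = numeric(0)))
  pj <- panels_j[pairs$j, ]
  pi_ <- panels_i[pairs$i, ]
  hx <- pj$da / 2
  p1x <- pj$bx + hx * pj$ny; p1y <- pj$by - hx * pj$nx
  p2x <- pj$bx - hx * pj$ny; p2y <- pj$by + hx * pj$nx
  dx1 <- p2x - p1x; dy1 <- p2y - p1y
  L2 <- pmax(dx1^2 + dy1^2, 1e-30)
  t <- pmin(pmax(((pi_$bx - p1x) * dx1 + (pi_$by - p1y) * dy1) / L2, 0), 1)
  s <- sqrt((pi_$bx - (p1x + t * dx1))^2 + (pi_$by - (p1y + t * dy1))^2)
  if (any(s <= 0)) stop("penetration error: zero surface separation")
  e1x <- p1x - pi_$bx; e1y <- p1y - pi_$by
  e2x <- p2x - pi_$bx; e2y <- p2y - pi_$by
  dalpha <- abs(atan2(e1x * e2y - e1y * e2x, e1x * e2x + e1y * e2y))
  # saturate the repulsion below the hard band so a grazing touch cannot
  # produce unbounded forces in the explicit loop
  s_eff <- pmax(s, 0.25 * params$r0)
  Iv <- ifelse(s < params$cutoff, lj_force_integral(s_eff, params), 0)
  mag <- params$beta_i * params$beta_j * pi_$da * dalpha * Iv
  cbind(fx = mag * pj$nx, fy = mag * pj$ny, s = s)
}

#' Contact forces between surface sets
#'
#' Accumulates the panel-pair forces of every interacting surface pair into
#' a nodal force vector (each panel's force split half-half between its
#' endpoint nodes). Both directions of every pair are evaluated, so the
#' totals on the two bodies balance at quadrature level.
#'
#' @param surfaces named list of [surface_panels()].
#' @param pairs list of character 2-vectors naming interacting surfaces.
#' @param params a [contact_params()].
#' @param ndof solid dof count (2 x node count).
#' @param exclude optional named list (key `"A|B"`) of character vectors
#'   `"i_j"` marking panel pairs that never interact (surfaces that are
#'   anatomically attached in the rest configuration, e.g. the leaflet
#'   commissure on the sinus).
#' @return list: `force` (nodal vector), `min_sep` (minimum candidate
#'   separation, cm), `max_panel_force`, per-surface force resultants.
#' @export
contact_forces <- function(surfaces, pairs, params, ndof, exclude = NULL) {
  force <- numeric(ndof)
  min_sep <- Inf; max_pf <- 0
  resultants <- list()
  for (pr in pairs) {
    a <- surfaces[[pr[1]]]; b <- surfaces[[pr[2]]]
    if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b)) next
    for (dirn in 1:2) {
      pi_ <- if (dirn == 1L) a else b
      pj <- if (dirn == 1L) b else a
      cand <- detect_candidates(pi_, pj, params)
      if (!is.null(exclude)) {
        key <- paste0(pr[dirn], "|", pr[3 - dirn])
        ex <- exclude[[key]]
        if (!is.null(ex) && nrow(cand))
          cand <- cand[!(paste0(cand$i, "_", cand$j) %in% ex), , drop = FALSE]
      }
      if (!nrow(cand)) next
      ff <- .pair_forces(pi_, pj, cand, params)
      min_sep <- min(min_sep, ff[, "s"])
      # accumulate per receiving panel, then half-half to endpoints
      fx <- rowsum(ff[, "fx"], cand$i); fy <- rowsum(ff[, "fy"], cand$i)
      prow <- as.integer(rownames(fx))
      max_pf <- max(max_pf, sqrt(fx^2 + fy^2))
      n1 <- pi_$n1[prow]; n2 <- pi_$n2[prow]
      idx <- c(2L * (n1 - 1L) + 1L, 2L * (n2 - 1L) + 1L, 2L * n1, 2L * n2)
      val <- c(fx / 2, fx / 2, fy / 2, fy / 2)
      agg <- rowsum(val, idx)
      ii <- as.integer(rownames(agg))
      force[ii] <- force[ii] + agg[, 1]
      key <- paste(pr[dirn], "<-", pr[3 - dirn])
      resultants[[key]] <- c(sum(fx), sum(fy))
    }
  }
  if (is.finite(params$force_ceiling) && max_pf > params$force_ceiling)
    warning("contact panel force ", signif(max_pf, 3),
            " exceeds the ceiling; consider a smaller time step",
            call. = FALSE)
  list(force = force, min_sep = min_sep, max_panel_force = max_pf,
       resultants = resultants)
}

#' Calibrate the contact well depth against the pressure load
#'
#' Sets `epsilon` so that the saturated hard-band repulsion on a typical
#' panel (at the saturation separation `0.25 r0`, subtending its own
#' length) balances `2 x` the peak transvalvular pressure load on that
#' panel: the maximum available repulsion bounds the strongest load, while
#' the adhesive tail stays small against the hemodynamic forces (consistent
#' with the dyne/cm-scale contact forces the leaning leaflets experience).
#'
#' @param params a [contact_params()] (epsilon ignored).
#' @param delta_p_max peak driving pressure (dyn/cm^2).
#' @param panel_length typical panel length (cm).
#' @return calibrated `contact_params`.
#' @export
calibrate_contact_epsilon <- function(params, delta_p_max, panel_length) {
  s <- 0.25 * params$r0
  dalpha <- panel_length / s
  # |F|/da = dalpha * I(s) with I(s) = eps * c(s); solve eps
  cs <- params$r0^12 / (10 * s^10) - params$r0^6 / (2 * s^4)
  eps <- 2 * delta_p_max / (dalpha * cs)
  params$epsilon <- eps
  params
}
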