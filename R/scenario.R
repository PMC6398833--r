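#' Simulation configuration
#'
#' Assembles the full configuration for a valve-cycle run. Resolution
#' presets: `paper` (h = 0.008 cm, dt = 0.0004 s, the reference resolution),
#' `coarse` (h = 0.02 cm, dt = 0.001 s) and `smoke` (h = 0.04 cm,
#' dt = 0.0025 s) for desk-scale work. All physical defaults are the
#' reference vein: geometry per [vein_geometry()], materials per
#' [wall_material()] / [valve_material()], loading per
#' [loading_protocol()].
#'
#' @param case lesion case id ("Normal", "CFV", "CAV", "IFV", "IAV").
#' @param preset resolution preset.
#' @param n_cycles cycles to run (fractions allowed for partial-cycle
#'   studies).
#' @param seed integer seed (runs are deterministic; kept for
#'   reproducibility bookkeeping).
#' @param overrides named list of config entries to replace (nested lists
#'   are merged shallowly).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(case = "Normal",
                              preset = c("smoke", "coarse", "paper"),
                              n_cycles = 1, seed = 1L, overrides = list()) {
  preset <- match.arg(preset)
  res <- switch(preset,
                paper = list(h = 0.008, dt = 4e-4),
                coarse = list(h = 0.02, dt = 1e-3),
                smoke = list(h = 0.05, dt = 3.5e-3))
  cfg <- list(
    case = case, preset = preset, n_cycles = n_cycles, seed = seed,
    resolution = res,
    geometry = list(),                       # vein_geometry() overrides
    materials = list(wall = list(), sinus = list(), valve = list()),
    loading = list(delta_p_max_mmhg = 4.0, cycle_period = 1.0,
                   relax_duration = 0.05, pulse_duration = 0.5,
                   inlet_mode = "velocity", v_mean_peak = 28.9),
    fluid = list(rho_f = 1.08, mu_f = 0.036, ghost_scale = 1e-6,
                 theta = 0.5, extrapolate = FALSE),
    solid = list(theta = 0.75, f_m = 0.05, f_k = 0.01, kappa_factor = 100,
                 max_iter = 3L, tol = 1e-4),
    contact = list(r0 = 0.036, beta = 1.0, cutoff_factor = 3,
                   calibration_factor = 10.0, closure_factor = 1.25),
    coupling = list(traction_offset_factor = 0.75, force_relax = 0.7,
                    added_mass_length = 0.35, implicit_above = Inf,
                    pc_tol = 2e-2, cfl_target = 2.2),
    output = list(wss_every = 10L, snapshot_every = 0L, dir = NULL))
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    else cfg[[nm]] <- overrides[[nm]]
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Read / write configurations as YAML
#' @param cfg a [simulation_config()].
#' @param file path.
#' @return `config_to_yaml` the path; `config_from_yaml` the config.
#' @export
config_to_yaml <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(file) {
  raw <- yaml::read_yaml(file)
  base <- simulation_config(case = raw$case %||% "Normal",
                            preset = raw$preset %||% "smoke")
  for (nm in names(raw)) {
    if (is.list(raw[[nm]]) && is.list(base[[nm]]))
      base[[nm]][names(raw[[nm]])] <- raw[[nm]]
    else base[[nm]] <- raw[[nm]]
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set up a valve-cycle simulation
#'
#' Builds the geometry, meshes, solvers, coupling cache and contact state
#' for a configuration.
#'
#' @param cfg a [simulation_config()].
#' @return simulation object of class `vv_simulation`.
#' @export
setup_simulation <- function(cfg) {
  set.seed(cfg$seed)
  geom <- do.call(vein_geometry, cfg$geometry)
  lesion <- configure_lesion(cfg$case)
  h <- cfg$resolution$h
  vm <- mesh_solid(geom, h, lesion,
                   leaflet_refine = cfg$solid$leaflet_refine %||% 1)

  mats <- list(
    wall = do.call(wall_material, cfg$materials$wall),
    sinus = do.call(sinus_material, cfg$materials$sinus))
  mat_by_part <- list(wall = mats$wall, sinus = mats$sinus)
  for (k in 1:2) {
    va <- cfg$materials$valve
    va$c0 <- lesion$c0_leaflet[k]
    fac <- lesion$c0_leaflet[k] / 417
    va$mu_baseline <- (va$mu_baseline %||% (200 / 3)) * fac
    mat_by_part[[paste0("valve_leaflet_", k)]] <- do.call(valve_material, va)
  }
  smod <- solid_model(vm$mesh, mat_by_part, fixed_nodes = vm$fixed_nodes,
                      kappa_factor = cfg$solid$kappa_factor)
  M <- solid_mass_matrix(smod)
  nm_par <- newmark_params(dt = cfg$resolution$dt, theta = cfg$solid$theta,
                           f_m = cfg$solid$f_m, f_k = cfg$solid$f_k,
                           max_iter = cfg$solid$max_iter, tol = cfg$solid$tol)

  props <- fluid_props(cfg$fluid$rho_f, cfg$fluid$mu_f, cfg$fluid$ghost_scale)
  grid <- build_fluid_grid(c(geom$L0, 1.071), h)
  fmod <- fluid_model(grid, props)
  coup <- fsi_coupling(vm, fmod)

  ld <- cfg$loading[intersect(names(cfg$loading),
                              names(formals(loading_protocol)))]
  protocol <- do.call(loading_protocol, c(ld, list(rho_f = props$rho_f,
                                                   L0 = geom$L0)))

  cp <- contact_params(epsilon = 1, r0 = cfg$contact$r0,
                       beta_i = cfg$contact$beta, beta_j = cfg$contact$beta,
                       cutoff = cfg$contact$cutoff_factor * cfg$contact$r0)
  # typical leaflet boundary panel length for the calibration
  et <- vm$edge_tags
  le <- et[grepl("leaflet_surface", et$tag), ]
  pl <- mean(sqrt(rowSums((vm$mesh$nodes[le$n1, , drop = FALSE] -
                           vm$mesh$nodes[le$n2, , drop = FALSE])^2)))
  cp <- calibrate_contact_epsilon(cp, protocol$delta_p_max, pl)
  cp$epsilon <- cp$epsilon * cfg$contact$calibration_factor

  # contact surface edge sets; panel pairs already close in the rest
  # configuration (the leaflet commissure on the sinus) are anatomically
  # attached and never interact
  contact_edges <- list(
    leaflet_1 = et[et$comp == "leaflet_1" & et$tag != "leaflet_base", ],
    leaflet_2 = et[et$comp == "leaflet_2" & et$tag != "leaflet_base", ],
    sinus_upper = et[et$comp == "band_upper" &
                       et$tag %in% c("sinus_inner", "lumen_wall"), ],
    sinus_lower = et[et$comp == "band_lower" &
                       et$tag %in% c("sinus_inner", "lumen_wall"), ])
  contact_pairs <- list(c("leaflet_1", "leaflet_2"),
                        c("leaflet_1", "sinus_upper"),
                        c("leaflet_2", "sinus_lower"))
  rest_panels <- lapply(contact_edges, function(e)
    surface_panels(vm$mesh$nodes, e, cfg$contact$beta))
  r_attach <- max(2 * cfg$contact$r0, 3 * h)
  contact_exclude <- list()
  for (pr in contact_pairs) for (dirn in 1:2) {
    a <- rest_panels[[pr[dirn]]]; b <- rest_panels[[pr[3 - dirn]]]
    dx <- outer(a$bx, b$bx, "-"); dy <- outer(a$by, b$by, "-")
    idx <- which(sqrt(dx^2 + dy^2) < r_attach, arr.ind = TRUE)
    if (nrow(idx))
      contact_exclude[[paste0(pr[dirn], "|", pr[3 - dirn])]] <-
        paste0(idx[, 1], "_", idx[, 2])
  }

  ndof <- 2L * smod$n
  # leaflet base / backside edge subsets for the WSS series
  base_edges <- list(); back_edges <- list(); up_edges <- list()
  for (k in 1:2) {
    comp <- paste0("leaflet_", k)
    ek <- et[et$comp == comp & et$tag %in% c("leaflet_surface_upper",
                                             "leaflet_surface_lower"), ]
    mid <- (vm$mesh$nodes[ek$n1, , drop = FALSE] +
              vm$mesh$nodes[ek$n2, , drop = FALSE]) / 2
    hx <- vm$mesh$nodes[vm$hinges[k], ]
    dist_h <- sqrt((mid[, 1] - hx[1])^2 + (mid[, 2] - hx[2])^2)
    base_edges[[k]] <- ek[dist_h < 0.3 * geom$d_v, ]
    back_edges[[k]] <- ek[dist_h < 0.4 * geom$d_v &
                            ek$tag == "leaflet_surface_lower", ]
    up_edges[[k]] <- ek[ek$tag == "leaflet_surface_upper", ]
  }
  # parent elements of tagged edges (needed for SWSS); match against the
  # component boundary-edge tables that carry elem ids
  all_bed <- do.call(rbind, lapply(coup$comps, function(cd) cd$edges))
  key_all <- paste(pmin(all_bed$n1, all_bed$n2), pmax(all_bed$n1, all_bed$n2))
  attach_elem <- function(df) {
    df$elem <- all_bed$elem[match(paste(pmin(df$n1, df$n2),
                                        pmax(df$n1, df$n2)), key_all)]
    df
  }
  base_edges <- lapply(base_edges, attach_elem)
  back_edges <- lapply(back_edges, attach_elem)
  up_edges <- lapply(up_edges, attach_elem)
  contact_edges <- lapply(contact_edges, attach_elem)

  # virtual interface added mass: lumped fluid inertia (rho_f times an
  # effective entrained-fluid length) on the wetted solid boundary nodes;
  # stabilizes the explicit partitioned coupling at near-unity density ratio
  m_add <- numeric(2L * smod$n)
  L_am <- cfg$coupling$added_mass_length
  if (L_am > 0) {
    for (cd in coup$comps) {
      e <- cd$edges
      len <- sqrt(rowSums((vm$mesh$nodes[e$n1, , drop = FALSE] -
                             vm$mesh$nodes[e$n2, , drop = FALSE])^2))
      trib <- rowsum(c(len, len) / 2, c(e$n1, e$n2))
      ids <- as.integer(rownames(trib))
      madd_n <- props$rho_f * L_am * trib[, 1]
      m_add[2L * (ids - 1L) + 1L] <- m_add[2L * (ids - 1L) + 1L] + madd_n
      m_add[2L * ids] <- m_add[2L * ids] + madd_n
    }
  }

  # smallest solid element edge, for the solid sub-stepping guard
  elv <- vm$mesh$elems
  edl <- Inf
  for (kk in 1:4) {
    a <- elv[, kk]; b <- elv[, if (kk == 4L) 1L else kk + 1L]
    edl <- min(edl, sqrt(rowSums((vm$mesh$nodes[a, , drop = FALSE] -
                                    vm$mesh$nodes[b, , drop = FALSE])^2)))
  }

  sim <- list(cfg = cfg, geom = geom, lesion = lesion, protocol = protocol,
              m_add = m_add, h_solid_min = edl,
              vm = vm, smod = smod, M = M, nm_par = nm_par,
              fmod = fmod, coup = coup, cp = cp,
              contact_edges = contact_edges, contact_pairs = contact_pairs,
              contact_exclude = contact_exclude,
              base_edges = base_edges, back_edges = back_edges,
              up_edges = up_edges,
              sstate = list(d = numeric(ndof), v = numeric(ndof),
                            a = numeric(ndof)),
              fstate = fluid_state(fmod),
              f_fluid = numeric(ndof), f_contact = numeric(ndof),
              contact_diag = list(min_sep = Inf, max_panel_force = 0),
              step = 0L, t = 0)
  class(sim) <- "vv_simulation"
  # initial contact force (tips start inside the interaction range)
  sim <- .update_contact(sim)
  sim
}

# current solid coordinates
.solid_coords <- function(sim) {
  n <- sim$smod$n
  sim$vm$mesh$nodes + cbind(sim$sstate$d[2L * (1:n) - 1L],
                            sim$sstate$d[2L * (1:n)])
}

.update_contact <- function(sim) {
  coords <- .solid_coords(sim)
  surf <- lapply(sim$contact_edges, function(e) surface_panels(coords, e,
                                                               sim$cp$beta_i))
  cf <- contact_forces(surf, sim$contact_pairs, sim$cp, 2L * sim$smod$n,
                       exclude = sim$contact_exclude)
  sim$f_contact <- cf$force
  sim$contact_diag <- cf[c("min_sep", "max_panel_force")]
  sim
}

#' Advance the coupled simulation one time step
#'
#' Executes the explicit partitioned ordering: (1) solid step under the
#' previous-step fluid traction and contact force; (2) node
#' re-classification, mixture update, and solid-to-fluid velocity
#' interpolation; (3) fluid step with the interface Dirichlet values;
#' (4) fluid-to-solid traction update (under-relaxed); (5) contact
#' detection and force for the next step.
#'
#' @param sim a `vv_simulation`.
#' @param dt time-step override (defaults to the configured step).
#' @return updated simulation; attribute `diag` carries step diagnostics.
#' @export
advance_coupled_step <- function(sim, dt = NULL, implicit = FALSE,
                                 max_pc = 8L,
                                 pc_tol = sim$cfg$coupling$pc_tol %||% 5e-3,
                                 strict = TRUE) {
  if (is.null(dt)) dt <- sim$cfg$resolution$dt
  t_new <- sim$t + dt
  n <- sim$smod$n

  phase_try <- function(expr, phase) {
    tryCatch(expr, error = function(e)
      stop("step ", sim$step + 1L, " [", phase, "]: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- sub-step kernels operating from the frozen states at t_n ---

  solid_advance <- function(F_fluid) {
    F_ext <- F_fluid + sim$f_contact
    sub_par <- sim$nm_par; sub_par$dt <- dt
    st <- phase_try(solid_step(sim$smod, sim$sstate, F_ext, sub_par,
                               sim$M, m_add = sim$m_add, strict = strict),
                    "solid")
    if (!all(is.finite(st$d)))
      stop("step ", sim$step + 1L, " [solid]: non-finite displacement")
    st
  }

  fluid_advance <- function(sstate) {
    coords <- sim$vm$mesh$nodes + cbind(sstate$d[2L * (1:n) - 1L],
                                        sstate$d[2L * (1:n)])
    cls <- classify_fluid_nodes(sim$coup, sim$fmod, coords)
    mix <- update_mixture_properties(cls$activity, sim$fmod$props)
    fst <- sim$fstate
    fst$activity <- cls$activity
    fst$rho <- mix$rho; fst$mu <- mix$mu
    map <- interface_map(sim$coup, sim$fmod, coords, cls)
    svel <- cbind(sstate$v[2L * (1:n) - 1L], sstate$v[2L * (1:n)])
    ghost <- velocity_solid_to_fluid(map, sim$fmod, coords, svel,
                                     sim$vm$mesh$elems)
    w_t <- pulse_waveform(t_new, sim$protocol)
    lum <- sim$vm$axis_y + c(-1, 1) * sim$geom$d0 / 2
    bn <- sim$fmod$bnodes
    if (identical(sim$cfg$loading$inlet_mode, "velocity")) {
      # parabolic pulsatile inflow over the luminal segment of the inlet
      # during the muscular-pump window; after the pump the posture head
      # re-establishes as an adverse pressure at the distal (outlet) end,
      # the inlet opening to let reflux pass (alternating pump / standing)
      bc <- channel_bc(sim$fmod, p_in = 0, lateral_mode = "clamp",
                       ghost = ghost)
      tc <- t_new %% sim$protocol$cycle_period
      t_on <- sim$protocol$relax_duration + sim$protocol$pulse_duration
      adverse <- if (tc > t_on) sin(min(1, (tc - t_on) / 0.1) * pi / 2)^2 else 0
      if (adverse > 0) {
        outl <- sort(bn$outlet)
        lumy <- (sim$fmod$grid$nodes[outl[-length(outl)], 2] +
                   sim$fmod$grid$nodes[outl[-1], 2]) / 2
        selo <- lumy >= lum[1] & lumy <= lum[2]
        bc$traction <- data.frame(n1 = outl[-length(outl)][selo],
                                  n2 = outl[-1][selo],
                                  tx = -adverse * sim$protocol$p_hydrostatic,
                                  ty = 0)
      } else {
        yl <- sim$fmod$grid$nodes[bn$inlet, 2]
        eta <- (yl - sim$vm$axis_y) / (sim$geom$d0 / 2)
        uprof <- ifelse(abs(eta) < 1, 1.5 * sim$cfg$loading$v_mean_peak *
                          w_t * (1 - eta^2), 0)
        bc$dirichlet <- rbind(bc$dirichlet,
                              data.frame(node = bn$inlet, comp = 1L,
                                         value = uprof))
      }
    } else {
      p_in <- sim$protocol$delta_p_max * w_t
      bc <- channel_bc(sim$fmod, p_in, lateral_mode = "clamp", ghost = ghost,
                       inlet_range = lum)
    }
    extra <- data.frame(node = c(bn$inlet, bn$outlet), comp = 2L, value = 0)
    inact <- which(cls$activity == ACT_INACTIVE)
    if (length(inact))
      # inactive nodes carry no flow but keep their pressure memory, so
      # re-activated cells re-enter with a continuous state
      extra <- rbind(extra,
                     data.frame(node = rep(inact, 3L),
                                comp = rep(1:3, each = length(inact)),
                                value = c(numeric(2L * length(inact)),
                                          sim$fstate$p[inact])))
    bc$dirichlet <- rbind(bc$dirichlet, extra)
    bc$dirichlet <- bc$dirichlet[!duplicated(bc$dirichlet[c("node", "comp")]), ]
    el <- sim$fmod$grid$elems
    active <- which(rowSums(matrix(cls$activity[el] == ACT_REAL, ncol = 4L)) > 0L &
                      !cls$elem_covered)
    fst <- phase_try(
      solve_ns_step(sim$fmod, fst, bc, dt,
                    theta = sim$cfg$fluid$theta,
                    extrapolate = sim$cfg$fluid$extrapolate,
                    active_elems = active), "fluid")
    if (!all(is.finite(fst$v)) || !all(is.finite(fst$p)))
      stop("step ", sim$step + 1L, " [fluid]: non-finite fields")
    list(fstate = fst, coords = coords, n_ghost = nrow(ghost))
  }

  traction_of <- function(fst, coords) {
    # samples falling into pinched-off cells (sealed tip gap, contact
    # zones) take the resolved funnel or pocket pressure of their side as
    # a subgrid fallback
    off <- sim$cfg$coupling$traction_offset_factor * sim$fmod$h
    ax <- sim$vm$axis_y
    probes <- rbind(
      c(sim$geom$valve_offset + 0.25 * sim$geom$d_v, ax),
      c(sim$geom$valve_offset + 0.45 * sim$geom$d_s,
        ax + sim$geom$d0 / 2 - 0.3 * sim$geom$h_v),
      c(sim$geom$valve_offset + 0.45 * sim$geom$d_s,
        ax - sim$geom$d0 / 2 + 0.3 * sim$geom$h_v))
    p_probe <- fluid_interp(sim$fmod, fst, probes[, 1], probes[, 2], "p")
    p_probe[!fluid_sample_resolved(sim$fmod, fst$activity,
                                   probes[, 1], probes[, 2])] <- 0
    fb <- function(px, py, nxv, nyv) {
      toward_axis <- (ax - py) * nyv > 0
      ifelse(toward_axis, p_probe[1],
             ifelse(py > ax, p_probe[2], p_probe[3]))
    }
    traction_fluid_to_solid(sim$coup, sim$fmod, fst, coords,
                            offset = off, fallback_pressure = fb,
                            smooth_passes = 2L)$force
  }

  if (!implicit) {
    # explicit ordering: solid under the lagged traction, then the fluid
    sstate <- solid_advance(sim$f_fluid)
    fa <- fluid_advance(sstate)
    w <- sim$cfg$coupling$force_relax
    f_fluid <- w * traction_of(fa$fstate, fa$coords) + (1 - w) * sim$f_fluid
    pc_iters <- 1L
  } else {
    # strongly coupled step: fixed-point iteration on the interface force
    # with Aitken relaxation, all sub-solves restarting from t_n
    Fcur <- sim$f_fluid
    omega <- 0.5
    r_prev <- NULL
    pc_iters <- 0L
    max_pc <- min(max_pc, 5L)
    for (j in seq_len(max_pc)) {
      sstate <- solid_advance(Fcur)
      fa <- fluid_advance(sstate)
      Fnew <- traction_of(fa$fstate, fa$coords)
      r <- Fnew - Fcur
      pc_iters <- j
      nr <- sqrt(sum(r^2)); nf <- max(sqrt(sum(Fnew^2)), 1e-8)
      if (nr < pc_tol * nf) { Fcur <- Fnew; break }
      if (!is.null(r_prev)) {
        dr <- r - r_prev
        den <- sum(dr^2)
        if (den > 0) omega <- max(0.05, min(1, -omega * sum(r_prev * dr) / den))
      }
      Fcur <- Fcur + omega * r
      r_prev <- r
    }
    f_fluid <- Fcur
  }

  sim$sstate <- sstate
  sim$fstate <- fa$fstate
  sim$f_fluid <- f_fluid

  # contact for the next step
  sim <- .update_contact(sim)

  sim$t <- t_new
  sim$step <- sim$step + 1L
  attr(sim, "diag") <- list(cfl = attr(sim$fstate, "cfl"),
                            div = attr(sim$fstate, "div_norm"),
                            newton = attr(sim$sstate, "iters"),
                            n_ghost = fa$n_ghost, pc_iters = pc_iters,
                            min_sep = sim$contact_diag$min_sep)
  sim
}

#' Advance one coupled step with automatic bisection on failure
#'
#' Retries a failing coupled step as two strongly coupled half-steps (up to
#' `max_depth` levels), which rides through impulsive transients (tip
#' entering the jet, first contact) that defeat a fixed step size.
#'
#' @param sim a `vv_simulation`.
#' @param dt step size (s).
#' @param implicit use the strongly coupled step at this level.
#' @param max_depth maximum bisection depth.
#' @return updated simulation.
#' @export
advance_coupled_adaptive <- function(sim, dt, implicit = FALSE,
                                     max_depth = 6L) {
  res <- tryCatch(advance_coupled_step(sim, dt, implicit = implicit),
                  error = function(e) e)
  if (!inherits(res, "error")) return(res)
  if (max_depth <= 0L) {
    # last resort: accept one unconverged (dissipation-smoothed) solid step
    # rather than abandoning the trajectory; inversion still aborts
    res2 <- tryCatch(advance_coupled_step(sim, dt, implicit = TRUE,
                                          strict = FALSE),
                     error = function(e) e)
    if (!inherits(res2, "error")) return(res2)
    stop(res)
  }
  # remember the failure: the caller keeps the strongly coupled halved mode
  # for a while instead of re-attempting (and re-failing) full steps
  sim$impl_sticky <- max(sim$impl_sticky %||% 0L, 6L)
  sim <- advance_coupled_adaptive(sim, dt / 2, implicit = TRUE,
                                  max_depth = max_depth - 1L)
  advance_coupled_adaptive(sim, dt / 2, implicit = TRUE,
                           max_depth = max_depth - 1L)
}

# leaflet-surface FWSS (max over edge midpoints of a tagged edge set)
.leaflet_fwss <- function(sim, edges, coords, svel) {
  if (!nrow(edges)) return(0)
  x1 <- coords[edges$n1, ]; x2 <- coords[edges$n2, ]
  mid <- (x1 + x2) / 2
  len <- sqrt(rowSums((x2 - x1)^2))
  nxv <- (x2[, 2] - x1[, 2]) / len; nyv <- -(x2[, 1] - x1[, 1]) / len
  wu <- (svel[edges$n1, 1] + svel[edges$n2, 1]) / 2
  wv <- (svel[edges$n1, 2] + svel[edges$n2, 2]) / 2
  wss <- wall_shear_stress_fluid(sim$fmod, sim$fstate, mid[, 1], mid[, 2],
                                 nxv, nyv, wu, wv)
  max(abs(wss))
}

#' Run a valve-cycle scenario
#'
#' Executes the coupled loop for the configured number of cycles, records
#' the cycle metrics, segments the phases and integrates the venous
#' volumes.
#'
#' @param cfg a [simulation_config()] (or a case id string).
#' @param progress print a progress line every `progress` steps (0 = quiet).
#' @return list of class `run_report`: `metrics` (per-step data.frame),
#'   `wss` (coarser-cadence data.frame), `phases`, `volumes`, `summary`,
#'   `config`.
#' @export
run_scenario <- function(cfg, progress = 0L) {
  if (is.character(cfg)) cfg <- simulation_config(case = cfg)
  sim <- setup_simulation(cfg)
  dt <- cfg$resolution$dt
  Tend <- cfg$n_cycles * cfg$loading$cycle_period
  nsteps <- as.integer(round(Tend / dt))
  geom <- sim$geom

  n <- sim$smod$n
  rows <- vector("list", nsteps)
  wrows <- list()
  x_tip <- geom$valve_offset + geom$d_v
  hmin <- min(sim$fmod$hx, sim$fmod$hy)
  run_error <- NULL
  for (k in seq_len(nsteps)) {
    # adaptive sub-cycling keeps the convective CFL of the coupled loop
    # bounded; fast transients (valve snap, jet onset) additionally switch
    # to the strongly coupled (Aitken sub-iterated) step
    vref <- max(max(abs(sim$fstate$v)), max(abs(sim$sstate$v)), 1e-9)
    nsub <- min(16L, max(1L, ceiling(vref * dt /
                                       ((cfg$coupling$cfl_target %||% 1.2) * hmin))))
    sticky <- (sim$impl_sticky %||% 0L) > 0L
    impl <- sticky || vref > cfg$coupling$implicit_above
    step_fail <- tryCatch({
      for (s in seq_len(nsub))
        sim <- advance_coupled_adaptive(sim, dt / nsub, implicit = impl)
      NULL
    }, error = function(e) e)
    if (!is.null(step_fail)) {
      # sub-solver failure: retain the partial trajectory
      run_error <- conditionMessage(step_fail)
      warning("run stopped early at t = ", signif(sim$t, 4), ": ",
              run_error, call. = FALSE)
      break
    }
    if (sticky) sim$impl_sticky <- sim$impl_sticky - 1L
    dg <- attr(sim, "diag")
    coords <- .solid_coords(sim)
    l <- orifice_width(coords, sim$vm$tips)
    hs <- current_sinus_bulge(sim$vm, coords)
    A <- orifice_area(l, geom$d0, hs)
    ytip <- sort(coords[sim$vm$tips, 2])
    xo <- mean(coords[sim$vm$tips, 1])
    Qo <- flow_rate(sim$fmod, sim$fstate, xo, ytip, geom$d0 + 2 * hs)
    ylum <- sim$vm$axis_y + c(-1, 1) * geom$d0 / 2
    Qi <- flow_rate(sim$fmod, sim$fstate, 2 * sim$fmod$hx, ylum, geom$d0)
    Qe <- flow_rate(sim$fmod, sim$fstate, geom$L0 - 2 * sim$fmod$hx, ylum,
                    geom$d0)
    vseg <- if (ytip[2] > ytip[1])
      max(abs(fluid_interp(sim$fmod, sim$fstate, rep(xo, 21),
                           seq(ytip[1], ytip[2], length.out = 21), "u")))
      else 0
    rot1 <- leaflet_rotation(sim$vm$mesh$nodes, coords, sim$vm$hinges[1],
                             sim$vm$tips[1])
    rot2 <- leaflet_rotation(sim$vm$mesh$nodes, coords, sim$vm$hinges[2],
                             sim$vm$tips[2])
    rows[[k]] <- data.frame(
      t = sim$t, waveform = pulse_waveform(sim$t, sim$protocol),
      l_goa = l, h_s = hs, A_goa = A, Q_orifice = Qo, Q_inlet = Qi,
      Q_outlet = Qe, v_orifice_max = vseg, rot_1 = rot1, rot_2 = rot2,
      cfl = dg$cfl, div = dg$div, newton = dg$newton,
      n_ghost = dg$n_ghost, min_sep = dg$min_sep,
      max_contact = sim$contact_diag$max_panel_force)
    if (cfg$output$wss_every > 0L && k %% cfg$output$wss_every == 0L) {
      svel <- cbind(sim$sstate$v[2L * (1:n) - 1L], sim$sstate$v[2L * (1:n)])
      wr <- data.frame(t = sim$t)
      for (j in 1:2) {
        wr[[paste0("fwss_up_", j)]] <-
          .leaflet_fwss(sim, sim$up_edges[[j]], coords, svel)
        wr[[paste0("fwss_back_", j)]] <-
          .leaflet_fwss(sim, sim$back_edges[[j]], coords, svel)
        sw <- wall_shear_stress_solid(sim$smod, sim$sstate$d,
                                      sim$base_edges[[j]], coords)
        wr[[paste0("swss_base_", j)]] <- max(abs(sw))
      }
      wrows[[length(wrows) + 1L]] <- wr
    }
    if (progress > 0L && k %% progress == 0L)
      cat(sprintf("step %d/%d t=%.3f l=%.3f Q=%.2f cfl=%.2f\n",
                  k, nsteps, sim$t, l, Qo, dg$cfl))
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  wss <- if (length(wrows)) do.call(rbind, wrows) else NULL

  closure <- cfg$contact$closure_factor * cfg$contact$r0
  phases <- tryCatch(
    phase_segmentation(metrics$t, metrics$l_goa,
                       relax_end = cfg$loading$relax_duration,
                       closure_threshold = closure),
    error = function(e) NULL)
  vols <- venous_volumes(metrics$t, metrics$Q_orifice,
                         cycle_period = cfg$loading$cycle_period)

  costs <- rep(NA_real_, 2)
  if (!is.null(wss) && !is.null(phases)) {
    win <- c(phases$t_start[3], max(metrics$t))
    for (j in 1:2) {
      mc <- tryCatch(mechanical_cost(wss$t, wss[[paste0("swss_base_", j)]],
                                     wss[[paste0("fwss_back_", j)]], win),
                     error = function(e) list(cost = NA_real_))
      costs[j] <- mc$cost
    }
  }

  # equilibrium-phase orifice area: mean over the detected equilibrium
  # window, or over the top quartile of the trace when segmentation failed
  A_equil <- if (!is.null(phases) && phases$t_end[2] > phases$t_start[2]) {
    sel <- metrics$t >= phases$t_start[2] & metrics$t <= phases$t_end[2]
    mean(metrics$A_goa[sel])
  } else mean(metrics$A_goa[metrics$A_goa >= stats::quantile(metrics$A_goa, 0.75)])

  summary <- list(
    case = cfg$case, preset = cfg$preset,
    completed_fraction = nrow(metrics) / nsteps,
    run_error = run_error,
    A_goa_equil = A_equil,
    l_goa_max = max(metrics$l_goa),
    l_goa_max_frac_d0 = max(metrics$l_goa) / geom$d0,
    A_goa_max = max(metrics$A_goa),
    Q_peak = max(metrics$Q_orifice),
    t_Q_peak = metrics$t[which.max(metrics$Q_orifice)],
    v_peak = max(metrics$v_orifice_max),
    forward_volume = vols$forward, reverse_volume = vols$reverse,
    critical_time_pct = vols$critical_time,
    incompetent = if (!is.null(phases)) attr(phases, "incompetent") else NA,
    rotation_final = c(metrics$rot_1[nrow(metrics)],
                       metrics$rot_2[nrow(metrics)]),
    mechanical_cost = costs)

  structure(list(metrics = metrics, wss = wss, phases = phases,
                 volumes = vols, summary = summary, config = cfg),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("valve cycle run:", s$case, "(", s$preset, ")\n")
  cat(sprintf("  peak l_GOA  : %.3f cm (%.1f%% of d0)\n", s$l_goa_max,
              100 * s$l_goa_max_frac_d0))
  cat(sprintf("  peak A_GOA  : %.3f cm^2\n", s$A_goa_max))
  cat(sprintf("  peak Q      : %.2f cm^3/s at %.2f s (peak v %.1f cm/s)\n",
              s$Q_peak, s$t_Q_peak, s$v_peak))
  cat(sprintf("  volumes     : forward %.3f cm^3, reverse %.4f cm^3\n",
              s$forward_volume, s$reverse_volume))
  cat(sprintf("  critical t  : %.0f%% of cycle\n", s$critical_time_pct))
  cat("  incompetent :", s$incompetent, "\n")
  invisible(x)
}

#' Write run outputs to a directory
#'
#' Writes the per-step metrics as CSV, the scalar summary as JSON, the final
#' solid and fluid states as legacy-VTK files, and a manifest with
#' checksums.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @param sim optional simulation object for field snapshots.
#' @return manifest data.frame (file, md5), invisibly.
#' @export
write_outputs <- function(report, dir, sim = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "metrics.csv")
  utils::write.csv(report$metrics, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(report$wss)) {
    f <- file.path(dir, "wss.csv")
    utils::write.csv(report$wss, f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(report$summary, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  if (!is.null(sim)) {
    f <- file.path(dir, "solid_final.vtk")
    n <- sim$smod$n
    coords <- .solid_coords(sim)
    mcur <- sim$vm$mesh; mcur$nodes <- coords
    write_vtk_quad(mcur, f,
                   point_data = list(displacement = cbind(
                     sim$sstate$d[2L * (1:n) - 1L], sim$sstate$d[2L * (1:n)])))
    files <- c(files, f)
    f <- file.path(dir, "fluid_final.vtk")
    write_vtk_quad(sim$fmod$grid, f,
                   point_data = list(velocity = sim$fstate$v,
                                     pressure = sim$fstate$p,
                                     activity = as.numeric(sim$fstate$activity)))
    files <- c(files, f)
  }
  manifest <- data.frame(file = files, md5 = as.vector(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
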