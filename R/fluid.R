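#' Fluid properties of blood
#'
#' Newtonian blood at full hematocrit; the ghost fluid occupying the region
#' covered by the solid carries infinitesimally scaled properties.
#'
#' @param rho_f density (g/cm^3).
#' @param mu_f dynamic viscosity (g/(cm s)); 0.0036 Pa.s = 0.036 poise.
#' @param ghost_scale property scale of the ghost fluid.
#' @return list of class `fluid_props`.
#' @export
fluid_props <- function(rho_f = 1.08, mu_f = 0.036, ghost_scale = 1e-6) {
  stopifnot(rho_f > 0, mu_f > 0, ghost_scale > 0, ghost_scale < 1)
  structure(list(rho_f = rho_f, mu_f = mu_f, ghost_scale = ghost_scale),
            class = "fluid_props")
}

# activity codes
ACT_REAL <- 1L; ACT_GHOST <- 2L; ACT_INACTIVE <- 3L

#' Fluid model on a structured grid
#'
#' Precomputes shape-function data at the 2x2 Gauss points of the uniform
#' rectangular Q1 cells (identical for every element) for the equal-order
#' stabilized solver.
#'
#' @param grid a grid from [build_fluid_grid()].
#' @param props a [fluid_props()].
#' @return object of class `fluid_model`.
#' @export
fluid_model <- function(grid, props = fluid_props()) {
  hx <- attr(grid, "hx"); hy <- attr(grid, "hy")
  xi_I <- c(-1, 1, 1, -1); eta_I <- c(-1, -1, 1, 1)
  a <- 1 / sqrt(3)
  gps <- cbind(c(-a, a, a, -a), c(-a, -a, a, a))
  shp <- vector("list", 4L)
  for (g in 1:4) {
    xi <- gps[g, 1]; eta <- gps[g, 2]
    Nv <- 0.25 * (1 + xi * xi_I) * (1 + eta * eta_I)
    dNdx <- 0.25 * xi_I * (1 + eta * eta_I) * 2 / hx
    dNdy <- 0.25 * eta_I * (1 + xi * xi_I) * 2 / hy
    shp[[g]] <- list(N = Nv, dNdx = dNdx, dNdy = dNdy, w = hx * hy / 4,
                     loc = c(xi, eta))
  }
  n <- nrow(grid$nodes)
  structure(list(grid = grid, props = props, shp = shp, n = n,
                 nx = attr(grid, "nx"), ny = attr(grid, "ny"),
                 hx = hx, hy = hy, h = sqrt(hx * hy),
                 bnodes = fluid_boundary_nodes(grid)),
            class = "fluid_model")
}

#' Initial fluid state
#'
#' @param model a [fluid_model()].
#' @return list of class `fluid_state`: nodal velocity `v` (n x 2), pressure
#'   `p`, previous velocity `v_prev`, per-node mixture `rho`, `mu`, activity
#'   labels, time `t`.
#' @export
fluid_state <- function(model) {
  n <- model$n
  structure(list(v = matrix(0, n, 2L), v_prev = matrix(0, n, 2L),
                 p = numeric(n),
                 rho = rep(model$props$rho_f, n),
                 mu = rep(model$props$mu_f, n),
                 activity = rep(ACT_REAL, n), t = 0),
            class = "fluid_state")
}

#' Mixture density and viscosity fields from activity labels
#'
#' Real nodes carry the blood properties; ghost and inactive nodes the
#' ghost-scaled values.
#'
#' @param activity integer labels (1 real, 2 ghost, 3 inactive).
#' @param props a [fluid_props()].
#' @return list with `rho` and `mu` nodal vectors.
#' @export
update_mixture_properties <- function(activity, props) {
  sc <- ifelse(activity == ACT_REAL, 1, props$ghost_scale)
  list(rho = props$rho_f * sc, mu = props$mu_f * sc)
}

#' Stabilization parameters
#'
#' Element SUPG/PSPG time-space-diffusion blended parameter
#' `tau = ((2/dt)^2 + (2|v|/h)^2 + (4 nu/h^2)^2)^(-1/2)` and the grad-div
#' (LSIC) coefficient `tau_lsic = rho h^2 / (4 tau)`.
#'
#' @param h element size (cm).
#' @param vmag advective speed (cm/s).
#' @param rho,mu element density and viscosity.
#' @param dt time step (s); `Inf` drops the transient contribution.
#' @return list with `tau_supg`, `tau_pspg`, `tau_lsic` (vectorized).
#' @export
stabilization_taus <- function(h, vmag, rho, mu, dt) {
  nu <- mu / rho
  t1 <- if (is.finite(dt)) (2 / dt)^2 else 0
  tau <- 1 / sqrt(t1 + (2 * vmag / h)^2 + (4 * nu / h^2)^2)
  list(tau_supg = tau, tau_pspg = tau, tau_lsic = rho * h^2 / (4 * tau))
}

#' Boundary condition set for the fluid solver
#'
#' @param dirichlet data.frame with columns `node`, `comp` (1 = u, 2 = v,
#'   3 = p), `value`.
#' @param traction optional data.frame with columns `n1`, `n2` (edge node
#'   ids), `tx`, `ty` (traction components, dyn/cm^2): integrated into the
#'   momentum right-hand side with linear edge quadrature.
#' @return list of class `fluid_bc`.
#' @export
fluid_bc <- function(dirichlet = NULL, traction = NULL) {
  if (is.null(dirichlet))
    dirichlet <- data.frame(node = integer(0), comp = integer(0),
                            value = numeric(0))
  du <- dirichlet[!duplicated(dirichlet[c("node", "comp")]), , drop = FALSE]
  if (nrow(du) != nrow(dirichlet)) {
    chk <- stats::aggregate(value ~ node + comp, dirichlet,
                            function(v) max(v) - min(v))
    if (any(chk$value > 1e-10))
      stop("configuration error: conflicting Dirichlet values at a node")
  }
  structure(list(dirichlet = du, traction = traction), class = "fluid_bc")
}

# assemble the stabilized Q1Q1 system; returns triplets and rhs.
# advection `adv` is the nodal advection field (n x 2); theta the
# Crank-Nicolson weight on the Galerkin convection/diffusion terms.
assemble_ns_system <- function(model, state, dt, theta = 0.5, adv = NULL,
                               body_force = NULL, active_elems = NULL) {
  grid <- model$grid; el <- grid$elems
  if (is.null(active_elems)) active_elems <- seq_len(nrow(el))
  el <- el[active_elems, , drop = FALSE]
  E <- nrow(el); n <- model$n
  if (is.null(adv)) adv <- state$v

  un <- matrix(state$v[el, 1L], ncol = 4L)
  vn <- matrix(state$v[el, 2L], ncol = 4L)
  a1 <- matrix(adv[el, 1L], ncol = 4L)
  a2 <- matrix(adv[el, 2L], ncol = 4L)
  rho_e <- rowMeans(matrix(state$rho[el], ncol = 4L))
  mu_e <- rowMeans(matrix(state$mu[el], ncol = 4L))

  amag <- sqrt(rowMeans(a1)^2 + rowMeans(a2)^2)
  taus <- stabilization_taus(model$h, amag, rho_e, mu_e, dt)
  tau <- taus$tau_supg; tlsic <- taus$tau_lsic

  zero_blk <- function() matrix(0, E, 16L)
  Auu <- zero_blk(); Auv <- zero_blk(); Avu <- zero_blk(); Avv <- zero_blk()
  Aup <- zero_blk(); Avp <- zero_blk(); Apu <- zero_blk(); Apv <- zero_blk()
  App <- zero_blk()
  ru <- matrix(0, E, 4L); rv <- matrix(0, E, 4L); rp <- matrix(0, E, 4L)
  idt <- if (is.finite(dt)) 1 / dt else 0

  # gauss-point coordinates needed only when a body force is given
  if (!is.null(body_force)) {
    ex <- matrix(grid$nodes[el, 1L], ncol = 4L)
    ey <- matrix(grid$nodes[el, 2L], ncol = 4L)
  }

  for (g in 1:4) {
    s <- model$shp[[g]]
    N <- s$N; dNx <- s$dNdx; dNy <- s$dNdy; w <- s$w
    a1g <- as.vector(a1 %*% N); a2g <- as.vector(a2 %*% N)
    ung <- as.vector(un %*% N); vng <- as.vector(vn %*% N)
    # strong-residual test weights
    sc <- lapply(1:4, function(I) a1g * dNx[I] + a2g * dNy[I])
    adv_n <- lapply(1:4, function(J) a1g * dNx[J] + a2g * dNy[J])
    un_x <- as.vector(un %*% dNx); un_y <- as.vector(un %*% dNy)
    vn_x <- as.vector(vn %*% dNx); vn_y <- as.vector(vn %*% dNy)
    conv_un <- a1g * un_x + a2g * un_y     # (a . grad) u^n at gp
    conv_vn <- a1g * vn_x + a2g * vn_y

    if (!is.null(body_force)) {
      xg <- as.vector(ex %*% N); yg <- as.vector(ey %*% N)
      tf <- if (is.finite(dt)) state$t + theta * dt else state$t
      bf <- body_force(xg, yg, tf)
      f1 <- bf[, 1]; f2 <- bf[, 2]
    } else f1 <- f2 <- NULL

    for (I in 1:4) {
      scI <- sc[[I]]
      for (J in 1:4) {
        k <- (J - 1L) * 4L + I
        m_ij <- w * rho_e * N[I] * N[J]
        ms_ij <- w * tau * rho_e * scI * N[J]
        c_ij <- w * rho_e * N[I] * adv_n[[J]]
        ks_ij <- w * tau * rho_e * scI * adv_n[[J]]
        kxx <- w * mu_e * (2 * dNx[I] * dNx[J] + dNy[I] * dNy[J])
        kxy <- w * mu_e * (dNy[I] * dNx[J])
        kyx <- w * mu_e * (dNx[I] * dNy[J])
        kyy <- w * mu_e * (dNx[I] * dNx[J] + 2 * dNy[I] * dNy[J])
        lxx <- w * tlsic * dNx[I] * dNx[J]
        lxy <- w * tlsic * dNx[I] * dNy[J]
        lyx <- w * tlsic * dNy[I] * dNx[J]
        lyy <- w * tlsic * dNy[I] * dNy[J]

        Auu[, k] <- Auu[, k] + (m_ij + ms_ij) * idt + theta * (c_ij + kxx) +
          ks_ij + lxx
        Auv[, k] <- Auv[, k] + theta * kxy + lxy
        Avu[, k] <- Avu[, k] + theta * kyx + lyx
        Avv[, k] <- Avv[, k] + (m_ij + ms_ij) * idt + theta * (c_ij + kyy) +
          ks_ij + lyy
        Aup[, k] <- Aup[, k] + w * (-dNx[I] * N[J] + tau * scI * dNx[J])
        Avp[, k] <- Avp[, k] + w * (-dNy[I] * N[J] + tau * scI * dNy[J])
        Apu[, k] <- Apu[, k] + w * (N[I] * dNx[J] +
          tau * rho_e * dNx[I] * (N[J] * idt + adv_n[[J]]))
        Apv[, k] <- Apv[, k] + w * (N[I] * dNy[J] +
          tau * rho_e * dNy[I] * (N[J] * idt + adv_n[[J]]))
        App[, k] <- App[, k] + w * tau * (dNx[I] * dNx[J] + dNy[I] * dNy[J])
      }
      # right-hand side: transient history + explicit theta part + forcing
      ru[, I] <- ru[, I] + w * (rho_e * N[I] * ung * idt +
        tau * rho_e * scI * ung * idt -
        (1 - theta) * rho_e * N[I] * conv_un -
        (1 - theta) * mu_e * (2 * dNx[I] * un_x + dNy[I] * (un_y + vn_x)))
      rv[, I] <- rv[, I] + w * (rho_e * N[I] * vng * idt +
        tau * rho_e * scI * vng * idt -
        (1 - theta) * rho_e * N[I] * conv_vn -
        (1 - theta) * mu_e * (dNx[I] * (vn_x + un_y) + 2 * dNy[I] * vn_y))
      rp[, I] <- rp[, I] + w * tau * rho_e *
        (dNx[I] * ung + dNy[I] * vng) * idt
      if (!is.null(f1)) {
        ru[, I] <- ru[, I] + w * rho_e * (N[I] + tau * scI) * f1
        rv[, I] <- rv[, I] + w * rho_e * (N[I] + tau * scI) * f2
        rp[, I] <- rp[, I] + w * tau * rho_e *
          (dNx[I] * f1 + dNy[I] * f2)
      }
    }
  }

  # triplets: dof layout u: 1..n, v: n+1..2n, p: 2n+1..3n
  II <- el[, rep(1:4, times = 4L)]
  JJ <- el[, rep(1:4, each = 4L)]
  iv <- c(II, II, II, II + n, II + n, II + n, II + 2L * n, II + 2L * n, II + 2L * n)
  jv <- c(JJ, JJ + n, JJ + 2L * n, JJ, JJ + n, JJ + 2L * n, JJ, JJ + n, JJ + 2L * n)
  xv <- c(Auu, Auv, Aup, Avu, Avv, Avp, Apu, Apv, App)

  rhs <- numeric(3L * n)
  ridx <- c(el, el + n, el + 2L * n)
  agg <- rowsum(c(ru, rv, rp), ridx)
  rhs[as.integer(rownames(agg))] <- agg[, 1]

  list(i = as.vector(iv), j = as.vector(jv), x = as.vector(xv), rhs = rhs,
       n = n, active_nodes = sort(unique(as.vector(el))))
}

#' Discrete stabilized Navier-Stokes residuals
#'
#' Steady-form momentum and continuity residuals (including the SUPG, PSPG
#' and LSIC terms) at a given state, assembled over active elements only.
#' Used by the verification harness; the time-stepping path shares the same
#' element integrals.
#'
#' @param model a [fluid_model()].
#' @param state a [fluid_state()] carrying the velocity/pressure to test.
#' @param bc a [fluid_bc()]; Dirichlet rows are zeroed in the residual.
#' @param body_force optional function `(x, y, t)` returning a matrix with
#'   two columns (acceleration, cm/s^2).
#' @param active_elems optional element subset.
#' @return list with `r_v` (momentum residual, length 2n) and `r_p`
#'   (continuity residual, length n).
#' @export
assemble_residuals <- function(model, state, bc = fluid_bc(),
                               body_force = NULL, active_elems = NULL) {
  sys <- assemble_ns_system(model, state, dt = Inf, theta = 1,
                            adv = state$v, body_force = body_force,
                            active_elems = active_elems)
  n <- model$n
  A <- Matrix::sparseMatrix(i = sys$i, j = sys$j, x = sys$x,
                            dims = c(3L * n, 3L * n))
  x <- c(state$v[, 1], state$v[, 2], state$p)
  rhs <- sys$rhs
  if (!is.null(bc$traction)) rhs <- rhs + .traction_rhs(model, bc$traction)
  r <- as.vector(A %*% x) - rhs
  if (nrow(bc$dirichlet)) {
    rows <- (bc$dirichlet$comp - 1L) * n + bc$dirichlet$node
    r[rows] <- 0
  }
  list(r_v = r[1:(2L * n)], r_p = r[(2L * n + 1L):(3L * n)])
}

# integrate edge tractions into the momentum rhs (linear edges)
.traction_rhs <- function(model, tr) {
  n <- model$n
  rhs <- numeric(3L * n)
  nd <- model$grid$nodes
  len <- sqrt((nd[tr$n1, 1] - nd[tr$n2, 1])^2 + (nd[tr$n1, 2] - nd[tr$n2, 2])^2)
  add <- function(nodes, vals) {
    agg <- rowsum(vals, nodes)
    idx <- as.integer(rownames(agg))
    rhs[idx] <<- rhs[idx] + agg[, 1]
  }
  add(c(tr$n1, tr$n2), c(tr$tx * len / 2, tr$tx * len / 2))
  add(c(tr$n1 + n, tr$n2 + n), c(tr$ty * len / 2, tr$ty * len / 2))
  rhs
}

#' Advance the fluid one time step
#'
#' Semi-implicit stabilized step: Crank-Nicolson Galerkin convection and
#' diffusion with the advection velocity extrapolated from previous steps
#' (`2 v^n - v^{n-1}`, or `v^n` in robust mode), implicit pressure, and
#' fully implicit SUPG/PSPG/LSIC stabilization; one sparse direct solve per
#' step.
#'
#' @param model a [fluid_model()].
#' @param state a [fluid_state()].
#' @param bc a [fluid_bc()].
#' @param dt time step (s).
#' @param theta Crank-Nicolson weight (0.5 second order, 1 backward Euler).
#' @param extrapolate use second-order advection extrapolation.
#' @param body_force optional `(x, y, t)` acceleration function.
#' @param active_elems optional active-element subset (immersed runs).
#' @param cfl_warn warn when the convective CFL exceeds this value.
#' @return updated `fluid_state`; attributes `cfl` and `div_norm` carry the
#'   step's convective CFL and the discrete divergence norm on real nodes.
#' @export
solve_ns_step <- function(model, state, bc, dt, theta = 0.5,
                          extrapolate = TRUE, body_force = NULL,
                          active_elems = NULL, cfl_warn = Inf) {
  n <- model$n
  # extrapolate the advection field to t^n + theta*dt, the time level at
  # which the theta-averaged convection term is evaluated
  adv <- if (extrapolate) (1 + theta) * state$v - theta * state$v_prev
         else state$v
  cfl <- max(abs(adv)) * dt / min(model$hx, model$hy)
  if (cfl > cfl_warn)
    warning("convective CFL ", signif(cfl, 3), " exceeds ", cfl_warn,
            call. = FALSE)
  sys <- assemble_ns_system(model, state, dt = dt, theta = theta, adv = adv,
                            body_force = body_force,
                            active_elems = active_elems)
  rhs <- sys$rhs
  if (!is.null(bc$traction)) rhs <- rhs + .traction_rhs(model, bc$traction)

  # Dirichlet rows + identity rows for nodes outside the active system;
  # orphaned nodes keep their previous values so that re-activated regions
  # re-enter with a continuous state (pinning them to zero drags a spurious
  # pressure depression along with a moving interface)
  drows <- (bc$dirichlet$comp - 1L) * n + bc$dirichlet$node
  dvals <- bc$dirichlet$value
  orphan <- setdiff(seq_len(n), sys$active_nodes)
  if (length(orphan)) {
    orows <- c(orphan, orphan + n, orphan + 2L * n)
    ovals <- c(state$v[orphan, 1], state$v[orphan, 2], state$p[orphan])
    keep_o <- !(orows %in% drows)
    drows <- c(drows, orows[keep_o]); dvals <- c(dvals, ovals[keep_o])
  }
  # eliminate Dirichlet dofs and solve the reduced system
  isdir <- logical(3L * n); isdir[drows] <- TRUE
  xfull <- numeric(3L * n); xfull[drows] <- dvals
  keep_fd <- !isdir[sys$i] & isdir[sys$j]
  if (any(keep_fd)) {
    mov <- rowsum(sys$x[keep_fd] * xfull[sys$j[keep_fd]], sys$i[keep_fd])
    ii <- as.integer(rownames(mov))
    rhs[ii] <- rhs[ii] - mov[, 1]
  }
  free <- which(!isdir)
  remap <- integer(3L * n); remap[free] <- seq_along(free)
  keep <- !isdir[sys$i] & !isdir[sys$j]
  A <- Matrix::sparseMatrix(i = remap[sys$i[keep]], j = remap[sys$j[keep]],
                            x = sys$x[keep],
                            dims = c(length(free), length(free)))
  sol_f <- as.vector(Matrix::solve(A, rhs[free]))
  xfull[free] <- sol_f
  sol <- xfull

  new <- state
  new$v_prev <- state$v
  new$v <- cbind(sol[1:n], sol[(n + 1L):(2L * n)])
  new$p <- sol[(2L * n + 1L):(3L * n)]
  new$t <- state$t + dt
  attr(new, "cfl") <- cfl
  attr(new, "div_norm") <- fluid_divergence_norm(model, new, active_elems)
  new
}

#' Steady stabilized Navier-Stokes solve (Picard)
#'
#' Fixed-point iteration on the advection field with the transient terms
#' dropped; used by the steady benchmarks (Poiseuille, lid-driven cavity).
#'
#' @param model a [fluid_model()].
#' @param bc a [fluid_bc()].
#' @param max_iter Picard iterations.
#' @param tol relative velocity-update tolerance.
#' @param relax under-relaxation factor on the advection update.
#' @param pin_pressure optional node id given reference pressure 0.
#' @return converged `fluid_state`; attribute `picard_iters`.
#' @export
fluid_steady_solve <- function(model, bc, max_iter = 40L, tol = 1e-8,
                               relax = 1.0, pin_pressure = NULL) {
  n <- model$n
  st <- fluid_state(model)
  dir <- bc$dirichlet
  if (!is.null(pin_pressure))
    dir <- rbind(dir, data.frame(node = pin_pressure, comp = 3L, value = 0))
  adv <- st$v
  iters <- 0L
  for (it in seq_len(max_iter)) {
    sys <- assemble_ns_system(model, st, dt = Inf, theta = 1, adv = adv)
    rhs <- sys$rhs
    if (!is.null(bc$traction)) rhs <- rhs + .traction_rhs(model, bc$traction)
    drows <- (dir$comp - 1L) * n + dir$node
    isdir <- logical(3L * n); isdir[drows] <- TRUE
    keep <- !isdir[sys$i]
    A <- Matrix::sparseMatrix(i = c(sys$i[keep], drows),
                              j = c(sys$j[keep], drows),
                              x = c(sys$x[keep], rep(1, length(drows))),
                              dims = c(3L * n, 3L * n))
    rhs[drows] <- dir$value
    sol <- as.vector(Matrix::solve(A, rhs))
    vnew <- cbind(sol[1:n], sol[(n + 1L):(2L * n)])
    dv <- max(abs(vnew - adv)) / max(max(abs(vnew)), 1e-12)
    st$v <- vnew; st$p <- sol[(2L * n + 1L):(3L * n)]
    adv <- relax * vnew + (1 - relax) * adv
    iters <- it
    if (dv < tol) break
  }
  attr(st, "picard_iters") <- iters
  st
}

#' Discrete divergence norm over real nodes
#'
#' RMS of the element-centre velocity divergence over elements whose nodes
#' are all real.
#'
#' @param model a [fluid_model()].
#' @param state a [fluid_state()].
#' @param active_elems optional subset.
#' @return scalar (1/s).
#' @export
fluid_divergence_norm <- function(model, state, active_elems = NULL) {
  el <- model$grid$elems
  if (!is.null(active_elems)) el <- el[active_elems, , drop = FALSE]
  allreal <- matrix(state$activity[el] == ACT_REAL, ncol = 4L)
  el <- el[rowSums(allreal) == 4L, , drop = FALSE]
  if (!nrow(el)) return(0)
  un <- matrix(state$v[el, 1L], ncol = 4L)
  vn <- matrix(state$v[el, 2L], ncol = 4L)
  # centre-point derivatives on the uniform cell
  dNx <- c(-1, 1, 1, -1) / (2 * model$hx)
  dNy <- c(-1, -1, 1, 1) / (2 * model$hy)
  div <- as.vector(un %*% dNx + vn %*% dNy)
  sqrt(mean(div^2))
}

#' Standard boundary conditions for channel-like runs
#'
#' Builds the [fluid_bc()] for the vein scenario and the channel benchmarks:
#' lateral boundaries clamped in velocity and pressure, inlet driven by a
#' normal traction (pressure), outlet at zero reference traction, optional
#' no-slip node set.
#'
#' @param model a [fluid_model()].
#' @param p_in inlet pressure (dyn/cm^2).
#' @param noslip_nodes extra nodes with zero velocity.
#' @param lateral_mode "clamp" (velocity and pressure zero) or "noslip"
#'   (velocity only).
#' @param ghost data.frame `node`, `u`, `v` of interface Dirichlet values.
#' @param inlet_range optional y-range: the inlet traction is applied only to
#'   inlet edges inside it (the luminal segment of an immersed vessel).
#' @return a [fluid_bc()].
#' @export
channel_bc <- function(model, p_in, noslip_nodes = integer(0),
                       lateral_mode = c("clamp", "noslip"), ghost = NULL,
                       inlet_range = NULL) {
  lateral_mode <- match.arg(lateral_mode)
  b <- model$bnodes
  lat <- setdiff(b$lateral, integer(0))
  dir <- data.frame(node = integer(0), comp = integer(0), value = numeric(0))
  # interface (ghost) values first: they take precedence on duplicates
  if (!is.null(ghost) && nrow(ghost))
    dir <- rbind(dir,
                 data.frame(node = rep(ghost$node, 2L),
                            comp = rep(c(1L, 2L), each = nrow(ghost)),
                            value = c(ghost$u, ghost$v)))
  dir <- rbind(dir, data.frame(node = rep(lat, 2L),
                               comp = rep(c(1L, 2L), each = length(lat)),
                               value = 0))
  if (lateral_mode == "clamp")
    dir <- rbind(dir, data.frame(node = lat, comp = 3L, value = 0))
  if (length(noslip_nodes))
    dir <- rbind(dir, data.frame(node = rep(noslip_nodes, 2L),
                                 comp = rep(c(1L, 2L), each = length(noslip_nodes)),
                                 value = 0))
  tr <- NULL
  if (!is.null(p_in) && p_in != 0) {
    inl <- sort(b$inlet)
    tr <- data.frame(n1 = inl[-length(inl)], n2 = inl[-1],
                     tx = p_in, ty = 0)
    if (!is.null(inlet_range)) {
      ymid <- (model$grid$nodes[tr$n1, 2] + model$grid$nodes[tr$n2, 2]) / 2
      tr <- tr[ymid >= inlet_range[1] & ymid <= inlet_range[2], , drop = FALSE]
    }
  }
  # first Dirichlet wins on duplicates (interface values take precedence if
  # given first); drop later duplicates silently
  dir <- dir[!duplicated(dir[c("node", "comp")]), , drop = FALSE]
  fluid_bc(dirichlet = dir, traction = tr)
}
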