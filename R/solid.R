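#' Solid finite element model
#'
#' Precomputes reference-configuration quantities for a total-Lagrangian Q1
#' quadrilateral discretization under plane strain: shape-function gradients
#' and integration weights at the 2x2 Gauss points (isochoric part) and at
#' the element center (volumetric penalty, selectively reduced to avoid
#' volumetric locking). Materials are assigned per part tag.
#'
#' @param mesh a `quad_mesh` (reference configuration).
#' @param materials named list mapping part tags to tissue materials.
#' @param fixed_nodes integer node ids with prescribed (zero by default)
#'   displacement.
#' @param kappa_factor volumetric penalty as a multiple of each material's
#'   reference shear modulus.
#' @return object of class `solid_model`.
#' @export
solid_model <- function(mesh, materials, fixed_nodes = integer(0),
                        kappa_factor = 100) {
  el <- mesh$elems; nd <- mesh$nodes
  E <- nrow(el); n <- nrow(nd)
  xi_I <- c(-1, 1, 1, -1); eta_I <- c(-1, -1, 1, 1)
  a <- 1 / sqrt(3)
  gp <- rbind(cbind(c(-a, a, a, -a), c(-a, -a, a, a)), c(0, 0))
  wg <- c(1, 1, 1, 1, 4)

  X <- matrix(nd[el, 1L], ncol = 4L); Y <- matrix(nd[el, 2L], ncol = 4L)
  shp <- vector("list", 5L)
  for (g in 1:5) {
    xi <- gp[g, 1]; eta <- gp[g, 2]
    Nv <- 0.25 * (1 + xi * xi_I) * (1 + eta * eta_I)
    dNdxi <- 0.25 * xi_I * (1 + eta * eta_I)
    dNdeta <- 0.25 * eta_I * (1 + xi * xi_I)
    dxdxi <- X %*% dNdxi; dxdeta <- X %*% dNdeta
    dydxi <- Y %*% dNdxi; dydeta <- Y %*% dNdeta
    detJ <- as.vector(dxdxi * dydeta - dxdeta * dydxi)
    if (any(detJ <= 0)) stop("assembly error: singular element Jacobian")
    # dN/dX = J^{-T} dN/dxi
    dNdX <- matrix(0, E, 4L); dNdY <- matrix(0, E, 4L)
    for (I in 1:4) {
      dNdX[, I] <- (dydeta * dNdxi[I] - dydxi * dNdeta[I]) / detJ
      dNdY[, I] <- (-dxdeta * dNdxi[I] + dxdxi * dNdeta[I]) / detJ
    }
    shp[[g]] <- list(N = Nv, dNdX = dNdX, dNdY = dNdY, w = wg[g] * detJ)
  }

  # per-element material coefficient vectors (CGS)
  miss <- setdiff(unique(mesh$part), names(materials))
  if (length(miss)) stop("no material assigned to part(s): ",
                         paste(miss, collapse = ", "))
  is_exp <- logical(E); c3v <- c5v <- c0v <- c1v <- mubv <- rhov <- kapv <- numeric(E)
  for (p in unique(mesh$part)) {
    m <- materials[[p]]; idx <- mesh$part == p
    rhov[idx] <- m$rho_s
    kapv[idx] <- kappa_factor * kpa_to_cgs(reference_shear_modulus(m))
    if (m$type == "poly") {
      c3v[idx] <- kpa_to_cgs(m$c3); c5v[idx] <- kpa_to_cgs(m$c5)
    } else {
      is_exp[idx] <- TRUE
      c0v[idx] <- kpa_to_cgs(m$c0); c1v[idx] <- m$c1_exp
      mubv[idx] <- kpa_to_cgs(m$mu_baseline)
    }
  }

  dof <- matrix(0L, E, 8L)  # columns: (I=1..4) x, then (I=1..4) y
  for (I in 1:4) {
    dof[, I] <- 2L * (el[, I] - 1L) + 1L
    dof[, I + 4L] <- 2L * el[, I]
  }
  fixed_dofs <- sort(unique(c(2L * (fixed_nodes - 1L) + 1L, 2L * fixed_nodes)))

  structure(list(mesh = mesh, n = n, E = E, shp = shp, dof = dof,
                 coef = list(is_exp = is_exp, c3 = c3v, c5 = c5v, c0 = c0v,
                             c1 = c1v, mub = mubv, rho = rhov, kap = kapv),
                 fixed_nodes = fixed_nodes, fixed_dofs = fixed_dofs,
                 materials = materials, kappa_factor = kappa_factor),
            class = "solid_model")
}

# vectorized W'(I1b) and W''(I1b) in CGS over elements
.solid_Wp <- function(I1b, cf) {
  x <- I1b - 3
  ex <- exp(pmin(cf$c1 * x^2, 400))
  ifelse(cf$is_exp, cf$c0 * ex * 2 * cf$c1 * x + cf$mub / 2, cf$c3 + 2 * cf$c5 * x)
}
.solid_Wpp <- function(I1b, cf) {
  x <- I1b - 3
  ex <- exp(pmin(cf$c1 * x^2, 400))
  ifelse(cf$is_exp, cf$c0 * ex * (2 * cf$c1 + (2 * cf$c1 * x)^2), 2 * cf$c5)
}

# cheap validity check: minimum det F over all integration points
solid_min_J <- function(model, d) {
  el <- model$mesh$elems
  dx <- matrix(d[2L * (el - 1L) + 1L], ncol = 4L)
  dy <- matrix(d[2L * el], ncol = 4L)
  mj <- Inf
  for (g in 1:5) {
    Fc <- .solid_F_at(model, g, dx, dy)
    mj <- min(mj, Fc$F11 * Fc$F22 - Fc$F12 * Fc$F21)
  }
  mj
}

# deformation gradient components at one integration point
.solid_F_at <- function(model, g, dx, dy) {
  s <- model$shp[[g]]
  list(F11 = 1 + rowSums(dx * s$dNdX), F12 = rowSums(dx * s$dNdY),
       F21 = rowSums(dy * s$dNdX), F22 = 1 + rowSums(dy * s$dNdY))
}

#' Assemble internal force and tangent stiffness
#'
#' Total-Lagrangian assembly of the nodal internal force
#' `f_int = int P : grad_X N dV` and the consistent material tangent
#' `K = d f_int / d d` for the nearly incompressible plane-strain energy
#' `W(I1_bar) + kappa/2 (J-1)^2` (isochoric part at 2x2 Gauss points,
#' penalty at the element center).
#'
#' @param model a [solid_model()].
#' @param d nodal displacement vector (length 2n, x/y interleaved).
#' @param tangent logical; also assemble the tangent matrix.
#' @return list with `f_int` (numeric) and, if requested, `K`
#'   (a `dgCMatrix`).
#' @export
solid_assemble <- function(model, d, tangent = TRUE) {
  E <- model$E; cf <- model$coef
  el <- model$mesh$elems
  dx <- matrix(d[2L * (el - 1L) + 1L], ncol = 4L)
  dy <- matrix(d[2L * el], ncol = 4L)
  fe <- matrix(0, E, 8L)
  Ke <- if (tangent) matrix(0, E, 64L) else NULL

  for (g in 1:5) {
    s <- model$shp[[g]]
    Fc <- .solid_F_at(model, g, dx, dy)
    F11 <- Fc$F11; F12 <- Fc$F12; F21 <- Fc$F21; F22 <- Fc$F22
    J <- F11 * F22 - F12 * F21
    if (any(J <= 0.01)) stop("element failure: (near-)inverted element (element ",
                             which(J <= 0.01)[1], ")")
    G11 <- F22 / J; G12 <- -F21 / J; G21 <- -F12 / J; G22 <- F11 / J
    w <- s$w

    if (g <= 4L) {
      # isochoric contribution
      Tt <- F11^2 + F12^2 + F21^2 + F22^2
      I1b <- Tt / J + 1
      Wp <- .solid_Wp(I1b, cf); cc <- 2 * Wp / J
      D11 <- F11 - Tt / 2 * G11; D12 <- F12 - Tt / 2 * G12
      D21 <- F21 - Tt / 2 * G21; D22 <- F22 - Tt / 2 * G22
      P11 <- cc * D11; P12 <- cc * D12; P21 <- cc * D21; P22 <- cc * D22
      for (I in 1:4) {
        fe[, I]      <- fe[, I]      + w * (P11 * s$dNdX[, I] + P12 * s$dNdY[, I])
        fe[, I + 4L] <- fe[, I + 4L] + w * (P21 * s$dNdX[, I] + P22 * s$dNdY[, I])
      }
      if (tangent) {
        Wpp <- .solid_Wpp(I1b, cf)
        Fm <- list(`11` = F11, `12` = F12, `21` = F21, `22` = F22)
        Gm <- list(`11` = G11, `12` = G12, `21` = G21, `22` = G22)
        Dm <- list(`11` = D11, `12` = D12, `21` = D21, `22` = D22)
        # dc[kL] = (2 Wpp / J)(2 F[kL]/J - (T/J) G[kL]) - (2 Wp / J) G[kL]
        dc <- list()
        for (k in 1:2) for (L in 1:2) {
          kl <- paste0(k, L)
          dc[[kl]] <- (2 * Wpp / J) * (2 * Fm[[kl]] / J - (Tt / J) * Gm[[kl]]) -
            cc * Gm[[kl]]
        }
        A <- array(list(), dim = c(2, 2, 2, 2))
        for (i in 1:2) for (Jj in 1:2) for (k in 1:2) for (L in 1:2) {
          v <- dc[[paste0(k, L)]] * Dm[[paste0(i, Jj)]] +
            cc * ((i == k) * (Jj == L) -
                    Fm[[paste0(k, L)]] * Gm[[paste0(i, Jj)]] +
                    (Tt / 2) * Gm[[paste0(i, L)]] * Gm[[paste0(k, Jj)]])
          A[[i, Jj, k, L]] <- v
        }
        Ke <- Ke + .solid_K_accum(A, s, w)
      }
    } else {
      # volumetric penalty, single point
      kap <- cf$kap
      cJ <- kap * J * (J - 1)
      P11 <- cJ * G11; P12 <- cJ * G12; P21 <- cJ * G21; P22 <- cJ * G22
      for (I in 1:4) {
        fe[, I]      <- fe[, I]      + w * (P11 * s$dNdX[, I] + P12 * s$dNdY[, I])
        fe[, I + 4L] <- fe[, I + 4L] + w * (P21 * s$dNdX[, I] + P22 * s$dNdY[, I])
      }
      if (tangent) {
        Gm <- list(`11` = G11, `12` = G12, `21` = G21, `22` = G22)
        A <- array(list(), dim = c(2, 2, 2, 2))
        for (i in 1:2) for (Jj in 1:2) for (k in 1:2) for (L in 1:2) {
          v <- kap * (2 * J - 1) * J * Gm[[paste0(k, L)]] * Gm[[paste0(i, Jj)]] -
            cJ * Gm[[paste0(i, L)]] * Gm[[paste0(k, Jj)]]
          A[[i, Jj, k, L]] <- v
        }
        Ke <- Ke + .solid_K_accum(A, s, w)
      }
    }
  }

  ndof <- 2L * model$n
  idx <- as.vector(model$dof)
  f <- numeric(ndof)
  agg <- rowsum(as.vector(fe), idx)
  f[as.integer(rownames(agg))] <- agg[, 1]

  out <- list(f_int = f)
  if (tangent) {
    ii <- model$dof[, rep(1:8, times = 8L)]
    jj <- model$dof[, rep(1:8, each = 8L)]
    out$K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                                  x = as.vector(Ke), dims = c(ndof, ndof))
  }
  out
}

# accumulate element stiffness contributions w * dN_I,J A[iJkL] dN_K,L into
# the E x 64 layout (column = (row dof a = I + 4(i-1), col dof b = K + 4(k-1))
# -> 8*(b-1)+a)
.solid_K_accum <- function(A, s, w) {
  E <- length(w)
  Ke <- matrix(0, E, 64L)
  dN <- list(s$dNdX, s$dNdY)  # index by J (1 = d/dX, 2 = d/dY)
  for (i in 1:2) for (k in 1:2) {
    # B[IK] = sum_{J,L} dN_I,J A[iJkL] dN_K,L
    for (I in 1:4) {
      tI1 <- dN[[1]][, I]; tI2 <- dN[[2]][, I]
      for (K in 1:4) {
        tK1 <- dN[[1]][, K]; tK2 <- dN[[2]][, K]
        v <- tI1 * (A[[i, 1, k, 1]] * tK1 + A[[i, 1, k, 2]] * tK2) +
             tI2 * (A[[i, 2, k, 1]] * tK1 + A[[i, 2, k, 2]] * tK2)
        a <- I + 4L * (i - 1L); b <- K + 4L * (k - 1L)
        Ke[, 8L * (b - 1L) + a] <- Ke[, 8L * (b - 1L) + a] + w * v
      }
    }
  }
  Ke
}

#' Consistent mass matrix
#'
#' `M_IJ = int N_I rho_s N_J dV` with 2x2 Gauss quadrature; identical blocks
#' for both displacement components.
#'
#' @param model a [solid_model()].
#' @return sparse symmetric mass matrix (2n x 2n).
#' @export
solid_mass_matrix <- function(model) {
  E <- model$E; rho <- model$coef$rho
  Me <- matrix(0, E, 64L)
  for (g in 1:4) {
    s <- model$shp[[g]]
    for (I in 1:4) for (K in 1:4) {
      v <- s$w * rho * s$N[I] * s$N[K]
      for (i in 1:2) {
        a <- I + 4L * (i - 1L); b <- K + 4L * (i - 1L)
        Me[, 8L * (b - 1L) + a] <- Me[, 8L * (b - 1L) + a] + v
      }
    }
  }
  ii <- model$dof[, rep(1:8, times = 8L)]
  jj <- model$dof[, rep(1:8, each = 8L)]
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                       x = as.vector(Me), dims = c(2L * model$n, 2L * model$n))
}

#' Cauchy stress at element integration points
#'
#' @param model a [solid_model()].
#' @param d displacement vector.
#' @return list with `gauss` (E x 4 x 3 array of s11, s22, s12 at the 2x2
#'   points, dyn/cm^2), `J` (E x 4).
#' @export
solid_element_stress <- function(model, d) {
  E <- model$E; cf <- model$coef
  el <- model$mesh$elems
  dx <- matrix(d[2L * (el - 1L) + 1L], ncol = 4L)
  dy <- matrix(d[2L * el], ncol = 4L)
  sig <- array(0, dim = c(E, 4L, 3L)); Jout <- matrix(0, E, 4L)
  for (g in 1:4) {
    Fc <- .solid_F_at(model, g, dx, dy)
    F11 <- Fc$F11; F12 <- Fc$F12; F21 <- Fc$F21; F22 <- Fc$F22
    J <- F11 * F22 - F12 * F21
    Tt <- F11^2 + F12^2 + F21^2 + F22^2
    I1b <- Tt / J + 1
    Wp <- .solid_Wp(I1b, cf)
    B11 <- F11^2 + F12^2; B22 <- F21^2 + F22^2; B12 <- F11 * F21 + F12 * F22
    c2 <- 2 * Wp / J^2
    pv <- cf$kap * (J - 1)
    sig[, g, 1] <- c2 * (B11 - Tt / 2) + pv
    sig[, g, 2] <- c2 * (B22 - Tt / 2) + pv
    sig[, g, 3] <- c2 * B12
    Jout[, g] <- J
  }
  list(gauss = sig, J = Jout)
}

# bilinear extrapolation of 2x2 Gauss values to a local point (xi, eta)
gauss_extrapolate <- function(vals, xi, eta) {
  a <- 1 / sqrt(3)
  xi_g <- c(-1, 1, 1, -1); eta_g <- c(-1, -1, 1, 1)
  wts <- 0.25 * (1 + (xi / a) * xi_g) * (1 + (eta / a) * eta_g)
  if (is.matrix(vals)) as.vector(vals %*% wts) else sum(vals * wts)
}

#' One linear Newmark step
#'
#' Generalized-trapezoidal Newmark update (`gamma = theta`,
#' `beta = theta^2`; `theta = 0.5` is the trapezoidal rule) for a linear
#' system `M a + C v + K d = F`. Used directly for small benchmark systems;
#' the nonlinear solid path is [solid_step()].
#'
#' @param state list with `d`, `v`, `a` (numeric vectors).
#' @param M,C,K system matrices (dense or sparse).
#' @param F_t load vector at the end of the step.
#' @param params list with `theta` (default 0.5) and `dt`.
#' @return updated state list.
#' @export
newmark_step <- function(state, M, C, K, F_t, params) {
  th <- if (is.null(params$theta)) 0.5 else params$theta
  stopifnot(th > 0, th <= 1, params$dt > 0)
  dt <- params$dt; beta <- th^2; gam <- th
  a0 <- 1 / (beta * dt^2); a1 <- gam / (beta * dt)
  Keff <- K + a1 * C + a0 * M
  rhs <- F_t +
    M %*% (a0 * state$d + state$v / (beta * dt) + (1 / (2 * beta) - 1) * state$a) +
    C %*% (a1 * state$d + (gam / beta - 1) * state$v +
             dt * (gam / (2 * beta) - 1) * state$a)
  d_new <- as.vector(Matrix::solve(Keff, rhs))
  a_new <- a0 * (d_new - state$d) - state$v / (beta * dt) -
    (1 / (2 * beta) - 1) * state$a
  v_new <- state$v + dt * ((1 - gam) * state$a + gam * a_new)
  list(d = d_new, v = v_new, a = a_new)
}

#' Newmark parameters
#' @param dt time step (s).
#' @param theta trapezoidal family parameter (0.5 default).
#' @param f_m,f_k Rayleigh mass and stiffness damping coefficients.
#' @param max_iter Newton corrections per step.
#' @param tol relative residual tolerance.
#' @return list of class `newmark_params`.
#' @export
newmark_params <- function(dt, theta = 0.5, f_m = 0.05, f_k = 0.005,
                           max_iter = 3L, tol = 1e-4) {
  stopifnot(theta > 0, theta <= 1, dt > 0)
  structure(list(dt = dt, theta = theta, f_m = f_m, f_k = f_k,
                 max_iter = max_iter, tol = tol), class = "newmark_params")
}

#' Nonlinear dynamic step of the solid
#'
#' Advances displacement/velocity/acceleration by one damped Newmark step
#' with Newton corrections on the hyperelastic internal force. Rayleigh
#' damping `C = f_m M + f_k K_t` uses the current tangent stiffness, so
#' rigid-body velocity fields of the deformed configuration are not
#' spuriously damped.
#'
#' @param model a [solid_model()].
#' @param state list `d`, `v`, `a`.
#' @param F_ext external nodal force vector.
#' @param params a [newmark_params()].
#' @param M mass matrix from [solid_mass_matrix()].
#' @param m_add optional diagonal virtual added-mass vector (length 2n):
#'   entrained-fluid inertia lumped on the wetted boundary nodes. It adds to
#'   the structural mass in the dynamic operator, representing the fluid the
#'   interface drags and stabilizing the partitioned coupling at near-unity
#'   density ratio; statics are unaffected.
#' @return updated state; attribute `iters` carries Newton iteration count.
#' @export
solid_step <- function(model, state, F_ext, params, M, m_add = NULL,
                       strict = TRUE) {
  dt <- params$dt; th <- params$theta
  beta <- th^2; gam <- th
  a0 <- 1 / (beta * dt^2); a1 <- gam / (beta * dt)
  fix <- model$fixed_dofs

  d_n <- state$d; v_n <- state$v; a_n <- state$a
  d <- d_n + dt * v_n + dt^2 / 2 * a_n
  d[fix] <- d_n[fix]
  # fall back toward d_n when the ballistic predictor would invert elements
  for (bt in 1:6) {
    ok <- solid_min_J(model, d) > 0.01
    if (ok) break
    d <- (d + d_n) / 2
  }
  if (!ok) d <- d_n
  iters <- 0L
  converged <- FALSE
  C <- NULL
  for (it in seq_len(params$max_iter)) {
    asm <- solid_assemble(model, d, tangent = TRUE)
    # tangent Rayleigh damping, frozen over the Newton loop so the
    # iteration Jacobian stays consistent
    if (is.null(C)) C <- params$f_m * M + params$f_k * asm$K
    a_new <- a0 * (d - d_n) - v_n / (beta * dt) - (1 / (2 * beta) - 1) * a_n
    v_new <- v_n + dt * ((1 - gam) * a_n + gam * a_new)
    R <- as.vector(M %*% a_new) + as.vector(C %*% v_new) + asm$f_int - F_ext
    if (!is.null(m_add)) R <- R + m_add * a_new
    R[fix] <- 0
    if (!all(is.finite(R))) stop("step error: non-finite solid residual")
    ref <- max(sum(abs(F_ext)), sum(abs(asm$f_int)), 1e-12)
    iters <- it
    if (sum(abs(R)) < params$tol * ref && it > 1L) { converged <- TRUE; break }
    Keff <- asm$K + a1 * C + a0 * M
    if (!is.null(m_add)) Keff <- Keff + Matrix::Diagonal(x = a0 * m_add)
    Keff <- .apply_dirichlet(Keff, fix)
    # Levenberg-style shift when the tangent passes through a singular
    # (snap-through) configuration
    dd <- NULL; shift <- 0
    for (reg in 1:4) {
      dd <- tryCatch(as.vector(Matrix::solve(
        if (shift > 0) Keff + Matrix::Diagonal(nrow(Keff), shift) else Keff,
        -R)), error = function(e) NULL)
      if (!is.null(dd) && all(is.finite(dd))) break
      shift <- if (shift == 0) 1e-8 * max(abs(Matrix::diag(Keff))) else shift * 1e3
    }
    if (is.null(dd) || !all(is.finite(dd)))
      stop("step error: singular effective stiffness")
    # damped Newton: cap the update, and backtrack when a trial update
    # would invert an element
    mdd <- max(abs(dd))
    if (mdd > 0.05) dd <- dd * (0.05 / mdd)
    for (bt in 1:6) {
      ok <- solid_min_J(model, d + dd) > 0.01
      if (ok) break
      dd <- dd / 2
      if (bt == 6L) stop("instability error: solid step cannot avoid element inversion")
    }
    d <- d + dd
    if (max(abs(d)) > 100) stop("instability error: solid displacement blow-up")
  }
  if (!converged && strict) {
    # tolerate a mildly unconverged but decent state; reject anything worse
    # so callers can retry with a smaller step
    asm2 <- solid_assemble(model, d, tangent = FALSE)
    a_chk <- a0 * (d - d_n) - v_n / (beta * dt) - (1 / (2 * beta) - 1) * a_n
    v_chk <- v_n + dt * ((1 - gam) * a_n + gam * a_chk)
    Rchk <- as.vector(M %*% a_chk) + as.vector(C %*% v_chk) + asm2$f_int - F_ext
    if (!is.null(m_add)) Rchk <- Rchk + m_add * a_chk
    Rchk[fix] <- 0
    refc <- max(sum(abs(F_ext)), sum(abs(asm2$f_int)), 1e-12)
    if (!all(is.finite(Rchk)) || sum(abs(Rchk)) > 1000 * params$tol * refc)
      stop("step error: solid Newton not converged")
  }
  a_new <- a0 * (d - d_n) - v_n / (beta * dt) - (1 / (2 * beta) - 1) * a_n
  v_new <- v_n + dt * ((1 - gam) * a_n + gam * a_new)
  a_new[fix] <- 0; v_new[fix] <- 0
  out <- list(d = d, v = v_new, a = a_new)
  attr(out, "iters") <- iters
  out
}

# zero rows/columns of fixed dofs and put 1 on the diagonal
.apply_dirichlet <- function(K, fix) {
  if (!length(fix)) return(K)
  n <- nrow(K)
  Dm <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% fix)))
  K2 <- Dm %*% K %*% Dm
  K2 + Matrix::Diagonal(n, x = as.numeric(seq_len(n) %in% fix))
}

#' Quasi-static solve with load stepping
#'
#' @param model a [solid_model()].
#' @param F_ext full external load vector.
#' @param nsteps load increments.
#' @param fixed_vals optional prescribed displacement values for the model's
#'   fixed dofs (applied proportionally to the load factor).
#' @param tol,max_iter Newton controls.
#' @return displacement vector at full load.
#' @export
solid_static_solve <- function(model, F_ext, nsteps = 5L, fixed_vals = NULL,
                               tol = 1e-9, max_iter = 40L) {
  fix <- model$fixed_dofs
  n2 <- 2L * model$n
  d <- numeric(n2)
  for (lam in seq_len(nsteps) / nsteps) {
    if (!is.null(fixed_vals)) d[fix] <- lam * fixed_vals
    for (it in seq_len(max_iter)) {
      asm <- solid_assemble(model, d, tangent = TRUE)
      R <- asm$f_int - lam * F_ext
      R[fix] <- 0
      K <- .apply_dirichlet(asm$K, fix)
      dd <- as.vector(Matrix::solve(K, -R))
      d <- d + dd
      if (sqrt(sum(dd^2)) < tol * max(1, sqrt(sum(d^2)))) break
    }
  }
  d
}
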