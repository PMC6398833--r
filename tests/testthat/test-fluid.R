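test_that("mixture properties follow the activity labels", {
  pr <- fluid_props(ghost_scale = 1e-6)
  act <- c(1L, 2L, 3L, 1L)
  mix <- update_mixture_properties(act, pr)
  expect_equal(mix$rho, c(1.08, 1.08e-6, 1.08e-6, 1.08))
  expect_equal(mix$mu[1], 0.036)
  # all-fluid domain gives uniform fields
  expect_true(all(update_mixture_properties(rep(1L, 10), pr)$rho == 1.08))
})

test_that("stabilization parameters have the documented limits", {
  # advective limit tau -> h / (2|v|)
  t1 <- stabilization_taus(0.01, 1e6, 1, 0.01, dt = 1)
  expect_equal(t1$tau_supg, 0.01 / (2 * 1e6), tolerance = 1e-6)
  # transient limit tau -> dt/2
  t2 <- stabilization_taus(0.01, 0, 1, 1e-9, dt = 1e-6)
  expect_equal(t2$tau_supg, 5e-7, tolerance = 1e-6)
  # non-negative for random inputs
  set.seed(2)
  for (k in 1:20) {
    tt <- stabilization_taus(runif(1, 1e-3, 1), runif(1, 0, 100),
                             runif(1, 0.5, 2), runif(1, 1e-3, 1),
                             runif(1, 1e-4, 1))
    expect_true(all(unlist(tt) >= 0))
  }
  expect_equal(t1$tau_supg, t1$tau_pspg)
})

test_that("discrete residuals vanish for rest and uniform states", {
  grid <- build_fluid_grid(c(1, 1), h = 0.25)
  fm <- fluid_model(grid)
  st <- fluid_state(fm)
  r0 <- assemble_residuals(fm, st)
  expect_lt(max(abs(r0$r_v)), 1e-12)
  expect_lt(max(abs(r0$r_p)), 1e-12)
  # uniform velocity: continuity residual zero on interior rows
  st$v[, 1] <- 2
  r1 <- assemble_residuals(fm, st)
  inner <- setdiff(seq_len(fm$n), unlist(fm$bnodes))
  expect_lt(max(abs(r1$r_p[inner])), 1e-10)
})

test_that("manufactured linear solution is advanced at second order in time", {
  rho <- 1.2; mu <- 0.05
  afun <- function(t) 0.4 * sin(2 * pi * t / 0.8)
  apr <- function(t) 0.4 * 2 * pi / 0.8 * cos(2 * pi * t / 0.8)
  bfun <- function(t) 3 * cos(2 * pi * t / 0.8)
  vex <- function(x, y, t) cbind(afun(t) * x, -afun(t) * y)
  bf <- function(x, y, t) cbind(apr(t) * x + afun(t)^2 * x + bfun(t) / rho,
                                -apr(t) * y + afun(t)^2 * y + bfun(t) / rho)
  grid <- build_fluid_grid(c(1, 1), h = 1 / 8)
  fm <- fluid_model(grid, fluid_props(rho_f = rho, mu_f = mu))
  bnodes <- unique(unlist(fm$bnodes))
  nd <- grid$nodes
  Tend <- 0.4
  errs <- sapply(c(8, 16, 32), function(nsteps) {
    dt <- Tend / nsteps
    st <- fluid_state(fm)
    st$v <- vex(nd[, 1], nd[, 2], 0)
    st$v_prev <- vex(nd[, 1], nd[, 2], -dt)
    st$p <- bfun(0) * (nd[, 1] + nd[, 2])
    for (k in 1:nsteps) {
      t1 <- k * dt
      dir <- rbind(data.frame(node = rep(bnodes, 2L),
                              comp = rep(c(1L, 2L), each = length(bnodes)),
                              value = as.vector(vex(nd[bnodes, 1],
                                                    nd[bnodes, 2], t1))),
                   data.frame(node = 1L, comp = 3L,
                              value = bfun(t1) * (nd[1, 1] + nd[1, 2])))
      st <- solve_ns_step(fm, st, fluid_bc(dirichlet = dir), dt,
                          theta = 0.5, extrapolate = TRUE, body_force = bf)
    }
    max(abs(st$v - vex(nd[, 1], nd[, 2], Tend)))
  })
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 1.8))
})

test_that("traction-driven channel reproduces the Poiseuille profile", {
  r <- cached_benchmark("poiseuille")
  expect_true(r$pass)
  expect_lt(r$error, 0.01)
})

test_that("zero driving leaves the fluid at rest and conserves mass when flowing", {
  grid <- build_fluid_grid(c(1, 0.5), h = 0.05)
  fm <- fluid_model(grid)
  bn <- fm$bnodes
  bc0 <- channel_bc(fm, p_in = 0, noslip_nodes = bn$lateral,
                    lateral_mode = "noslip")
  st <- fluid_state(fm)
  for (k in 1:5) st <- solve_ns_step(fm, st, bc0, 0.01)
  expect_lt(max(abs(st$v)), 1e-12)
  # driven channel: inlet flux equals outlet flux within 0.1%
  bc <- channel_bc(fm, p_in = 20, noslip_nodes = bn$lateral,
                   lateral_mode = "noslip")
  bc$dirichlet <- rbind(bc$dirichlet,
                        data.frame(node = c(bn$inlet, bn$outlet),
                                   comp = 2L, value = 0))
  bc$dirichlet <- bc$dirichlet[!duplicated(bc$dirichlet[c("node", "comp")]), ]
  st <- fluid_steady_solve(fm, bc, tol = 1e-10)
  ny <- attr(grid, "ny"); nx <- attr(grid, "nx"); hy <- attr(grid, "hy")
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  flux <- function(i) {
    u <- st$v[nid(i, 1:(ny + 1L)), 1]
    sum((u[-1] + u[-length(u)]) / 2) * hy
  }
  expect_lt(abs(flux(1L) - flux(nx + 1L)), 1e-3 * abs(flux(1L)))
  expect_lt(attr(st, "picard_iters"), 40L)
})

test_that("lid-driven cavity at Re 100 matches the reference centerline", {
  r <- cached_benchmark("cavity")
  expect_true(r$pass)
  expect_lt(r$error, 0.03)
})

test_that("parabolic inlet centerline carries 1.5x the mean", {
  # property of the imposed profile used in velocity-driven mode
  H <- 1; ys <- seq(0, H, length.out = 101)
  vbar <- 2.5
  prof <- 6 * vbar * ys * (H - ys) / H^2
  expect_equal(max(prof), 1.5 * vbar, tolerance = 1e-3)
  expect_equal(mean(prof[-101]), vbar, tolerance = 1e-2)
})
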