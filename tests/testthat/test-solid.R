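test_that("strain-energy densities match direct substitution", {
  # reference state is energy free
  expect_equal(strain_energy_wall(3, 1, wall_material(c3 = 2, c5 = 187.5)), 0)
  expect_equal(strain_energy_valve(3, 1,
                                   valve_material(mu_baseline = 0)), 0)
  # direct substitution in the polynomial law
  expect_equal(strain_energy_wall(3.1, 1, wall_material(c3 = 2.0, c5 = 187.5)),
               2.0 * 0.1 + 187.5 * 0.01, tolerance = 1e-12)
  # direct substitution in the exponential law
  expect_equal(strain_energy_valve(3.5, 1,
                                   valve_material(c0 = 417, c1_exp = 0.06,
                                                  mu_baseline = 0)),
               417 * (exp(0.06 * 0.25) - 1), tolerance = 1e-12)
  # dW/dI1 at the reference state equals c3
  eps <- 1e-6
  m <- wall_material(c3 = 2.0, c5 = 187.5)
  dfd <- (strain_energy_wall(3 + eps, 1, m) -
            strain_energy_wall(3 - eps, 1, m)) / (2 * eps)
  expect_equal(dfd, 2.0, tolerance = 1e-6)
  # monotone increase of the valve energy beyond the reference
  I1s <- seq(3.01, 4, length.out = 20)
  W <- strain_energy_valve(I1s, 1, valve_material())
  expect_true(all(diff(W) > 0))
})

test_that("Cauchy stress is stress-free at rest, frame-indifferent, and matches the energy", {
  mat <- valve_material()
  expect_equal(cauchy_stress(kinematics(diag(2)), mat), matrix(0, 2, 2))
  # pure rotation leaves the stress at its reference value
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(cauchy_stress(kinematics(R), mat), matrix(0, 2, 2),
               tolerance = 1e-10)
  # simple shear: sigma_12 ~ 2 dW/dI1|_ref * gamma for small gamma
  gam <- 1e-4
  F <- matrix(c(1, 0, gam, 1), 2)
  s <- cauchy_stress(kinematics(F), mat)
  expect_equal(s[1, 2], kpa_to_cgs(2 * venofsi:::dW_dI1(3, mat)) * gam,
               tolerance = 1e-3 * abs(s[1, 2]) + 1e-8)
  # stress from finite differences of the energy density (Piola transform)
  set.seed(7)
  F <- diag(2) + matrix(rnorm(4, 0, 0.05), 2)
  eps <- 1e-6
  P_fd <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + eps
    Fm <- F; Fm[i, j] <- Fm[i, j] - eps
    P_fd[i, j] <- (solid_energy_density(Fp, mat) -
                     solid_energy_density(Fm, mat)) / (2 * eps)
  }
  sig_fd <- P_fd %*% t(F) / det(F)
  expect_equal(cauchy_stress(kinematics(F), mat), (sig_fd + t(sig_fd)) / 2,
               tolerance = 1e-5)
})

test_that("assembled tangent matches finite differences of the internal force", {
  set.seed(1)
  m <- single_distorted_element()
  for (mat in list(valve_material(), wall_material())) {
    mod <- solid_model(m, list(body = mat))
    d <- rnorm(8, 0, 0.05)
    asm <- solid_assemble(mod, d)
    eps <- 1e-6
    Kfd <- matrix(0, 8, 8)
    for (j in 1:8) {
      dp <- d; dp[j] <- dp[j] + eps
      dm <- d; dm[j] <- dm[j] - eps
      Kfd[, j] <- (solid_assemble(mod, dp, tangent = FALSE)$f_int -
                     solid_assemble(mod, dm, tangent = FALSE)$f_int) / (2 * eps)
    }
    expect_lt(max(abs(as.matrix(asm$K) - Kfd)) / max(abs(Kfd)), 1e-6)
  }
})

test_that("internal force vanishes for rigid-body motion and at rest", {
  m <- single_distorted_element()
  mod <- solid_model(m, list(body = valve_material()))
  expect_equal(max(abs(solid_assemble(mod, numeric(8),
                                      tangent = FALSE)$f_int)), 0)
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  drot <- as.vector(t(m$nodes %*% t(R) - m$nodes))
  f <- solid_assemble(mod, drot, tangent = FALSE)$f_int
  expect_lt(max(abs(f)), 1e-8 * kpa_to_cgs(mat <- 417))
  dtr <- rep(c(0.3, -0.2), 4)
  expect_lt(max(abs(solid_assemble(mod, dtr, tangent = FALSE)$f_int)), 1e-9)
})

test_that("consistent mass matrix conserves total mass", {
  m <- single_distorted_element()
  mod <- solid_model(m, list(body = wall_material()))
  M <- solid_mass_matrix(mod)
  expect_equal(sum(M) / 2, mod$coef$rho[1] * mesh_element_areas(m),
               tolerance = 1e-12)
})

test_that("stress power matches the energy rate along a deformation path", {
  set.seed(3)
  mat <- wall_material()
  F0 <- diag(2) + matrix(rnorm(4, 0, 0.03), 2)
  Fdot <- matrix(rnorm(4, 0, 0.1), 2)
  dt <- 1e-6
  F1 <- F0 + dt * Fdot
  # dPsi/dt per unit reference volume vs J sigma : d
  dW <- (solid_energy_density(F1, mat) - solid_energy_density(F0, mat)) / dt
  Fm <- (F0 + F1) / 2
  L <- Fdot %*% solve(Fm)
  dsym <- (L + t(L)) / 2
  sig <- cauchy_stress(kinematics(Fm), mat)
  expect_equal(dW, det(Fm) * sum(sig * dsym), tolerance = 1e-4 * abs(dW))
})

test_that("Newmark integrator is exact-order-two and damps with Rayleigh coefficients", {
  omega <- 2 * pi
  # zero load, zero state stays zero
  st <- list(d = 0, v = 0, a = 0)
  st <- newmark_step(st, matrix(1), matrix(0), matrix(omega^2), 0,
                     list(theta = 0.5, dt = 0.01))
  expect_equal(st$d, 0)
  # period error converges at second order (oscillator benchmark)
  r <- cached_benchmark("oscillator")
  expect_true(r$pass)
  expect_true(all(r$details$orders > 1.8 & r$details$orders < 2.2))
  # free vibration with the reference damping pair decays monotonically
  st <- list(d = 1, v = 0, a = -omega^2)
  C <- matrix(0.05 + 0.272 * omega^2)
  peaks <- abs(st$d)
  for (k in 1:300) {
    st <- newmark_step(st, matrix(1), C, matrix(omega^2), 0,
                       list(theta = 0.5, dt = 0.01))
    peaks <- c(peaks, abs(st$d))
  }
  env <- sapply(split(peaks, rep(1:10, length.out = length(peaks))), max)
  expect_lt(peaks[length(peaks)], peaks[1])
})

test_that("dynamic solid step reaches the static solution under constant load", {
  m <- mesh_block(function(s, t) s * 0.5, function(s, t) t * 0.1, 10L, 2L,
                  part = "b")
  left <- which(abs(m$nodes[, 1]) < 1e-12)
  mod <- solid_model(m, list(b = valve_material()), fixed_nodes = left)
  n <- nrow(m$nodes)
  tip <- which(abs(m$nodes[, 1] - 0.5) < 1e-12)
  F <- numeric(2L * n); F[2L * tip] <- 0.05
  d_static <- solid_static_solve(mod, F)
  M <- solid_mass_matrix(mod)
  par <- newmark_params(dt = 5e-3, theta = 0.6, f_m = 1, f_k = 0.05,
                        max_iter = 4L, tol = 1e-6)
  st <- list(d = numeric(2L * n), v = numeric(2L * n), a = numeric(2L * n))
  for (k in 1:400) st <- solid_step(mod, st, F, par, M)
  expect_equal(mean(st$d[2L * tip]), mean(d_static[2L * tip]),
               tolerance = 0.05 * abs(mean(d_static[2L * tip])))
})
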