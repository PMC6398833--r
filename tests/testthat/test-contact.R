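test_that("Lennard-Jones potential has its well at r0 and vanishes at range", {
  cp <- contact_params(epsilon = 4, r0 = 0.036)
  expect_equal(lj_potential(0.036, cp), -4)
  expect_equal(lj_potential(0.036 * 2^(-1 / 6), cp), 0, tolerance = 1e-12)
  expect_lt(abs(lj_potential(100, cp)), 1e-12)
  expect_error(lj_potential(-1, cp), "domain error")
})

test_that("closed-form tail integral matches adaptive quadrature", {
  cp <- contact_params(epsilon = 2.5, r0 = 0.036)
  for (s in seq(0.4, 3, length.out = 9) * cp$r0) {
    qn <- stats::integrate(function(r) lj_potential(r, cp) * r, s, Inf,
                           rel.tol = 1e-12)$value
    expect_equal(lj_force_integral(s, cp), qn,
                 tolerance = 1e-8 * max(abs(qn), 1e-12))
  }
  # the printed special value at s = r0
  expect_equal(lj_force_integral(cp$r0, cp),
               cp$epsilon * cp$r0^2 * (1 / 10 - 1 / 2), tolerance = 1e-12)
  # repulsive below the zero crossing r0 * 5^(-1/6), adhesive beyond
  s_star <- cp$r0 * 5^(-1 / 6)
  expect_gt(lj_force_integral(0.99 * s_star, cp), 0)
  expect_lt(lj_force_integral(1.01 * s_star, cp), 0)
})

test_that("panel pair force is repulsive, decays, and respects set semantics", {
  cp <- contact_params(epsilon = 1, r0 = 0.036)
  mk_panel <- function(y, ny) data.frame(bx = 0, by = y, nx = 0, ny = ny,
                                         da = 0.02, n1 = 1L, n2 = 2L,
                                         beta = 1)
  pj <- mk_panel(0, 1)    # source facing up
  # receiver above, inside the repulsive band: pushed up (+y)
  f1 <- panel_pair_force(mk_panel(0.4 * cp$r0, -1), pj, cp)
  expect_gt(f1[2], 0)
  # far receiver: zero beyond the cutoff
  f2 <- panel_pair_force(mk_panel(10, -1), pj, cp)
  expect_equal(f2, c(0, 0))
  # monotone decay of repulsion with separation below the zero crossing
  mags <- sapply(seq(0.4, 0.7, length.out = 8) * cp$r0, function(s)
    panel_pair_force(mk_panel(s, -1), pj, cp)[2])
  expect_true(all(diff(mags) < 0))
  # candidate detection is symmetric under reordering
  # two facing panels: lower one with outward normal up, upper one down
  coords <- rbind(c(0, 0), c(0.02, 0), c(0, 0.02), c(0.02, 0.02))
  e1 <- data.frame(n1 = 2L, n2 = 1L)
  e2 <- data.frame(n1 = 3L, n2 = 4L)
  s1 <- surface_panels(coords, e1); s2 <- surface_panels(coords, e2)
  c12 <- detect_candidates(s1, s2, cp)
  c21 <- detect_candidates(s2, s1, cp)
  expect_equal(nrow(c12), nrow(c21))
  expect_gt(nrow(c12), 0)
  # widely separated surfaces yield no candidates
  far <- surface_panels(coords + 10, e2)
  expect_equal(nrow(detect_candidates(s1, far, cp)), 0L)
})

test_that("symmetric closure balances forces and impact does not penetrate", {
  r <- cached_benchmark("contact_blocks")
  expect_true(r$pass)
  expect_gt(r$details$min_sep_over_r0, 0.3)
  expect_lt(r$details$imbalance, 1e-6)
})

test_that("contact force calibration bounds the pressure load scale", {
  cp <- contact_params(epsilon = 1, r0 = 0.036)
  dp <- mmhg_to_cgs(4)
  cp <- calibrate_contact_epsilon(cp, dp, panel_length = 0.02)
  s <- 0.25 * cp$r0
  dalpha <- 0.02 / s
  expect_equal(dalpha * lj_force_integral(s, cp), 2 * dp,
               tolerance = 1e-10 * dp)
  # the adhesive tail well beyond the zero crossing is small against the
  # peak pressure load per unit panel length
  s_ad <- 1.2 * cp$r0
  expect_lt(abs((0.02 / s_ad) * lj_force_integral(s_ad, cp)), 0.05 * dp)
})
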