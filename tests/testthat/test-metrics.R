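test_that("orifice width and area follow their definitions", {
  coords <- rbind(c(1.0, 0.6), c(1.0, 0.4))
  expect_equal(orifice_width(coords, c(1L, 2L)), 0.2)
  expect_error(orifice_width(coords, c(1L, NA)), "configuration error")
  # undeformed vein mesh: l equals the initial gap
  vm <- mesh_solid(vein_geometry(), 0.04)
  expect_equal(orifice_width(vm$mesh$nodes, vm$tips), 0.018, tolerance = 0.02)
  # rigid symmetric tip displacement widens the orifice by 2 delta
  c2 <- vm$mesh$nodes
  c2[vm$tips[1], 2] <- c2[vm$tips[1], 2] + 0.1
  c2[vm$tips[2], 2] <- c2[vm$tips[2], 2] - 0.1
  expect_equal(orifice_width(c2, vm$tips), 0.218, tolerance = 1e-3)
  # elliptical area with the stated axes
  expect_equal(orifice_area(0, 0.691, 0.05), 0)
  expect_equal(orifice_area(0.494, 0.691, 0.05), pi * 0.791 * 0.494 / 4,
               tolerance = 1e-12)
  expect_equal(orifice_area(0.2, 0.691, 0.05),
               orifice_area(0.1, 0.691, 0.05) * 2, tolerance = 1e-12)
})

test_that("flow rate integrates the axial velocity over the orifice", {
  grid <- build_fluid_grid(c(1, 1), h = 0.05)
  fm <- fluid_model(grid)
  st <- fluid_state(fm)
  st$v[, 1] <- 10
  Q <- flow_rate(fm, st, 0.5, c(0.3, 0.7), long_axis = 0.8)
  expect_equal(Q, pi * 0.8 * 10 * 0.4 / 4, tolerance = 1e-6)
  st$v[, 1] <- -10
  expect_equal(flow_rate(fm, st, 0.5, c(0.3, 0.7), 0.8), -Q,
               tolerance = 1e-9)
  st$v[, 1] <- 0
  expect_equal(flow_rate(fm, st, 0.5, c(0.3, 0.7), 0.8), 0)
})

test_that("venous volumes and critical time match the analytic sine case", {
  t <- seq(0, 1, length.out = 4001)
  Q <- sin(2 * pi * t)
  v <- venous_volumes(t, Q, cycle_period = 1)
  expect_equal(v$forward, 1 / pi, tolerance = 1e-5)
  expect_equal(v$reverse, -1 / pi, tolerance = 1e-5)
  expect_equal(v$critical_time, 50, tolerance = 0.1)
  # bookkeeping: forward + reverse equals the net integral
  set.seed(11)
  Q2 <- stats::filter(rnorm(401), rep(1 / 20, 20), circular = TRUE)
  t2 <- seq(0, 1, length.out = 401)
  v2 <- venous_volumes(t2, as.numeric(Q2), 1)
  net <- sum((Q2[-1] + Q2[-401]) / 2) * diff(t2)[1]
  expect_equal(v2$forward + v2$reverse, net, tolerance = 1e-9)
  # non-reversing flow: reverse volume zero and the no-crossing flag set
  v3 <- venous_volumes(t, abs(Q) + 0.1, 1)
  expect_equal(v3$reverse, 0)
  expect_true(attr(v3, "no_crossing"))
  expect_equal(v3$critical_time, 100)
})

test_that("fluid wall shear stress is exact for a resolved Poiseuille profile", {
  H <- 0.5; L <- 1
  grid <- build_fluid_grid(c(L, H), h = H / 20)
  fm <- fluid_model(grid)
  vbar <- 8
  nd <- grid$nodes
  st <- fluid_state(fm)
  st$v[, 1] <- 6 * vbar * nd[, 2] * (H - nd[, 2]) / H^2
  xs <- seq(0.2, 0.8, by = 0.1)
  wss <- wall_shear_stress_fluid(fm, st, xs, rep(0, length(xs)),
                                 nx = rep(0, length(xs)),
                                 ny = rep(1, length(xs)))
  expect_equal(abs(wss), rep(6 * fm$props$mu_f * vbar / H, length(xs)),
               tolerance = 0.02 * 6 * fm$props$mu_f * vbar / H)
  # quiescent fluid: zero WSS
  st0 <- fluid_state(fm)
  expect_equal(wall_shear_stress_fluid(fm, st0, 0.5, 0, 0, 1), 0)
  # flow reversal flips the sign
  wss_f <- wall_shear_stress_fluid(fm, st, 0.5, 0, 0, 1)
  st$v[, 1] <- -st$v[, 1]
  wss_r <- wall_shear_stress_fluid(fm, st, 0.5, 0, 0, 1)
  expect_lt(wss_f * wss_r, 0)
})

test_that("solid wall shear stress decomposes the surface traction", {
  # homogeneous simple shear of a block: SWSS on the top face equals the
  # applied shear stress
  mat <- wall_material()
  m <- mesh_block(function(s, t) s, function(s, t) t * 0.5, 8L, 4L, "b")
  mod <- solid_model(m, list(b = mat))
  gam <- 0.02
  d <- numeric(2L * nrow(m$nodes))
  d[2L * (seq_len(nrow(m$nodes)) - 1L) + 1L] <- gam * m$nodes[, 2]
  st <- solid_element_stress(mod, d)
  kin <- kinematics(matrix(c(1, 0, gam, 1), 2))
  s_exact <- cauchy_stress(kin, mat)
  top <- mesh_boundary_edges(m)
  nd <- m$nodes
  ymid <- (nd[top$n1, 2] + nd[top$n2, 2]) / 2
  top <- top[abs(ymid - 0.5) < 1e-9, ]
  coords <- nd + cbind(d[2 * seq_len(nrow(nd)) - 1], d[2 * seq_len(nrow(nd))])
  sw <- wall_shear_stress_solid(mod, d, top, coords)
  expect_equal(mean(sw), abs(s_exact[1, 2]),
               tolerance = 0.05 * abs(s_exact[1, 2]))
  # hydrostatic state has zero SWSS: uniform volumetric contraction
  d2 <- -0.005 * as.vector(t(nd))
  sw2 <- wall_shear_stress_solid(mod, d2, top, nd * 0.995)
  st2 <- solid_element_stress(mod, d2)
  expect_lt(mean(sw2), 0.02 * max(abs(st2$gauss)))
})

test_that("mechanical cost picks the minimum-FWSS moment", {
  t <- seq(0, 1, by = 0.01)
  fwss <- 1 + cos(2 * pi * t)      # minimum 0 at t = 0.5
  swss <- 2 + 0 * t
  mc <- mechanical_cost(t, swss, fwss + 0.5, window = c(0.3, 0.8))
  expect_equal(mc$t_selected, 0.5)
  expect_equal(mc$cost, 2 / 0.5)
  # equal stresses give cost 1
  expect_equal(mechanical_cost(t, fwss + 1, fwss + 1)$cost, 1)
})

test_that("leaflet rotation measures the hinge-tip chord angle", {
  ref <- rbind(c(0, 0), c(1, 0))
  cur <- rbind(c(0, 0), c(0, 1))
  expect_equal(leaflet_rotation(ref, cur, 1L, 2L), 90)
  expect_equal(leaflet_rotation(ref, ref, 1L, 2L), 0)
  # invariant to stretch along the chord
  cur2 <- rbind(c(0, 0), c(3, 0))
  expect_equal(leaflet_rotation(ref, cur2, 1L, 2L), 0)
})

test_that("phase segmentation finds the four phases in order", {
  t <- seq(0, 1, by = 0.002)
  l <- ifelse(t < 0.05, 0.018,
              ifelse(t < 0.2, 0.018 + (0.5 - 0.018) * (t - 0.05) / 0.15,
                     ifelse(t < 0.4, 0.5,
                            ifelse(t < 0.7, pmax(0.02, 0.5 - 1.7 * (t - 0.4)),
                                   0.02))))
  ph <- phase_segmentation(t, l, relax_end = 0.05, closure_threshold = 0.045)
  expect_equal(ph$phase, c("opening", "equilibrium", "closing", "closed"))
  expect_true(all(diff(ph$t_start) > 0))
  expect_false(attr(ph, "incompetent"))
  expect_equal(ph$t_start[2], 0.19, tolerance = 0.03)
  # a trace that never closes raises the incompetence flag
  l2 <- pmax(l, 0.2)
  ph2 <- phase_segmentation(t, l2, 0.05, closure_threshold = 0.045)
  expect_true(attr(ph2, "incompetent"))
  expect_error(phase_segmentation(t, rep(1, length(t)), 0.05, 0.045),
               "degenerate")
})
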