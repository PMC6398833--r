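test_that("vein geometry validates its parameters", {
  expect_s3_class(vein_geometry(), "vein_geometry")
  expect_error(vein_geometry(d0 = -1), "d0")
  expect_error(vein_geometry(u_g0 = 0.8), "u_g0")
  expect_error(vein_geometry(valve_offset = 3), "valve_offset")
  expect_error(vein_geometry(h_v = 0.4), "h_v")
})

test_that("part outlines are closed, symmetric, and the tips sit u_g0 apart", {
  g <- vein_geometry()
  o <- build_vein_geometry(g)
  expect_setequal(names(o), c("wall_upper", "wall_lower", "sinus_upper",
                              "sinus_lower", "leaflet_1", "leaflet_2"))
  ax <- attr(o, "axis_y")
  # mirror symmetry about the vessel axis
  up <- o$leaflet_1; lo <- o$leaflet_2
  expect_equal(up[, 1], lo[, 1], tolerance = 1e-12)
  expect_equal(up[, 2] - ax, -(lo[, 2] - ax), tolerance = 1e-12)
  # minimum distance between the two leaflet outlines equals the gap
  d2 <- outer(up[, 1], lo[, 1], "-")^2 + outer(up[, 2], lo[, 2], "-")^2
  expect_equal(sqrt(min(d2)), g$u_g0, tolerance = 2e-3)
  # degenerate sinus bulge still yields valid outlines
  o0 <- build_vein_geometry(vein_geometry(h_s = 0))
  expect_true(all(abs(o0$sinus_upper[1:50, 2] - (ax + g$d0 / 2)) < 1e-12))
})

test_that("solid meshing reproduces the reference part counts at 0.008 cm", {
  vm <- mesh_solid(vein_geometry(), 0.008)
  counts <- vein_mesh_counts(vm)
  expect_lt(abs(counts[["wall"]] - 1408) / 1408, 0.15)
  expect_lt(abs(counts[["valve"]] - 632) / 632, 0.15)
  expect_lt(abs(counts[["sinus"]] - 824) / 824, 0.15)
  expect_lt(abs(mesh_mean_edge_length(vm$mesh) - 0.008) / 0.008, 0.20)
  expect_true(all(mesh_min_corner_jacobian(vm$mesh) > 0))
  # undeformed tip gap equals u_g0 (up to the tangent-offset discretization)
  expect_equal(orifice_width(vm$mesh$nodes, vm$tips), 0.018,
               tolerance = 0.02)
})

test_that("mesh refinement scales element counts quadratically", {
  # 0.016 -> 0.008 doubles both the columns and the layer counts
  c1 <- sum(vein_mesh_counts(mesh_solid(vein_geometry(), 0.016)))
  c2 <- sum(vein_mesh_counts(mesh_solid(vein_geometry(), 0.008)))
  expect_gt(c2 / c1, 3)
  expect_lt(c2 / c1, 6)
})

test_that("mean luminal diameter matches the bulge-weighted analytic value", {
  g <- vein_geometry()
  vm <- mesh_solid(g, 0.02)
  et <- vm$edge_tags
  lum <- et[et$tag %in% c("lumen_wall", "sinus_inner"), ]
  nodes <- unique(c(lum$n1, lum$n2))
  y <- vm$mesh$nodes[nodes, 2]
  mean_diam <- 2 * mean(abs(y - vm$axis_y))
  # half-cosine bulge of height h_s over d_s raises the mean diameter by
  # 2 h_s (d_s/2) / L0
  d_expected <- g$d0 + 2 * g$h_s * g$d_s / (2 * g$L0)
  expect_lt(abs(mean_diam - d_expected) / d_expected, 0.01)
})

test_that("structured unit-square meshing gives the expected cells", {
  m <- build_fluid_grid(c(1, 1), h = 0.5)
  expect_equal(nrow(m$elems), 4L)
  g <- build_fluid_grid(c(2.5, 1.071), h = 0.008)
  expect_equal(nrow(g$elems), ceiling(2.5 / 0.008) * ceiling(1.071 / 0.008))
  # single cell row when h equals the domain height
  expect_equal(attr(build_fluid_grid(c(1, 0.2), h = 0.2), "ny"), 1L)
})

test_that("lesion cases follow the fibrosis/atrophy rules", {
  expect_equal(configure_lesion("CFV")$c0_leaflet, c(4170, 4170))
  expect_equal(configure_lesion("CFV")$thickness_factor, c(1.25, 1.25))
  expect_equal(configure_lesion("IAV")$c0_leaflet, c(41.7, 417))
  expect_equal(configure_lesion("Normal")$c0_leaflet, c(417, 417))
  expect_equal(configure_lesion("Normal")$thickness_factor, c(1, 1))
  expect_error(configure_lesion("XYZ"), "unknown lesion")
})

test_that("pulsed-wave function is periodic, normalized and zero during relaxation", {
  pr <- loading_protocol()
  expect_equal(pulse_waveform(0.02, pr), 0)
  ts <- seq(0, 0.0499, by = 1e-3)
  expect_true(all(pulse_waveform(ts, pr) == 0))
  tt <- seq(0, 1, by = 1e-3)
  expect_equal(max(pulse_waveform(tt, pr)), 1, tolerance = 1e-6)
  expect_equal(pulse_waveform(tt, pr), pulse_waveform(tt + 1.0, pr),
               tolerance = 1e-12)
  expect_true(all(pulse_waveform(tt, pr) >= 0 & pulse_waveform(tt, pr) <= 1))
  # peak pressure composes hydrostatic column and pump
  expect_equal(pr$delta_p_max, pr$p_hydrostatic + pr$p_pump)
  expect_equal(pr$delta_p_max, mmhg_to_cgs(4.0))
})
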