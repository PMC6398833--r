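test_that("configuration presets and YAML round trip", {
  cfg <- simulation_config("CAV", "coarse")
  expect_equal(cfg$resolution$h, 0.02)
  expect_equal(cfg$resolution$dt, 1e-3)
  expect_equal(simulation_config(preset = "paper")$resolution$dt, 4e-4)
  cfg2 <- simulation_config("Normal", "smoke",
                            overrides = list(contact = list(r0 = 0.05)))
  expect_equal(cfg2$contact$r0, 0.05)
  expect_equal(cfg2$contact$cutoff_factor, 3)
  f <- tempfile(fileext = ".yaml")
  config_to_yaml(cfg2, f)
  cfg3 <- config_from_yaml(f)
  expect_equal(cfg3$contact$r0, 0.05)
  expect_equal(cfg3$case, "Normal")
  unlink(f)
})

test_that("legacy-VTK export/import round-trips meshes and fields", {
  m <- mesh_solid(vein_geometry(), 0.04)$mesh
  f <- tempfile(fileext = ".vtk")
  set.seed(4)
  pd <- list(pressure = rnorm(nrow(m$nodes)),
             velocity = matrix(rnorm(2 * nrow(m$nodes)), ncol = 2))
  write_vtk_quad(m, f, point_data = pd)
  rt <- read_vtk_quad(f)
  expect_equal(rt$mesh$nodes, m$nodes, ignore_attr = TRUE)
  expect_equal(rt$mesh$elems, m$elems, ignore_attr = TRUE)
  expect_identical(rt$point_data$pressure, pd$pressure)
  expect_identical(rt$point_data$velocity, pd$velocity, )
  unlink(f)
})

test_that("simulation setup produces a consistent coupled system", {
  cfg <- simulation_config("IFV", "smoke")
  sim <- setup_simulation(cfg)
  # lesion materials: leaflet 1 fibrotic (x10), leaflet 2 healthy
  m1 <- sim$smod$materials$valve_leaflet_1
  m2 <- sim$smod$materials$valve_leaflet_2
  expect_equal(m1$c0, 4170)
  expect_equal(m2$c0, 417)
  expect_equal(m1$mu_baseline / m2$mu_baseline, 10)
  # fibrotic leaflet is meshed 25% thicker
  expect_equal(sim$vm$comp_thickness[["leaflet_1"]] /
                 sim$vm$comp_thickness[["leaflet_2"]], 1.25)
  # lesion scenarios differ from Normal only in the lesion-derived entries
  cfgN <- simulation_config("Normal", "smoke")
  expect_equal(cfgN[setdiff(names(cfgN), "case")],
               cfg[setdiff(names(cfg), "case")])
})

test_that("a short coupled run is deterministic and physically quiet at rest", {
  cfg <- simulation_config("Normal", "smoke")
  run_some <- function() {
    sim <- setup_simulation(cfg)
    for (k in 1:6) sim <- advance_coupled_step(sim)
    sim
  }
  s1 <- run_some(); s2 <- run_some()
  expect_identical(s1$sstate$d, s2$sstate$d)
  expect_identical(s1$fstate$v, s2$fstate$v)
  # during the relaxation window (zero driving) everything stays small
  expect_lt(max(abs(s1$fstate$v)), 0.5)
  expect_lt(max(abs(s1$sstate$d)), 5e-3)
})

test_that("write_outputs produces the manifest it promises", {
  rep <- list(metrics = data.frame(t = c(0.1, 0.2), l_goa = c(0.1, 0.2)),
              wss = NULL,
              summary = list(case = "Normal", l_goa_max = 0.2),
              phases = NULL, volumes = NULL,
              config = simulation_config())
  class(rep) <- "run_report"
  d <- tempfile()
  man <- write_outputs(rep, d)
  expect_true(all(file.exists(man$file)))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  js <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(js$case, "Normal")
  unlink(d, recursive = TRUE)
})

test_that("benchmark dispatcher covers the canonical cases", {
  expect_error(run_benchmark("nope"))
  r <- run_benchmark("oscillator")
  expect_true(all(c("name", "pass", "error", "tol") %in% names(r)))
})
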