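# shared small fixtures for the unit tests

unit_square_mesh <- function(n = 1L) {
  mesh_block(function(s, t) s, function(s, t) t, n, n, part = "body")
}

single_distorted_element <- function() {
  nd <- rbind(c(0, 0), c(1.1, 0.05), c(0.95, 1.0), c(-0.02, 0.9))
  quad_mesh(nd, matrix(1:4, 1), part = "body")
}

# memoised valve-cycle runs and benchmarks shared between the acceptance
# tests and other tests; computed at most once per session. The healthy
# valve runs a full cycle; the lesion comparisons use the horizon over
# which their compared quantities are settled (the pump pulse ends at
# 0.55 s), with the never-closing CAV followed deep into the reflux phase.
.run_cache <- new.env(parent = emptyenv())

run_horizon <- function(case) {
  switch(toupper(case), NORMAL = 1.0, CAV = 0.9, 0.7)
}

cached_run <- function(case) {
  key <- toupper(case)
  if (is.null(.run_cache[[key]])) {
    cfg <- simulation_config(case, "smoke", n_cycles = run_horizon(case))
    .run_cache[[key]] <- run_scenario(cfg)
  }
  .run_cache[[key]]
}

cached_benchmark <- function(name) {
  key <- paste0("bench_", name)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_benchmark(name)
  .run_cache[[key]]
}
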