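test_that("point classification distinguishes real, ghost and inactive nodes", {
  grid <- build_fluid_grid(c(1, 1), h = 0.1)
  fm <- fluid_model(grid)
  # large immersed square: centre inactive, rim ghost, outside real
  sq <- mesh_block(function(s, t) 0.25 + 0.5 * s,
                   function(s, t) 0.25 + 0.5 * t, 5L, 5L, "blob")
  vmx <- list(mesh = sq, comp = rep("blob", nrow(sq$elems)),
              comp_thickness = c(blob = 0.5), target_size = 0.1)
  class(vmx) <- "vein_mesh"
  coup <- suppressWarnings(fsi_coupling(vmx, fm))
  cls <- classify_fluid_nodes(coup, fm, sq$nodes)
  nd <- grid$nodes
  centre <- which.min((nd[, 1] - 0.5)^2 + (nd[, 2] - 0.5)^2)
  corner <- which.min((nd[, 1] - 0)^2 + (nd[, 2] - 0)^2)
  expect_equal(cls$activity[centre], 3L)  # deep inside: inactive
  expect_equal(cls$activity[corner], 1L)  # far outside: real
  # ghosts are exactly the covered nodes with a real 4-neighbour
  nx <- attr(grid, "nx")
  for (g in which(cls$activity == 2L)) {
    i <- (g - 1L) %% (nx + 1L); j <- (g - 1L) %/% (nx + 1L)
    nbr <- c(g - 1L, g + 1L, g - (nx + 1L), g + (nx + 1L))
    nbr <- nbr[nbr >= 1 & nbr <= nrow(nd)]
    expect_true(any(cls$activity[nbr] == 1L))
  }
})

test_that("interface velocity transfer is exact for rigid motion", {
  grid <- build_fluid_grid(c(1, 1), h = 0.05)
  fm <- fluid_model(grid)
  sq <- mesh_block(function(s, t) 0.3 + 0.4 * s,
                   function(s, t) 0.3 + 0.4 * t, 8L, 8L, "blob")
  vmx <- list(mesh = sq, comp = rep("blob", nrow(sq$elems)),
              comp_thickness = c(blob = 0.4), target_size = 0.05)
  class(vmx) <- "vein_mesh"
  coup <- suppressWarnings(fsi_coupling(vmx, fm))
  cls <- classify_fluid_nodes(coup, fm, sq$nodes)
  map <- interface_map(coup, fm, sq$nodes, cls)
  expect_gt(nrow(map), 0)
  expect_true(all(map$tpar >= 0 & map$tpar <= 1))
  expect_true(all(map$dist <= sqrt(2) * 0.05 + 1e-9))
  # rigid translation: every ghost node receives exactly v0
  v0 <- c(3.2, -1.4)
  vel <- matrix(rep(v0, each = nrow(sq$nodes)), ncol = 2)
  gh <- velocity_solid_to_fluid(map, fm, sq$nodes, vel, sq$elems)
  expect_equal(max(abs(gh$u - v0[1])), 0, tolerance = 1e-12)
  expect_equal(max(abs(gh$v - v0[2])), 0, tolerance = 1e-12)
  # rigid rotation: ghost velocities match omega x r at the ghost location
  om <- 2.5; ctr <- c(0.5, 0.5)
  vel <- cbind(-om * (sq$nodes[, 2] - ctr[2]), om * (sq$nodes[, 1] - ctr[1]))
  gh <- velocity_solid_to_fluid(map, fm, sq$nodes, vel, sq$elems)
  gx <- grid$nodes[gh$node, 1]; gy <- grid$nodes[gh$node, 2]
  expect_lt(max(abs(gh$u - (-om * (gy - ctr[2])))), 1e-9)
  expect_lt(max(abs(gh$v - om * (gx - ctr[1]))), 1e-9)
})

test_that("bilinear interpolation weights are exact for linear fields", {
  grid <- build_fluid_grid(c(1, 1), h = 0.1)
  fm <- fluid_model(grid)
  st <- fluid_state(fm)
  st$p <- 3 * grid$nodes[, 1] - 2 * grid$nodes[, 2] + 0.7
  set.seed(5)
  px <- runif(30, 0.05, 0.95); py <- runif(30, 0.05, 0.95)
  expect_equal(fluid_interp(fm, st, px, py, "p"), 3 * px - 2 * py + 0.7,
               tolerance = 1e-12)
  w <- bilinear_weights(fm, px, py)
  pr <- w$alpha * w$beta * st$p[w$n_a] + w$beta * (1 - w$alpha) * st$p[w$n_b] +
    (1 - w$alpha) * (1 - w$beta) * st$p[w$n_c] +
    w$alpha * (1 - w$beta) * st$p[w$n_e]
  expect_equal(pr, 3 * px - 2 * py + 0.7, tolerance = 1e-12)
  # corner coincidence: weights degenerate to the corner value
  w1 <- bilinear_weights(fm, 0.1, 0.1)
  expect_equal(w1$alpha, 0)
  expect_equal(st$p[w1$n_c],
               fluid_interp(fm, st, 0.1, 0.1, "p"), tolerance = 1e-12)
})

test_that("pressure traction integrates to zero on a closed boundary", {
  grid <- build_fluid_grid(c(1, 1), h = 0.05)
  fm <- fluid_model(grid)
  sq <- mesh_block(function(s, t) 0.3 + 0.4 * s,
                   function(s, t) 0.35 + 0.3 * t, 8L, 6L, "blob")
  vmx <- list(mesh = sq, comp = rep("blob", nrow(sq$elems)),
              comp_thickness = c(blob = 0.3), target_size = 0.05)
  class(vmx) <- "vein_mesh"
  coup <- suppressWarnings(fsi_coupling(vmx, fm))
  st <- fluid_state(fm)
  # uniform pressure: net force on the closed boundary vanishes
  st$p[] <- 250
  tr <- traction_fluid_to_solid(coup, fm, st, sq$nodes)
  n <- nrow(sq$nodes)
  expect_lt(abs(sum(tr$force[2 * (1:n) - 1])), 1e-9)
  expect_lt(abs(sum(tr$force[2 * (1:n)])), 1e-9)
  expect_equal(unique(round(stats::na.omit(tr$pressure), 9)), 250)
  # linear pressure field: interpolated nodal pressures exact
  st$p <- 5 * grid$nodes[, 1] + 2 * grid$nodes[, 2]
  tr <- traction_fluid_to_solid(coup, fm, st, sq$nodes)
  bnd <- which(!is.na(tr$pressure))
  expect_equal(tr$pressure[bnd],
               5 * sq$nodes[bnd, 1] + 2 * sq$nodes[bnd, 2],
               tolerance = 1e-10)
  # and the resultant matches the buoyancy-type closed-surface identity
  # F = -integral p n ds = -(grad p) * Area for a linear field
  area <- sum(mesh_element_areas(sq))
  expect_equal(sum(tr$force[2 * (1:n) - 1]), -5 * area, tolerance = 1e-6)
  expect_equal(sum(tr$force[2 * (1:n)]), -2 * area, tolerance = 1e-6)
})

test_that("immersed no-slip audit passes for an impulsively moved plate", {
  r <- cached_benchmark("immersed_plate")
  expect_true(r$pass)
  expect_lt(r$details$dirichlet_err, 1e-10)
  expect_lt(r$details$near_plate_rel_err, 0.5)
})

test_that("mesh ratio policy warns outside its band", {
  grid <- build_fluid_grid(c(1, 1), h = 0.2)
  fm <- fluid_model(grid)
  sq <- mesh_block(function(s, t) 0.3 + 0.4 * s,
                   function(s, t) 0.3 + 0.4 * t, 20L, 20L, "blob")
  vmx <- list(mesh = sq, comp = rep("blob", nrow(sq$elems)),
              comp_thickness = c(blob = 0.4), target_size = 0.02)
  class(vmx) <- "vein_mesh"
  expect_warning(fsi_coupling(vmx, fm), "ratio")
})
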