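test_that("the hexahedral element has the canonical stiffness structure", {
  K <- hex8_stiffness(3200, 0.3, 0.16)
  expect_equal(K, t(K), tolerance = 1e-14)

  # rigid-body translations produce no force
  for (comp in 1:3) {
    u <- rep(0, 24)
    u[seq(comp, 24, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
  }

  # exactly six zero-energy modes, all other eigenvalues positive
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < 1e-9 * max(ev)), 6L)
  expect_true(all(ev[1:18] > 0))

  # linear scaling in E and in voxel size
  expect_equal(hex8_stiffness(6400, 0.3, 0.16), 2 * K, tolerance = 1e-12)
  expect_equal(hex8_stiffness(3200, 0.3, 0.32), 2 * K, tolerance = 1e-12)
  expect_error(hex8_stiffness(3200, 0.5, 1), "poisson")
})

test_that("a homogeneous block recovers its material modulus exactly", {
  g <- fixture_grid("all_solid_box", shape = c(8, 8, 8), voxel_size = 0.16)
  sol <- fe_solve(g, fe_config(bc_mode = "frictionless"))
  expect_lt(abs(sol$apparent_modulus - 3200) / 3200, 1e-6)
  # reaction balance between the two prescribed faces
  expect_lt(abs(sol$reaction_force_top + sol$reaction_force_bottom),
            1e-6 * abs(sol$reaction_force_top))
})

test_that("series and parallel two-phase fixtures hit the mixture bounds", {
  reuss <- 2 * 3200 * 2000 / (3200 + 2000)
  gs <- fixture_grid("slab_series", shape = c(8, 8, 8))
  ss <- fe_solve(gs, fe_config(poisson = 0, bc_mode = "frictionless"))
  expect_lt(abs(ss$apparent_modulus - reuss) / reuss, 1e-3)

  gp <- fixture_grid("column_parallel", shape = c(8, 8, 8))
  sp <- fe_solve(gp, fe_config(poisson = 0, bc_mode = "frictionless"))
  expect_lt(abs(sp$apparent_modulus - 2600) / 2600, 1e-3)
})

test_that("any two-phase solid lies within its Reuss and Voigt bounds", {
  set.seed(8)
  labels <- array(ifelse(runif(6^3) < 0.4, 2L, 1L), c(6, 6, 6))
  g <- voxel_grid(labels, 1)
  f2 <- mean(labels == 2L)
  sol <- fe_solve(g, fe_config(poisson = 0, bc_mode = "frictionless"))
  reuss <- 1 / ((1 - f2) / 3200 + f2 / 2000)
  voigt <- (1 - f2) * 3200 + f2 * 2000
  expect_gte(sol$apparent_modulus, reuss * (1 - 1e-9))
  expect_lte(sol$apparent_modulus, voigt * (1 + 1e-9))
})

test_that("the apparent modulus is independent of the voxel size", {
  g <- generate_open_cell(structure_spec(c(10, 10, 10), 0.6, seed = 2,
                                         voxel_size = 0.5))
  g2 <- voxel_grid(g$labels, 2)
  e1 <- fe_solve(g, fe_config())$apparent_modulus
  e2 <- fe_solve(g2, fe_config())$apparent_modulus
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("paper and frictionless modes agree for slender homogeneous blocks", {
  g <- fixture_grid("all_solid_box", shape = c(6, 6, 18), voxel_size = 1)
  ep <- fe_solve(g, fe_config(bc_mode = "paper"))$apparent_modulus
  ef <- fe_solve(g, fe_config(bc_mode = "frictionless"))$apparent_modulus
  expect_lt(abs(ep - ef) / ef, 0.02)
})

test_that("degenerate inputs raise informative errors", {
  empty <- fixture_grid("all_void_box", shape = c(4, 4, 4))
  expect_error(fe_solve(empty), "empty grid")

  # solid exists but no component spans bottom to top
  labels <- array(0L, c(4, 4, 6))
  labels[, , 1:2] <- 1L
  labels[, , 5:6] <- 1L
  g <- voxel_grid(labels, 1)
  expect_error(fe_solve(g), "disconnected load path.*32 voxels")

  expect_error(improvement(100, 0), "positive")
})

test_that("improvement arithmetic and sign are correct", {
  expect_equal(improvement(100, 100), 0)
  expect_equal(improvement(250, 100), 150)

  # adding cement to a structure never lowers its stiffness
  g <- random_connected_grid(c(4, 4, 4), p_solid = 0.5, seed = 3)
  e0 <- fe_solve(g, fe_config())$apparent_modulus
  voids <- which(g$labels == 0L, arr.ind = TRUE)
  aug <- g
  aug$labels[voids[1, 1], voids[1, 2], voids[1, 3]] <- 2L
  e1 <- fe_solve(aug, fe_config())$apparent_modulus
  expect_gte(improvement(e1, e0), -1e-9)
})

test_that("multigrid and direct solvers agree on a porous grid", {
  g <- generate_open_cell(structure_spec(c(14, 14, 14), 0.6, seed = 6))
  e_direct <- fe_solve(g, fe_config())$apparent_modulus
  cfg_mg <- fe_config(direct_max_dofs = 0, mg_coarse_max_dofs = 1500,
                      solver_tol = 1e-8)
  sol_mg <- fe_solve(g, cfg_mg)
  expect_identical(sol_mg$method, "mgcg")
  expect_equal(sol_mg$apparent_modulus, e_direct, tolerance = 1e-5)
})
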