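test_that("cloud extraction respects 26-connectivity and size ordering", {
  empty <- fixture_grid("all_void_box", shape = c(4, 4, 4))
  cl <- extract_cloud(empty)
  expect_identical(cl$n_components, 0L)
  expect_identical(sum(cl$mask), 0L)

  # two voxels sharing only a corner form one 26-connected component
  labels <- array(0L, c(4, 4, 4))
  labels[1, 1, 1] <- 2L
  labels[2, 2, 2] <- 2L
  cl <- extract_cloud(voxel_grid(labels, 1))
  expect_identical(cl$n_components, 1L)

  # components come back ordered by size
  labels <- array(0L, c(10, 4, 4))
  labels[1:2, 1, 1] <- 2L       # size 2
  labels[6:10, 1, 1] <- 2L      # size 5 (disjoint: gap at 3:5)
  cl <- extract_cloud(voxel_grid(labels, 1))
  expect_identical(cl$sizes, c(5L, 2L))
  expect_identical(cl$components[6, 1, 1], 1L)

  ball <- fixture_grid("digital_ball", shape = c(24, 24, 24), radius = 7)
  cl <- extract_cloud(ball)
  expect_identical(cl$n_components, 1L)
  expect_identical(cl$sizes[1], sum(ball$labels == 2L))
})

test_that("face-counted sphericity matches closed forms for cubes", {
  cube <- fixture_grid("all_solid_box", shape = c(6, 6, 6))
  psi <- sphericity(cube$labels == 1L, voxel_size = 1, method = "faces")
  expect_equal(psi, (pi / 6)^(1 / 3), tolerance = 1e-12)

  # any cube gives the same value (shape similarity), including one voxel
  single <- fixture_grid("single_voxel", shape = c(5, 5, 5))
  expect_equal(sphericity(single$labels == 2L, 2, method = "faces"),
               (pi / 6)^(1 / 3), tolerance = 1e-12)
  expect_equal(sphericity(cube$labels == 1L, 0.16, method = "faces"),
               (pi / 6)^(1 / 3), tolerance = 1e-12)

  expect_error(sphericity(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("the mesh estimator is accurate for a digital ball", {
  ball <- fixture_grid("digital_ball", shape = c(36, 36, 36), radius = 12)
  psi <- sphericity(ball$labels == 2L, voxel_size = 1, method = "mesh")
  expect_lt(abs(psi - 1), 0.03)
  # face counting overestimates curved area, biasing psi low
  psi_faces <- sphericity(ball$labels == 2L, 1, method = "faces")
  expect_lt(psi_faces, 0.72)
})

test_that("sphericity is invariant under translation and axis permutation", {
  base <- array(FALSE, c(30, 30, 30))
  ctr <- as.matrix(expand.grid(1:8, 1:5, 1:3))  # a brick
  base[ctr + 5] <- TRUE
  shifted <- array(FALSE, c(30, 30, 30))
  shifted[ctr + 12] <- TRUE
  permuted <- aperm(base, c(3, 1, 2))
  for (meth in c("faces", "mesh")) {
    p0 <- sphericity(base, 1, meth)
    expect_equal(sphericity(shifted, 1, meth), p0, tolerance = 1e-9)
    expect_equal(sphericity(permuted, 1, meth), p0, tolerance = 1e-9)
  }
})

test_that("the ball maximizes sphericity over a fixture family", {
  shapes <- list(
    ball = fixture_grid("digital_ball", shape = c(30, 30, 30), radius = 9)$labels == 2L,
    cube = fixture_grid("all_solid_box", shape = c(15, 15, 15))$labels == 1L,
    rod = {
      m <- array(FALSE, c(40, 8, 8)); m[1:36, 3:6, 3:6] <- TRUE; m
    },
    plate = {
      m <- array(FALSE, c(30, 30, 6)); m[2:29, 2:29, 3:4] <- TRUE; m
    }
  )
  psis <- vapply(shapes, sphericity, numeric(1), voxel_size = 1, method = "mesh")
  expect_identical(names(which.max(psis)), "ball")
  expect_lt(psis["plate"], psis["cube"])
})

test_that("cloud metrics report volume, centroid and gyration consistently", {
  ball <- fixture_grid("digital_ball", shape = c(24, 24, 24), radius = 6,
                       voxel_size = 0.5)
  m <- cloud_metrics(ball)
  expect_identical(m$n_voxels, sum(ball$labels == 2L))
  expect_equal(m$volume, m$n_voxels * 0.5^3)
  expect_equal(m$centroid, (c(24, 24, 24) / 2) * 0.5, tolerance = 1e-9)
  # radius of gyration of a solid ball is sqrt(3/5) r
  expect_equal(m$radius_of_gyration, sqrt(3 / 5) * 6 * 0.5, tolerance = 0.1)
  expect_identical(m$n_components, 1L)
  expect_identical(length(m$sphericity_per_component), 1L)

  none <- cloud_metrics(fixture_grid("all_void_box", shape = c(4, 4, 4)))
  expect_identical(none$n_voxels, 0L)
  expect_identical(none$n_components, 0L)
})

test_that("fill fraction tracks VOID -> CEMENT flips and rejects others", {
  cav <- walled_cavity(inner = c(4, 4, 4))
  expect_equal(fill_fraction(cav$grid, cav$grid), 0)

  full <- cav$grid
  full$labels[full$labels == 0L] <- 2L
  expect_equal(fill_fraction(cav$grid, full), 1)

  bad <- cav$grid
  bad$labels[1, 1, 1] <- 0L  # a bone voxel vanished
  expect_error(fill_fraction(cav$grid, bad), "BONE")

  wrong_size <- fixture_grid("all_void_box", shape = c(3, 3, 3))
  expect_error(fill_fraction(cav$grid, wrong_size), "shape")
})
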