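test_that("achieved porosity matches the target to within one voxel", {
  for (target in c(0.5, 0.69, 0.79, 0.85, 0.95)) {
    g <- generate_open_cell(structure_spec(c(32, 32, 32), target, seed = 2))
    expect_lte(abs(porosity(g) - target), 1 / 32^3)
  }
})

test_that("generation is deterministic and degenerate targets are rejected", {
  spec <- structure_spec(c(24, 24, 24), 0.8, seed = 17)
  g1 <- generate_open_cell(spec)
  g2 <- generate_open_cell(spec)
  expect_identical(g1$labels, g2$labels)
  expect_error(structure_spec(c(16, 16, 16), 1), "strictly between")
  expect_error(structure_spec(c(16, 16, 16), 0), "strictly between")
})

test_that("the void phase is open-cell: one dominant spanning component", {
  for (target in c(0.85, 0.79, 0.69)) {
    fracs <- vapply(1:10, function(s) {
      g <- generate_open_cell(structure_spec(c(64, 64, 64), target, seed = 100 + s))
      comp <- array(
        voxcem:::cc_label_cpp(as.integer(g$labels == 0L), dim(g), 26L),
        dim = dim(g)
      )
      sizes <- tabulate(comp[comp > 0])
      max(sizes) / sum(sizes)
    }, numeric(1))
    expect_gte(mean(fracs), 0.99)
  }
})

test_that("wall padding is BONE on the lateral faces only", {
  g <- generate_open_cell(structure_spec(c(20, 20, 20), 0.8, seed = 5,
                                         wall_thickness = 2))
  expect_true(all(g$labels[1:2, , ] == 1L))
  expect_true(all(g$labels[19:20, , ] == 1L))
  expect_true(all(g$labels[, 1:2, ] == 1L))
  expect_true(any(g$labels[, , 1] == 0L))  # k faces stay open for injection
})

test_that("fixture grids have their closed-form properties", {
  expect_equal(porosity(fixture_grid("all_solid_box", shape = c(8, 8, 8))), 0)

  ball <- fixture_grid("digital_ball", shape = c(32, 32, 32), radius = 10)
  n_ball <- sum(ball$labels == 2L)
  expect_identical(n_ball, ball_lattice_count(32, 10))
  expect_lt(abs(n_ball - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.01)

  slab <- fixture_grid("slab_series", shape = c(6, 6, 8))
  expect_true(all(slab$labels[, , 1:4] == 1L))
  expect_true(all(slab$labels[, , 5:8] == 2L))

  cols <- fixture_grid("column_parallel", shape = c(8, 6, 6))
  expect_true(all(cols$labels[1:4, , ] == 1L))
  expect_true(all(cols$labels[5:8, , ] == 2L))

  single <- fixture_grid("single_voxel", shape = c(5, 5, 5))
  expect_identical(sum(single$labels == 2L), 1L)
})
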