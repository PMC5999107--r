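test_that("particle count follows the volume / voxel-volume mass balance", {
  expect_identical(compute_num_particles(4, 0.16), 976562)
  expect_identical(compute_num_particles(0, 0.16), 0)
  expect_identical(compute_num_particles(0.16^3 / 1000, 0.16), 1)
  expect_error(compute_num_particles(1, 0), "positive")
})

test_that("a single vacant offset is chosen with probability one", {
  labels <- array(1L, c(3, 3, 3))
  labels[2, 2, 2] <- 0L  # particle position
  labels[2, 2, 3] <- 0L  # the only vacancy
  g <- voxel_grid(labels, 1)
  m <- direction_model("vertical")
  for (s in 1:20) {
    out <- sample_step(c(2, 2, 2), g, m, jump_size = 1)
    expect_false(out$blocked)
    expect_identical(out$pos, c(2L, 2L, 3L))
  }
})

test_that("jumps truncate at obstacles instead of tunnelling", {
  # open corridor along +k, bone wall two voxels ahead
  labels <- array(1L, c(3, 3, 8))
  labels[2, 2, 2:4] <- 0L  # positions 2 (start), 3, 4 free; 5 is bone
  g <- voxel_grid(labels, 1)
  m <- direction_model("vertical")
  out <- sample_step(c(2, 2, 2), g, m, jump_size = 5)
  expect_identical(out$pos, c(2L, 2L, 4L))  # exactly 2 voxels of travel

  # fully enclosed particle is blocked, not an error
  solid <- array(1L, c(3, 3, 3))
  solid[2, 2, 2] <- 0L
  blocked <- sample_step(c(2, 2, 2), voxel_grid(solid, 1), m)
  expect_true(blocked$blocked)
})

test_that("particles never remain in place when an offset is admissible", {
  g <- fixture_grid("all_void_box", shape = c(7, 7, 7))
  m <- direction_model("diagonal")
  for (jump in c(1L, 5L)) {
    d <- sample_steps(c(4, 4, 4), g, m, jump_size = jump, n = 500)
    expect_true(all(rowSums(abs(d)) > 0))
    expect_lte(max(abs(d)), jump)
  }
})

test_that("settlement prefers the current voxel, then nearby shells", {
  g <- fixture_grid("all_void_box", shape = c(5, 5, 5))
  out <- settle_particle(c(3, 3, 3), g)
  expect_false(out$blocked)
  expect_identical(out$pos, c(3L, 3L, 3L))

  labels <- array(1L, c(3, 3, 3))
  labels[2, 2, 2] <- 2L  # occupied by cement
  labels[1, 1, 1] <- 0L  # single vacancy in the shell
  out <- settle_particle(c(2, 2, 2), voxel_grid(labels, 1))
  expect_identical(out$pos, c(1L, 1L, 1L))

  solid <- fixture_grid("all_solid_box", shape = c(9, 9, 9))
  out <- settle_particle(c(5, 5, 5), solid, max_radius = 1)
  expect_true(out$blocked)
})

test_that("injection conserves bone, counts settled cement, and is reproducible", {
  g <- generate_open_cell(structure_spec(c(32, 32, 32), 0.8, seed = 4,
                                         voxel_size = 0.16))
  entry <- find_entry(g)
  cfg <- injection_config(V_cement_ml = 0.003, viscosity = "high",
                          direction = "vertical", entry = entry, seed = 9)
  out <- run_injection(g, cfg)

  expect_identical(which(out$grid$labels == 1L), which(g$labels == 1L))
  expect_identical(sum(out$grid$labels == 2L), out$result$n_settled)
  expect_equal(out$result$n_settled + out$result$n_blocked,
               out$result$n_requested)
  changed <- g$labels != out$grid$labels
  expect_true(all(g$labels[changed] == 0L))

  # settled volume never exceeds the requested volume
  expect_lte(out$result$n_settled * 0.16^3, cfg$V_cement_ml * 1000)

  out2 <- run_injection(g, cfg)
  expect_identical(out$result$settled_positions, out2$result$settled_positions)

  # every settled voxel is reachable from the entry through void or cement
  comp <- array(
    voxcem:::cc_label_cpp(as.integer(out$grid$labels != 1L), dim(g), 26L),
    dim = dim(g)
  )
  entry_comp <- comp[entry[1], entry[2], entry[3]]
  pos <- out$result$settled_positions
  expect_true(all(comp[cbind(pos[, 1], pos[, 2], pos[, 3])] == entry_comp))
})

test_that("one particle settles exactly one voxel; entry is validated", {
  g <- fixture_grid("all_void_box", shape = c(10, 10, 10), voxel_size = 1)
  cfg <- injection_config(V_cement_ml = 0.001, viscosity = "high",
                          direction = "vertical", entry = c(5, 5, 1), seed = 1)
  out <- run_injection(g, cfg)
  expect_identical(out$result$n_settled, 1L)
  expect_identical(sum(out$grid$labels == 2L), 1L)

  solid <- fixture_grid("all_solid_box", shape = c(10, 10, 10))
  expect_error(run_injection(solid, cfg), "not VOID")
  cfg_out <- injection_config(0.001, "high", "vertical", c(99, 1, 1), seed = 1)
  expect_error(run_injection(g, cfg_out), "outside")
})

test_that("vertical injection drifts the cloud upward from the entry", {
  g <- fixture_grid("all_void_box", shape = c(21, 21, 40), voxel_size = 1)
  ks <- vapply(1:10, function(s) {
    cfg <- injection_config(V_cement_ml = 0.05, viscosity = "high",
                            direction = "vertical", entry = c(11, 11, 2),
                            seed = s)
    mean(run_injection(g, cfg)$result$settled_positions[, 3])
  }, numeric(1))
  expect_gt(mean(ks), 2)  # positive drift (exact rate 215/269 per step)
})

test_that("low viscosity spreads the cloud wider than high viscosity", {
  g <- generate_open_cell(structure_spec(c(32, 32, 32), 0.8, seed = 21,
                                         voxel_size = 0.16))
  entry <- find_entry(g)
  rg <- function(visc, s) {
    cfg <- injection_config(0.002, visc, "vertical", entry, seed = 400 + s)
    out <- run_injection(g, cfg)
    cloud_metrics(out$grid, method = "faces")$radius_of_gyration
  }
  rg_high <- vapply(1:10, function(s) rg("high", s), numeric(1))
  rg_low <- vapply(1:10, function(s) rg("low", s), numeric(1))
  expect_gt(mean(rg_low), mean(rg_high))
})
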