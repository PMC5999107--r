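test_that("probability classes solve the ratio chains exactly", {
  v <- direction_model("vertical")
  expect_identical(unname(p1_fraction(v)), c(150L, 269L))
  expect_identical(v$class_sizes, c(1L, 8L, 8L, 9L))
  # p2 = 10/269, p3 = 3/269, p4 = 5/807 from the 15:50:90 chain
  expect_identical(v$prob_num, c(150L, 10L, 3L, 5L))
  expect_identical(v$prob_den, c(269L, 269L, 269L, 807L))

  d <- direction_model("diagonal")
  expect_identical(unname(p1_fraction(d)), c(90L, 163L))
  expect_identical(d$class_sizes, c(1L, 2L, 4L, 19L))

  expect_error(direction_model("sideways"))
})

test_that("normalization holds in exact integer arithmetic", {
  for (dir in c("vertical", "diagonal")) {
    m <- direction_model(dir)
    den <- Reduce(voxcem:::lcm_int, m$prob_den)
    total <- sum(m$class_sizes * m$prob_num * (den / m$prob_den))
    expect_identical(total, den)  # sum n_i p_i == 1 as integers
    expect_true(all(diff(m$prob_num / m$prob_den) < 0))  # p1 > p2 > p3 > p4
    expect_true(all(m$prob_num > 0))
  }
})

test_that("the model enumerates the 26-voxel Moore neighbourhood", {
  for (dir in c("vertical", "diagonal")) {
    m <- direction_model(dir)
    expect_identical(nrow(m$offsets), 26L)
    expect_identical(nrow(unique(m$offsets)), 26L)
    expect_true(all(m$offsets %in% -1:1))
    expect_false(any(rowSums(abs(m$offsets)) == 0))
    expect_identical(sum(m$class_sizes), 26L)
    expect_identical(tabulate(m$class_of_offset, 4L), m$class_sizes)
  }
})

test_that("class geometry matches the stated partitions", {
  v <- direction_model("vertical")
  off_of <- function(m, cls) m$offsets[m$class_of_offset == cls, , drop = FALSE]
  expect_equal(unname(off_of(v, 1)), matrix(c(0L, 0L, 1L), 1))
  expect_true(all(off_of(v, 2)[, 3] == 1L))
  expect_true(all(off_of(v, 3)[, 3] == 0L))
  expect_true(all(off_of(v, 4)[, 3] == -1L))

  d <- direction_model("diagonal")
  expect_equal(unname(off_of(d, 1)), matrix(c(1L, 0L, 1L), 1))
  c2 <- off_of(d, 2)
  expect_true(all(c2[, 1] == 1L & c2[, 3] == 1L & abs(c2[, 2]) == 1L))
})

test_that("mean free-space drift equals the exact class-probability sum", {
  v <- direction_model("vertical")
  expect_equal(step_drift(v), c(0, 0, 215 / 269), tolerance = 1e-12)
  # brute-force oracle: enumerate the 26 offsets against their class probs
  drift_bf <- colSums(v$offsets * (v$prob_num[v$class_of_offset] /
                                     v$prob_den[v$class_of_offset]))
  expect_equal(unname(drift_bf[3]), 215 / 269, tolerance = 1e-15)

  d <- direction_model("diagonal")
  dd <- step_drift(d)
  expect_gt(dd[1], 0)  # drift points along the preferred oblique direction
  expect_gt(dd[3], 0)
  expect_equal(dd[2], 0, tolerance = 1e-12)
})
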