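test_that("grids roundtrip bit-faithfully through every supported format", {
  g <- fixture_grid("digital_ball", shape = c(9, 7, 11), radius = 3,
                    voxel_size = 0.16)
  g$labels[1, 1, 1] <- 1L  # all three labels present

  for (ext in c("mhd", "tiff", "rds")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_grid(g, path)
    vs <- if (ext == "tiff") 0.16 else NULL
    back <- read_grid(path, voxel_size = vs)
    expect_identical(back$labels, g$labels, label = ext)
    expect_equal(back$voxel_size, g$voxel_size)
  }
})

test_that("counts survive a roundtrip and empty grids stay empty", {
  g <- fixture_grid("all_solid_box", shape = c(2, 2, 2))
  path <- tempfile(fileext = ".mhd")
  write_grid(g, path)
  expect_identical(unname(label_counts(read_grid(path))[["BONE"]]), 8L)

  v <- fixture_grid("all_void_box", shape = c(4, 4, 4))
  pv <- tempfile(fileext = ".mhd")
  write_grid(v, pv)
  expect_identical(unname(label_counts(read_grid(pv))[["BONE"]]), 0L)
})

test_that("MetaImage metadata carries the voxel size and origin", {
  g <- voxel_grid(array(0L, c(3, 3, 3)), voxel_size = 0.25,
                  origin = c(1, 2, 3))
  path <- tempfile(fileext = ".mhd")
  write_grid(g, path)
  hdr <- readLines(path)
  expect_true(any(grepl("^ElementSpacing = 0.25 0.25 0.25", hdr)))
  expect_true(any(grepl("^ElementType = MET_UCHAR", hdr)))
  back <- read_grid(path)
  expect_equal(back$origin, c(1, 2, 3))
})

test_that("stored labels outside {0,1,2} are an error naming the value", {
  g <- fixture_grid("all_void_box", shape = c(2, 2, 2))
  path <- tempfile(fileext = ".mhd")
  write_grid(g, path)
  raw_path <- sub("\\.mhd$", ".raw", path)
  bytes <- readBin(raw_path, "raw", n = 8)
  bytes[3] <- as.raw(7)
  writeBin(bytes, raw_path)
  expect_error(read_grid(path), "7")
})

test_that("constructor rejects malformed grids", {
  expect_error(voxel_grid(array(3L, c(2, 2, 2)), 1), "labels")
  expect_error(voxel_grid(array(0L, c(2, 2, 2)), -1), "voxel_size")
  expect_error(voxel_grid(array(0L, c(2, 2, 2)), c(1, 1, 2)), "anisotropic")
  expect_error(voxel_grid(matrix(0L, 2, 2), 1), "3-D")
  expect_error(read_grid(tempfile(fileext = ".mhd")), "not found")
})

test_that("porosity counts cement as solid and is invariant under axis moves", {
  expect_equal(porosity(fixture_grid("all_void_box", shape = c(4, 4, 4))), 1)
  expect_equal(porosity(fixture_grid("all_solid_box", shape = c(4, 4, 4))), 0)
  expect_equal(porosity(fixture_grid("slab_series", shape = c(4, 4, 4))), 0)

  g <- generate_open_cell(structure_spec(c(16, 16, 16), 0.7, seed = 3))
  p0 <- porosity(g)
  perm <- voxel_grid(aperm(g$labels, c(3, 1, 2)), g$voxel_size)
  flip <- voxel_grid(g$labels[dim(g)[1]:1, , ], g$voxel_size)
  expect_equal(porosity(perm), p0)
  expect_equal(porosity(flip), p0)
})
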