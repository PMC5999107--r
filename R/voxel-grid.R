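#' Labeled voxel grid
#'
#' The shared substrate of all modules: a dense 3-D array of occupancy labels
#' (`VOID = 0`, `BONE = 1`, `CEMENT = 2`) on an isotropic lattice with a
#' physical voxel size in millimetres.  Index convention: 1-based `(i, j, k)`
#' with `k` the injection/compression ("vertical") axis; the physical centre
#' of voxel `(i, j, k)` is `origin + (c(i, j, k) - 0.5) * voxel_size`.
#'
#' @param labels 3-D integer array (or vector with `dim`) over `{0, 1, 2}`.
#' @param voxel_size Isotropic edge length of a voxel, in mm.  Must be a
#'   single positive number; anisotropic spacings are rejected, not resampled.
#' @param origin Physical position (mm) of the corner of voxel `(1, 1, 1)`.
#'
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(array(0L, c(4, 4, 4)), voxel_size = 0.16)
#' porosity(g)
voxel_grid <- function(labels, voxel_size, origin = c(0, 0, 0)) {
  if (is.null(dim(labels)) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3-D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  bad <- !(labels %in% c(VOID, BONE, CEMENT))
  if (any(bad)) {
    stop(
      "labels outside {0, 1, 2} found (e.g. value ",
      labels[which(bad)[1L]], ")",
      call. = FALSE
    )
  }
  if (length(voxel_size) == 3L) {
    if (length(unique(voxel_size)) != 1L) {
      stop("anisotropic voxel sizes are not supported: ",
           paste(voxel_size, collapse = " x "), call. = FALSE)
    }
    voxel_size <- voxel_size[1L]
  }
  if (length(voxel_size) != 1L || !is.finite(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number (mm)", call. = FALSE)
  }
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(
    list(
      labels = labels,
      voxel_size = as.numeric(voxel_size),
      origin = as.numeric(origin)
    ),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$labels)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  n <- prod(d)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d @ %g mm (%.4g x %.4g x %.4g mm)\n",
    d[1], d[2], d[3], x$voxel_size,
    d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size
  ))
  cnt <- label_counts(x)
  cat(sprintf(
    "  VOID %d (%.1f%%) | BONE %d (%.1f%%) | CEMENT %d (%.1f%%)\n",
    cnt[["VOID"]], 100 * cnt[["VOID"]] / n,
    cnt[["BONE"]], 100 * cnt[["BONE"]] / n,
    cnt[["CEMENT"]], 100 * cnt[["CEMENT"]] / n
  ))
  invisible(x)
}

#' Count voxels per label
#'
#' @param grid A [voxel_grid()].
#' @return Named integer vector with counts for VOID, BONE and CEMENT.
#' @export
label_counts <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  c(
    VOID = sum(grid$labels == VOID),
    BONE = sum(grid$labels == BONE),
    CEMENT = sum(grid$labels == CEMENT)
  )
}

#' Porosity of a voxel grid
#'
#' Fraction of voxels labelled VOID.  Cement counts as solid, so porosity
#' decreases as an injection fills the pore space.
#'
#' @param grid A [voxel_grid()].
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' porosity(fixture_grid("all_void_box", shape = c(8, 8, 8)))
porosity <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  mean(grid$labels == VOID)
}

#' Physical centre coordinates of voxels
#'
#' @param grid A [voxel_grid()].
#' @param idx Integer matrix (n x 3) of 1-based voxel indices.
#' @return Numeric matrix (n x 3) of positions in mm.
#' @export
voxel_centers <- function(grid, idx) {
  stopifnot(inherits(grid, "voxel_grid"))
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep((idx - 0.5) * grid$voxel_size, 2L, grid$origin, "+")
}
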