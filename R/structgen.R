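#' Specification of a synthetic open-cell structure
#'
#' Parameters of the Gaussian-random-field generator used to emulate
#' open-cell (Sawbones-like) trabecular surrogates at a prescribed porosity.
#'
#' @param shape Integer triple: grid dimensions in voxels.
#' @param target_porosity Void fraction in (0, 1) before wall padding.
#' @param correlation_length Smoothing kernel scale in voxels (>= 1); sets the
#'   strut/pore length scale.
#' @param seed RNG seed.
#' @param wall_thickness BONE padding (in voxels) added to the four lateral
#'   faces after porosity matching, emulating the rigid confining shell.
#' @param voxel_size Voxel edge length in mm.
#' @param method `"struts"` (default) thresholds the pointwise maximum of the
#'   absolute values of two independent smoothed Gaussian fields, placing the
#'   solid in a thin neighbourhood of the intersection of their zero
#'   surfaces: a rod-like, well-connected strut network like open-cell foam.
#'   `"blobs"` thresholds a single smoothed field directly; simpler, but the
#'   solid phase fragments near 85% porosity (it sits close to the
#'   percolation threshold of level sets).
#'
#' @return An object of class `structure_spec`.
#' @export
structure_spec <- function(shape = c(64, 64, 64), target_porosity,
                           correlation_length = 3, seed = 1,
                           wall_thickness = 0, voxel_size = 0.16,
                           method = c("struts", "blobs")) {
  method <- match.arg(method)
  stopifnot(length(shape) == 3L, all(shape >= 2))
  if (!is.numeric(target_porosity) || target_porosity <= 0 || target_porosity >= 1) {
    stop("`target_porosity` must be strictly between 0 and 1; use ",
         "fixture_grid() for degenerate all-void/all-solid grids", call. = FALSE)
  }
  stopifnot(correlation_length >= 1, wall_thickness >= 0, voxel_size > 0)
  structure(
    list(
      shape = as.integer(shape),
      target_porosity = target_porosity,
      correlation_length = correlation_length,
      seed = as.integer(seed),
      wall_thickness = as.integer(wall_thickness),
      voxel_size = voxel_size,
      method = method
    ),
    class = "structure_spec"
  )
}

# Periodic Gaussian smoothing of a 3-D array via FFT.
gaussian_smooth_fft <- function(arr, sigma) {
  d <- dim(arr)
  ax <- lapply(d, function(n) {
    x <- ((seq_len(n) - 1 + n %/% 2) %% n) - n %/% 2
    exp(-x^2 / (2 * sigma^2))
  })
  ker <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  ker <- ker / sum(ker)
  Re(fft(fft(arr) * fft(ker), inverse = TRUE)) / prod(d)
}

#' Generate a synthetic open-cell structure
#'
#' Builds a scalar field from Gaussian white noise smoothed with an isotropic
#' kernel of scale `correlation_length` (see the `method` argument of
#' [structure_spec()] for the two field constructions) and thresholds it at
#' the exact quantile of `target_porosity`, so the achieved porosity matches
#' the target to within one voxel by construction.  The void phase is
#' required to contain a connected component (26-connectivity) spanning the
#' injection (k) axis; if it does not, the field is redrawn with an
#' incremented seed up to `max_retries` times.
#'
#' @param spec A [structure_spec()].
#' @param max_retries Redraw budget for the percolation requirement.
#' @return A [voxel_grid()] of BONE/VOID with attributes `spec` (the
#'   generating spec) and `interior_porosity` (achieved porosity before wall
#'   padding).
#' @export
#' @examples
#' g <- generate_open_cell(structure_spec(c(32, 32, 32), 0.85, seed = 7))
#' porosity(g)
generate_open_cell <- function(spec, max_retries = 20) {
  stopifnot(inherits(spec, "structure_spec"))
  d <- spec$shape
  n <- prod(d)
  n_void <- round(spec$target_porosity * n)

  for (attempt in 0:max_retries) {
    field <- with_seed(spec$seed + attempt, {
      if (spec$method == "struts") {
        f1 <- gaussian_smooth_fft(array(rnorm(n), dim = d), spec$correlation_length)
        f2 <- gaussian_smooth_fft(array(rnorm(n), dim = d), spec$correlation_length)
        # solid where BOTH fields are near zero -> rods along the
        # intersection curves of the two zero surfaces; negate so that
        # small values of `field` are VOID, as for the single-field case
        -pmax(abs(f1) / sd(f1), abs(f2) / sd(f2))
      } else {
        gaussian_smooth_fft(array(rnorm(n), dim = d), spec$correlation_length)
      }
    })
    # exact-quantile threshold: the n_void smallest field values become VOID
    ord <- order(field)
    labels <- array(BONE, dim = d)
    labels[ord[seq_len(n_void)]] <- VOID
    if (void_percolates(labels, d)) {
      interior_por <- n_void / n
      if (spec$wall_thickness > 0) labels <- pad_walls(labels, spec$wall_thickness)
      g <- voxel_grid(labels, spec$voxel_size)
      attr(g, "spec") <- spec
      attr(g, "interior_porosity") <- interior_por
      attr(g, "seed_used") <- spec$seed + attempt
      return(g)
    }
  }
  stop("no percolating void phase after ", max_retries + 1,
       " draws (porosity ", spec$target_porosity,
       ", correlation length ", spec$correlation_length, ")", call. = FALSE)
}

# TRUE when some 26-connected VOID component touches both k = 1 and k = nz.
void_percolates <- function(labels, d) {
  comp <- array(
    cc_label_cpp(as.integer(labels == VOID), as.integer(d), 26L),
    dim = d
  )
  bottom <- unique(comp[, , 1L])
  top <- unique(comp[, , d[3]])
  any(setdiff(intersect(bottom, top), 0L) > 0L)
}

pad_walls <- function(labels, w) {
  d <- dim(labels)
  labels[c(seq_len(w), d[1] - seq_len(w) + 1L), , ] <- BONE
  labels[, c(seq_len(w), d[2] - seq_len(w) + 1L), ] <- BONE
  labels
}

#' Deterministic fixture grids
#'
#' Canonical grids with closed-form properties, used as oracles throughout
#' the test-suite and documentation:
#' \describe{
#'   \item{all_void_box / all_solid_box}{uniform VOID / BONE boxes.}
#'   \item{slab_series}{bottom half of the k-layers BONE, top half CEMENT:
#'     two phases stacked along the load axis (Reuss/series composite).}
#'   \item{column_parallel}{left half of the i-columns BONE, right half
#'     CEMENT, full height (Voigt/parallel composite).}
#'   \item{digital_ball}{CEMENT voxels whose centre lies within `radius`
#'     voxels of the grid centre, in VOID.}
#'   \item{single_voxel}{one CEMENT voxel at the grid centre, in VOID.}
#' }
#'
#' @param name Fixture name (see above).
#' @param shape Integer triple of grid dimensions.
#' @param radius Ball radius in voxels (digital_ball only).
#' @param voxel_size Voxel edge length in mm.
#' @return A [voxel_grid()].
#' @export
#' @examples
#' porosity(fixture_grid("all_solid_box", shape = c(8, 8, 8)))
fixture_grid <- function(name = c("all_void_box", "all_solid_box", "slab_series",
                                  "column_parallel", "digital_ball", "single_voxel"),
                         shape = c(16, 16, 16), radius = 5, voxel_size = 1) {
  name <- match.arg(name)
  d <- as.integer(shape)
  stopifnot(length(d) == 3L, all(d >= 1))
  labels <- array(VOID, dim = d)
  if (name == "all_solid_box") {
    labels[] <- BONE
  } else if (name == "slab_series") {
    stopifnot(d[3] %% 2L == 0L)
    labels[, , seq_len(d[3] %/% 2L)] <- BONE
    labels[, , (d[3] %/% 2L + 1L):d[3]] <- CEMENT
  } else if (name == "column_parallel") {
    stopifnot(d[1] %% 2L == 0L)
    labels[seq_len(d[1] %/% 2L), , ] <- BONE
    labels[(d[1] %/% 2L + 1L):d[1], , ] <- CEMENT
  } else if (name == "digital_ball") {
    ctr <- (d + 1) / 2
    ii <- slice.index(labels, 1L) - ctr[1]
    jj <- slice.index(labels, 2L) - ctr[2]
    kk <- slice.index(labels, 3L) - ctr[3]
    labels[ii^2 + jj^2 + kk^2 <= radius^2] <- CEMENT
  } else if (name == "single_voxel") {
    ctr <- pmax(1L, d %/% 2L)
    labels[ctr[1], ctr[2], ctr[3]] <- CEMENT
  }
  voxel_grid(labels, voxel_size)
}
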