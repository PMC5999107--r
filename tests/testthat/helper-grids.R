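# Shared grid builders for the test-suite.

# A box of BONE walls enclosing a fully VOID cavity of the given inner
# dimensions; entry at the cavity centre.
walled_cavity <- function(inner = c(6, 6, 6), wall = 1, voxel_size = 1) {
  d <- inner + 2L * wall
  labels <- array(1L, dim = d)
  labels[wall + seq_len(inner[1]), wall + seq_len(inner[2]),
         wall + seq_len(inner[3])] <- 0L
  list(
    grid = voxel_grid(labels, voxel_size),
    entry = as.integer(wall + ceiling(inner / 2)),
    n_void = prod(inner)
  )
}

# Random solid/void grid whose solid phase 6-connects bottom to top; used by
# the FE monotonicity checks.  Draws until a solid column guarantees a path.
random_connected_grid <- function(shape = c(3, 3, 3), p_solid = 0.6,
                                  seed = 1, voxel_size = 1) {
  set.seed(seed)
  labels <- array(ifelse(runif(prod(shape)) < p_solid, 1L, 0L), dim = shape)
  ctr <- pmax(1L, shape %/% 2L)
  labels[ctr[1], ctr[2], ] <- 1L  # guaranteed load path
  voxel_grid(labels, voxel_size)
}

# Count of lattice points within radius r of the centre of an n^3 grid:
# brute-force oracle for the digital-ball fixture.
ball_lattice_count <- function(n, r) {
  ctr <- (n + 1) / 2
  x <- seq_len(n) - ctr
  sum(outer(outer(x^2, x^2, "+"), x^2, "+") <= r^2)
}
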