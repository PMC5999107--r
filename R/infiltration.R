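#' Injection configuration
#'
#' Parameters of one simulated cement injection.  Viscosity enters the model
#' phenomenologically as the per-iteration jump size: high-viscosity cement
#' advances one voxel per iteration, low-viscosity cement five.
#'
#' @param V_cement_ml Injected cement volume in ml (>= 0).
#' @param viscosity `"high"` (jump size 1) or `"low"` (jump size 5).
#' @param direction Injection direction, `"vertical"` or `"diagonal"`
#'   (see [direction_model()]).
#' @param entry 1-based voxel index triple where particles are released;
#'   must be VOID in the starting grid.
#' @param seed RNG seed for the particle walk.
#' @param jump_size Override of the viscosity-derived jump size (voxels).
#' @param max_steps_per_particle Walk length per particle; particles stop
#'   early when no admissible offset remains.
#' @param settle_radius Maximum Chebyshev shell radius searched for a vacant
#'   voxel at settlement; beyond it the particle is counted as blocked.
#'
#' @return An object of class `injection_config`.
#' @export
injection_config <- function(V_cement_ml, viscosity = c("high", "low"),
                             direction = c("vertical", "diagonal"),
                             entry, seed = 1, jump_size = NULL,
                             max_steps_per_particle = 200,
                             settle_radius = 3) {
  viscosity <- match.arg(viscosity)
  direction <- match.arg(direction)
  stopifnot(V_cement_ml >= 0, length(entry) == 3L,
            max_steps_per_particle >= 1, settle_radius >= 1)
  if (is.null(jump_size)) jump_size <- if (viscosity == "high") 1L else 5L
  stopifnot(jump_size >= 1)
  structure(
    list(
      V_cement_ml = V_cement_ml,
      viscosity = viscosity,
      direction = direction,
      entry = as.integer(entry),
      seed = as.integer(seed),
      jump_size = as.integer(jump_size),
      max_steps_per_particle = as.integer(max_steps_per_particle),
      settle_radius = as.integer(settle_radius)
    ),
    class = "injection_config"
  )
}

#' Number of discrete particles for a cement volume
#'
#' Mass balance of the particle model: each settled particle occupies one
#' voxel, so `V_cement = N * voxel_size^3` and
#' `N = floor(V_cement_ml * 1000 / voxel_size^3)`.
#'
#' @param V_cement_ml Cement volume in ml.
#' @param voxel_size Voxel edge length in mm.
#' @return Integer particle count.
#' @export
#' @examples
#' compute_num_particles(4, 0.16)  # 976562
compute_num_particles <- function(V_cement_ml, voxel_size) {
  if (!is.numeric(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be positive", call. = FALSE)
  }
  stopifnot(V_cement_ml >= 0)
  # epsilon guards an exact multiple of the voxel volume against FP round-down
  floor(V_cement_ml * 1000 / voxel_size^3 + 1e-9)
}

#' One biased step of a cement particle
#'
#' The 26 offsets are weighted by their class probabilities; offsets whose
#' immediate neighbour voxel is outside the grid or not VOID are excluded and
#' the remaining weights renormalized.  One offset is drawn and the particle
#' advances up to `jump_size` voxels along it through VOID only, truncating
#' before the first bone/cement/out-of-bounds voxel (no tunnelling).  A
#' particle never remains in place when at least one offset is admissible.
#'
#' @param pos 1-based voxel index triple of the particle.
#' @param grid A [voxel_grid()].
#' @param model A [direction_model()].
#' @param jump_size Maximum displacement along the drawn offset, in voxels.
#' @return List with `pos` (new position), `blocked` (TRUE when no offset was
#'   admissible) and `offset_index` (row of `model$offsets` drawn).
#' @export
sample_step <- function(pos, grid, model, jump_size = 1) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(model, "direction_model"))
  sample_step_cpp(
    as.integer(grid$labels), dim(grid), model$offsets, model$probs,
    as.integer(pos) - 1L, as.integer(jump_size)
  )
}

#' Draw many independent single steps from one position
#'
#' Vectorized form of [sample_step()] for statistical verification of the
#' direction model: `n` independent draws from the same starting position on
#' an unmodified grid.
#'
#' @inheritParams sample_step
#' @param n Number of independent draws.
#' @return Integer matrix (`n` x 3) of displacement vectors.
#' @export
sample_steps <- function(pos, grid, model, jump_size = 1, n = 1000) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(model, "direction_model"))
  sample_steps_cpp(
    as.integer(grid$labels), dim(grid), model$offsets, model$probs,
    as.integer(pos) - 1L, as.integer(jump_size), as.integer(n)
  )
}

#' Settle a cement particle
#'
#' If `pos` is VOID the particle settles there; otherwise a vacant voxel is
#' drawn uniformly from the 26-neighbourhood, and failing that from
#' Chebyshev shells of increasing radius up to `max_radius`.  When no vacancy
#' exists within the search radius the particle is blocked (a recorded
#' outcome, not an error).
#'
#' @inheritParams sample_step
#' @param max_radius Largest Chebyshev shell searched.
#' @return List with `blocked` and (when settled) `pos`.
#' @export
settle_particle <- function(pos, grid, max_radius = 3) {
  stopifnot(inherits(grid, "voxel_grid"))
  settle_cpp(as.integer(grid$labels), dim(grid), as.integer(pos) - 1L,
             as.integer(max_radius))
}

#' Run a full cement injection
#'
#' Releases `compute_num_particles(V, voxel_size)` particles sequentially
#' from the entry voxel.  Each particle performs up to
#' `max_steps_per_particle` biased steps (stopping early when jammed) and
#' then settles; settled voxels become CEMENT and obstruct all subsequent
#' particles ("contact inhibition").  Bone is never overwritten.
#'
#' @param grid A [voxel_grid()]; the entry voxel must be VOID.
#' @param config An [injection_config()].
#' @return A list with `grid` (augmented [voxel_grid()]) and `result`, an
#'   `injection_result` with fields `n_requested`, `n_settled`, `n_blocked`,
#'   `settled_positions` (matrix of 1-based indices), `steps_taken`,
#'   `mass_balance` (settled volume in ml) and the config echo.
#' @export
#' @examples
#' g <- fixture_grid("all_void_box", shape = c(12, 12, 12), voxel_size = 1)
#' cfg <- injection_config(
#'   V_cement_ml = 0.00002, viscosity = "high",
#'   direction = "vertical", entry = c(6, 6, 1), seed = 42
#' )
#' out <- run_injection(g, cfg)
#' out$result$n_settled
run_injection <- function(grid, config) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(config, "injection_config"))
  d <- dim(grid)
  e <- config$entry
  if (any(e < 1L) || any(e > d)) stop("entry voxel outside grid", call. = FALSE)
  if (grid$labels[e[1], e[2], e[3]] != VOID) {
    stop("entry voxel is not VOID", call. = FALSE)
  }
  n <- compute_num_particles(config$V_cement_ml, grid$voxel_size)
  model <- direction_model(config$direction)

  if (n == 0) {
    res <- walk_result(grid, config, n, matrix(integer(0), 0, 3), 0, integer(0))
    return(list(grid = grid, result = res))
  }

  raw <- with_seed(config$seed, {
    walk_injection_cpp(
      as.integer(grid$labels), d, model$offsets, model$probs,
      as.numeric(n), e - 1L, config$jump_size,
      config$max_steps_per_particle, config$settle_radius
    )
  })

  aug <- voxel_grid(array(raw$labels, dim = d), grid$voxel_size, grid$origin)
  res <- walk_result(grid, config, n, raw$settled, raw$n_blocked, raw$steps_taken)
  list(grid = aug, result = res)
}

walk_result <- function(grid, config, n_requested, settled, n_blocked, steps) {
  structure(
    list(
      n_requested = as.numeric(n_requested),
      n_settled = nrow(settled),
      n_blocked = as.numeric(n_blocked),
      settled_positions = settled,
      steps_taken = steps,
      settled_volume_ml = nrow(settled) * grid$voxel_size^3 / 1000,
      voxel_size = grid$voxel_size,
      config = config
    ),
    class = "injection_result"
  )
}

#' Find an entry voxel for injection
#'
#' Returns the VOID voxel nearest (squared Euclidean distance on indices) to
#' a requested position, by default the centre of the bottom (k = 1) face —
#' the drilled entry point of the injection.
#'
#' @param grid A [voxel_grid()].
#' @param near 1-based index triple to search from; default bottom-centre.
#' @return Integer index triple of a VOID voxel.
#' @export
find_entry <- function(grid, near = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid)
  if (is.null(near)) near <- c(ceiling(d[1] / 2), ceiling(d[2] / 2), 1)
  void_idx <- which(grid$labels == VOID, arr.ind = TRUE)
  if (nrow(void_idx) == 0) stop("grid contains no VOID voxel", call. = FALSE)
  d2 <- colSums((t(void_idx) - near)^2)
  as.integer(void_idx[which.min(d2), ])
}

#' @export
print.injection_result <- function(x, ...) {
  cat(sprintf(
    "<injection_result> %s viscosity (jump %d), %s direction\n",
    x$config$viscosity, x$config$jump_size, x$config$direction
  ))
  cat(sprintf(
    "  requested %s, settled %s, blocked %s (%.4g ml of %.4g ml placed)\n",
    format(x$n_requested, big.mark = ","), format(x$n_settled, big.mark = ","),
    format(x$n_blocked, big.mark = ","),
    x$settled_volume_ml, x$config$V_cement_ml
  ))
  invisible(x)
}

#' @export
glance.injection_result <- function(x, ...) {
  tibble::tibble(
    n_requested = x$n_requested,
    n_settled = x$n_settled,
    n_blocked = x$n_blocked,
    settled_volume_ml = x$settled_volume_ml,
    viscosity = x$config$viscosity,
    direction = x$config$direction,
    jump_size = x$config$jump_size,
    seed = x$config$seed
  )
}

#' @export
tidy.injection_result <- function(x, ...) {
  pos <- x$settled_positions
  tibble::tibble(
    particle = seq_len(nrow(pos)),
    i = pos[, 1],
    j = pos[, 2],
    k = pos[, 3]
  )
}
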