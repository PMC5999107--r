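#' Anisotropic direction model over the 26-voxel Moore neighbourhood
#'
#' Partitions the 26 nonzero offsets in \{-1, 0, 1\}^3 into four probability
#' classes and solves the per-offset probabilities exactly from a ratio chain
#' and the normalization `sum(n_i * p_i) = 1`:
#'
#' * `vertical` (preferred direction `(0, 0, +1)`): ratio chain
#'   `p1 = 15 p2 = 50 p3 = 90 p4` with class sizes `(1, 8, 8, 9)` —
#'   class 1 is the on-axis forward offset, class 2 the 8 remaining
#'   forward-layer offsets, class 3 the 8 same-layer lateral offsets and
#'   class 4 the 9 backward-layer offsets.  This yields `p1 = 150/269`.
#' * `diagonal` (preferred direction `(+1, 0, +1)`): ratio chain
#'   `p1 = 5 p2 = 20 p3 = 90 p4` with class sizes `(1, 2, 4, 19)` —
#'   class 1 the preferred edge-diagonal, class 2 its two adjacent body
#'   diagonals `(+1, +1, +1)` and `(+1, -1, +1)`, class 3 the four offsets
#'   next closest in angle to the preferred direction (ties broken
#'   lexicographically) and class 4 the remaining 19.  This yields
#'   `p1 = 90/163`.
#'
#' Probabilities are carried as exact integer fractions (`prob_num`,
#' `prob_den` per class) alongside their floating-point values; floating
#' conversion happens only at sampling time.
#'
#' @param direction `"vertical"` or `"diagonal"`.
#' @return An object of class `direction_model` with fields `direction`,
#'   `offsets` (26 x 3 integer matrix), `class_of_offset` (length 26),
#'   `class_sizes`, `prob_num`/`prob_den` (per class, reduced), and `probs`
#'   (numeric, per offset).
#' @export
#' @examples
#' m <- direction_model("vertical")
#' m$prob_num[1] / m$prob_den[1]  # 150/269
direction_model <- function(direction = c("vertical", "diagonal")) {
  direction <- match.arg(direction)
  offs <- moore_offsets()

  if (direction == "vertical") {
    ratio <- c(1, 15, 50, 90)
    cls <- integer(26)
    cls[offs[, 3] == 1] <- 2L
    cls[offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 1] <- 1L
    cls[offs[, 3] == 0] <- 3L
    cls[offs[, 3] == -1] <- 4L
  } else {
    ratio <- c(1, 5, 20, 90)
    pref <- c(1, 0, 1)
    cls <- rep(4L, 26)
    is_class1 <- offs[, 1] == 1 & offs[, 2] == 0 & offs[, 3] == 1
    is_class2 <- offs[, 1] == 1 & abs(offs[, 2]) == 1 & offs[, 3] == 1
    cls[is_class1] <- 1L
    cls[is_class2] <- 2L
    # class 3: the four remaining offsets closest in angle to the preferred
    # direction, ties broken lexicographically on (di, dj, dk)
    rest <- which(!(is_class1 | is_class2))
    ang <- acos(pmin(1, (offs[rest, , drop = FALSE] %*% pref) /
                       (sqrt(rowSums(offs[rest, , drop = FALSE]^2)) * sqrt(2))))
    ord <- rest[order(ang, offs[rest, 1], offs[rest, 2], offs[rest, 3])]
    cls[ord[1:4]] <- 3L
  }

  n_cls <- tabulate(cls, nbins = 4L)
  pr <- solve_class_probs(n_cls, ratio)
  probs <- pr$num[cls] / pr$den[cls]

  structure(
    list(
      direction = direction,
      offsets = offs,
      class_of_offset = cls,
      class_sizes = n_cls,
      ratio = ratio,
      prob_num = pr$num,
      prob_den = pr$den,
      probs = probs
    ),
    class = "direction_model"
  )
}

# All 26 nonzero offsets of the Moore neighbourhood, in a fixed
# lexicographic order on (di, dj, dk).
moore_offsets <- function() {
  g <- expand.grid(dk = -1:1, dj = -1:1, di = -1:1)[, 3:1]
  g <- as.matrix(g[order(g[, 1], g[, 2], g[, 3]), ])
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  dimnames(g) <- list(NULL, c("di", "dj", "dk"))
  storage.mode(g) <- "integer"
  g
}

# Solve p1 = ratio[i] * p_i under sum(n_i p_i) = 1, exactly in integers:
# with D = lcm(ratio), p1 = D / sum(n_i * D / ratio[i]); p_i = p1 / ratio[i].
solve_class_probs <- function(n_cls, ratio) {
  stopifnot(length(n_cls) == 4L, length(ratio) == 4L, sum(n_cls) == 26L)
  D <- Reduce(lcm_int, ratio)
  S <- sum(n_cls * (D / ratio))
  num <- integer(4)
  den <- integer(4)
  for (i in 1:4) {
    f <- reduce_frac(D, S * ratio[i])
    num[i] <- f[1]
    den[i] <- f[2]
  }
  list(num = num, den = den)
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

lcm_int <- function(a, b) a / gcd_int(a, b) * b

reduce_frac <- function(num, den) {
  g <- gcd_int(num, den)
  as.integer(c(num / g, den / g))
}

#' The most-preferred step probability as an irreducible fraction
#'
#' @param model A [direction_model()].
#' @return Integer vector `c(numerator, denominator)` of the class-1
#'   probability in lowest terms (150/269 vertical, 90/163 diagonal).
#' @export
p1_fraction <- function(model) {
  stopifnot(inherits(model, "direction_model"))
  c(numerator = model$prob_num[1], denominator = model$prob_den[1])
}

#' Exact mean displacement per free-space step
#'
#' The expected signed displacement (in voxels, per unit jump) along each
#' axis for a single unconstrained step, computed from the exact class
#' probabilities: `sum_o p_o * offset_o`.
#'
#' @param model A [direction_model()].
#' @return Numeric length-3 vector (mean di, dj, dk).
#' @export
#' @examples
#' step_drift(direction_model("vertical"))[3]  # 215/269
step_drift <- function(model) {
  stopifnot(inherits(model, "direction_model"))
  unname(drop(model$probs %*% model$offsets))
}

#' @export
print.direction_model <- function(x, ...) {
  cat(sprintf("<direction_model> %s\n", x$direction))
  for (i in 1:4) {
    cat(sprintf("  class %d: n = %2d, p = %d/%d (%.6f)\n",
                i, x$class_sizes[i], x$prob_num[i], x$prob_den[i],
                x$prob_num[i] / x$prob_den[i]))
  }
  invisible(x)
}
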