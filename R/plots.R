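#' Plot a slice of a voxel grid
#'
#' Raster image of one k-slice with the three labels colour-coded
#' (void white, bone grey, cement red) — the quickest way to inspect a
#' structure or an injected cement cloud.
#'
#' @param grid A [voxel_grid()].
#' @param k Slice index along the third axis; default mid-plane.
#' @return A ggplot object.
#' @export
plot_slice <- function(grid, k = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid)
  if (is.null(k)) k <- ceiling(d[3] / 2)
  stopifnot(k >= 1, k <= d[3])
  sl <- grid$labels[, , k]
  df <- tibble::tibble(
    i = rep(seq_len(d[1]), times = d[2]),
    j = rep(seq_len(d[2]), each = d[1]),
    label = factor(as.vector(sl), levels = c(0, 1, 2),
                   labels = c("void", "bone", "cement"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(void = "white", bone = "grey55", cement = "firebrick"),
      drop = FALSE
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("slice k = %d", k), x = "i", y = "j") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.voxel_grid <- function(object, k = NULL, ...) {
  plot_slice(object, k = k)
}

#' @export
autoplot.study_result <- function(object, type = c("improvement", "sphericity"),
                                  ...) {
  type <- match.arg(type)
  rec <- dplyr::filter(object$records, is.na(.data$error))
  rec$condition <- factor(sprintf("%.0f%%", 100 * rec$porosity_target))
  yvar <- if (type == "improvement") "improvement_pct" else "sphericity"
  ylab <- if (type == "improvement") {
    "Young's modulus improvement (%)"
  } else {
    "cement cloud sphericity"
  }
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$condition,
                                    y = .data[[yvar]],
                                    colour = .data$viscosity)) +
    ggplot2::geom_boxplot(outlier.shape = NA, position = "dodge") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.75),
                        alpha = 0.6) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "structure porosity", y = ylab,
                  colour = "viscosity") +
    ggplot2::theme_minimal()
}
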