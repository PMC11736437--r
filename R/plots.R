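#' Plot a stability diagram
#'
#' Fold boundary in the leakage/expression-strength plane with the cusp
#' marked; the bistable wedge lies between the two branches.
#'
#' @param object An `rm_boundary` from [stability_boundary()].
#' @param r_max Right edge of the plotted `r` range.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rm_boundary <- function(object, r_max = 50, ...) {
  cusp <- attr(object, "cusp")
  df <- dplyr::filter(as_tibble(object), .data$r <= r_max, .data$s >= 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$s,
                                   group = .data$fold)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = cusp$r, y = cusp$s, shape = 4, size = 3) +
    ggplot2::labs(x = "expression strength r", y = "promoter leakage s",
                  title = "Fold (saddle-node) boundary; x marks the cusp") +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram
#'
#' Steady-state branches of total C versus expression strength; solid lines
#' are stable branches, dashed the unstable branch.
#'
#' @param object An `rm_bifurcation` from [bifurcation_diagram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rm_bifurcation <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$c_total,
                               colour = .data$branch,
                               linetype = .data$stability)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = "expression strength r", y = "total C (rescaled)") +
    ggplot2::theme_minimal()
}

#' Plot an M-to-R ratio curve
#'
#' @param object An `rm_mr_curve` from [mr_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rm_mr_curve <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$m_over_r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$m_over_r,
                                   colour = .data$branch,
                                   linetype = .data$stability)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = "expression strength r", y = "M-to-R ratio") +
    ggplot2::theme_minimal()
}

#' Plot ensemble M-to-R summary statistics across divisions
#'
#' @param object A summary tibble from [summarize_ensemble()].
#' @param ... Unused.
#' @return A ggplot object showing the robust CV of M/R and the median R
#'   count per division.
#' @export
plot_ensemble_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "division", "robust_cv_mr", "median_r"),
    -"division", names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$division, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "cell division") +
    ggplot2::theme_minimal()
}
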