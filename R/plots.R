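# ggplot2 methods for the package's result objects.

#' @method autoplot wid_sweep
#' @export
autoplot.wid_sweep <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$n, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "optimal_n"),
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "CpGs used to train the classifier",
                  y = "Validation AUC",
                  title = "Index-size sweep") +
    ggplot2::theme_minimal()
}

#' @method autoplot wid_shift_curve
#' @export
autoplot.wid_shift_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rho, y = .data$shift)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "target_shift_sd"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Tumour DNA proportion",
                  y = "Mean index shift (control SD units)",
                  title = "In-silico tumour contamination") +
    ggplot2::theme_minimal()
}

#' @method autoplot wid_quartile_table
#' @export
autoplot.wid_quartile_table <- function(object, ...) {
  df <- tibble::as_tibble(object)[-1L, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$quartile)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_conf_lo,
                                         xmax = .data$or_conf_hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio vs Q1 (mid-p, log scale)", y = NULL,
                  title = "Quartile odds ratios") +
    ggplot2::theme_minimal()
}

#' Visualize the intercept method at one CpG
#'
#' Scatter of beta against immune-cell fraction, with the separate
#' case/control regression lines whose intercept differences at IC = 0 and
#' IC = 1 define the epithelial and immune delta-betas.
#'
#' @param beta CpG x sample matrix.
#' @param fractions IC fractions (tibble with `sample_id`/`ic`, or vector).
#' @param labels Case/control labels.
#' @param cpg CpG id to display.
#' @return A ggplot object.
#' @export
plot_delta_beta_fit <- function(beta, fractions, labels, cpg) {
  ic <- if (is.data.frame(fractions)) {
    setNames(fractions$ic, fractions$sample_id)[colnames(beta)]
  } else as.numeric(fractions)
  df <- tibble(ic = ic, beta = beta[cpg, ],
               group = get_group_labels(labels, colnames(beta)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ic, y = .data$beta,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         fullrange = TRUE) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Immune cell fraction (IC)", y = "Beta", title = cpg) +
    ggplot2::theme_minimal()
}
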