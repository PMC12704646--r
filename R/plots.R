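# ggplot2 displays for the main result types.

#' Instrument scatter with the fitted causal slope
#'
#' Per-variant exposure effects against outcome effects with error bars and
#' the estimate's slope through the origin.
#'
#' @param object An `mr_estimate`.
#' @param pairs The harmonized instrument table the estimate was fitted on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_estimate
#' @export
autoplot.mr_estimate <- function(object, pairs, ...) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$beta_exp,
                                      y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = object$beta,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "variant effect on exposure (SD per allele)",
      y = "variant effect on outcome",
      title = sprintf("%s: beta = %.3g (se %.3g)", object$method,
                      object$beta, object$se))
}

#' Forest-style plot of oriented, significant protein-outcome estimates
#'
#' @param x An `mr_forward` object or its `concordance` tibble.
#' @param level Confidence level for the intervals (default 0.95).
#' @return A ggplot object.
#' @export
plot_concordance <- function(x, level = 0.95) {
  tbl <- if (inherits(x, "mr_forward")) x$concordance else x
  z <- stats::qnorm(1 - (1 - level) / 2)
  tbl <- tbl %>%
    mutate(pair = paste(.data$protein, .data$outcome, sep = " → "),
           flag = dplyr::case_when(
             is.na(.data$concordant) ~ "unobserved in trial",
             .data$concordant == 1L ~ "concordant",
             TRUE ~ "discordant"))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$beta,
                                    y = stats::reorder(.data$pair,
                                                       .data$beta),
                                    colour = .data$flag)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta - z * .data$se,
                                         xmax = .data$beta + z * .data$se),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(
      concordant = "#b2182b", discordant = "#2166ac",
      `unobserved in trial` = "grey40")) +
    ggplot2::labs(x = "MR estimate per SD change in the trial direction",
                  y = NULL, colour = NULL)
}

#' Bar plot of reverse-MR per-outcome protein counts
#'
#' @param x An `mr_reverse` object or an [intersection_counts()] list.
#' @return A ggplot object.
#' @export
plot_reverse_counts <- function(x) {
  counts <- if (inherits(x, "mr_reverse")) x$counts else x
  ggplot2::ggplot(counts$per_exposure,
                  ggplot2::aes(x = .data$n,
                               y = stats::reorder(.data$exposure,
                                                  .data$n))) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "proteins influenced", y = NULL)
}
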