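# ggplot2 displays for support counts and recovery evaluations

#' Stacked conformation-support bars per repeat
#'
#' @param support tibble with `repeat_id`, `mac1`, `mac2`, `mic1`,
#'   `mic2` (the [count_support()] layout)
#' @return a ggplot object
#' @export
plot_support <- function(support) {
  long <- tidyr::pivot_longer(
    dplyr::select(support, "repeat_id", "mac1", "mac2", "mic1", "mic2"),
    cols = c("mac1", "mac2", "mic1", "mic2"),
    names_to = "conformation", values_to = "reads")
  long$class <- ifelse(long$conformation %in% c("mac1", "mac2"),
                       "major (Mac)", "minor (Mic)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$repeat_id, y = .data$reads,
                                     fill = .data$conformation)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(mac1 = "#33548f", mac2 = "#7da0d6",
                                          mic1 = "#b2432f", mic2 = "#e08a70")) +
    ggplot2::labs(x = "repeat", y = "spanning reads",
                  title = "Spanning-read support per junction conformation") +
    ggplot2::theme_minimal()
}

#' @rdname plot_support
#' @param object a support tibble (for `autoplot`)
#' @param ... unused
#' @export
autoplot.support_counts <- function(object, ...) plot_support(object)

#' Estimated versus planted recombination frequency
#'
#' Plots point estimates with Clopper-Pearson intervals against the
#' planted minor fraction.
#'
#' @param object a `recovery_eval` from [evaluate_recovery()]
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.recovery_eval <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$minor_fraction,
                                       y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "planted minor fraction",
                  y = "estimated recombination frequency",
                  title = "Recovery of planted minor fractions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
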