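# ggplot2 figures for the diagnostic objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_vline
#'   geom_segment geom_hline geom_errorbar labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Love plot of covariate balance
#'
#' Lollipop plot of the per-covariate standardized mean differences with the
#' noteworthy-imbalance threshold marked.
#'
#' @param object A `balance_report`.
#' @param threshold Reference line (default 0.10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balance_report <- function(object, threshold = 0.10, ...) {
  d <- object |>
    dplyr::filter(is.na(.data$level) | .data$level == "(max over levels)" |
                    !.data$variable %in% .data$variable[.data$level == "(max over levels)"]) |>
    dplyr::group_by(.data$variable) |>
    dplyr::slice_max(.data$smd, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$smd) |>
    dplyr::mutate(variable = factor(.data$variable, levels = .data$variable))
  ggplot(d, aes(x = .data$smd, y = .data$variable)) +
    geom_segment(aes(x = 0, xend = .data$smd, yend = .data$variable),
                 colour = "grey70") +
    geom_point(aes(colour = .data$flag), size = 2) +
    geom_vline(xintercept = threshold, linetype = "dashed") +
    labs(x = "standardized mean difference", y = NULL, colour = paste0("SMD > ", threshold)) +
    theme_minimal()
}

#' Histogram of estimated propensity scores
#'
#' @param object A `positivity_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.positivity_report <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = diff(object$histogram$mid[1:2]), fill = "steelblue") +
    geom_vline(xintercept = c(object$min, object$max), linetype = "dotted") +
    geom_vline(xintercept = object$bounds, linetype = "dashed", colour = "firebrick") +
    labs(x = "propensity score P(remote | W)", y = "episodes") +
    theme_minimal()
}

#' Forest-style plot of the targeted estimates per stratum
#'
#' @param object A `tmle_analysis`.
#' @param parameter `"ate"` or `"or"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmle_analysis <- function(object, parameter = c("ate", "or"), ...) {
  parameter <- match.arg(parameter)
  d <- dplyr::filter(tidy(object), .data$parameter == .env$parameter)
  ref <- if (parameter == "ate") 0 else 1
  ggplot(d, aes(x = .data$estimate, y = .data$stratum)) +
    geom_point(size = 2) +
    geom_errorbar(aes(xmin = .data$ci_lower, xmax = .data$ci_upper), width = 0.15) +
    geom_vline(xintercept = ref, linetype = "dashed") +
    labs(x = if (parameter == "ate") "average treatment effect" else "marginal odds ratio",
         y = NULL) +
    theme_minimal()
}
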