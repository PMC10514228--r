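# broom-style tidiers and accessors.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted twin model
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return Tibble of free parameters: `term`, `block`, `phenotype`,
#'   `estimate`, and `std.error` when a sandwich covariance is attached.
#' @export
tidy.twin_fit <- function(x, ...) {
  out <- dplyr::mutate(x$spec$par_info,
    estimate = as.numeric(x$theta[.data$name])
  )
  out <- dplyr::rename(out, term = "name")
  if (!is.null(x$vcov)) {
    out$std.error <- sqrt(pmax(diag(x$vcov)[out$term], 0))
  }
  tibble::as_tibble(out)
}

#' One-row fit summary
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return Tibble: label, convergence, `F_min`, free parameter and moment
#'   counts, totals.
#' @export
glance.twin_fit <- function(x, ...) {
  tibble::tibble(
    label = x$spec$label, kind = x$spec$kind, converged = x$converged,
    F_min = x$F_min, n_parameters = length(x$theta),
    n_moments = x$n_moments, df = x$n_moments - length(x$theta),
    n_total = x$n_total, boundary = isTRUE(x$boundary),
    weight_mode = x$weight_mode
  )
}

#' Standardized variance proportions of a fit
#'
#' @param fit A `twin_fit`.
#' @return Long tibble: `phenotype`, `component`, `proportion`.
#' @export
variance_components <- function(fit) {
  dec <- fit$decomposition
  tidyr::pivot_longer(dec,
    cols = dplyr::any_of(c(
      "general_a", "general_c", "general_e",
      "specific_a", "specific_c", "specific_e"
    )),
    names_to = "component", values_to = "proportion"
  )
}

#' @export
tidy.twin_ladder <- function(x, ...) x$table

#' @export
glance.twin_ladder <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$fits),
    n_converged = sum(vapply(x$fits, function(f) !is.null(f) && f$converged, logical(1))),
    baseline_T = x$baseline$T, baseline_df = x$baseline$df,
    N_total = x$N_total, G = x$G
  )
}

#' @export
tidy.twin_boot <- function(x, ...) x$intervals

#' Stacked variance-decomposition bar chart
#'
#' @param object A `twin_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.twin_fit <- function(object, ...) {
  vc <- variance_components(object)
  vc$component <- factor(vc$component, levels = c(
    "general_a", "general_c", "general_e",
    "specific_a", "specific_c", "specific_e"
  ))
  vc$phenotype <- factor(vc$phenotype, levels = object$spec$phenotypes)
  ggplot2::ggplot(vc, ggplot2::aes(
    x = .data$phenotype, y = .data$proportion, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Paired") +
    ggplot2::labs(
      x = NULL, y = "Proportion of liability variance",
      fill = NULL, title = object$spec$label
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Fit-index overview of a model ladder
#'
#' @param object A `twin_ladder`.
#' @param ... Unused.
#' @return A ggplot of RMSEA (with its interval) by model.
#' @export
autoplot.twin_ladder <- function(object, ...) {
  tb <- object$table[!is.na(object$table$RMSEA), ]
  tb <- tb[!duplicated(tb$model), ]
  tb$model <- factor(tb$model, levels = rev(unique(tb$model)))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$RMSEA, y = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$RMSEA_lo, xmax = .data$RMSEA_hi),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0.05, linetype = 2) +
    ggplot2::labs(x = "RMSEA (90% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Interval plot for bootstrap results
#'
#' @param object A `twin_boot`.
#' @param terms Optional term subset (regular expression).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.twin_boot <- function(object, terms = NULL, ...) {
  tb <- object$intervals
  if (!is.null(terms)) tb <- tb[grepl(terms, tb$term), ]
  tb$term <- factor(tb$term, levels = rev(tb$term))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
      height = 0.2
    ) +
    ggplot2::labs(
      x = "Estimate (BCa interval)", y = NULL,
      title = sprintf("%.0f%% bootstrap intervals", 100 * object$level)
    ) +
    ggplot2::theme_minimal()
}
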