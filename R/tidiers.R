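#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidy.fersig_fit
#' @export
glance.fersig_fit <- function(x, ...) {
  tibble(
    n = nrow(x$scores),
    threshold = x$threshold,
    sign_A = unname(x$sign_class["A"]),
    sign_B = unname(x$sign_class["B"]),
    beta_A = x$cox$A$beta, p_A = x$cox$A$p,
    beta_B = x$cox$B$beta, p_B = x$cox$B$p
  )
}

#' Tidy and summarize a Fersig fit
#'
#' `tidy()` returns the per-sample score table; `glance()` a one-row summary
#' with the per-signature Cox coefficients and sign classes.
#'
#' @param x A `"fersig_fit"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fersig_fit <- function(x, ...) x$scores

#' Tidy and summarize a consensus clustering result
#'
#' `tidy()` returns the rank survey (rank, cophenetic coefficient,
#' dispersion); `glance()` the selected rank and its stability.
#'
#' @param x A `"consensus_result"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.consensus_result <- function(x, ...) x$survey

#' @rdname tidy.consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  best <- select_rank(x)
  srv <- x$survey
  tibble(best_rank = as.integer(best),
         cophenetic = srv$cophenetic[srv$rank == best],
         n_runs = x$runs, n_ranks = nrow(srv))
}

#' Tidy a univariate Cox fit
#'
#' One row in the broom convention: term, estimate (log hazard ratio),
#' std.error, statistic (Wald z), p.value.
#'
#' @param x A `"cox_fit"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble(term = "x", estimate = x$beta, std.error = x$se,
         statistic = x$z, p.value = x$p)
}

#' @rdname tidy.cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, events = x$events, hr = x$hr,
         converged = x$converged, ties = x$ties)
}

#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate with censoring ticks.
#'
#' @param object A `"km_curve"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, survival = 1), as_tibble(object))
  cens <- df[!is.na(df$n_censor) & df$n_censor > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot a consensus rank survey
#'
#' Cophenetic coefficient (and dispersion) against candidate rank; the
#' customary display for choosing the NMF rank.
#'
#' @param object A `"consensus_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_result <- function(object, ...) {
  srv <- tidyr::pivot_longer(object$survey, c("cophenetic", "dispersion"),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(srv, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "NMF rank", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Fersig score distributions by group
#'
#' @param object A `"fersig_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fersig_fit <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$fersig, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "Fersig score", y = "Samples") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
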