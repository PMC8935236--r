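#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Efron tie handling) for a single
#' covariate and reports the log hazard ratio with its Wald test. A monotone
#' partial likelihood (perfect separation) is flagged and the coefficient
#' reported with a warning rather than trusted silently.
#'
#' @param x Numeric covariate, aligned with `time`/`event`.
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicator (>= 1 event required).
#' @return List of class `"cox_fit"`: beta, hr, se, z, p, n, events,
#'   converged, separation, ties.
#' @export
cox_univariate <- function(x, time, event) {
  if (length(x) != length(time) || length(time) != length(event)) {
    stop_input("x, time and event must be aligned")
  }
  ok <- is.finite(x) & is.finite(time) & is.finite(event)
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  if (sum(event) < 1) stop_input("no events; Cox model undefined")
  if (stats::sd(x) == 0) stop_input("non-identifiable: constant covariate")
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (separation) {
    warn("monotone partial likelihood (possible perfect separation); coefficient capped")
    beta <- sign(beta) * min(abs(beta), 20)
  }
  z <- beta / se
  structure(list(beta = beta, hr = exp(beta), se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)), n = length(x),
                 events = sum(event), converged = !separation,
                 separation = separation, ties = "efron"),
            class = "cox_fit")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with censoring marks; an optional truncation
#' restricts the reported curve (values before the cut are unchanged --
#' truncation is display-level only).
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicator.
#' @param truncate_days Optional upper limit on reported times.
#' @return Tibble of class `"km_curve"`: time, n_risk, n_event, n_censor,
#'   survival.
#' @export
km_estimate <- function(time, event, truncate_days = NULL) {
  if (length(time) < 1) stop_input("need >= 1 subject")
  if (any(time < 0)) stop_input("negative survival time")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                n_censor = sf$n.censor, survival = sf$surv)
  if (!is.null(truncate_days)) out <- out[out$time <= truncate_days, , drop = FALSE]
  class(out) <- c("km_curve", class(out))
  out
}

#' k-group log-rank test
#'
#' Observed-minus-expected events with hypergeometric variance at each event
#' time; chi-square on `k - 1` degrees of freedom.
#'
#' @param time,event Survival data.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List: statistic, df, p.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop_input("log-rank test needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median split into high/low groups
#'
#' Scores strictly above the median are `"high"`, the rest (median members
#' included) `"low"`.
#'
#' @param scores Named (or plain) numeric vector, >= 2 values.
#' @return Tibble: sample_id, score, group; threshold in `attr(, "threshold")`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop_input("need >= 2 samples to split")
  if (stats::sd(scores) == 0) stop_input("degenerate split: all scores identical")
  med <- stats::median(scores)
  grp <- ifelse(scores > med, "high", "low")
  out <- tibble(
    sample_id = names(scores) %||% as.character(seq_along(scores)),
    score = unname(scores), group = unname(grp)
  )
  attr(out, "threshold") <- med
  attr(out, "sizes") <- table(grp)
  out
}
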