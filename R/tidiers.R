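#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted trend
#'
#' Coefficient-level summary of a [fit_incidence_trend()] /
#' [fit_prevalence_trend()] object, with the year term's annual percent
#' change appended.
#'
#' @param x a `pd_trend`.
#' @param ... unused.
#' @return tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `apc`, `apc_lower`, `apc_upper` (APC columns only on the year term).
#' @method tidy pd_trend
#' @export
tidy.pd_trend <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble(term = rownames(sm), estimate = sm[, 1],
                std.error = sm[, 2], statistic = sm[, 3],
                p.value = sm[, 4])
  out$apc <- ifelse(out$term == "year", x$apc, NA_real_)
  out$apc_lower <- ifelse(out$term == "year", x$apc_lower, NA_real_)
  out$apc_upper <- ifelse(out$term == "year", x$apc_upper, NA_real_)
  out
}

#' One-row model summary of a fitted trend
#' @param x a `pd_trend`.
#' @param ... unused.
#' @return tibble: `family`, `beta`, `se`, `dispersion`, `deviance`,
#'   `df.residual`, `apc`, `apc_lower`, `apc_upper`.
#' @method glance pd_trend
#' @export
glance.pd_trend <- function(x, ...) {
  tibble(family = x$family, beta = x$beta, se = x$se,
         dispersion = x$dispersion, deviance = x$deviance,
         df.residual = x$df_residual, apc = x$apc,
         apc_lower = x$apc_lower, apc_upper = x$apc_upper)
}

#' Plot an incidence rate table
#'
#' Annual rates per 100,000 by age group with exact Poisson CI ribbons.
#'
#' @param object a `pd_rate_table` from [crude_incidence()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pd_rate_table
#' @export
autoplot.pd_rate_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = year, y = rate,
                                       colour = age_group,
                                       fill = age_group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_lower, ymax = ci_upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Calendar year", y = "Incidence per 100,000",
                  colour = "Age group", fill = "Age group") +
    ggplot2::theme_minimal()
}

#' Plot cohort classification counts
#'
#' @param object a `pd_cohort` from [classify_cohort()].
#' @param ... unused.
#' @return a ggplot bar chart of status counts.
#' @method autoplot pd_cohort
#' @export
autoplot.pd_cohort <- function(object, ...) {
  d <- as_tibble(object) %>% count(status)
  ggplot2::ggplot(d, ggplot2::aes(x = status, y = n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Patients") +
    ggplot2::theme_minimal()
}

#' Plot pre-diagnostic prevalence divergence
#'
#' Case and control year-offset prevalences per diagnosis code, index date
#' at the right edge.
#'
#' @param points output of [annual_dx_prevalence()] (possibly several codes
#'   bound together).
#' @return a ggplot, faceted by code.
#' @export
plot_prediagnostic <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(x = year_offset, y = proportion,
                                       colour = group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~code, scales = "free_y") +
    ggplot2::labs(x = "Years before index date", y = "Annual prevalence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
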