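#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a variance-component fit
#'
#' One row per component (residual included): variance on the standardized
#' and raw phenotype scales, the phenotypic fraction with its delta-method
#' standard error, and the z-test p-value.
#'
#' @param x An `hgcta_fit` from [fit_reml()] or [run_design()].
#' @param ... Unused.
#' @return A tibble with columns `component`, `sigma2`, `sigma2_raw`,
#'   `h2`, `se_h2`, `p.value`.
#' @export
tidy.hgcta_fit <- function(x, ...) {
  tibble::tibble(
    component = x$components,
    sigma2 = unname(x$sigma2),
    sigma2_raw = unname(x$sigma2_raw),
    h2 = unname(x$h2),
    se_h2 = unname(x$se_h2),
    p.value = unname(x$pvalues)
  )
}

#' Glance at a variance-component fit
#'
#' @param x An `hgcta_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `n_iter`, `converged`, `bounded`,
#'   `nobs`, `total_h2` (sum of the genetic fractions).
#' @export
glance.hgcta_fit <- function(x, ...) {
  genetic <- x$components != "residual"
  tibble::tibble(
    logLik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged,
    bounded = x$bounded,
    nobs = x$n,
    total_h2 = sum(x$h2[genetic])
  )
}

#' Plot a variance-component fit
#'
#' Bar chart of the estimated phenotypic variance fractions with +/- 1 SE
#' error bars, residual excluded.
#'
#' @param object An `hgcta_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hgcta_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$component != "residual", ]
  d$component <- factor(d$component, levels = d$component)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$h2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$h2 - .data$se_h2,
                   ymax = .data$h2 + .data$se_h2),
      width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "variance fraction") +
    ggplot2::theme_minimal()
}

#' Plot a recovery study against its closed-form expectations
#'
#' Replicate-mean variance fractions per design and component, with +/- 2
#' standard errors of the replicate mean, and the closed-form expected
#' fractions overlaid as crossbars where available.
#'
#' @param object A [recovery_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_study <- function(object, ...) {
  s <- summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$component, y = .data$mean_h2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_h2 - 2 * .data$se_mean,
                   ymax = .data$mean_h2 + 2 * .data$se_mean),
      width = 0.2) +
    ggplot2::geom_point(data = s[!is.na(s$expected), ],
                        ggplot2::aes(y = .data$expected),
                        shape = 4, size = 3, colour = "firebrick") +
    ggplot2::facet_wrap(~design, scales = "free_x") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "mean variance fraction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
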