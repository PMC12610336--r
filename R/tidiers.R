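#' Tidy posterior summaries of a fitted mixed membership model
#'
#' Returns one row per scalar summary: feature mean curves on a grid
#' (`type = "means"`), allocation summaries (`type = "allocations"`), or
#' scalar parameters (`type = "parameters"`: noise variance, mixing
#' proportions, concentration).
#'
#' @param x An `fmm_fit`.
#' @param type One of `"means"`, `"allocations"`, `"parameters"`.
#' @param ... Passed to [summarize_fit()] for `"means"`/`"allocations"`.
#' @return A tibble.
#' @method tidy fmm_fit
#' @export
tidy.fmm_fit <- function(x, type = c("allocations", "means", "parameters"), ...) {
  type <- match.arg(type)
  if (type == "parameters") {
    d <- x$draws
    rows <- list(tibble(term = "sigma2",
                        estimate = median(d$sigma2),
                        conf.low = quantile(d$sigma2, 0.025),
                        conf.high = quantile(d$sigma2, 0.975)))
    for (k in seq_len(x$K)) {
      rows[[length(rows) + 1L]] <- tibble(
        term = sprintf("pi[%d]", k),
        estimate = median(d$pi[, k]),
        conf.low = quantile(d$pi[, k], 0.025),
        conf.high = quantile(d$pi[, k], 0.975))
    }
    rows[[length(rows) + 1L]] <- tibble(
      term = "alpha3", estimate = median(d$alpha3),
      conf.low = quantile(d$alpha3, 0.025),
      conf.high = quantile(d$alpha3, 0.975))
    return(dplyr::bind_rows(rows))
  }
  sm <- summarize_fit(x, ...)
  if (type == "means") sm$means else sm$allocations
}

#' One-row model summary
#'
#' Model dimensions, the maximum marginal log-likelihood, information
#' criteria, pseudo-marginal likelihood and the allocation acceptance rate.
#'
#' @param x An `fmm_fit`.
#' @param cpo Include the (more expensive) CPO-based pseudo-marginal
#'   likelihood? Default `TRUE`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance fmm_fit
#' @export
glance.fmm_fit <- function(x, cpo = TRUE, ...) {
  ic <- information_criteria(x)
  out <- tibble(K = x$K, P = x$P, M = x$M, N = x$data$N, R = x$data$R,
                n_draws = n_draws(x),
                loglik_hat = ic$loglik_hat, AIC = ic$AIC, BIC = ic$BIC,
                DIC = ic$DIC,
                accept_alloc = as.numeric(x$accept$allocations))
  if (cpo) out$PsML <- cpo_psml(x)$psml
  out
}

#' Plot posterior feature mean bands
#'
#' Pointwise posterior median and credible band of each feature's mean
#' curve, faceted by covariate setting when several are requested.
#'
#' @param object An `fmm_fit`.
#' @param x_values,grid,quantiles Passed to [summarize_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fmm_fit
#' @export
autoplot.fmm_fit <- function(object, x_values = NULL, grid = 100L,
                             quantiles = c(0.025, 0.975), ...) {
  sm <- summarize_fit(object, x_values = x_values, grid = grid,
                      quantiles = quantiles)
  ggplot2::ggplot(sm$means, ggplot2::aes(x = .data$t, y = .data$median,
                                         colour = factor(.data$feature),
                                         fill = factor(.data$feature))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~x_label) +
    ggplot2::labs(x = "t", y = "feature mean", colour = "feature",
                  fill = "feature") +
    ggplot2::theme_minimal()
}

#' Plot posterior allocation distributions
#'
#' Dot-and-interval plot of the posterior median and credible interval of
#' each curve's membership in each feature.
#'
#' @param fit An `fmm_fit`.
#' @param feature Feature index to display (default 1).
#' @return A ggplot object.
#' @export
plot_allocations <- function(fit, feature = 1L) {
  sm <- summarize_fit(fit)
  d <- dplyr::filter(sm$allocations, .data$feature == !!feature)
  d <- dplyr::arrange(d, .data$median)
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::labs(x = "curve (sorted)", y = sprintf("membership in feature %d", feature)) +
    ggplot2::theme_minimal()
}

#' Plot the eigen-structure of the posterior covariance
#'
#' Posterior median eigenfunctions (with bands) from a [covariance_eigen()]
#' result.
#'
#' @param object An `fmm_eigen`.
#' @param components Which components to show (default all kept).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fmm_eigen
#' @export
autoplot.fmm_eigen <- function(object, components = NULL, ...) {
  n_keep <- dim(object$functions)[3]
  components <- components %||% seq_len(n_keep)
  tb <- dplyr::bind_rows(lapply(components, function(m) {
    F <- object$functions[, , m, drop = FALSE][, , 1, drop = TRUE]
    F <- matrix(F, nrow = dim(object$functions)[1])
    tibble(component = m, t = object$grid,
           median = apply(F, 2, median),
           lower = apply(F, 2, quantile, 0.025),
           upper = apply(F, 2, quantile, 0.975))
  }))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$t, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "t", y = "eigenfunction") +
    ggplot2::theme_minimal()
}
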