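#' Tidy a variance-component fit
#'
#' @param x A `vc_fit`.
#' @param proportions Include variance proportions of the total.
#' @param ... Unused.
#' @return Tibble with one row per estimated component: `component`,
#'   `estimate`, `se` (and proportion columns when requested).
#' @method tidy vc_fit
#' @export
tidy.vc_fit <- function(x, proportions = FALSE, ...) {
  free <- vc_free(x$model)
  out <- tibble(component = free,
                estimate = unname(x$estimates[free]),
                se = unname(x$se[free]))
  if (proportions) {
    vp <- variance_proportions(x)
    out <- dplyr::left_join(out,
                            dplyr::select(vp, "component", "proportion",
                                          "proportion_se"),
                            by = "component")
  }
  out
}

#' Model-level summary of a variance-component fit
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return One-row tibble: model, neg2ll, aic, bic, k, n, converged,
#'   iterations, negative_variance.
#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble(model = x$model, neg2ll = x$neg2ll, aic = x$aic, bic = x$bic,
         k = x$k, n = x$n, converged = x$converged,
         iterations = x$iterations,
         negative_variance = x$negative_variance)
}

#' Tidy a trio-PGS regression fit
#'
#' @param x A `trio_pgs_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `trait`, `role`, `estimate`, `se`,
#'   `statistic`, `p_raw`, `conf_low`, `conf_high`.
#' @method tidy trio_pgs_fit
#' @export
tidy.trio_pgs_fit <- function(x, ...) {
  dplyr::mutate(x$coef_map,
                estimate = unname(x$coefficients),
                se = unname(x$se),
                statistic = unname(x$z),
                p_raw = unname(x$p_raw),
                conf_low = unname(x$ci95[, 1]),
                conf_high = unname(x$ci95[, 2]))
}

#' Model-level summary of a trio-PGS fit
#'
#' @param x A `trio_pgs_fit`.
#' @param ... Unused.
#' @return One-row tibble with sample sizes and the direct/indirect
#'   partial r-squared decomposition.
#' @method glance trio_pgs_fit
#' @export
glance.trio_pgs_fit <- function(x, ...) {
  tibble(outcome = x$outcome, n_obs = x$n_obs, n_clusters = x$n_clusters,
         partial_r2_direct = x$partial_r2_direct,
         partial_r2_indirect = x$partial_r2_indirect)
}

#' Plot variance proportions of a fitted trio model
#'
#' Bar chart of each component's share of the phenotypic variance with
#' +/- 1 SE whiskers (SEs treat the total as fixed).
#'
#' @param object A `vc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vc_fit
#' @export
autoplot.vc_fit <- function(object, ...) {
  vp <- variance_proportions(object)
  vp$component <- factor(vp$component, levels = vp$component)
  ggplot2::ggplot(vp, ggplot2::aes(x = .data$component,
                                   y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$proportion - .data$proportion_se,
      ymax = .data$proportion + .data$proportion_se), width = 0.25,
      na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "proportion of phenotypic variance",
                  title = paste0("Variance decomposition (",
                                 object$model, " model)")) +
    ggplot2::theme_minimal()
}

#' Forest plot of trio-PGS coefficients
#'
#' Point estimates with 95% cluster-robust confidence intervals for the
#' PGS terms, coloured by family role.
#'
#' @param object A `trio_pgs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trio_pgs_fit
#' @export
autoplot.trio_pgs_fit <- function(object, ...) {
  td <- dplyr::filter(tidy(object), !is.na(.data$role))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = paste(.data$trait, .data$role),
                                   colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "standardized coefficient", y = NULL,
                  colour = "role",
                  title = paste("Trio-PGS associations:", object$outcome)) +
    ggplot2::theme_minimal()
}
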