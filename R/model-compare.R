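#' Information criteria of a fitted variance-component model
#'
#' `AIC = -2lR + 2k` and `BIC = -2lR + k log(n)`, with `k` the total
#' parameter count (fixed-effect columns plus free variance/covariance
#' components) and `n` the number of phenotyped children.
#'
#' @param fit A `vc_fit`.
#' @return Named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!fit$converged) warn("model did not converge; criteria are unreliable.")
  c(aic = fit$neg2ll + 2 * fit$k, bic = fit$neg2ll + fit$k * log(fit$n))
}

#' Likelihood-ratio test between nested variance-component models
#'
#' `chi2 = neg2ll(nested) - neg2ll(containing)` (floored at zero) referred
#' to a chi-square with df equal to the difference in free component counts.
#' The naive chi-square reference is used deliberately (no boundary 1/2-1/2
#' mixture correction), matching common practice for these nested trio
#' model comparisons.
#'
#' @param nested,containing `vc_fit` objects for the same outcome/sample,
#'   with `nested` the smaller model.
#' @return One-row tibble: `nested`, `containing`, `chi2`, `delta_df`,
#'   `p_raw` (`p_adj` is added by [bh_adjust()]/[compare_model_ladder()]).
#' @export
likelihood_ratio_test <- function(nested, containing) {
  stopifnot(inherits(nested, "vc_fit"), inherits(containing, "vc_fit"))
  if (nested$k >= containing$k)
    abort("`nested` must have fewer parameters than `containing`.")
  if (nested$n != containing$n)
    abort("fits must share the same sample.")
  chi2 <- nested$neg2ll - containing$neg2ll
  if (chi2 < -1e-4)
    warn("nested model has better likelihood than containing model; optimizer failure likely.")
  chi2 <- max(chi2, 0)
  delta_df <- length(vc_free(containing$model)) - length(vc_free(nested$model))
  tibble(nested = nested$model, containing = containing$model,
         chi2 = chi2, delta_df = delta_df,
         p_raw = pchisq(chi2, delta_df, lower.tail = FALSE))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment, delegated to [stats::p.adjust()]. Kept as a named
#' surface so every multiple-testing correction in the package flows
#' through one place.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Compare nested model ladders across outcomes
#'
#' For each outcome, tabulates `-2lR`, AIC, BIC and parameter counts for
#' the four nested models and marks the AIC-best model (ties resolved in
#' favour of fewer parameters). For each adjacent comparison level
#' (full vs no-covariance, no-covariance vs direct-only, direct-only vs
#' null), likelihood-ratio tests are computed per outcome and BH-adjusted
#' *across outcomes within that level* — mirroring correction over the set
#' of outcomes analysed.
#'
#' @param fits Named list: one `vc_ladder` (or named list of the four
#'   `vc_fit`s) per outcome. A single ladder is also accepted.
#' @return A `vc_model_comparison`: list of tibbles `models` (outcome,
#'   model, neg2ll, aic, bic, df, best) and `lrt` (outcome, nested,
#'   containing, chi2, delta_df, p_raw, p_adj).
#' @export
compare_model_ladder <- function(fits) {
  if (inherits(fits, "vc_ladder")) fits <- list(outcome = fits)
  for (oc in names(fits)) {
    if (!all(vc_models() %in% names(fits[[oc]])))
      abort(paste0("outcome '", oc, "' is missing models: ",
                   paste(setdiff(vc_models(), names(fits[[oc]])),
                         collapse = ", ")))
  }
  models <- purrr::map_dfr(names(fits), function(oc) {
    purrr::map_dfr(vc_models(), function(m) {
      f <- fits[[oc]][[m]]
      tibble(outcome = oc, model = m, neg2ll = f$neg2ll,
             aic = f$aic, bic = f$bic, df = f$k, n = f$n,
             converged = f$converged)
    })
  })
  models <- models |>
    dplyr::group_by(.data$outcome) |>
    dplyr::mutate(best = rank(.data$aic + 1e-9 * .data$df,
                              ties.method = "first") == 1L) |>
    dplyr::ungroup()
  levels_ <- list(c("no_covariance", "full"),
                  c("direct_only", "no_covariance"),
                  c("null", "direct_only"))
  lrt <- purrr::map_dfr(levels_, function(lv) {
    per_outcome <- purrr::map_dfr(names(fits), function(oc) {
      dplyr::mutate(
        likelihood_ratio_test(fits[[oc]][[lv[1]]], fits[[oc]][[lv[2]]]),
        outcome = oc, .before = 1)
    })
    dplyr::mutate(per_outcome, p_adj = bh_adjust(.data$p_raw))
  })
  structure(list(models = models, lrt = lrt),
            class = "vc_model_comparison")
}

#' @export
print.vc_model_comparison <- function(x, ...) {
  cat("<vc_model_comparison> over",
      dplyr::n_distinct(x$models$outcome), "outcome(s)\n")
  print(as.data.frame(x$models), row.names = FALSE)
  cat("\nLikelihood-ratio tests (BH-adjusted across outcomes per level):\n")
  print(as.data.frame(x$lrt), row.names = FALSE)
  invisible(x)
}

#' Variance proportions from a fitted model
#'
#' Expresses each estimated component as a proportion of the total
#' phenotypic variance `sigma_c2 + sigma_m2 + sigma_p2 + sigma_om +
#' sigma_op + sigma_e2`. The mother-father covariance is excluded from the
#' total under the random-mating assumption (parents have expected
#' relatedness zero, so sigma_mp does not contribute to Var(Y)).
#' Approximate proportion SEs treat the total as fixed (`se / total`).
#'
#' @param fit A `vc_fit`.
#' @return Tibble: `component`, `estimate`, `se`, `proportion`,
#'   `proportion_se`.
#' @export
variance_proportions <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!fit$converged) warn("model did not converge; proportions unreliable.")
  est <- fit$estimates
  in_total <- setdiff(vc_names(), "sigma_mp")
  total <- sum(est[in_total])
  if (total <= 0) abort("total phenotypic variance is not positive.")
  se_all <- setNames(rep(NA_real_, 7), vc_names())
  se_all[names(fit$se)] <- fit$se
  tibble(component = in_total,
         estimate = unname(est[in_total]),
         se = unname(se_all[in_total]),
         proportion = unname(est[in_total]) / total,
         proportion_se = unname(se_all[in_total]) / total)
}

#' Recompute information criteria and FDR-adjusted tests from reported
#' model-fit statistics
#'
#' Takes a table of reported `-2 log-likelihood` and parameter counts for
#' the four nested trio models across outcomes — the form in which
#' variance-component model comparisons are published when individual-level
#' data cannot be shared — and reconstructs the downstream inference chain:
#' `AIC = -2ll + 2k`, optionally `BIC = -2ll + k log(n)`, likelihood-ratio
#' chi-squares between adjacent models, and BH adjustment of each
#' comparison level across outcomes.
#'
#' @param stats Tibble with columns `outcome`, `model` (values in
#'   `vc_models()`), `neg2ll`, `df` (total parameter count), and optionally
#'   `n` (per-outcome sample size for BIC).
#' @param n Optional single sample size used for BIC when `stats` has no
#'   `n` column.
#' @return A `vc_model_comparison` with `models` (outcome, model, neg2ll,
#'   aic, bic, df, best) and `lrt` tibbles.
#' @export
#' @examples
#' path <- system.file("extdata", "neurodev_fit_stats.tsv",
#'                     package = "triogen")
#' stats <- read_fit_stats(path)
#' reanalyze_fit_stats(stats)$lrt
reanalyze_fit_stats <- function(stats, n = NULL) {
  stats <- as_tibble(stats)
  need <- c("outcome", "model", "neg2ll", "df")
  if (!all(need %in% names(stats)))
    abort(paste0("`stats` must have columns: ", paste(need, collapse = ", ")))
  if (!all(stats$model %in% vc_models()))
    abort("`model` values must be full/no_covariance/direct_only/null.")
  counts <- table(stats$outcome)
  if (any(counts != 4) ||
      !all(vapply(split(stats$model, stats$outcome),
                  function(m) setequal(m, vc_models()), logical(1))))
    abort("every outcome needs exactly the four nested models.")
  if (!"n" %in% names(stats)) stats$n <- if (is.null(n)) NA_real_ else n
  models <- stats |>
    dplyr::mutate(aic = .data$neg2ll + 2 * .data$df,
                  bic = .data$neg2ll + .data$df * log(.data$n)) |>
    dplyr::group_by(.data$outcome) |>
    dplyr::mutate(best = rank(.data$aic + 1e-9 * .data$df,
                              ties.method = "first") == 1L) |>
    dplyr::ungroup()
  free_k <- vapply(vc_models(), function(m) length(vc_free(m)), numeric(1))
  levels_ <- list(c("no_covariance", "full"),
                  c("direct_only", "no_covariance"),
                  c("null", "direct_only"))
  get_val <- function(oc, m, col) {
    models[[col]][models$outcome == oc & models$model == m]
  }
  outcomes <- unique(models$outcome)
  lrt <- purrr::map_dfr(levels_, function(lv) {
    per <- purrr::map_dfr(outcomes, function(oc) {
      chi2 <- max(get_val(oc, lv[1], "neg2ll") - get_val(oc, lv[2], "neg2ll"),
                  0)
      ddf <- unname(free_k[lv[2]] - free_k[lv[1]])
      tibble(outcome = oc, nested = lv[1], containing = lv[2],
             chi2 = chi2, delta_df = ddf,
             p_raw = pchisq(chi2, ddf, lower.tail = FALSE))
    })
    dplyr::mutate(per, p_adj = bh_adjust(.data$p_raw))
  })
  structure(list(models = models, lrt = lrt),
            class = "vc_model_comparison")
}

#' Read a model-fit statistics table
#'
#' Reads a TSV with columns `outcome`, `model`, `neg2ll`, `df` (and
#' optionally `n`) as consumed by [reanalyze_fit_stats()]. The package
#' ships one such table (`inst/extdata/neurodev_fit_stats.tsv`): published
#' fit statistics for four nested trio variance-component models of six
#' mother-reported neurodevelopmental outcomes at age 3 in a Norwegian
#' birth cohort.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_fit_stats <- function(path) {
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
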