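#' Simulate one complete trio dataset and fit variance-component models
#'
#' Convenience wrapper chaining the simulator stages (genotypes, effect
#' sizes, phenotypes), GRM construction and block extraction, then fitting
#' either a single model or the full nested ladder. One building block of
#' [run_parameter_recovery()].
#'
#' @param n_trios,n_snps Simulation sizes.
#' @param truth Named list/vector of true components (`var_c`, `var_m`,
#'   `var_p`, `cov_om`, `cov_op`, `cov_mp`, `var_e`), missing entries 0
#'   (residual defaults to 1 minus the genetic total).
#' @param causal_fraction Proportion of causal SNPs.
#' @param models `"ladder"` for all four models, or a subset of
#'   [vc_models()].
#' @param covars Fixed-effect covariates included in the REML design
#'   (subset of `c("sex", "batch")`; intercept always included).
#' @param sibling_fraction Passed to [simulate_trio_genotypes()].
#' @param maf_range Passed to [simulate_trio_genotypes()].
#' @param constrain Passed to [fit_variance_components()].
#' @param seed Master seed for this replicate (split internally per stage).
#' @return List: `fits` (named list of `vc_fit`), `geno`, `pheno`,
#'   `blocks`, `truth`.
#' @export
simulate_and_fit <- function(n_trios, n_snps, truth = list(),
                             causal_fraction = 1, models = "ladder",
                             covars = c("sex", "batch"),
                             sibling_fraction = 0,
                             maf_range = c(0.05, 0.5),
                             constrain = FALSE, seed = 1) {
  tv <- function(nm, default = 0) if (!is.null(truth[[nm]])) truth[[nm]] else default
  gen_total <- tv("var_c") + tv("var_m") + tv("var_p") +
    tv("cov_om") + tv("cov_op")
  var_e <- tv("var_e", default = max(1 - gen_total, 0.1))
  seeds <- derive_seeds(seed, 3)
  geno <- simulate_trio_genotypes(n_trios, n_snps, maf_range = maf_range,
                                  sibling_fraction = sibling_fraction,
                                  seed = seeds[1])
  eff <- simulate_effect_sizes(
    n_snps, causal_fraction,
    vc_target_matrix(tv("var_c"), tv("var_m"), tv("var_p"),
                     tv("cov_om"), tv("cov_op"), tv("cov_mp")),
    seed = seeds[2])
  pheno <- simulate_phenotypes(geno, eff, sigma_e2 = var_e, seed = seeds[3])
  grm <- compute_grm(stack_trio_dosage(geno))
  blocks <- extract_trio_blocks(grm, geno$trios)
  X <- vc_design(pheno, covars)
  model_set <- if (identical(models, "ladder")) vc_models() else models
  fits <- lapply(model_set, function(m)
    fit_variance_components(blocks, pheno$y, X, model = m,
                            constrain = constrain))
  names(fits) <- model_set
  class(fits) <- "vc_ladder"
  list(fits = fits, geno = geno, pheno = pheno, blocks = blocks,
       truth = list(var_c = tv("var_c"), var_m = tv("var_m"),
                    var_p = tv("var_p"), cov_om = tv("cov_om"),
                    cov_op = tv("cov_op"), cov_mp = tv("cov_mp"),
                    var_e = var_e))
}

#' Fixed-effect design matrix from a phenotype table
#'
#' Intercept plus any of child sex and genotyping-batch dummies (and extra
#' numeric columns if named), the default fixed-effect structure of the
#' synthetic variance-component pipeline.
#'
#' @param pheno A `phenotype_table`.
#' @param covars Columns to include (`"sex"`, `"batch"`, or other columns
#'   of `pheno`).
#' @return Numeric design matrix with intercept.
#' @export
vc_design <- function(pheno, covars = c("sex", "batch")) {
  covars <- intersect(covars, names(pheno))
  if (length(covars) == 0) return(matrix(1, nrow(pheno), 1))
  stats::model.matrix(stats::reformulate(covars),
                      data = as.data.frame(pheno))
}

#' Parameter-recovery study over simulation scenarios
#'
#' For each scenario and seed: simulate a trio dataset under the scenario's
#' true components, build the GRM, fit the requested models, and record
#' component estimates, standard errors and (when the ladder is fitted)
#' the AIC-best model. Aggregation gives mean estimates, empirical SEs and
#' model-selection frequencies per scenario — the package's substitute
#' evidence that the estimator recovers known truth, since the original
#' cohort data cannot be redistributed.
#'
#' @param scenarios Data frame with a `name` column and any of `var_c`,
#'   `var_m`, `var_p`, `cov_om`, `cov_op`, `var_e`, `n_trios`, `n_snps`,
#'   `causal_fraction` (defaults 0, 2000, 1000, 1).
#' @param n_seeds Replicates per scenario.
#' @param base_seed Master seed; per-replicate seeds are derived
#'   deterministically.
#' @param models `"ladder"` or a subset of [vc_models()].
#' @param covars Fixed-effect covariates for the fits.
#' @param constrain Constrain variances at zero.
#' @return A `recovery_report`: tibbles `estimates` (scenario, seed,
#'   model, component, truth, estimate, se, converged, aic_best) and
#'   `summary` (per scenario/model/component mean estimate, empirical SE,
#'   mean SE, coverage of truth by +/- 2 SE, and best-model frequencies).
#' @export
run_parameter_recovery <- function(scenarios, n_seeds = 20, base_seed = 1,
                                   models = "no_covariance",
                                   covars = c("sex", "batch"),
                                   constrain = FALSE) {
  scenarios <- as_tibble(scenarios)
  if (!"name" %in% names(scenarios))
    scenarios$name <- paste0("scenario_", seq_len(nrow(scenarios)))
  col_or <- function(df, nm, default) {
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  n_trios <- col_or(scenarios, "n_trios", 2000)
  n_snps <- col_or(scenarios, "n_snps", 1000)
  causal <- col_or(scenarios, "causal_fraction", 1)
  seed_grid <- matrix(derive_seeds(base_seed, nrow(scenarios) * n_seeds),
                      nrow(scenarios), n_seeds)
  truth_name <- c(sigma_c2 = "var_c", sigma_m2 = "var_m",
                  sigma_p2 = "var_p", sigma_om = "cov_om",
                  sigma_op = "cov_op", sigma_mp = "cov_mp",
                  sigma_e2 = "var_e")
  rows <- list()
  for (s in seq_len(nrow(scenarios))) {
    truth <- as.list(scenarios[s, intersect(names(scenarios),
                                            unname(truth_name))])
    for (r in seq_len(n_seeds)) {
      res <- tryCatch(
        simulate_and_fit(n_trios[s], n_snps[s], truth = truth,
                         causal_fraction = causal[s], models = models,
                         covars = covars, constrain = constrain,
                         seed = seed_grid[s, r]),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- tibble(
          scenario = scenarios$name[s], seed = seed_grid[s, r],
          model = NA_character_, component = NA_character_,
          truth = NA_real_, estimate = NA_real_, se = NA_real_,
          converged = FALSE, aic_best = NA_character_,
          error = conditionMessage(res))
        next
      }
      aics <- vapply(res$fits, function(f) f$aic, numeric(1))
      best <- if (length(aics) > 1) names(which.min(aics)) else NA_character_
      for (m in names(res$fits)) {
        f <- res$fits[[m]]
        free <- vc_free(m)
        rows[[length(rows) + 1]] <- tibble(
          scenario = scenarios$name[s], seed = seed_grid[s, r],
          model = m, component = free,
          truth = vapply(free, function(cp)
            res$truth[[truth_name[[cp]]]] %||% 0, numeric(1)),
          estimate = unname(f$estimates[free]),
          se = unname(f$se[free]),
          converged = f$converged, aic_best = best,
          error = NA_character_)
      }
    }
  }
  estimates <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(estimates, !is.na(.data$model))
  summary <- ok |>
    dplyr::group_by(.data$scenario, .data$model, .data$component) |>
    dplyr::summarise(
      truth = .data$truth[1],
      mean_estimate = mean(.data$estimate),
      empirical_se = sd(.data$estimate),
      mean_se = mean(.data$se),
      coverage_2se = mean(abs(.data$estimate - .data$truth) <= 2 * .data$se,
                          na.rm = TRUE),
      n_fits = dplyr::n(), .groups = "drop")
  selection <- ok |>
    dplyr::distinct(.data$scenario, .data$seed, .data$aic_best) |>
    dplyr::count(.data$scenario, .data$aic_best) |>
    dplyr::group_by(.data$scenario) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  structure(list(estimates = estimates, summary = summary,
                 selection = selection, base_seed = base_seed,
                 n_seeds = n_seeds),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$n_seeds, "seeds, base seed", x$base_seed, "\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  if (nrow(x$selection) && !all(is.na(x$selection$aic_best))) {
    cat("\nAIC-best model frequencies:\n")
    print(as.data.frame(x$selection), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object$estimates, !is.na(.data$model)),
                  ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$truth), colour = "red",
                        shape = 4, size = 3) +
    ggplot2::facet_grid(.data$scenario ~ .data$model, scales = "free_y") +
    ggplot2::labs(y = "estimate (red cross = truth)", x = NULL) +
    ggplot2::theme_minimal()
}
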