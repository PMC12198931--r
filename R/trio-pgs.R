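#' Cluster-robust sandwich covariance for OLS coefficients
#'
#' `(X'X)^-1 [ sum_g (X_g'e_g)(X_g'e_g)' ] (X'X)^-1`, scaled by the
#' small-sample factor `G/(G-1) * (n-1)/(n-k)` (the common default of
#' standard cluster-robust implementations; disable with
#' `small_sample = FALSE`). With all-singleton clusters this equals the
#' HC1-type heteroskedasticity-robust estimator.
#'
#' @param X n x k design matrix.
#' @param residuals n-vector of OLS residuals.
#' @param clusters Length-n cluster labels (e.g. maternal IDs).
#' @param small_sample Apply the `G/(G-1) * (n-1)/(n-k)` correction.
#' @return k x k symmetric covariance matrix.
#' @export
cluster_robust_vcov <- function(X, residuals, clusters,
                                small_sample = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (k >= n) abort("need more observations than coefficients.")
  if (length(residuals) != n || length(clusters) != n)
    abort("`residuals` and `clusters` must have one entry per row of `X`.")
  xe <- X * residuals
  s <- rowsum(xe, group = as.character(clusters))  # G x k cluster scores
  g <- nrow(s)
  meat <- crossprod(s)
  bread <- solve(crossprod(X))
  vc <- bread %*% meat %*% bread
  if (small_sample) {
    if (g < 2) abort("need at least 2 clusters.")
    vc <- vc * (g / (g - 1)) * ((n - 1) / (n - k))
  }
  (vc + t(vc)) / 2
}

#' Partial r-squared of a coefficient group under cluster-robust inference
#'
#' For a single coefficient, `t^2 / (t^2 + df_res)`; for a group of `q`
#' coefficients, `qF / (qF + df_res)` where `F` is the cluster-robust Wald
#' statistic divided by `q` and `df_res = n - k`. This is the proportion of
#' residual outcome variance attributable to the group given the other
#' model terms, and is invariant to invertible linear reparameterizations
#' of the group's columns.
#'
#' @param fit A `trio_pgs_fit`, or a list with `coefficients`, `vcov`,
#'   `n_obs`.
#' @param group Character names or integer indices of the coefficients in
#'   the group (must not include the intercept).
#' @return Scalar partial r-squared in [0, 1].
#' @export
partial_r2 <- function(fit, group) {
  b <- fit$coefficients
  v <- fit$vcov
  if (length(group) == 0) abort("`group` must be non-empty.")
  if (is.character(group)) group <- match(group, names(b))
  if (anyNA(group)) abort("unknown coefficient in `group`.")
  if (any(names(b)[group] == "(Intercept)"))
    abort("`group` must not include the intercept.")
  q <- length(group)
  df_res <- fit$n_obs - length(b)
  wald <- drop(crossprod(b[group],
                         solve(v[group, group, drop = FALSE], b[group])))
  wald / (wald + df_res)
}

# shared regression engine for single- and multi-trait trio-PGS models
trio_pgs_engine <- function(data, outcome, pgs_cols, covars, cluster,
                            small_sample = TRUE) {
  stopifnot(is.data.frame(pgs_cols),
            all(c("trait", "role", "column") %in% names(pgs_cols)))
  needed <- c(outcome, pgs_cols$column, covars, cluster)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  d <- data[, needed, drop = FALSE]
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  y <- as.numeric(d[[outcome]])
  rhs <- c(pgs_cols$column, covars)
  X <- stats::model.matrix(
    stats::reformulate(rhs), data = d)
  if (qr(X)$rank < ncol(X)) abort("design matrix is singular.")
  cl <- as.character(d[[cluster]])
  if (dplyr::n_distinct(cl) < 2) abort("need at least 2 clusters.")
  ols <- stats::lm.fit(X, y)
  beta <- ols$coefficients
  res <- ols$residuals
  vc <- cluster_robust_vcov(X, res, cl, small_sample = small_sample)
  dimnames(vc) <- list(names(beta), names(beta))
  se <- sqrt(diag(vc))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  ci <- cbind(beta - qnorm(0.975) * se, beta + qnorm(0.975) * se)
  # coefficient bookkeeping: map PGS columns back to trait/role
  cmap <- tibble(term = names(beta)) |>
    dplyr::left_join(
      tibble(term = pgs_cols$column, trait = pgs_cols$trait,
             role = pgs_cols$role),
      by = "term")
  fit <- structure(list(
    coefficients = beta, vcov = vc, se = se, z = z,
    p_raw = p, ci95 = ci,
    coef_map = cmap,
    n_obs = length(y), n_clusters = dplyr::n_distinct(cl),
    outcome = outcome,
    traits = unique(pgs_cols$trait),
    residuals = res
  ), class = "trio_pgs_fit")
  direct_cols <- pgs_cols$column[pgs_cols$role == "child"]
  indirect_cols <- pgs_cols$column[pgs_cols$role %in% c("mother", "father")]
  fit$partial_r2_direct <- partial_r2(fit, direct_cols)
  fit$partial_r2_indirect <- if (length(indirect_cols))
    partial_r2(fit, indirect_cols) else NA_real_
  fit
}

#' Trio polygenic-score regression with cluster-robust inference
#'
#' Fits `outcome = b0 + b1 childPGS + b2 motherPGS + b3 fatherPGS +
#' b4 sex + b5 ageQreturn` by OLS, with coefficient covariance from the
#' clustered sandwich estimator (observations clustered on maternal ID, so
#' siblings sharing a mother do not masquerade as independent). `b1` is
#' read as the direct genetic association of the trait's polygenic score,
#' `b2`/`b3` as maternal/paternal indirect associations. Partial
#' r-squared splits the explained variance into the direct (child PGS) and
#' indirect (mother + father PGS) groups. Confidence intervals use the
#' normal reference.
#'
#' @param data Data frame holding outcome, PGS columns, covariates and the
#'   cluster column (e.g. a join of [simulate_phenotypes()] and
#'   [compute_trio_pgs()] output).
#' @param outcome Name of the outcome column.
#' @param pgs Either a `pgs_triple` (its columns are joined by `child_id`),
#'   or a named character vector
#'   `c(child = "...", mother = "...", father = "...")` of column names in
#'   `data`.
#' @param covars Covariate column names (default sex and age at
#'   questionnaire return).
#' @param cluster Cluster column name (default `"maternal_cluster_id"`).
#' @param trait Trait label (defaults to the `pgs_triple` attribute).
#' @param small_sample Apply the small-sample sandwich correction.
#' @return A `trio_pgs_fit`: coefficients, cluster-robust `vcov`, `se`,
#'   `z`, `p_raw`, `ci95`, `partial_r2_direct`, `partial_r2_indirect`,
#'   `n_obs`, `n_clusters`.
#' @export
fit_trio_pgs <- function(data, outcome = "y", pgs = NULL,
                         covars = c("sex", "age_q_return"),
                         cluster = "maternal_cluster_id",
                         trait = NULL, small_sample = TRUE) {
  if (inherits(pgs, "pgs_triple")) {
    if (is.null(trait)) trait <- attr(pgs, "trait") %||% "trait"
    data <- dplyr::left_join(data, pgs, by = "child_id",
                             suffix = c("", ".pgs"))
    cols <- c(child = "pgs_child", mother = "pgs_mother",
              father = "pgs_father")
  } else if (!is.null(pgs)) {
    stopifnot(all(c("child", "mother", "father") %in% names(pgs)))
    cols <- pgs
    if (is.null(trait)) trait <- "trait"
  } else {
    cols <- c(child = "pgs_child", mother = "pgs_mother",
              father = "pgs_father")
    if (is.null(trait)) trait <- "trait"
  }
  map <- tibble(trait = trait, role = names(cols), column = unname(cols))
  trio_pgs_engine(data, outcome, map, covars, cluster,
                  small_sample = small_sample)
}

#' Multi-trait trio polygenic-score regression
#'
#' One regression containing the child, mother and father scores of
#' *every* trait simultaneously, plus covariates. The direct partial
#' r-squared is computed jointly over all child-PGS columns and the
#' indirect one jointly over all parental-PGS columns, giving the total
#' variance attributable to direct vs indirect polygenic associations.
#' With a single trait this reproduces [fit_trio_pgs()] exactly.
#'
#' @inheritParams fit_trio_pgs
#' @param pgs_map Data frame with columns `trait`, `role`
#'   (child/mother/father) and `column` naming the PGS columns in `data`;
#'   or a named list of `pgs_triple` objects (joined by `child_id`, columns
#'   suffixed by trait).
#' @return A `trio_pgs_fit`.
#' @export
fit_multi_trait <- function(data, outcome = "y", pgs_map,
                            covars = c("sex", "age_q_return"),
                            cluster = "maternal_cluster_id",
                            small_sample = TRUE) {
  if (is.list(pgs_map) && !is.data.frame(pgs_map)) {
    stopifnot(all(vapply(pgs_map, inherits, logical(1), "pgs_triple")))
    traits <- names(pgs_map) %||%
      vapply(pgs_map, function(p) attr(p, "trait"), character(1))
    rows <- list()
    for (i in seq_along(pgs_map)) {
      tr <- traits[i]
      p <- pgs_map[[i]]
      renamed <- dplyr::rename_with(p, function(x)
        paste0(x, "_", tr), dplyr::starts_with("pgs_"))
      data <- dplyr::left_join(data, renamed, by = "child_id")
      rows[[i]] <- tibble(trait = tr, role = c("child", "mother", "father"),
                          column = paste0(c("pgs_child", "pgs_mother",
                                            "pgs_father"), "_", tr))
    }
    pgs_map <- dplyr::bind_rows(rows)
  }
  trio_pgs_engine(data, outcome, pgs_map, covars, cluster,
                  small_sample = small_sample)
}

#' Grid-wide FDR adjustment for trio-PGS results
#'
#' Applies BH step-up adjustment within the declared testing family:
#' by default one family per coefficient role (child; mother; father) of
#' size outcomes x traits, so a grid of 10 outcomes x 5 traits is
#' corrected as 50 tests per role.
#'
#' @param results Tidy results tibble with at least `p_raw` and the
#'   grouping columns.
#' @param family Column names defining the families (default `"role"`).
#' @return `results` with a `p_adj` column.
#' @export
fdr_grid <- function(results, family = "role") {
  stopifnot("p_raw" %in% names(results))
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(family))) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p_raw)) |>
    dplyr::ungroup()
}

#' @export
print.trio_pgs_fit <- function(x, ...) {
  cat("<trio_pgs_fit> outcome =", x$outcome, "| n =", x$n_obs,
      "| clusters =", x$n_clusters, "\n")
  cat("partial r2: direct =", signif(x$partial_r2_direct, 4),
      "| indirect =", signif(x$partial_r2_indirect, 4), "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
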