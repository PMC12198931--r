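# score-level data for inference checks come from the package's own
# simulate_trio_scores(); a thin alias keeps the call sites short
simulate_pgs_data <- function(n_clusters, beta = c(0.2, 0.1, 0),
                              sibling_fraction = 0, maternal_env_sd = 0,
                              seed = 1) {
  simulate_trio_scores(n_clusters, beta = beta,
                       sibling_fraction = sibling_fraction,
                       maternal_env_sd = maternal_env_sd, seed = seed)
}

test_that("cluster-robust sandwich matches the hand-evaluated toy case", {
  # intercept-only design, residuals that cancel within clusters
  X <- matrix(1, 4, 1)
  v <- cluster_robust_vcov(X, c(1, -1, 2, -2), c("A", "A", "B", "B"))
  expect_equal(as.numeric(v), 0)
  # all residuals zero -> zero matrix
  X2 <- cbind(1, rnorm(10))
  v2 <- cluster_robust_vcov(X2, rep(0, 10), rep(letters[1:5], 2))
  expect_equal(max(abs(v2)), 0)
})

test_that("singleton clusters collapse to the HC1-type robust estimator", {
  set.seed(21)
  n <- 60
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- X %*% c(1, 0.5, -0.2) + rnorm(n) * (1 + 0.5 * abs(X[, 2]))
  fitlm <- lm(y ~ X - 1)
  e <- residuals(fitlm)
  v_mine <- cluster_robust_vcov(X, e, seq_len(n))
  # independent route: sandwich::vcovCL with singleton clusters
  v_ref <- sandwich::vcovCL(fitlm, cluster = seq_len(n), type = "HC1")
  expect_equal(unname(v_mine), unname(v_ref), tolerance = 1e-10)
})

test_that("clustered vcov agrees with the sandwich package", {
  d <- simulate_pgs_data(150, sibling_fraction = 0.4, maternal_env_sd = 0.5,
                         seed = 31)
  X <- stats::model.matrix(~ pgs_child + pgs_mother + pgs_father + sex +
                             age_q_return, d)
  fitlm <- lm(d$y ~ X - 1)
  v_mine <- cluster_robust_vcov(X, residuals(fitlm), d$maternal_cluster_id)
  v_ref <- sandwich::vcovCL(fitlm, cluster = d$maternal_cluster_id,
                            type = "HC1", cadjust = TRUE)
  expect_equal(unname(v_mine), unname(v_ref), tolerance = 1e-8)
})

test_that("trio-PGS point estimates equal plain OLS", {
  d <- simulate_pgs_data(400, seed = 41)
  fit <- fit_trio_pgs(d)
  ref <- lm(y ~ pgs_child + pgs_mother + pgs_father + sex + age_q_return,
            data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(fit$n_obs, 400)
  expect_equal(fit$n_clusters, 400)
  expect_equal(fit$se, sqrt(diag(fit$vcov)))
  td <- tidy(fit)
  expect_true(all(c("trait", "role", "estimate", "conf_low") %in% names(td)))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("trio-PGS coefficients recover the generative effects", {
  ests <- sapply(1:20, function(r) {
    d <- simulate_pgs_data(5000, beta = c(0.2, 0.1, 0), seed = 100 + r)
    fit_trio_pgs(d)$coefficients[c("pgs_child", "pgs_mother", "pgs_father")]
  })
  expect_lt(max(abs(rowMeans(ests) - c(0.2, 0.1, 0))), 0.03)
})

test_that("null outcomes give PGS coefficients within 2 SE of zero", {
  hits <- sapply(1:20, function(r) {
    d <- simulate_pgs_data(5000, beta = c(0, 0, 0), seed = 300 + r)
    fit <- fit_trio_pgs(d)
    idx <- c("pgs_child", "pgs_mother", "pgs_father")
    all(abs(fit$coefficients[idx]) <= 2 * fit$se[idx])
  })
  expect_gte(mean(hits), 0.75)
})

test_that("partial r2 follows the Wald formula and its oracles", {
  # t = 2, df_res = 100 -> 4/104
  fake <- list(coefficients = c(`(Intercept)` = 1, x = 0.2),
               vcov = diag(c(1, 0.01)), n_obs = 102)
  expect_equal(partial_r2(fake, "x"), 4 / 104)
  expect_error(partial_r2(fake, character(0)), "non-empty")
  expect_error(partial_r2(fake, "(Intercept)"), "intercept")

  # homoskedastic singleton-cluster case equals squared partial
  # correlation from residual-on-residual regression
  set.seed(51)
  n <- 200
  d <- tibble::tibble(child_id = paste0("c", 1:n),
                      pgs_child = rnorm(n), pgs_mother = rnorm(n),
                      pgs_father = rnorm(n), sex = rbinom(n, 1, 0.5),
                      age_q_return = runif(n, 3, 4),
                      maternal_cluster_id = paste0("m", 1:n))
  d$y <- 0.3 * d$pgs_child + rnorm(n)
  # classical (non-robust) partial r2 via double residualization
  r_y <- residuals(lm(y ~ pgs_mother + pgs_father + sex + age_q_return, d))
  r_x <- residuals(lm(pgs_child ~ pgs_mother + pgs_father + sex +
                        age_q_return, d))
  oracle <- cor(r_y, r_x)^2
  # classical partial r2 from the t statistic with homoskedastic vcov
  ref <- lm(y ~ pgs_child + pgs_mother + pgs_father + sex + age_q_return, d)
  tstat <- summary(ref)$coefficients["pgs_child", "t value"]
  df_res <- n - 6
  expect_equal(tstat^2 / (tstat^2 + df_res), oracle, tolerance = 1e-6)
  # partial_r2 with a homoskedastic vcov hits the oracle exactly
  classical <- list(coefficients = coef(ref), vcov = vcov(ref), n_obs = n)
  expect_equal(partial_r2(classical, "pgs_child"), oracle, tolerance = 1e-6)
  # the package's robust version approaches this on homoskedastic data
  fit <- fit_trio_pgs(d)
  expect_lt(abs(fit$partial_r2_direct - oracle), 0.25 * oracle)
})

test_that("group partial r2 is invariant to reparameterization", {
  d <- simulate_pgs_data(500, beta = c(0.2, 0.15, 0.05), seed = 61)
  fit <- fit_trio_pgs(d)
  r2_orig <- fit$partial_r2_indirect
  # invertible linear recombination of the parental score columns
  d2 <- dplyr::mutate(d, q1 = pgs_mother + pgs_father,
                      q2 = pgs_mother - 2 * pgs_father)
  fit2 <- fit_trio_pgs(d2, pgs = c(child = "pgs_child", mother = "q1",
                                   father = "q2"))
  expect_equal(fit2$partial_r2_indirect, r2_orig, tolerance = 1e-10)
  expect_equal(fit2$partial_r2_direct, fit$partial_r2_direct,
               tolerance = 1e-10)
})

test_that("multi-trait fit with one trait reproduces the single fit", {
  d <- simulate_pgs_data(400, seed = 71)
  single <- fit_trio_pgs(d, trait = "t1")
  map <- tibble::tibble(trait = "t1", role = c("child", "mother", "father"),
                        column = c("pgs_child", "pgs_mother", "pgs_father"))
  multi <- fit_multi_trait(d, "y", map)
  expect_equal(multi$coefficients, single$coefficients)
  expect_equal(multi$partial_r2_direct, single$partial_r2_direct)
})

test_that("multi-trait partial r2 separates direct from indirect signal", {
  # five traits; only trait 1 carries a direct effect
  wins <- sapply(1:20, function(r) {
    base <- simulate_pgs_data(1500, beta = c(0.25, 0, 0), seed = 400 + r)
    d <- base
    for (tr in 2:5) {
      extra <- simulate_pgs_data(1500, beta = c(0, 0, 0), seed = 4000 + 10 * r + tr)
      d[[paste0("pgs_child_t", tr)]] <- extra$pgs_child
      d[[paste0("pgs_mother_t", tr)]] <- extra$pgs_mother
      d[[paste0("pgs_father_t", tr)]] <- extra$pgs_father
    }
    d$pgs_child_t1 <- base$pgs_child
    d$pgs_mother_t1 <- base$pgs_mother
    d$pgs_father_t1 <- base$pgs_father
    map <- tidyr::expand_grid(trait = paste0("t", 1:5),
                              role = c("child", "mother", "father"))
    map$column <- paste0("pgs_", map$role, "_", map$trait)
    fit <- fit_multi_trait(d, "y", map)
    fit$partial_r2_direct > fit$partial_r2_indirect
  })
  expect_gte(sum(wins), 18)
})

test_that("independent null traits explain almost nothing jointly", {
  d <- simulate_pgs_data(5000, beta = c(0, 0, 0), seed = 81)
  for (tr in 2:5) {
    extra <- simulate_pgs_data(5000, seed = 800 + tr)
    d[[paste0("pgs_child_t", tr)]] <- extra$pgs_child
    d[[paste0("pgs_mother_t", tr)]] <- extra$pgs_mother
    d[[paste0("pgs_father_t", tr)]] <- extra$pgs_father
  }
  d$pgs_child_t1 <- d$pgs_child
  d$pgs_mother_t1 <- d$pgs_mother
  d$pgs_father_t1 <- d$pgs_father
  map <- tidyr::expand_grid(trait = paste0("t", 1:5),
                            role = c("child", "mother", "father"))
  map$column <- paste0("pgs_", map$role, "_", map$trait)
  fit <- fit_multi_trait(d, "y", map)
  expect_lt(fit$partial_r2_direct, 0.01)
  expect_lt(fit$partial_r2_indirect, 0.01)
})

test_that("ignoring sibling clustering is anti-conservative", {
  ratios <- sapply(1:30, function(r) {
    d <- simulate_pgs_data(400, beta = c(0.2, 0.1, 0),
                           sibling_fraction = 0.3, maternal_env_sd = 0.7,
                           seed = 600 + r)
    fit_cl <- fit_trio_pgs(d)
    d_single <- dplyr::mutate(d, maternal_cluster_id = child_id)
    fit_un <- fit_trio_pgs(d_single)
    fit_cl$se["pgs_mother"] / fit_un$se["pgs_mother"]
  })
  expect_gt(mean(ratios), 1)
})

test_that("grid-wide FDR corrects within coefficient-role families", {
  res <- tibble::tibble(role = rep(c("child", "mother"), each = 50),
                        p_raw = c(0.0005, rep(1, 49), runif(50)))
  adj <- fdr_grid(res)
  # one signal among 50 tests: 50 * 0.0005 / 1 = 0.025
  expect_equal(adj$p_adj[1], 0.025)
  expect_true(all(adj$p_adj[2:50] == 1))
  # monotone in the raw values within a family
  m <- adj[adj$role == "mother", ]
  expect_true(all(diff(m$p_adj[order(m$p_raw)]) >= 0))
})

test_that("degenerate regression inputs are rejected", {
  d <- simulate_pgs_data(50, seed = 91)
  d$dup <- d$pgs_child
  expect_error(fit_trio_pgs(d, pgs = c(child = "pgs_child", mother = "dup",
                                       father = "pgs_father")),
               "singular")
  d1 <- dplyr::mutate(d, maternal_cluster_id = "all")
  expect_error(fit_trio_pgs(d1), "clusters")
})
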