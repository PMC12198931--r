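# shared fixtures and independent oracles, built once per test run

# small simulated trio dataset reused across modules
small_trio_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geno <- simulate_trio_genotypes(200, 800, seed = 101)
      eff <- simulate_effect_sizes(800, 1,
                                   vc_target_matrix(0.10, 0.10, 0.05),
                                   seed = 102)
      pheno <- simulate_phenotypes(geno, eff, sigma_e2 = 0.75, seed = 103)
      grm <- compute_grm(stack_trio_dosage(geno))
      blocks <- extract_trio_blocks(grm, geno$trios)
      cache <<- list(geno = geno, eff = eff, pheno = pheno, grm = grm,
                     blocks = blocks)
    }
    cache
  }
})

# independent step-up Benjamini-Hochberg implementation (oracle)
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (j in rev(seq_len(m))) {
    running_min <- min(running_min, m * p[o[j]] / j)
    adj[o[j]] <- running_min
  }
  pmin(adj, 1)
}

# dense-matrix evaluation of the restricted -2 log-likelihood (oracle)
neg2ll_dense_oracle <- function(vc, blocks, y, X) {
  v <- build_covariance(vc, blocks)
  vi <- solve(v)
  xtvix <- t(X) %*% vi %*% X
  p_mat <- vi - vi %*% X %*% solve(xtvix) %*% t(X) %*% vi
  as.numeric(determinant(v, logarithm = TRUE)$modulus +
               determinant(xtvix, logarithm = TRUE)$modulus +
               t(y) %*% p_mat %*% y + (length(y) - ncol(X)) * log(2 * pi))
}

# exhaustive Mendel-consistency check: child dosage must be attainable
# from the parents' transmissible alleles
mendel_consistent <- function(geno) {
  k <- geno$child_dosage; m <- geno$mother_dosage; p <- geno$father_dosage
  lo <- (m == 2) + (p == 2)              # minimum transmissible
  hi <- 2 - ((m == 0) + (p == 0))        # maximum transmissible
  ok <- is.na(k) | is.na(m) | is.na(p) | (k >= lo & k <= hi)
  all(ok)
}

# a hand-built trio_grm for tiny algebraic tests
toy_trio_grm <- function(n = 1, a_cc = diag(n), a_mm = diag(n),
                         a_pp = diag(n), a_cm = diag(0.5, n),
                         a_cp = diag(0.5, n), a_mp = matrix(0, n, n)) {
  structure(list(A_cc = a_cc, A_mm = a_mm, A_pp = a_pp, A_cm = a_cm,
                 A_cp = a_cp, A_mp = a_mp,
                 trios = tibble::tibble(child_id = sprintf("C%03d", 1:n)),
                 n_snps_used = NA_integer_),
            class = "trio_grm")
}

published_fit_stats <- function() {
  read_fit_stats(system.file("extdata", "neurodev_fit_stats.tsv",
                             package = "triogen"))
}

# deterministic seed streams for replicate loops in tests
derive_seeds_for_tests <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
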