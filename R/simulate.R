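#' Simulate genotypes for parent-offspring trios
#'
#' Draws unlinked biallelic SNP genotypes for mothers and fathers in
#' Hardy-Weinberg proportions and derives child genotypes by Mendelian
#' transmission. Parents are sampled independently (no assortative mating),
#' so mother-father genomic relatedness is centred on zero while
#' child-parent relatedness is centred on 0.5. Optionally a fraction of
#' mothers receive a second child, creating sibling trios that share a
#' maternal cluster.
#'
#' @param n_trios Number of base trios (one child per mother before siblings
#'   are added).
#' @param n_snps Number of unlinked SNPs.
#' @param maf_range Length-2 numeric interval in (0, 0.5]; per-SNP allele
#'   frequencies are drawn uniformly from it.
#' @param sibling_fraction Proportion of mothers given a second child. Each
#'   sibling appears as an additional trio row sharing mother, father and
#'   `maternal_cluster_id`.
#' @param missing_rate Proportion of dosages set missing completely at
#'   random (default 0, i.e. off).
#' @param seed Integer seed; fixing it reproduces the output exactly.
#'
#' @return A `trio_genotypes` object: matrices `child_dosage`,
#'   `mother_dosage`, `father_dosage` ((n_trios + n_siblings) x n_snps, values
#'   0/1/2 or NA), per-SNP `snp_id`, `effect_allele`, `other_allele`, `maf`,
#'   and a `trios` tibble (`child_id`, `mother_id`, `father_id`,
#'   `maternal_cluster_id`).
#' @export
#' @examples
#' g <- simulate_trio_genotypes(50, 100, seed = 1)
#' dim(g$child_dosage)
simulate_trio_genotypes <- function(n_trios, n_snps,
                                    maf_range = c(0.05, 0.5),
                                    sibling_fraction = 0,
                                    missing_rate = 0,
                                    seed = NULL) {
  if (!is.numeric(n_trios) || n_trios < 1) abort("`n_trios` must be >= 1.")
  if (!is.numeric(n_snps) || n_snps < 1) abort("`n_snps` must be >= 1.")
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    abort("`maf_range` must be an interval within (0, 0.5].")
  if (sibling_fraction < 0 || sibling_fraction >= 1)
    abort("`sibling_fraction` must be in [0, 1).")
  with_seed_(seed, {
    n_trios <- as.integer(n_trios); n_snps <- as.integer(n_snps)
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    # build column-wise so each SNP uses its own allele frequency
    draw_parent <- function(n) {
      m <- matrix(0L, n, n_snps)
      for (j in seq_len(n_snps)) m[, j] <- rbinom(n, 2L, maf[j])
      m
    }
    mom <- draw_parent(n_trios)
    dad <- draw_parent(n_trios)
    kid <- mendelian_transmit(mom, dad)

    n_sib <- as.integer(floor(sibling_fraction * n_trios))
    if (n_sib > 0) {
      sib_of <- sort(sample.int(n_trios, n_sib))
      sib_kid <- mendelian_transmit(mom[sib_of, , drop = FALSE],
                                    dad[sib_of, , drop = FALSE])
      kid <- rbind(kid, sib_kid)
      mom <- rbind(mom, mom[sib_of, , drop = FALSE])
      dad <- rbind(dad, dad[sib_of, , drop = FALSE])
    } else sib_of <- integer(0)

    n_all <- n_trios + n_sib
    pad <- function(pre, i) sprintf("%s%05d", pre, i)
    child_id  <- pad("C", seq_len(n_all))
    mother_id <- pad("M", c(seq_len(n_trios), sib_of))
    father_id <- pad("F", c(seq_len(n_trios), sib_of))

    if (missing_rate > 0) {
      for (nm in c("kid", "mom", "dad")) {
        m <- get(nm)
        miss <- matrix(runif(length(m)) < missing_rate, nrow(m))
        m[miss] <- NA_integer_
        assign(nm, m)
      }
    }
    snp_id <- sprintf("snp%06d", seq_len(n_snps))
    dimnames(kid) <- list(child_id, snp_id)
    dimnames(mom) <- list(mother_id, snp_id)
    dimnames(dad) <- list(father_id, snp_id)
    structure(list(
      child_dosage = kid, mother_dosage = mom, father_dosage = dad,
      snp_id = snp_id,
      effect_allele = rep("A", n_snps), other_allele = rep("G", n_snps),
      maf = maf,
      trios = tibble(child_id = child_id, mother_id = mother_id,
                     father_id = father_id,
                     maternal_cluster_id = mother_id)
    ), class = "trio_genotypes")
  })
}

#' @export
print.trio_genotypes <- function(x, ...) {
  cat("<trio_genotypes> ", nrow(x$child_dosage), " trios x ",
      length(x$snp_id), " SNPs; ",
      dplyr::n_distinct(x$trios$maternal_cluster_id),
      " maternal clusters\n", sep = "")
  invisible(x)
}

#' Mendelian transmission of parental genotypes
#'
#' Each parent transmits one allele: a homozygote transmits its allele with
#' certainty, a heterozygote transmits either allele with probability 1/2,
#' independently across parents and SNPs. The child dosage is the sum of the
#' two transmitted alleles, so e.g. parents (0,0) always yield 0 and (2,0)
#' always yield 1.
#'
#' @param mother_dosage,father_dosage Integer vectors or matrices with
#'   values in \{0, 1, 2\} (equal shapes).
#' @param seed Optional integer seed.
#' @return Child dosages with the same shape as the inputs.
#' @export
#' @examples
#' mendelian_transmit(2L, 0L) # always 1
mendelian_transmit <- function(mother_dosage, father_dosage, seed = NULL) {
  if (length(mother_dosage) != length(father_dosage))
    abort("parental dosage shapes differ.")
  ok <- function(g) all(is.na(g) | g %in% c(0L, 1L, 2L))
  if (!ok(mother_dosage) || !ok(father_dosage))
    abort("dosages must be 0, 1 or 2.")
  with_seed_(seed, {
    transmit <- function(g) {
      t <- as.integer(g == 2L)
      het <- which(!is.na(g) & g == 1L)
      if (length(het)) t[het] <- rbinom(length(het), 1L, 0.5)
      t[is.na(g)] <- NA_integer_
      t
    }
    child <- transmit(mother_dosage) + transmit(father_dosage)
    if (is.matrix(mother_dosage))
      child <- matrix(child, nrow(mother_dosage), ncol(mother_dosage))
    child
  })
}

#' Target covariance matrix for trio effect sizes
#'
#' Convenience constructor for the 3x3 covariance of (direct, maternal,
#' paternal) genetic values used by [simulate_effect_sizes()]. Entries are
#' the target variance components on the phenotypic scale.
#'
#' @param var_c,var_m,var_p Target variances of the child (direct), maternal
#'   and paternal genetic values.
#' @param cov_om,cov_op,cov_mp Target covariance parameters between
#'   direct/maternal, direct/paternal and maternal/paternal effects, on the
#'   variance-decomposition scale (see [simulate_effect_sizes()] details).
#' @return A symmetric 3x3 matrix with dimnames c("c", "m", "p").
#' @export
vc_target_matrix <- function(var_c = 0, var_m = 0, var_p = 0,
                             cov_om = 0, cov_op = 0, cov_mp = 0) {
  s <- matrix(c(var_c, cov_om, cov_op,
                cov_om, var_m, cov_mp,
                cov_op, cov_mp, var_p), 3, 3,
              dimnames = list(c("c", "m", "p"), c("c", "m", "p")))
  s
}

#' Simulate per-SNP direct and indirect effect sizes
#'
#' Causal SNPs receive a triple (beta_c, beta_m, beta_p) drawn i.i.d. from a
#' trivariate normal with covariance `sigma_beta / n_causal`, so that the
#' genetic values built from standardized genotypes have total
#' variance/covariance structure `sigma_beta` in expectation. Non-causal
#' SNPs get exact zeros.
#'
#' @details The entries of `sigma_beta` are the variance-component targets
#' on the scale of the phenotypic variance decomposition: the diagonal gives
#' the variances of the child/mother/father genetic values, and an
#' off-diagonal entry is the covariance *parameter* sigma_om (etc.) as it
#' enters the decomposition `Var(Y) = sigma_c2 + sigma_m2 + sigma_p2 +
#' sigma_om + sigma_op + sigma_e2`. Because a child and its mother share
#' half their genome, the realized sample covariance between child and
#' mother genetic values is approximately `sigma_om * 0.5` — the
#' decomposition counts it twice (once via each direction of sharing), which
#' is why the single parameter appears once in the total.
#'
#' @param n_snps Total number of SNPs.
#' @param causal_fraction Proportion of SNPs that are causal.
#' @param sigma_beta 3x3 symmetric positive semidefinite target matrix, see
#'   [vc_target_matrix()].
#' @param seed Optional integer seed.
#' @return An `effect_triples` object: vectors `beta_c`, `beta_m`, `beta_p`
#'   (length n_snps), logical `causal_mask`, and the `sigma_beta` used.
#' @export
simulate_effect_sizes <- function(n_snps, causal_fraction = 1,
                                  sigma_beta = vc_target_matrix(),
                                  seed = NULL) {
  if (!is.matrix(sigma_beta) || any(dim(sigma_beta) != 3) ||
      max(abs(sigma_beta - t(sigma_beta))) > 1e-12)
    abort("`sigma_beta` must be a symmetric 3x3 matrix.")
  ev <- eigen(sigma_beta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    abort("`sigma_beta` must be positive semidefinite.")
  if (causal_fraction <= 0 || causal_fraction > 1)
    abort("`causal_fraction` must be in (0, 1].")
  with_seed_(seed, {
    n_snps <- as.integer(n_snps)
    n_causal <- max(1L, as.integer(round(causal_fraction * n_snps)))
    causal <- sort(sample.int(n_snps, n_causal))
    beta <- matrix(0, n_snps, 3)
    if (any(sigma_beta != 0)) {
      # draw via eigen square root; PSD (possibly rank-deficient) allowed
      e <- eigen(sigma_beta / n_causal, symmetric = TRUE)
      rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 3) %*% t(e$vectors)
      beta[causal, ] <- matrix(rnorm(n_causal * 3), n_causal, 3) %*% rt
    }
    mask <- rep(FALSE, n_snps); mask[causal] <- TRUE
    structure(list(beta_c = beta[, 1], beta_m = beta[, 2], beta_p = beta[, 3],
                   causal_mask = mask, sigma_beta = sigma_beta),
              class = "effect_triples")
  })
}

# internal: column-standardize dosages with pooled trio allele frequencies;
# monomorphic SNPs contribute zero columns
standardize_trio_dosages <- function(geno) {
  stack <- rbind(geno$child_dosage, geno$mother_dosage, geno$father_dosage)
  p <- colMeans(stack, na.rm = TRUE) / 2
  sdz <- sqrt(2 * p * (1 - p))
  zfun <- function(d) {
    z <- sweep(d, 2, 2 * p)
    z <- sweep(z, 2, ifelse(sdz > 0, sdz, Inf), "/")
    z[is.na(z)] <- 0
    z
  }
  list(z_c = zfun(geno$child_dosage), z_m = zfun(geno$mother_dosage),
       z_p = zfun(geno$father_dosage), p = p)
}

#' Simulate child phenotypes from trio genotypes and effect sizes
#'
#' Builds `y = G_c + G_m + G_p + fixed effects + e`, where `G_c` is the
#' child's direct genetic value (standardized child dosages times `beta_c`),
#' `G_m`/`G_p` are the maternal/paternal indirect genetic values computed
#' from the *parents'* genotypes, and `e ~ N(0, sigma_e2)`. Dosages are
#' standardized with pooled allele frequencies across all trio members,
#' matching [compute_grm()]. Covariates are generated alongside: child sex
#' (Bernoulli 0.5), age at questionnaire return (uniform on 3.0-4.0 years)
#' and a genotyping batch assigned round-robin.
#'
#' @param geno A `trio_genotypes` object.
#' @param effects An `effect_triples` object on the same SNP set.
#' @param sigma_e2 Residual variance (>= 0).
#' @param fixed_effects Optional named list of coefficients applied to the
#'   generated covariates: `intercept`, `sex`, `age`, and `batch` (a vector,
#'   one coefficient per batch level, first level as reference).
#' @param n_batches Number of genotyping-batch levels.
#' @param seed Optional integer seed.
#' @return A tibble (class `phenotype_table`) with `child_id`, `y`, `sex`,
#'   `age_q_return`, `batch`, and bookkeeping columns `g_c`, `g_m`, `g_p`,
#'   `fixed`, `resid` whose sum equals `y` exactly.
#' @export
simulate_phenotypes <- function(geno, effects, sigma_e2 = 1,
                                fixed_effects = NULL, n_batches = 3,
                                seed = NULL) {
  stopifnot(inherits(geno, "trio_genotypes"),
            inherits(effects, "effect_triples"))
  if (length(effects$beta_c) != length(geno$snp_id))
    abort("SNP sets of `geno` and `effects` do not align.")
  if (sigma_e2 < 0) abort("`sigma_e2` must be >= 0.")
  with_seed_(seed, {
    z <- standardize_trio_dosages(geno)
    g_c <- drop(z$z_c %*% effects$beta_c)
    g_m <- drop(z$z_m %*% effects$beta_m)
    g_p <- drop(z$z_p %*% effects$beta_p)
    n <- nrow(geno$child_dosage)
    sex <- rbinom(n, 1L, 0.5)
    age <- runif(n, 3.0, 4.0)
    batch <- factor(rep_len(paste0("b", seq_len(n_batches)), n))
    fixed <- rep(0, n)
    if (!is.null(fixed_effects)) {
      fe <- fixed_effects
      if (!is.null(fe$intercept)) fixed <- fixed + fe$intercept
      if (!is.null(fe$sex)) fixed <- fixed + fe$sex * sex
      if (!is.null(fe$age)) fixed <- fixed + fe$age * age
      if (!is.null(fe$batch)) fixed <- fixed + fe$batch[as.integer(batch)]
    }
    resid <- rnorm(n, 0, sqrt(sigma_e2))
    out <- tibble(
      child_id = geno$trios$child_id,
      y = g_c + g_m + g_p + fixed + resid,
      sex = sex, age_q_return = age, batch = batch,
      g_c = g_c, g_m = g_m, g_p = g_p, fixed = fixed, resid = resid
    )
    class(out) <- c("phenotype_table", class(out))
    out
  })
}

#' Simulate ordinal questionnaire item responses from a latent trait
#'
#' Each item adds independent Gaussian noise to the child's latent value and
#' discretizes the result at the supplied thresholds into ordinal categories
#' 0..length(thresholds). Entries are then set missing completely at random,
#' and reverse-keyed items are emitted on the inverted scale (max - value),
#' emulating questionnaire instruments whose scoring requires reverse-coding
#' and tolerates partial missingness.
#'
#' @param latent A `phenotype_table` (or any tibble with `child_id` and `y`).
#' @param n_items Number of items.
#' @param missing_rate Per-entry missingness probability in [0, 1).
#' @param reverse_items Integer indices of reverse-keyed items.
#' @param thresholds Increasing numeric cut points on the latent + noise
#'   scale.
#' @param noise_sd Item-specific noise standard deviation.
#' @param seed Optional integer seed.
#' @return A tibble with `child_id` and item columns `item_01`..; attributes
#'   `reverse_coded` (logical per item) and `item_range` (c(0, max level)).
#' @export
simulate_item_responses <- function(latent, n_items, missing_rate = 0,
                                    reverse_items = integer(0),
                                    thresholds = c(-0.5, 0.5, 1.5),
                                    noise_sd = 1, seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1)
    abort("`missing_rate` must be in [0, 1).")
  if (is.unsorted(thresholds, strictly = TRUE))
    abort("`thresholds` must be strictly increasing.")
  with_seed_(seed, {
    y <- latent$y
    n <- length(y)
    k <- as.integer(n_items)
    max_level <- length(thresholds)
    items <- matrix(NA_integer_, n, k)
    for (j in seq_len(k)) {
      lat <- y + rnorm(n, 0, noise_sd)
      v <- findInterval(lat, thresholds)
      if (j %in% reverse_items) v <- max_level - v
      miss <- runif(n) < missing_rate
      v[miss] <- NA_integer_
      items[, j] <- v
    }
    colnames(items) <- sprintf("item_%02d", seq_len(k))
    out <- dplyr::bind_cols(tibble(child_id = latent$child_id),
                            as_tibble(items))
    attr(out, "reverse_coded") <- seq_len(k) %in% reverse_items
    attr(out, "item_range") <- c(0L, max_level)
    out
  })
}

#' Simulate trio polygenic scores and outcomes at the score level
#'
#' Generates standardized polygenic scores for mother, father and child
#' (child = mid-parent mean plus segregation noise, giving the expected
#' ~0.7 child-parent score correlation), an outcome built from supplied
#' direct/maternal/paternal coefficients, and optional sibling pairs that
#' share both parents' scores and a common maternal environmental effect
#' in the error. This bypasses genotypes entirely: it is the calibration
#' bed for cluster-robust inference, where many replicates are needed and
#' the genotype layer would add nothing but runtime.
#'
#' @param n_clusters Number of maternal clusters (one child each before
#'   siblings are added).
#' @param beta Length-3 coefficients for (child, mother, father) scores.
#' @param sibling_fraction Fraction of mothers with a second child.
#' @param maternal_env_sd SD of a cluster-level environmental effect added
#'   to every child of a mother (induces within-cluster error correlation).
#' @param sex_beta,age_beta Fixed covariate effects.
#' @param seed Optional integer seed.
#' @return Tibble with `child_id`, `y`, `pgs_child`, `pgs_mother`,
#'   `pgs_father`, `sex`, `age_q_return`, `maternal_cluster_id`.
#' @export
simulate_trio_scores <- function(n_clusters, beta = c(0.2, 0.1, 0),
                                 sibling_fraction = 0,
                                 maternal_env_sd = 0,
                                 sex_beta = 0.1, age_beta = -0.05,
                                 seed = NULL) {
  stopifnot(length(beta) == 3, n_clusters >= 2)
  with_seed_(seed, {
    tm <- rnorm(n_clusters)
    tf <- rnorm(n_clusters)
    n_sib <- floor(sibling_fraction * n_clusters)
    fam <- c(seq_len(n_clusters), seq_len(n_sib))
    env <- rnorm(n_clusters, 0, maternal_env_sd)
    pm <- tm[fam]
    pf <- tf[fam]
    pc <- (pm + pf) / 2 + rnorm(length(fam), 0, sqrt(1 / 2))
    sex <- rbinom(length(fam), 1L, 0.5)
    age <- runif(length(fam), 3, 4)
    y <- beta[1] * pc + beta[2] * pm + beta[3] * pf + env[fam] +
      sex_beta * sex + age_beta * age + rnorm(length(fam))
    tibble(child_id = sprintf("c%06d", seq_along(fam)), y = y,
           pgs_child = pc, pgs_mother = pm, pgs_father = pf,
           sex = sex, age_q_return = age,
           maternal_cluster_id = sprintf("m%06d", fam))
  })
}
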