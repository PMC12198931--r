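#' Compute polygenic scores from a weight table
#'
#' The scoring step of polygenic prediction: for each individual the score
#' is the weighted sum of effect-allele dosages over the SNPs shared
#' between the genotype data and the weight table. SNPs are matched by
#' identifier; when the weight table's effect/other alleles are swapped
#' relative to the stored coding, the dosage is flipped (`2 - d`).
#' Irreconcilable allele pairs are skipped with a warning (no strand
#' flipping is attempted). Weight *derivation* from GWAS summary statistics
#' is out of scope — any weight table can be supplied.
#'
#' @param dosage Individuals x SNPs matrix with SNP IDs as column names.
#' @param snp_meta Tibble with `snp_id`, `effect_allele`, `other_allele`
#'   describing the stored dosage coding.
#' @param weights Tibble with `snp_id`, `effect_allele`, `other_allele`,
#'   `weight`.
#' @return Numeric score vector (one per individual) with attributes
#'   `n_matched`, `n_swapped`, `skipped_snps`.
#' @export
compute_pgs <- function(dosage, snp_meta, weights) {
  stopifnot(all(c("snp_id", "effect_allele", "other_allele") %in%
                  names(snp_meta)),
            all(c("snp_id", "effect_allele", "other_allele", "weight") %in%
                  names(weights)))
  if (anyDuplicated(weights$snp_id)) abort("duplicate SNPs in weight table.")
  idx <- match(weights$snp_id, snp_meta$snp_id)
  present <- !is.na(idx)
  w <- weights[present, , drop = FALSE]
  meta <- snp_meta[idx[present], , drop = FALSE]
  direct <- w$effect_allele == meta$effect_allele &
    w$other_allele == meta$other_allele
  swapped <- w$effect_allele == meta$other_allele &
    w$other_allele == meta$effect_allele
  bad <- !(direct | swapped)
  if (any(bad))
    warn(paste0(sum(bad), " SNP(s) skipped: allele pairs irreconcilable (",
                paste(head(w$snp_id[bad], 3), collapse = ", "), " ...)"))
  use <- which(!bad)
  if (length(use) == 0) abort("no SNPs in the weight table match the data.")
  cols <- match(w$snp_id[use], colnames(dosage))
  d <- dosage[, cols, drop = FALSE]
  sw <- swapped[use]
  if (any(sw)) d[, sw] <- 2 - d[, sw, drop = FALSE]
  d[is.na(d)] <- 0  # missing dosages contribute nothing
  score <- drop(d %*% w$weight[use])
  attr(score, "n_matched") <- length(use)
  attr(score, "n_swapped") <- sum(sw)
  attr(score, "skipped_snps") <- c(weights$snp_id[!present], w$snp_id[bad])
  score
}

#' Principal components of a genotype matrix
#'
#' Top-k principal component scores of the column-standardized dosage
#' matrix (monomorphic SNPs dropped), as used to control population
#' structure when residualizing polygenic scores. Components are
#' orthogonal and ordered by explained variance.
#'
#' @param dosage Individuals x SNPs dosage matrix.
#' @param k Number of components, `k < min(n, m)`.
#' @return n x k matrix of PC scores (columns `PC1`..`PCk`).
#' @export
genotype_pca <- function(dosage, k) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (k >= min(n, m)) abort("`k` must be smaller than min(n individuals, m SNPs).")
  p <- colMeans(dosage, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  z <- scale(dosage[, poly, drop = FALSE])
  z[is.na(z)] <- 0
  sv <- svd(z, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(dosage)
  scores
}

#' Residualize and standardize polygenic scores
#'
#' Ordinary least-squares residuals of the raw scores on the supplied
#' covariates (typically genomic PCs and genotyping/imputation batch
#' dummies), then z-standardized to mean 0 and SD 1. This removes
#' population-structure and batch signal from the scores before they enter
#' trio regressions. Residualization should be run separately within each
#' family role (children, mothers, fathers), since each role's scores enter
#' the trio model as distinct predictors.
#'
#' @param scores Numeric vector of raw scores.
#' @param covariates Data frame or matrix of covariates (an intercept is
#'   added automatically); `NULL` for plain standardization.
#' @return Numeric vector with mean 0 and SD 1.
#' @export
residualize_standardize <- function(scores, covariates = NULL) {
  y <- as.numeric(scores)
  if (is.null(covariates)) {
    x <- matrix(1, length(y), 1)
  } else {
    if (is.data.frame(covariates))
      x <- stats::model.matrix(~ ., data = covariates)
    else x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  }
  if (qr(x)$rank < ncol(x)) abort("covariate design is rank deficient.")
  r <- stats::lm.fit(x, y)$residuals
  s <- sd(r)
  if (s == 0) abort("residualized scores are constant.")
  (r - mean(r)) / s
}

#' Build residualized, standardized trio PGS for one trait
#'
#' Scores children, mothers and fathers with [compute_pgs()] and
#' residualizes each role separately with [residualize_standardize()].
#'
#' @param geno A `trio_genotypes` object.
#' @param weights PGS weight table (see [compute_pgs()]).
#' @param trait Trait label carried through to results.
#' @param covariates Optional per-role covariates: a single data frame used
#'   for every role, or a named list `list(child = , mother = , father = )`.
#' @return Tibble (class `pgs_triple`): `child_id`, `pgs_child`,
#'   `pgs_mother`, `pgs_father`, attribute `trait`.
#' @export
compute_trio_pgs <- function(geno, weights, trait = "trait",
                             covariates = NULL) {
  stopifnot(inherits(geno, "trio_genotypes"))
  meta <- tibble(snp_id = geno$snp_id, effect_allele = geno$effect_allele,
                 other_allele = geno$other_allele)
  role_cov <- function(role) {
    if (is.null(covariates)) NULL
    else if (is.data.frame(covariates)) covariates
    else covariates[[role]]
  }
  one <- function(d, role) {
    residualize_standardize(compute_pgs(d, meta, weights), role_cov(role))
  }
  out <- tibble(
    child_id = geno$trios$child_id,
    pgs_child = one(geno$child_dosage, "child"),
    pgs_mother = one(geno$mother_dosage, "mother"),
    pgs_father = one(geno$father_dosage, "father")
  )
  attr(out, "trait") <- trait
  class(out) <- c("pgs_triple", class(out))
  out
}
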