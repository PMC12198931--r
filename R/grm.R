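#' Compute a genomic relatedness matrix (GRM)
#'
#' Standard GREML relatedness: per-SNP dosages are standardized as
#' `z = (g - 2p) / sqrt(2p(1-p))` and relatedness is `A = Z Z' / m` over the
#' m polymorphic SNPs. Monomorphic SNPs (p = 0 or 1) are excluded; missing
#' dosages are mean-imputed to `2p` before standardization (i.e. they
#' contribute zero).
#'
#' @param dosage Numeric matrix, individuals x SNPs, values in [0, 2]
#'   (NA allowed). Row names are used as individual IDs.
#' @param freq Optional vector of per-SNP allele frequencies; by default
#'   frequencies are pooled estimates `colMeans(dosage)/2` over all
#'   individuals supplied.
#' @param ids Individual identifiers; defaults to `rownames(dosage)`.
#' @return A `grm` object: `values` (symmetric n x n), `ids`, `n_snps_used`.
#' @export
#' @examples
#' d <- rbind(i1 = c(0, 2), i2 = c(2, 0), i3 = c(1, 1))
#' compute_grm(d)$values
compute_grm <- function(dosage, freq = NULL, ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) < 2) abort("need at least 2 individuals.")
  if (is.null(ids)) ids <- sprintf("ind%05d", seq_len(nrow(dosage)))
  if (anyDuplicated(ids)) abort("individual IDs must be unique.")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) abort("dosages must lie in [0, 2].")
  p <- if (is.null(freq)) colMeans(dosage, na.rm = TRUE) / 2 else freq
  if (length(p) != ncol(dosage)) abort("`freq` length must match SNP count.")
  poly <- which(p > 0 & p < 1)
  if (length(poly) == 0) abort("all SNPs are monomorphic; no GRM computable.")
  d <- dosage[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(d, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0  # mean imputation to 2p maps to zero after centering
  a <- tcrossprod(z) / length(poly)
  a <- (a + t(a)) / 2
  dimnames(a) <- list(ids, ids)
  structure(list(values = a, ids = ids, n_snps_used = length(poly)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", length(x$ids), " individuals, ", x$n_snps_used,
      " SNPs used; mean diag = ", round(mean(diag(x$values)), 4), "\n",
      sep = "")
  invisible(x)
}

#' Stack trio dosages into one individuals-by-SNPs matrix
#'
#' Binds child, mother and father dosage matrices row-wise (IDs preserved),
#' the form [compute_grm()] expects for a full-sample GRM.
#'
#' @param geno A `trio_genotypes` object.
#' @return A numeric matrix with one row per individual.
#' @export
stack_trio_dosage <- function(geno) {
  stopifnot(inherits(geno, "trio_genotypes"))
  # duplicated parents (sibling trios) appear once
  stack <- rbind(geno$child_dosage,
                 geno$mother_dosage[!duplicated(rownames(geno$mother_dosage)), ,
                                    drop = FALSE],
                 geno$father_dosage[!duplicated(rownames(geno$father_dosage)), ,
                                    drop = FALSE])
  stack
}

#' Extract the six trio relatedness blocks from a full-sample GRM
#'
#' Slices the child-child, mother-mother, father-father within-role blocks
#' and the child-mother, child-father, mother-father cross blocks, all in
#' trio order. Cross blocks are oriented so that entry (i, j) relates the
#' first-named role of trio i to the second-named role of trio j; the
#' diagonal of `A_cm`/`A_cp` therefore holds within-trio parent-offspring
#' relatedness (expected 0.5).
#'
#' @param grm A `grm` covering every trio member.
#' @param trios Tibble with `child_id`, `mother_id`, `father_id` (and
#'   optionally `maternal_cluster_id`).
#' @return A `trio_grm` object with blocks `A_cc`, `A_mm`, `A_pp`, `A_cm`,
#'   `A_cp`, `A_mp`, the trio table, and `n_snps_used`.
#' @export
extract_trio_blocks <- function(grm, trios) {
  stopifnot(inherits(grm, "grm"))
  need <- c(trios$child_id, trios$mother_id, trios$father_id)
  missing_ids <- setdiff(unique(need), grm$ids)
  if (length(missing_ids))
    abort(paste0("trio members absent from GRM: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  ic <- match(trios$child_id, grm$ids)
  im <- match(trios$mother_id, grm$ids)
  ip <- match(trios$father_id, grm$ids)
  v <- grm$values
  structure(list(
    A_cc = v[ic, ic, drop = FALSE], A_mm = v[im, im, drop = FALSE],
    A_pp = v[ip, ip, drop = FALSE], A_cm = v[ic, im, drop = FALSE],
    A_cp = v[ic, ip, drop = FALSE], A_mp = v[im, ip, drop = FALSE],
    trios = as_tibble(trios), n_snps_used = grm$n_snps_used
  ), class = "trio_grm")
}

#' @export
print.trio_grm <- function(x, ...) {
  cat("<trio_grm> ", nrow(x$trios), " trios; mean within-trio child-mother",
      " relatedness = ", round(mean(diag(x$A_cm)), 3), "\n", sep = "")
  invisible(x)
}

#' Prune trios until no cross-trio relatedness exceeds a threshold
#'
#' Builds the graph of individual pairs with relatedness strictly above
#' `threshold`, excluding each trio's own child-mother, child-father and
#' mother-father pairs, then greedily removes whole trios: at each step the
#' trio whose members cover the most remaining edges is dropped (ties broken
#' by smallest child ID) until no edges remain. This is a greedy
#' vertex-cover analogue of relatedness-based sample pruning, keeping the
#' analysis sample free of cryptic relatedness while never penalizing the
#' expected ~0.5 relatedness within a trio.
#'
#' @param grm A `grm` covering all trio members.
#' @param trios Trio tibble (`child_id`, `mother_id`, `father_id`, ...).
#' @param threshold Relatedness cut-off; pairs strictly above it count as
#'   edges. Default 0.1.
#' @return The retained subset of `trios` (same columns, original order).
#' @export
prune_related <- function(grm, trios, threshold = 0.1) {
  stopifnot(inherits(grm, "grm"))
  if (threshold <= 0) abort("`threshold` must be > 0.")
  n_t <- nrow(trios)
  idx <- cbind(match(trios$child_id, grm$ids),
               match(trios$mother_id, grm$ids),
               match(trios$father_id, grm$ids))
  if (anyNA(idx)) abort("trio member absent from GRM.")
  v <- grm$values
  n <- length(grm$ids)
  # trio membership of each individual (an individual can sit in several
  # trio rows, e.g. shared parents of sibling trios)
  member_of <- vector("list", n)
  for (t in seq_len(n_t)) for (i in idx[t, ])
    member_of[[i]] <- c(member_of[[i]], t)
  ut <- upper.tri(v)
  hot <- which(ut & v > threshold, arr.ind = TRUE)
  if (nrow(hot)) {
    # drop within-trio pairs of the same trio row
    same_trio <- vapply(seq_len(nrow(hot)), function(r) {
      length(intersect(member_of[[hot[r, 1]]], member_of[[hot[r, 2]]])) > 0
    }, logical(1))
    hot <- hot[!same_trio, , drop = FALSE]
  }
  keep <- rep(TRUE, n_t)
  while (nrow(hot) > 0) {
    cover <- integer(n_t)
    for (r in seq_len(nrow(hot))) {
      ts <- unique(c(member_of[[hot[r, 1]]], member_of[[hot[r, 2]]]))
      cover[ts] <- cover[ts] + 1L
    }
    cover[!keep] <- 0L
    cand <- which(cover == max(cover))
    drop_t <- cand[order(trios$child_id[cand])][1]
    keep[drop_t] <- FALSE
    # an individual stays in the sample iff some retained trio contains it
    present <- vapply(seq_len(n), function(i) {
      ts <- member_of[[i]]
      length(ts) > 0 && any(keep[ts])
    }, logical(1))
    alive <- vapply(seq_len(nrow(hot)), function(r) {
      present[hot[r, 1]] && present[hot[r, 2]]
    }, logical(1))
    hot <- hot[alive, , drop = FALSE]
  }
  trios[keep, , drop = FALSE]
}
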