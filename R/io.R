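#' Write trio genotypes as a PLINK fileset
#'
#' Emits `.bed` (SNP-major, 2-bit codes), `.bim` and `.fam` files plus a
#' trio TSV. The `.fam` file carries within-family parental IDs so the
#' trio structure is recoverable: each child row names its father and
#' mother, and parents appear as founders. Dosages are stored as counts of
#' the effect allele (allele 1 in the `.bim`).
#'
#' @param geno A `trio_genotypes` object.
#' @param prefix Output path prefix (directories must exist).
#' @return Invisibly, the prefix. Side effects: writes `<prefix>.bed/.bim/`
#'   `.fam` and `<prefix>.trios.tsv`.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "trio_genotypes"))
  d <- stack_trio_dosage(geno)
  ids <- rownames(d)
  tr <- geno$trios
  fam <- data.frame(
    fid = ids, iid = ids,
    pid = ifelse(ids %in% tr$child_id,
                 tr$father_id[match(ids, tr$child_id)], "0"),
    mid = ifelse(ids %in% tr$child_id,
                 tr$mother_id[match(ids, tr$child_id)], "0"),
    sex = 0L, pheno = -9L)
  fam$fid <- ifelse(ids %in% tr$child_id,
                    tr$maternal_cluster_id[match(ids, tr$child_id)], ids)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = 1L, snp = geno$snp_id, cm = 0,
                    bp = seq_along(geno$snp_id),
                    a1 = geno$effect_allele, a2 = geno$other_allele)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # bed encoding per SNP-major byte stream: 00 hom a1a1 (dosage 2),
  # 10 het, 11 hom a2a2 (dosage 0), 01 missing
  n <- nrow(d)
  code <- function(g) {
    out <- integer(length(g))
    out[is.na(g)] <- 1L
    out[!is.na(g) & g == 2] <- 0L
    out[!is.na(g) & g == 1] <- 2L
    out[!is.na(g) & g == 0] <- 3L
    out
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  n_bytes <- ceiling(n / 4)
  for (j in seq_len(ncol(d))) {
    cc <- code(d[, j])
    length(cc) <- n_bytes * 4    # pad with NA -> 0
    cc[is.na(cc)] <- 0L
    m <- matrix(cc, 4, n_bytes)
    bytes <- m[1, ] + 4L * m[2, ] + 16L * m[3, ] + 64L * m[4, ]
    writeBin(as.raw(bytes), con)
  }
  write.table(tr, paste0(prefix, ".trios.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK fileset into dosage matrices
#'
#' Reads `.bed/.bim/.fam` (SNP-major `.bed` only) and returns the dosage
#' matrix (counts of allele 1) with individual and SNP metadata. When the
#' `.fam` parental IDs define complete trios, a trio table is attached.
#'
#' @param prefix Path prefix of the fileset.
#' @return List: `dosage` (individuals x SNPs, NA for missing), `fam`,
#'   `bim` tibbles, and `trios` (possibly 0-row).
#' @export
read_plink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"),
                    col.names = c("fid", "iid", "pid", "mid", "sex",
                                  "pheno"),
                    colClasses = c(rep("character", 4), "integer",
                                   "numeric"))
  bim <- read.table(paste0(prefix, ".bim"),
                    col.names = c("chr", "snp", "cm", "bp", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    abort("not a SNP-major PLINK .bed file.")
  n_bytes <- ceiling(n / 4)
  raw <- readBin(con, "raw", n_bytes * m)
  if (length(raw) < n_bytes * m) abort("truncated .bed file.")
  vals <- as.integer(raw)
  # unpack 2-bit codes: 00->2, 10->1, 11->0, 01->NA
  lut <- c(2L, NA_integer_, 1L, 0L)
  g <- matrix(NA_integer_, n, m)
  shift <- c(1L, 4L, 16L, 64L)
  for (s in 1:4) {
    codes <- (vals %/% shift[s]) %% 4L
    slot <- matrix(lut[codes + 1L], n_bytes, m)
    rows <- seq.int(s, by = 4, length.out = n_bytes)
    keep <- rows <= n
    g[rows[keep], ] <- slot[keep, ]
  }
  dimnames(g) <- list(fam$iid, bim$snp)
  child <- fam$pid != "0" & fam$mid != "0" &
    fam$pid %in% fam$iid & fam$mid %in% fam$iid
  trios <- tibble(child_id = fam$iid[child], mother_id = fam$mid[child],
                  father_id = fam$pid[child],
                  maternal_cluster_id = fam$mid[child])
  list(dosage = g, fam = as_tibble(fam), bim = as_tibble(bim),
       trios = trios)
}

#' Write a GRM to disk
#'
#' Either the GCTA-style binary triple (`.grm.bin`: lower triangle as
#' float32, `.grm.id`, `.grm.N.bin`: per-pair SNP counts as float32) or a
#' plain TSV square matrix with IDs as header.
#'
#' @param grm A `grm` object.
#' @param prefix Output prefix (binary) or file path (TSV).
#' @param format `"gcta"` or `"tsv"`.
#' @return Invisibly, the prefix/path.
#' @export
write_grm <- function(grm, prefix, format = c("gcta", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(grm, "grm"))
  if (format == "tsv") {
    m <- grm$values
    df <- data.frame(id = grm$ids, m, check.names = FALSE)
    colnames(df) <- c("id", grm$ids)
    write.table(df, prefix, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(prefix))
  }
  n <- length(grm$ids)
  lower <- grm$values[upper.tri(grm$values, diag = TRUE)]
  # GCTA stores row-wise lower triangle: entries (i,j) j<=i; equal to the
  # column-wise upper triangle of the symmetric matrix
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(lower, con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps_used), n * (n + 1) / 2), con, size = 4)
  close(con)
  write.table(data.frame(fid = grm$ids, iid = grm$ids),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM from disk
#'
#' Counterpart of [write_grm()]. Binary values are float32, so the binary
#' round trip is exact at single precision; the TSV round trip is exact at
#' the printed precision (full double precision by default).
#'
#' @param prefix Prefix of a GCTA triple, or TSV path.
#' @param format `"gcta"` or `"tsv"`.
#' @return A `grm` object.
#' @export
read_grm <- function(prefix, format = c("gcta", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(prefix, check.names = FALSE)
    ids <- as.character(df$id)
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(ids, ids)
    return(structure(list(values = (m + t(m)) / 2, ids = ids,
                          n_snps_used = NA_integer_), class = "grm"))
  }
  id <- read.table(paste0(prefix, ".grm.id"),
                   col.names = c("fid", "iid"),
                   colClasses = "character")
  n <- nrow(id)
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, "numeric", n * (n + 1) / 2, size = 4)
  close(con)
  m <- matrix(0, n, n)
  m[upper.tri(m, diag = TRUE)] <- vals
  m <- m + t(m) - diag(diag(m))
  dimnames(m) <- list(id$iid, id$iid)
  nsnp <- NA_integer_
  nfile <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nfile)) {
    con <- file(nfile, "rb")
    nvals <- readBin(con, "numeric", 1, size = 4)
    close(con)
    nsnp <- as.integer(round(nvals[1]))
  }
  structure(list(values = m, ids = id$iid, n_snps_used = nsnp),
            class = "grm")
}

#' Write a phenotype/covariate table as TSV
#'
#' @param pheno A `phenotype_table` (or any data frame).
#' @param path Output file.
#' @param true_components Include the simulation bookkeeping columns
#'   (`g_c`, `g_m`, `g_p`, `fixed`, `resid`) when present.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(pheno, path, true_components = FALSE) {
  keep <- c("child_id", "y", "sex", "age_q_return", "batch")
  if (true_components)
    keep <- c(keep, intersect(c("g_c", "g_m", "g_p", "fixed", "resid"),
                              names(pheno)))
  write.table(as.data.frame(pheno)[, intersect(keep, names(pheno))],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
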