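#' Fisher's exact test of allelic association (2 x 2)
#'
#' Exact two-sided p-value for a case/control by allele-A/allele-B count
#' table, computed by direct hypergeometric enumeration at fixed margins:
#' the p-value is the sum of the probabilities of all tables at least as
#' extreme as (probability no larger than) the observed one.
#'
#' @param table 2 x 2 matrix of non-negative integer allele counts, rows
#'   case/control, columns allele A/allele B.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_allelic_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(table < 0)) stop("negative count in allele table")
  if (sum(table) == 0) stop("allele table has zero grand total")
  m <- sum(table[, 1])          # allele A total (white balls)
  n <- sum(table[, 2])          # allele B total
  k <- sum(table[1, ])          # case alleles drawn
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  x_obs <- table[1, 1]
  support <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

#' Per-SNP Fisher allelic association scan
#'
#' Builds a 2 x 2 allele-count table per SNP from case and control diploid
#' genotypes (animals with a missing genotype are dropped at that SNP
#' only) and applies [fisher_allelic_test()]. Monomorphic SNPs receive
#' p = 1 and a flag. A Bonferroni-adjusted column is provided for
#' convenience; the primary p-values are unadjusted.
#'
#' @param case_genotypes,control_genotypes matrices of alt-allele dosage
#'   (0/1/2, `NA` missing), animals in rows, SNPs in columns; equal column
#'   counts.
#' @param map `data.frame` with columns `chrom` and `pos` (one row per
#'   SNP), or a numeric position vector.
#' @return `data.frame` sorted by position: `chrom`, `pos`, `p`,
#'   `p_bonferroni`, `monomorphic`.
#' @export
association_scan <- function(case_genotypes, control_genotypes, map) {
  case_genotypes <- as.matrix(case_genotypes)
  control_genotypes <- as.matrix(control_genotypes)
  stopifnot(ncol(case_genotypes) == ncol(control_genotypes))
  if (is.numeric(map) && is.null(dim(map)))
    map <- data.frame(chrom = "1", pos = map)
  stopifnot(nrow(map) == ncol(case_genotypes))

  nsnp <- nrow(map)
  counts <- function(g) {
    called <- colSums(!is.na(g))
    b <- colSums(g, na.rm = TRUE)          # alt-allele count
    cbind(A = 2 * called - b, B = b)
  }
  ca <- counts(case_genotypes); co <- counts(control_genotypes)
  p <- numeric(nsnp); mono <- logical(nsnp)
  for (i in seq_len(nsnp)) {
    tab <- rbind(ca[i, ], co[i, ])
    mono[i] <- sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0
    p[i] <- if (sum(tab) == 0) NA_real_ else fisher_allelic_test(tab)
  }
  out <- data.frame(chrom = map$chrom, pos = map$pos, p = p,
                    p_bonferroni = pmin(1, p * nsnp), monomorphic = mono)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Shared homozygosity segments across affected animals
#'
#' Autozygosity mapping: a SNP qualifies when every case is homozygous and
#' all cases carry the same allele (the shared founder-haplotype reading of
#' autozygosity). By default a missing genotype in any case disqualifies
#' the SNP; with `missing_tolerant = TRUE` missing cases are ignored as
#' long as at least one case is called. Segments are maximal runs of at
#' least `min_snps` consecutive qualifying SNPs, reported with the
#' positions of their first and last qualifying SNP, longest run first.
#'
#' @param case_genotypes matrix of alt-allele dosage (0/1/2, `NA` missing)
#'   for the affected animals, one chromosome, SNPs in column order.
#' @param map `data.frame` with `chrom` and `pos` (position-sorted), or a
#'   sorted numeric position vector.
#' @param min_snps minimum number of consecutive qualifying SNPs.
#' @param missing_tolerant missing-genotype handling (see above).
#' @return `data.frame` with `chrom`, `start`, `end`, `n_snps`,
#'   `start_index`, `end_index`, and list column `shared_allele` (the
#'   shared dosage, 0 or 2, per SNP in the segment).
#' @export
shared_homozygosity_segments <- function(case_genotypes, map, min_snps = 20,
                                         missing_tolerant = FALSE) {
  g <- as.matrix(case_genotypes)
  if (is.numeric(map) && is.null(dim(map)))
    map <- data.frame(chrom = "1", pos = map)
  stopifnot(nrow(map) == ncol(g))
  if (length(unique(map$chrom)) > 1L)
    stop("segments are defined on a single chromosome")
  if (is.unsorted(map$pos, strictly = TRUE))
    stop("map positions must be sorted and unique")

  qual <- logical(ncol(g)); allele <- rep(NA_real_, ncol(g))
  for (i in seq_len(ncol(g))) {
    x <- g[, i]
    if (anyNA(x)) {
      if (!missing_tolerant) next
      x <- x[!is.na(x)]
      if (length(x) == 0L) next
    }
    u <- unique(x)
    if (length(u) == 1L && u %in% c(0, 2)) {
      qual[i] <- TRUE; allele[i] <- u
    }
  }
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_snps
  if (!any(keep))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      start_index = integer(0), end_index = integer(0)))
  si <- starts[keep]; ei <- ends[keep]
  out <- data.frame(chrom = map$chrom[si], start = map$pos[si],
                    end = map$pos[ei], n_snps = ei - si + 1L,
                    start_index = si, end_index = ei)
  out$shared_allele <- lapply(seq_along(si),
                              function(j) allele[si[j]:ei[j]])
  out[order(-out$n_snps), , drop = FALSE]
}
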