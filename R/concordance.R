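GT_STATES <- c("hom_ref", "het", "hom_alt", "missing")
SEQ_STATES <- c("hom_ref", "het", "hom_alt", "missing_or_filtered")

#' Build a genotype-call table
#'
#' Normalises a set of per-site, per-animal diploid genotype calls into the
#' long format consumed by [build_concordance_table()].
#'
#' @param chrom,pos site coordinates (1-based positions).
#' @param animal animal/sample id.
#' @param gt genotype state, one of `"hom_ref"`, `"het"`, `"hom_alt"`,
#'   `"missing"`.
#' @param quality phred-scaled genotype quality (`NA` for array calls or
#'   missing genotypes).
#' @param ref,alt optional allele columns used to detect cross-platform
#'   allele mismatches.
#' @return `data.frame` with one row per (site, animal) call.
#' @export
genotype_calls <- function(chrom, pos, animal, gt, quality = NA_real_,
                           ref = NULL, alt = NULL) {
  gt <- as.character(gt)
  bad <- setdiff(unique(gt), GT_STATES)
  if (length(bad)) stop("unknown genotype states: ", paste(bad, collapse = ", "))
  if (any(pos < 1)) stop("positions must be >= 1")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   animal = as.character(animal), gt = gt,
                   quality = as.numeric(quality), stringsAsFactors = FALSE)
  if (!is.null(ref)) df$ref <- as.character(ref)
  if (!is.null(alt)) df$alt <- as.character(alt)
  df
}

#' Cross-platform genotype concordance table
#'
#' Tallies array-derived against sequence-derived genotypes over shared
#' (site, animal) pairs into a 3 x 4 table: array state (hom_ref / het /
#' hom_alt) by sequence state (hom_ref / het / hom_alt /
#' missing_or_filtered). Sequence genotypes that are missing or whose
#' phred-scaled quality falls below `min_phred` are tallied as
#' `missing_or_filtered`. Pairs with an uncalled array genotype, pairs
#' present on only one platform, and sites whose ref/alt alleles disagree
#' between platforms (when both tables carry allele columns) are excluded
#' from the table and reported in attributes and a message.
#'
#' @param array_calls,seq_calls call tables as produced by
#'   [genotype_calls()] (array calls are treated as truth).
#' @param min_phred phred-scaled quality threshold for sequence calls.
#' @return 3 x 4 integer matrix of class `"concordance_table"` with
#'   attributes `n_unmatched` (pairs on one platform only) and
#'   `n_allele_mismatch` (pairs at excluded mismatching sites).
#' @export
build_concordance_table <- function(array_calls, seq_calls, min_phred = 0) {
  key <- function(d) paste(d$chrom, d$pos, d$animal, sep = "\r")
  skey <- function(d) paste(d$chrom, d$pos, sep = "\r")

  n_mismatch <- 0L
  if (all(c("ref", "alt") %in% names(array_calls)) &&
      all(c("ref", "alt") %in% names(seq_calls))) {
    asite <- unique(array_calls[c("chrom", "pos", "ref", "alt")])
    ssite <- unique(seq_calls[c("chrom", "pos", "ref", "alt")])
    m <- merge(asite, ssite, by = c("chrom", "pos"),
               suffixes = c("_array", "_seq"))
    bad <- m[m$ref_array != m$ref_seq | m$alt_array != m$alt_seq, ,
             drop = FALSE]
    if (nrow(bad)) {
      badkey <- paste(bad$chrom, bad$pos, sep = "\r")
      n_mismatch <- sum(skey(array_calls) %in% badkey)
      message(nrow(bad), " site(s) with allele mismatch between platforms excluded")
      array_calls <- array_calls[!(skey(array_calls) %in% badkey), , drop = FALSE]
      seq_calls <- seq_calls[!(skey(seq_calls) %in% badkey), , drop = FALSE]
    }
  }

  array_calls <- array_calls[array_calls$gt != "missing", , drop = FALSE]
  ak <- key(array_calls); sk <- key(seq_calls)
  shared <- ak %in% sk
  n_unmatched <- sum(!shared) + sum(!(sk %in% ak))
  if (n_unmatched)
    message(n_unmatched, " (site, animal) pair(s) present on one platform only excluded")
  a <- array_calls[shared, , drop = FALSE]
  s <- seq_calls[match(key(a), sk), , drop = FALSE]

  seq_state <- s$gt
  filtered <- seq_state == "missing" |
    (!is.na(s$quality) & s$quality < min_phred) |
    (is.na(s$quality) & min_phred > 0)
  seq_state[filtered] <- "missing_or_filtered"

  tab <- table(factor(a$gt, levels = GT_STATES[1:3]),
               factor(seq_state, levels = SEQ_STATES))
  out <- matrix(as.integer(tab), nrow = 3,
                dimnames = list(array = GT_STATES[1:3], seq = SEQ_STATES))
  structure(out, class = c("concordance_table", class(out)),
            n_unmatched = n_unmatched, n_allele_mismatch = n_mismatch)
}

#' Non-reference sensitivity and discrepancy
#'
#' Genotype-level concordance metrics for sequence-derived against
#' array-derived (truth) genotypes:
#' \describe{
#'   \item{NRS}{non-reference sensitivity: of the pairs where the array
#'     genotype is non-reference (het or hom_alt), the fraction recovered as
#'     non-reference by sequencing. A missing or quality-filtered sequence
#'     genotype counts as a failure.}
#'   \item{NRD}{non-reference discrepancy: among pairs where both platforms
#'     yield a called genotype, the fraction discordant, with the concordant
#'     hom_ref / hom_ref cell excluded from the denominator.}
#' }
#' A metric whose denominator is zero is undefined and returned as `NA`.
#'
#' @param table a `"concordance_table"` from [build_concordance_table()].
#' @return List with numeric scalars `nrs` and `nrd` (fractions in
#'   \[0, 1\], or `NA` when undefined).
#' @export
concordance_metrics <- function(table) {
  stopifnot(inherits(table, "concordance_table"))
  nonref <- c("het", "hom_alt")
  nrs_den <- sum(table[nonref, ])
  nrs_num <- sum(table[nonref, nonref])
  nrs <- if (nrs_den > 0) nrs_num / nrs_den else NA_real_

  bc <- table[, GT_STATES[1:3]]
  nrd_den <- sum(bc) - bc["hom_ref", "hom_ref"]
  nrd_num <- sum(bc) - sum(diag(bc))
  nrd <- if (nrd_den > 0) nrd_num / nrd_den else NA_real_
  list(nrs = nrs, nrd = nrd)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Array (rows, truth) vs sequence (columns) genotype concordance\n")
  print(unclass(x)[, , drop = FALSE])
  m <- concordance_metrics(x)
  cat(sprintf("NRS = %s, NRD = %s\n",
              format(m$nrs, digits = 4), format(m$nrd, digits = 4)))
  if (attr(x, "n_unmatched") > 0 || attr(x, "n_allele_mismatch") > 0)
    cat(sprintf("excluded: %d unmatched pair(s), %d at allele-mismatch site(s)\n",
                attr(x, "n_unmatched"), attr(x, "n_allele_mismatch")))
  invisible(x)
}
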