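VARIANT_CLASSES <- c("biallelic_snv", "triallelic", "insertion", "deletion",
                     "other")

#' Classify variant records
#'
#' Assigns every variant one of five classes from its alleles (VCF
#' left-anchored convention): a single length-1 alternate of a length-1
#' reference is a biallelic SNV; two length-1 alternates a triallelic site;
#' a single longer (shorter) alternate an insertion (deletion); anything
#' else `other`.
#'
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref` and `alt`
#'   (alternate alleles, comma-separated for multi-allelic sites).
#' @return The input with an added factor column `class`.
#' @export
classify_variants <- function(variants) {
  ref <- toupper(variants$ref)
  altl <- strsplit(toupper(variants$alt), ",", fixed = TRUE)
  ok <- grepl("^[ACGT]+$", ref) &
    vapply(altl, function(a) length(a) > 0 && all(grepl("^[ACGT]+$", a)),
           logical(1))
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf("malformed alleles at %s:%d (ref '%s', alt '%s')",
                 variants$chrom[i], variants$pos[i],
                 variants$ref[i], variants$alt[i]))
  }
  n_alt <- lengths(altl)
  alt1 <- vapply(altl, `[`, character(1), 1L)
  len_ok1 <- nchar(alt1)
  cls <- rep("other", nrow(variants))
  snv <- n_alt == 1L & nchar(ref) == 1L & len_ok1 == 1L
  tri <- n_alt == 2L & nchar(ref) == 1L &
    vapply(altl, function(a) all(nchar(a) == 1L), logical(1))
  ins <- n_alt == 1L & len_ok1 > nchar(ref)
  del <- n_alt == 1L & len_ok1 < nchar(ref)
  cls[ins] <- "insertion"; cls[del] <- "deletion"
  cls[tri] <- "triallelic"; cls[snv] <- "biallelic_snv"
  variants$class <- factor(cls, levels = VARIANT_CLASSES)
  if (any(cls == "other"))
    message(sum(cls == "other"), " variant(s) classified as 'other'")
  variants
}

#' Transition/transversion ratio
#'
#' Ratio of transitions (A<->G, C<->T) to transversions among biallelic
#' SNVs. Multi-allelic sites and InDels do not contribute. Undefined ratios
#' (no transversions, or no biallelic SNVs at all) are returned as `NA`
#' rather than 0.
#'
#' @param variants variant table; classified with [classify_variants()] if
#'   the `class` column is absent.
#' @return Numeric scalar (or `NA` when undefined).
#' @export
titv_ratio <- function(variants) {
  if (is.null(variants$class)) variants <- classify_variants(variants)
  snv <- variants[variants$class == "biallelic_snv", , drop = FALSE]
  if (nrow(snv) == 0L) return(NA_real_)
  pair <- paste0(toupper(snv$ref), toupper(snv$alt))
  ti <- pair %in% c("AG", "GA", "CT", "TC")
  n_tv <- sum(!ti)
  if (n_tv == 0L) return(NA_real_)
  sum(ti) / n_tv
}

#' Variant catalogue summary
#'
#' Per-chromosome counts of variants by class, the Ti/Tv ratio, and the
#' partition into novel versus known sites (keyed by chromosome, position,
#' ref and alt). Duplicate records are removed with a message. When a
#' pseudoautosomal boundary is supplied, X-chromosome rows are split into
#' `"X (non PAR)"` (proximal of the boundary) and `"X (PAR)"` (from the
#' boundary to the distal end).
#'
#' @param variants variant table with `chrom`, `pos`, `ref`, `alt`.
#' @param known_sites optional `data.frame` with the same four key columns
#'   (e.g. a dbSNP extract); `NULL` means every variant is novel.
#' @param par_boundary optional 1-based position on chromosome `x_chrom`
#'   from which the pseudoautosomal region extends distally.
#' @param x_chrom name of the X chromosome in `variants`.
#' @return List of class `"variant_catalogue"`: `by_chromosome` (counts per
#'   chromosome and class), `n_total`, `n_known`, `n_novel`, `pct_novel`,
#'   `titv`.
#' @export
catalogue_summary <- function(variants, known_sites = NULL,
                              par_boundary = NULL, x_chrom = "X") {
  if (is.null(variants$class)) variants <- classify_variants(variants)
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = "\r")
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate variant record(s) removed")
    variants <- variants[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }

  chrom_label <- as.character(variants$chrom)
  if (!is.null(par_boundary)) {
    on_x <- chrom_label == x_chrom
    chrom_label[on_x] <- ifelse(variants$pos[on_x] >= par_boundary,
                                paste(x_chrom, "(PAR)"),
                                paste(x_chrom, "(non PAR)"))
  }
  indel <- variants$class %in% c("insertion", "deletion")
  grp <- as.character(variants$class)
  grp[indel] <- "indel"
  tab <- table(chromosome = chrom_label,
               class = factor(grp, levels = c("biallelic_snv", "triallelic",
                                              "indel", "other")))
  by_chrom <- as.data.frame.matrix(tab)
  by_chrom <- data.frame(chromosome = rownames(by_chrom), by_chrom,
                         row.names = NULL, check.names = FALSE)

  n_known <- 0L
  if (!is.null(known_sites) && nrow(known_sites) > 0) {
    kkey <- paste(known_sites$chrom, known_sites$pos, known_sites$ref,
                  known_sites$alt, sep = "\r")
    n_known <- sum(key %in% kkey)
  }
  n_total <- nrow(variants)
  structure(list(by_chromosome = by_chrom, n_total = n_total,
                 n_known = n_known, n_novel = n_total - n_known,
                 pct_novel = if (n_total > 0) 100 * (n_total - n_known) / n_total
                             else NA_real_,
                 titv = titv_ratio(variants)),
            class = "variant_catalogue")
}

#' @export
print.variant_catalogue <- function(x, ...) {
  cat("Variant catalogue:", x$n_total, "unique variants\n")
  print(x$by_chromosome, row.names = FALSE)
  cat(sprintf("novel: %d (%.2f%%), known: %d; Ti/Tv = %s\n",
              x$n_novel, x$pct_novel, x$n_known, format(x$titv, digits = 4)))
  invisible(x)
}
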