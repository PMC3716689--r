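#' Write genotypes to a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 file with GT (and optionally GQ) fields,
#' one sample column per animal. Dosage `NA` becomes `./.`.
#'
#' @param sites `data.frame` with `chrom`, `pos`, `ref`, `alt` (one row per
#'   site, `alt` comma-separated for multi-allelic records).
#' @param genotypes animals x sites matrix of alt-allele dosage (0/1/2,
#'   `NA` missing); rownames are the sample ids.
#' @param path output path.
#' @param quality optional animals x sites matrix of phred-scaled genotype
#'   qualities (written as GQ, rounded).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, genotypes, path, quality = NULL) {
  g <- as.matrix(genotypes)
  stopifnot(ncol(g) == nrow(sites))
  if (is.null(rownames(g))) rownames(g) <- sprintf("S%03d", seq_len(nrow(g)))
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  fmt <- "GT"
  if (!is.null(quality)) {
    q <- as.matrix(quality)
    qs <- matrix(as.character(round(q)), nrow(q), ncol(q))
    qs[is.na(q)] <- "."
    gt <- matrix(paste(gt, qs, sep = ":"), nrow(g), ncol(g))
    fmt <- "GT:GQ"
  }
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              if (!is.null(quality))
                "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i)
    paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", fmt, gt[, i]), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# vcfR::getFIX drops to a vector for single-record files
vcf_fix <- function(v) {
  f <- vcfR::getFIX(v)
  if (is.null(dim(f))) f <- t(as.matrix(f))
  f
}

gt_to_state <- function(gt) {
  gt <- sub(":.*$", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(x) {
    if (length(x) != 2L || any(x == ".")) return("missing")
    d <- sum(as.integer(x) > 0L)
    c("hom_ref", "het", "hom_alt")[d + 1L]
  }, character(1))
}

#' Read genotype calls from a VCF
#'
#' Reads GT and genotype quality for every sample into the long call table
#' used by the concordance module. Quality is taken from GQ when present;
#' otherwise it is derived from PL as the gap between the second-smallest
#' and smallest phred-scaled likelihood.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @param samples optional subset of sample names.
#' @return Long `data.frame` as from [genotype_calls()], with `ref` and
#'   `alt` columns.
#' @export
read_genotype_calls <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix(v)
  gt <- vcfR::extract.gt(v, element = "GT", return.alleles = FALSE)
  if (is.null(gt)) stop("VCF has no genotype (GT) field: ", path)
  qual <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  if (is.null(qual) || all(is.na(qual))) {
    pl <- vcfR::extract.gt(v, element = "PL")
    if (!is.null(pl) && any(!is.na(pl))) {
      qual <- apply(pl, c(1, 2), function(x) {
        if (is.na(x)) return(NA_real_)
        p <- sort(as.numeric(strsplit(x, ",")[[1]]))
        p[2] - p[1]
      })
    } else qual <- matrix(NA_real_, nrow(gt), ncol(gt))
  }
  if (!is.null(samples)) {
    gt <- gt[, samples, drop = FALSE]
    qual <- qual[, samples, drop = FALSE]
  }
  n_site <- nrow(gt); n_samp <- ncol(gt)
  genotype_calls(
    chrom = rep(fix[, "CHROM"], n_samp),
    pos = rep(as.integer(fix[, "POS"]), n_samp),
    animal = rep(colnames(gt), each = n_site),
    gt = gt_to_state(as.vector(gt)),
    quality = as.vector(qual),
    ref = rep(fix[, "REF"], n_samp),
    alt = rep(fix[, "ALT"], n_samp))
}

#' Read a VCF as a dosage matrix plus site map
#'
#' @param path VCF file path.
#' @return List with `genotypes` (animals x sites alt-allele dosage, `NA`
#'   missing) and `map` (`chrom`, `pos`, `ref`, `alt`).
#' @export
read_genotype_matrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  state <- matrix(gt_to_state(as.vector(gt)), nrow(gt), ncol(gt))
  dose <- matrix(c(hom_ref = 0L, het = 1L, hom_alt = 2L,
                   missing = NA_integer_)[state], nrow(gt), ncol(gt))
  list(genotypes = t(`dimnames<-`(dose, dimnames(gt))),
       map = data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE))
}

#' Read a variant site table from a VCF
#'
#' @param path VCF file path.
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt` suitable for
#'   [classify_variants()] and [catalogue_summary()].
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix(v)
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             stringsAsFactors = FALSE)
}

#' Write a pedigree to CSV
#'
#' @param ped a `"pedigree"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped)[c("animal", "sire", "dam",
                                        "birth_year")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}
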