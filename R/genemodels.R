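#' Construct a gene-model table
#'
#' One protein-coding transcript per gene, in 1-based closed genomic
#' coordinates: transcript bounds, CDS bounds, and the exon blocks as list
#' columns. Invariants (tx_start <= cds_start <= cds_end <= tx_end; exons
#' sorted, non-overlapping, inside the transcript) are checked.
#'
#' @param gene gene symbols.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end transcript bounds.
#' @param cds_start,cds_end coding-region bounds.
#' @param exon_starts,exon_ends lists of integer vectors, one per model.
#' @return `data.frame` of class `"gene_models"`.
#' @export
gene_models <- function(gene, chrom, strand, tx_start, tx_end,
                        cds_start, cds_end, exon_starts, exon_ends) {
  n <- length(gene)
  stopifnot(all(strand %in% c("+", "-")),
            length(exon_starts) == n, length(exon_ends) == n)
  for (i in seq_len(n)) {
    es <- as.integer(exon_starts[[i]]); ee <- as.integer(exon_ends[[i]])
    if (length(es) == 0L || length(es) != length(ee) || any(es > ee))
      stop("malformed exon blocks for gene ", gene[i])
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1] <= ee[-length(ee)]))
      stop("exon blocks overlap or are unsorted for gene ", gene[i])
    if (es[1] < tx_start[i] || ee[length(ee)] > tx_end[i])
      stop("exon outside transcript bounds for gene ", gene[i])
    if (!(tx_start[i] <= cds_start[i] && cds_start[i] <= cds_end[i] &&
          cds_end[i] <= tx_end[i]))
      stop("coding-region bounds outside transcript for gene ", gene[i])
  }
  df <- data.frame(gene = as.character(gene), chrom = as.character(chrom),
                   strand = as.character(strand),
                   tx_start = as.integer(tx_start),
                   tx_end = as.integer(tx_end),
                   cds_start = as.integer(cds_start),
                   cds_end = as.integer(cds_end),
                   stringsAsFactors = FALSE)
  df$exon_starts <- lapply(exon_starts, as.integer)
  df$exon_ends <- lapply(exon_ends, as.integer)
  class(df) <- c("gene_models", "data.frame")
  df
}

# coding blocks (exon intersect CDS), ascending genomic order
coding_blocks <- function(model) {
  es <- model$exon_starts[[1]]; ee <- model$exon_ends[[1]]
  cs <- pmax(es, model$cds_start); ce <- pmin(ee, model$cds_end)
  keep <- cs <= ce
  list(start = cs[keep], end = ce[keep])
}

# genomic positions of CDS bases in transcription order (5' -> 3')
coding_positions <- function(model) {
  b <- coding_blocks(model)
  pos <- unlist(mapply(seq.int, b$start, b$end, SIMPLIFY = FALSE),
                use.names = FALSE)
  if (model$strand == "-") rev(pos) else pos
}

#' Spliced coding sequence of a gene model
#'
#' Extracts and splices the CDS from the reference, reverse-complementing
#' minus-strand models, so the result starts at the initiator codon.
#'
#' @param model single-row `"gene_models"` table.
#' @param reference named [Biostrings::DNAStringSet] covering the model's
#'   chromosome.
#' @return A [Biostrings::DNAString] with the strand-oriented CDS.
#' @export
cds_sequence <- function(model, reference) {
  if (!model$chrom %in% names(reference))
    stop("reference lacks chromosome ", model$chrom)
  b <- coding_blocks(model)
  chrseq <- reference[[model$chrom]]
  parts <- lapply(seq_along(b$start),
                  function(i) Biostrings::subseq(chrseq, b$start[i], b$end[i]))
  cds <- do.call(Biostrings::xscat, parts)
  if (model$strand == "-") cds <- Biostrings::reverseComplement(cds)
  cds
}

#' Load and filter gene models
#'
#' Reads gene models from BED12, GFF3 or a tab-delimited dialect (see
#' [read_gene_models_tsv()]), keeps one transcript per gene (longest CDS on
#' ties), and removes models whose reference CDS cannot encode a clean open
#' reading frame: CDS length not divisible by three, or a translation with
#' an internal stop codon. Exclusions are reported in the `"excluded"`
#' attribute and a message.
#'
#' @param x path to a gene-model file, or a `"gene_models"` table.
#' @param reference named [Biostrings::DNAStringSet]; must contain every
#'   chromosome named by a model.
#' @param format file format; `"auto"` guesses from the extension.
#' @return Filtered `"gene_models"` table with attribute `excluded`
#'   (`data.frame` of gene and reason).
#' @export
load_gene_models <- function(x, reference,
                             format = c("auto", "bed", "gff3", "tsv")) {
  format <- match.arg(format)
  models <- if (inherits(x, "gene_models")) x else {
    if (format == "auto")
      format <- switch(tolower(tools::file_ext(x)),
                       bed = "bed", gff3 = , gff = "gff3", "tsv")
    switch(format,
           bed = read_gene_models_bed12(x),
           gff3 = read_gene_models_gff3(x),
           tsv = read_gene_models_tsv(x))
  }
  missing_chr <- setdiff(unique(models$chrom), names(reference))
  if (length(missing_chr))
    stop("reference lacks chromosome(s): ", paste(missing_chr, collapse = ", "))

  reason <- rep(NA_character_, nrow(models))
  cds_len <- integer(nrow(models))
  for (i in seq_len(nrow(models))) {
    b <- coding_blocks(models[i, ])
    cds_len[i] <- sum(b$end - b$start + 1L)
    if (cds_len[i] %% 3L != 0L) {
      reason[i] <- "CDS length not divisible by 3"
      next
    }
    aa <- suppressWarnings(Biostrings::translate(
      cds_sequence(models[i, ], reference), no.init.codon = TRUE))
    aa <- as.character(aa)
    internal <- substr(aa, 1, nchar(aa) - 1L)
    if (grepl("*", internal, fixed = TRUE))
      reason[i] <- "internal stop codon in reference CDS"
  }
  keep <- is.na(reason)
  excluded <- data.frame(gene = models$gene[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)

  kept <- models[keep, , drop = FALSE]
  kept_len <- cds_len[keep]
  if (anyDuplicated(kept$gene)) {
    ord <- order(kept$gene, -kept_len)
    kept <- kept[ord, , drop = FALSE]
    dup <- duplicated(kept$gene)
    message(sum(dup), " extra transcript(s) dropped (one per gene, longest CDS kept)")
    kept <- kept[!dup, , drop = FALSE]
  }
  if (nrow(excluded))
    message(nrow(excluded), " gene model(s) excluded: ",
            paste(sprintf("%s (%s)", excluded$gene, excluded$reason),
                  collapse = "; "))
  rownames(kept) <- NULL
  attr(kept, "excluded") <- excluded
  kept
}

#' Read gene models from BED12
#'
#' BED12 uses 0-based half-open coordinates; they are converted to the
#' package's 1-based closed convention on import (via rtracklayer).
#'
#' @param path BED12 file path.
#' @return `"gene_models"` table.
#' @export
read_gene_models_bed12 <- function(path) {
  g <- rtracklayer::import(path, format = "bed")
  thick <- g$thick
  blocks <- g$blocks   # transcript-relative, 1-based
  tx_start <- GenomicRanges::start(g)
  es <- ee <- vector("list", length(g))
  for (i in seq_along(g)) {
    b <- blocks[[i]]
    es[[i]] <- tx_start[i] + GenomicRanges::start(b) - 1L
    ee[[i]] <- tx_start[i] + GenomicRanges::end(b) - 1L
  }
  gene_models(gene = g$name,
              chrom = as.character(GenomicRanges::seqnames(g)),
              strand = as.character(GenomicRanges::strand(g)),
              tx_start = tx_start, tx_end = GenomicRanges::end(g),
              cds_start = GenomicRanges::start(thick),
              cds_end = GenomicRanges::end(thick),
              exon_starts = es, exon_ends = ee)
}

#' Read gene models from GFF3
#'
#' Assembles one model per mRNA feature from its child `exon` and `CDS`
#' features (GFF3 is 1-based closed, matching the internal convention).
#'
#' @param path GFF3 file path.
#' @return `"gene_models"` table.
#' @export
read_gene_models_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  mrna <- g[g$type %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) stop("no mRNA/transcript features in ", path)
  ids <- mrna$ID
  gene <- if (!is.null(mrna$gene)) mrna$gene else
    if (!is.null(mrna$Name)) mrna$Name else ids
  es <- ee <- vector("list", length(mrna))
  cs <- cx <- integer(length(mrna))
  parent <- vapply(as.list(g$Parent),
                   function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  for (i in seq_along(mrna)) {
    ex <- g[g$type == "exon" & parent == ids[i]]
    cds <- g[g$type == "CDS" & parent == ids[i]]
    if (length(ex) == 0L) ex <- mrna[i]
    if (length(cds) == 0L)
      stop("mRNA ", ids[i], " has no CDS features")
    ord <- order(GenomicRanges::start(ex))
    es[[i]] <- GenomicRanges::start(ex)[ord]
    ee[[i]] <- GenomicRanges::end(ex)[ord]
    cs[i] <- min(GenomicRanges::start(cds))
    cx[i] <- max(GenomicRanges::end(cds))
  }
  gene_models(gene = gene,
              chrom = as.character(GenomicRanges::seqnames(mrna)),
              strand = as.character(GenomicRanges::strand(mrna)),
              tx_start = GenomicRanges::start(mrna),
              tx_end = GenomicRanges::end(mrna),
              cds_start = cs, cds_end = cx,
              exon_starts = es, exon_ends = ee)
}

#' Read gene models from the tab-delimited annotation dialect
#'
#' Columns: `Gene` (symbol), `Chr` with the strand in parentheses, e.g.
#' `29 (+)`, `txStart`, `txEnd`, `cdsStart`, `cdsEnd`, `exons` (exon
#' count), all 1-based closed. If comma-separated `exonStarts`/`exonEnds`
#' columns are present they define the exon blocks; otherwise each model
#' falls back to a single exon spanning the transcript, with a warning
#' (BED12 or GFF3 input is preferred for multi-exon models).
#'
#' @param path TSV file path.
#' @return `"gene_models"` table.
#' @export
read_gene_models_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(x) <- tolower(names(x))
  chr <- sub("\\s*\\(.*$", "", x$chr)
  strand <- sub("^.*\\(([+-])\\).*$", "\\1", x$chr)
  if (all(c("exonstarts", "exonends") %in% names(x))) {
    es <- lapply(strsplit(x$exonstarts, ","), as.integer)
    ee <- lapply(strsplit(x$exonends, ","), as.integer)
  } else {
    warning("no exon-block columns; falling back to single-exon models")
    es <- as.list(as.integer(x$txstart))
    ee <- as.list(as.integer(x$txend))
  }
  gene_models(gene = x$gene, chrom = chr, strand = strand,
              tx_start = x$txstart, tx_end = x$txend,
              cds_start = x$cdsstart, cds_end = x$cdsend,
              exon_starts = es, exon_ends = ee)
}

#' Write gene models as BED12
#'
#' @param models `"gene_models"` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
    sizes <- ee - es + 1L
    rel <- es - m$tx_start
    paste(m$chrom, m$tx_start - 1L, m$tx_end, m$gene, 0L, m$strand,
          m$cds_start - 1L, m$cds_end, "0", length(es),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(rel, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
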