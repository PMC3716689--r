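REGIONS <- c("promoter", "utr5", "cds", "splice_site", "intron", "utr3",
             "intergenic")
EFFECTS <- c("synonymous", "missense", "stop_gain", "stop_loss", "start_loss",
             "inframe_indel", "frameshift", "none")

# leftmost affected base of a VCF left-anchored record; for InDels the
# shared anchor base is unchanged, so the first affected base is pos + 1
affected_range <- function(pos, ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) return(c(pos, pos))
  if (nchar(ref) > nchar(alt)) return(c(pos + 1L, pos + nchar(ref) - 1L))
  c(pos + 1L, pos + 1L)
}

#' Genic region of a position relative to one gene model
#'
#' Region categories: `promoter` (the `promoter_bp` bases immediately
#' upstream of the transcription start, strand-aware), `utr5`/`utr3`
#' (exonic transcript sequence outside the CDS, oriented by strand), `cds`
#' (exonic within the coding bounds), `splice_site` (the `splice_bp`
#' intronic bases flanking each exon-intron junction), `intron` (remaining
#' intra-transcript), else `intergenic`. Precedence for conflicts:
#' splice_site > cds > UTR > promoter > intron.
#'
#' @param pos 1-based genomic position.
#' @param model single-row `"gene_models"` table on the same chromosome.
#' @param promoter_bp promoter extent upstream of the transcription start.
#' @param splice_bp intronic bases per junction side treated as splice site.
#' @return One of `"promoter"`, `"utr5"`, `"cds"`, `"splice_site"`,
#'   `"intron"`, `"utr3"`, `"intergenic"`.
#' @export
assign_region <- function(pos, model, promoter_bp = 1000, splice_bp = 2) {
  es <- model$exon_starts[[1]]; ee <- model$exon_ends[[1]]
  plus <- model$strand == "+"
  in_tx <- pos >= model$tx_start && pos <= model$tx_end
  if (!in_tx) {
    prom <- if (plus)
      pos >= model$tx_start - promoter_bp && pos <= model$tx_start - 1L
    else
      pos >= model$tx_end + 1L && pos <= model$tx_end + promoter_bp
    return(if (prom) "promoter" else "intergenic")
  }
  exonic <- any(pos >= es & pos <= ee)
  if (exonic) {
    if (pos >= model$cds_start && pos <= model$cds_end) return("cds")
    upstream <- if (plus) pos < model$cds_start else pos > model$cds_end
    return(if (upstream) "utr5" else "utr3")
  }
  # intronic: splice sites are the first splice_bp bases of each intron
  n <- length(es)
  donor <- acceptor <- FALSE
  if (n > 1L) {
    donor <- any(pos >= ee[-n] + 1L & pos <= ee[-n] + splice_bp)
    acceptor <- any(pos >= es[-1] - splice_bp & pos <= es[-1] - 1L)
  }
  if (donor || acceptor) "splice_site" else "intron"
}

#' Coding effect of a variant within a CDS
#'
#' For a biallelic SNV, splices the CDS from the exon blocks
#' (reverse-complementing minus-strand models), locates the affected codon,
#' and translates reference and mutant codons with the standard nuclear
#' code: same amino acid is `synonymous`; a change in the initiator codon
#' `start_loss`; a new internal stop `stop_gain`; loss of the terminal stop
#' `stop_loss`; any other amino-acid change `missense`. InDels are
#' `frameshift` when the length difference is not a multiple of three, else
#' `inframe_indel`.
#'
#' @param pos,ref,alt variant (VCF plus-strand alleles, left-anchored).
#' @param model single-row `"gene_models"` table whose CDS covers the
#'   variant's affected base.
#' @param reference named [Biostrings::DNAStringSet].
#' @return List with `effect`, `codon_change` and `aa_change` (strings, or
#'   `NA` for InDels).
#' @export
coding_effect <- function(pos, ref, alt, model, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    shift <- abs(nchar(ref) - nchar(alt))
    eff <- if (shift %% 3L == 0L) "inframe_indel" else "frameshift"
    return(list(effect = eff, codon_change = NA_character_,
                aa_change = NA_character_))
  }
  genome_base <- as.character(Biostrings::subseq(reference[[model$chrom]],
                                                 pos, pos))
  if (genome_base != ref)
    stop(sprintf("reference base at %s:%d is %s, record says %s",
                 model$chrom, pos, genome_base, ref))

  cpos <- coding_positions(model)
  idx <- match(pos, cpos)
  if (is.na(idx))
    stop(sprintf("position %s:%d is not a coding base of gene %s",
                 model$chrom, pos, model$gene))
  cds <- as.character(cds_sequence(model, reference))
  n_codon <- nchar(cds) / 3L
  codon_i <- (idx - 1L) %/% 3L + 1L
  offset <- (idx - 1L) %% 3L + 1L
  codon_ref <- substr(cds, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
  alt_cds <- if (model$strand == "-") comp_base(alt) else alt
  codon_alt <- codon_ref
  substr(codon_alt, offset, offset) <- alt_cds

  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon_ref]); aa_alt <- unname(code[codon_alt])
  effect <-
    if (codon_i == 1L && codon_alt != "ATG") "start_loss"
    else if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*" && codon_i < n_codon) "stop_gain"
    else if (aa_ref == "*" && aa_alt != "*") "stop_loss"
    else "missense"
  list(effect = effect,
       codon_change = paste0(codon_ref, ">", codon_alt),
       aa_change = paste0(aa_ref, codon_i, aa_alt))
}

comp_base <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

#' Annotate a variant catalogue against gene models
#'
#' Annotates every variant against every gene model whose footprint
#' (transcript plus promoter) contains its leftmost affected base: one
#' annotation row per overlapping (variant, gene) pair, plus a single
#' `intergenic` row for variants overlapping no model. CDS SNVs receive a
#' coding effect from [coding_effect()]; CDS InDels are classed
#' frameshift/inframe by length; triallelic sites receive a region but no
#' coding effect. Duplicated variant records are dropped first
#' (idempotent). A `spanning` flag marks InDels whose affected bases cross
#' a region boundary.
#'
#' @param variants variant table (`chrom`, `pos`, `ref`, `alt`), classified
#'   with [classify_variants()] if needed.
#' @param models `"gene_models"` table, already filtered by
#'   [load_gene_models()].
#' @param reference named [Biostrings::DNAStringSet].
#' @param promoter_bp,splice_bp region parameters, see [assign_region()].
#' @return List of class `"annotation_result"`: `annotations` (one row per
#'   variant-gene pair with `region`, `effect`, `codon_change`,
#'   `aa_change`, `spanning`, and an empty `prediction` column for joining
#'   external damage predictions), `region_counts`, `effect_counts`.
#' @export
annotate_catalogue <- function(variants, models, reference,
                               promoter_bp = 1000, splice_bp = 2) {
  if (is.null(variants$class)) variants <- classify_variants(variants)
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = "\r")
  variants <- variants[!duplicated(key), , drop = FALSE]

  fp_start <- ifelse(models$strand == "+", models$tx_start - promoter_bp,
                     models$tx_start)
  fp_end <- ifelse(models$strand == "+", models$tx_end,
                   models$tx_end + promoter_bp)

  rows <- vector("list", nrow(variants))
  for (v in seq_len(nrow(variants))) {
    chrom <- variants$chrom[v]; pos <- variants$pos[v]
    ref <- variants$ref[v]
    alt1 <- strsplit(variants$alt[v], ",", fixed = TRUE)[[1]][1]
    rng <- affected_range(pos, ref, alt1)
    hit <- which(models$chrom == chrom & rng[1] >= fp_start &
                   rng[1] <= fp_end)
    if (length(hit) == 0L) {
      rows[[v]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                              alt = variants$alt[v], gene = NA_character_,
                              region = "intergenic", effect = "none",
                              codon_change = NA_character_,
                              aa_change = NA_character_, spanning = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    sub <- lapply(hit, function(m) {
      model <- models[m, ]
      region <- assign_region(rng[1], model, promoter_bp, splice_bp)
      spanning <- rng[2] > rng[1] &&
        assign_region(rng[2], model, promoter_bp, splice_bp) != region
      effect <- "none"; cc <- NA_character_; ac <- NA_character_
      if (region == "cds" && variants$class[v] != "triallelic") {
        ce <- coding_effect(pos, ref, alt1, model, reference)
        effect <- ce$effect; cc <- ce$codon_change; ac <- ce$aa_change
      }
      data.frame(chrom = chrom, pos = pos, ref = ref,
                 alt = variants$alt[v], gene = model$gene, region = region,
                 effect = effect, codon_change = cc, aa_change = ac,
                 spanning = spanning, stringsAsFactors = FALSE)
    })
    rows[[v]] <- do.call(rbind, sub)
  }
  ann <- do.call(rbind, rows)
  ann$prediction <- NA_character_
  structure(list(annotations = ann,
                 region_counts = table(factor(ann$region, levels = REGIONS)),
                 effect_counts = table(factor(ann$effect, levels = EFFECTS))),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("Variant annotation:", nrow(x$annotations), "annotation rows\n")
  cat("Regions:\n"); print(x$region_counts)
  cat("Coding effects:\n")
  print(x$effect_counts[names(x$effect_counts) != "none"])
  invisible(x)
}
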