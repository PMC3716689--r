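# hand-built two-gene reference: GENE_P (+ strand, CDS ATGGCTTAA split over
# two exons) and a single-exon model used for effect tests
tiny_reference <- function() {
  # layout (1-based): 1..30 pad, gene tx 31..70
  #   exon1 31..45 (utr5 31..36, cds ATGGCT 37..42, first 3 of GCT.. wait)
  # simpler: single exon, tx 31..60: utr5 31..36, CDS 37..45 = ATGGCTTAA,
  # utr3 46..60
  pad <- strrep("C", 30)
  utr5 <- "TTTTTT"
  cds <- "ATGGCTTAA"
  utr3 <- strrep("A", 15)
  tail <- strrep("G", 40)
  Biostrings::DNAStringSet(c("1" = paste0(pad, utr5, cds, utr3, tail)))
}

tiny_model <- function(strand = "+") {
  if (strand == "+")
    gene_models("g1", "1", "+", 31, 60, 37, 45, list(31), list(60))
  else {
    # minus-strand gene encoding the same protein placed on 31..60 of the
    # reverse complement layout: CDS on plus strand is revcomp(ATGGCTTAA)
    NULL
  }
}

test_that("gene-model filtering removes internal-stop and frame-broken models", {
  ref <- tiny_reference()
  ok <- tiny_model()
  kept <- load_gene_models(ok, ref)
  expect_equal(nrow(kept), 1)
  expect_equal(nrow(attr(kept, "excluded")), 0)

  # internal stop: ATG GCT TGA TAA
  seq2 <- Biostrings::DNAStringSet(c(
    "1" = paste0(strrep("C", 30), "ATGGCTTGATAA", strrep("G", 20))))
  m2 <- gene_models("g2", "1", "+", 31, 42, 31, 42, list(31), list(42))
  expect_message(kept2 <- load_gene_models(m2, seq2), "internal stop")
  expect_equal(nrow(kept2), 0)
  expect_equal(attr(kept2, "excluded")$reason,
               "internal stop codon in reference CDS")

  # CDS length not divisible by 3
  m3 <- gene_models("g3", "1", "+", 31, 40, 31, 40, list(31), list(40))
  expect_message(kept3 <- load_gene_models(m3, seq2), "divisible")
  expect_equal(nrow(kept3), 0)
})

test_that("minus-strand models translate through the reverse complement", {
  # plus strand carries revcomp(ATGGCTTAA) = TTAAGCCAT at 31..39
  seq <- Biostrings::DNAStringSet(c(
    "1" = paste0(strrep("C", 30), "TTAAGCCAT", strrep("G", 20))))
  m <- gene_models("gm", "1", "-", 31, 39, 31, 39, list(31), list(39))
  expect_equal(as.character(cds_sequence(m, seq)), "ATGGCTTAA")
  kept <- load_gene_models(m, seq)
  expect_equal(nrow(kept), 1)
})

test_that("one transcript is retained per gene, longest CDS first", {
  ref <- Biostrings::DNAStringSet(c(
    "1" = paste0(strrep("C", 30), "ATGGCTGCTTAA", strrep("G", 30))))
  short <- gene_models("g", "1", "+", 31, 39, 31, 39, list(31), list(39))
  long <- gene_models("g", "1", "+", 31, 42, 31, 42, list(31), list(42))
  both <- rbind(short, long)
  class(both) <- class(short)
  expect_message(kept <- load_gene_models(both, ref), "one per gene")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$cds_end, 42L)
})

test_that("region assignment matches the strand-aware geometry", {
  m <- gene_models("g", "1", "+", 2001, 2600, 2101, 2500,
                   list(c(2001, 2301)), list(c(2200, 2600)))
  expect_equal(assign_region(2001 - 500, m), "promoter")
  expect_equal(assign_region(2001 - 1000, m), "promoter")
  expect_equal(assign_region(2001 - 1001, m), "intergenic")
  expect_equal(assign_region(2050, m), "utr5")
  expect_equal(assign_region(2150, m), "cds")
  expect_equal(assign_region(2201, m), "splice_site")  # 1st intronic base
  expect_equal(assign_region(2202, m), "splice_site")
  expect_equal(assign_region(2203, m), "intron")
  expect_equal(assign_region(2300, m), "splice_site")  # acceptor side
  expect_equal(assign_region(2550, m), "utr3")
  expect_equal(assign_region(2601, m), "intergenic")
  # minus strand: promoter upstream means right of tx_end, UTR roles swap
  mm <- gene_models("g", "1", "-", 2001, 2600, 2101, 2500,
                    list(c(2001, 2301)), list(c(2200, 2600)))
  expect_equal(assign_region(2601, mm), "promoter")
  expect_equal(assign_region(2600 + 1000, mm), "promoter")
  expect_equal(assign_region(2050, mm), "utr3")
  expect_equal(assign_region(2550, mm), "utr5")
})

test_that("region categories partition the transcript footprint exactly", {
  st <- simulate_annotation_truth(n_genes = 3, seed = 31)
  for (i in seq_len(nrow(st$models))) {
    m <- st$models[i, ]
    prom <- if (m$strand == "+") (m$tx_start - 1000):(m$tx_start - 1)
            else (m$tx_end + 1):(m$tx_end + 1000)
    fp <- c(prom, m$tx_start:m$tx_end)
    regions <- vapply(fp, assign_region, character(1), model = m)
    expect_false(any(regions == "intergenic"))
    n_ex <- length(m$exon_starts[[1]])
    exonic_len <- sum(m$exon_ends[[1]] - m$exon_starts[[1]] + 1)
    w <- pmin(m$exon_ends[[1]], m$cds_end) -
      pmax(m$exon_starts[[1]], m$cds_start) + 1
    cds_len <- sum(w[w > 0])
    expect_equal(sum(regions == "promoter"), 1000)
    expect_equal(sum(regions == "cds"), cds_len)
    expect_equal(sum(regions == "splice_site"), 4 * (n_ex - 1))
    expect_equal(sum(regions %in% c("utr5", "utr3")), exonic_len - cds_len)
    expect_length(regions, length(fp))  # every base exactly one category
  }
})

test_that("coding effects follow the standard code on both strands", {
  ref <- tiny_reference()
  m <- tiny_model()
  # CDS offset 6 (third base of codon 2, GCT): T>A gives GCA, still Ala
  eff <- coding_effect(42, "T", "A", m, ref)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$aa_change, "A2A")
  # codon 2 GCT -> TCT: missense Ala>Ser
  eff2 <- coding_effect(40, "G", "T", m, ref)
  expect_equal(eff2$effect, "missense")
  # codon 2 GCT -> TAA needs two changes; use G>T at first base then check
  # a designed stop: CDS ATG TAT TAA would stop-gain at TAT>TAA; here mutate
  # codon2 GCT>GCT impossible, so test stop_gain on a dedicated sequence
  seq3 <- Biostrings::DNAStringSet(c(
    "1" = paste0(strrep("C", 30), "ATGTATTAA", strrep("G", 20))))
  m3 <- gene_models("g", "1", "+", 31, 39, 31, 39, list(31), list(39))
  eff3 <- coding_effect(36, "T", "A", m3, seq3)  # TAT -> TAA
  expect_equal(eff3$effect, "stop_gain")
  # start loss
  eff4 <- coding_effect(31, "A", "G", m3, seq3)
  expect_equal(eff4$effect, "start_loss")
  # stop loss at the terminal codon
  eff5 <- coding_effect(38, "A", "C", m3, seq3)  # TAA -> TCA
  expect_equal(eff5$effect, "stop_loss")
  # frameshift / in-frame by InDel length
  expect_equal(coding_effect(35, "AT", "A", m3, seq3)$effect, "frameshift")
  expect_equal(coding_effect(33, "GTAT", "G", m3, seq3)$effect,
               "inframe_indel")
  # reference mismatch guard
  expect_error(coding_effect(42, "G", "A", m, ref), "reference base")
})

test_that("annotation recovers every planted truth label exactly", {
  st <- simulate_annotation_truth(n_genes = 10, seed = 77)
  models <- load_gene_models(st$models, st$reference)
  expect_equal(nrow(attr(models, "excluded")), 0)
  ann <- annotate_catalogue(st$variants, models, st$reference)
  a <- ann$annotations
  expect_equal(nrow(a), nrow(st$truth))  # disjoint footprints: one row each
  m <- match(paste(st$truth$chrom, st$truth$pos),
             paste(a$chrom, a$pos))
  expect_false(anyNA(m))
  expect_equal(a$region[m], st$truth$region)
  got_eff <- a$effect[m]
  expect_equal(got_eff, st$truth$effect)
  genic <- !is.na(st$truth$gene)
  expect_equal(a$gene[m][genic], st$truth$gene[genic])
})

test_that("codon-local effects agree with full rebuild-and-translate", {
  st <- simulate_annotation_truth(n_genes = 6, seed = 13)
  models <- load_gene_models(st$models, st$reference)
  cdssnv <- st$truth[st$truth$region == "cds" &
                       nchar(st$truth$ref) == 1 & nchar(st$truth$alt) == 1, ]
  expect_gte(nrow(cdssnv), 20)
  for (i in seq_len(nrow(cdssnv))) {
    v <- cdssnv[i, ]
    model <- models[models$gene == v$gene, ]
    expect_equal(coding_effect(v$pos, v$ref, v$alt, model,
                               st$reference)$effect,
                 coding_effect_oracle(v$pos, v$ref, v$alt, model,
                                      st$reference),
                 label = paste("variant at", v$pos))
  }
})

test_that("annotation is strand-symmetric under genome reverse complement", {
  st <- simulate_annotation_truth(n_genes = 4, seed = 19)
  models <- load_gene_models(st$models, st$reference)
  L <- Biostrings::width(st$reference)[1]
  rc_ref <- Biostrings::DNAStringSet(
    c("1" = as.character(Biostrings::reverseComplement(st$reference[[1]]))))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip_pos <- function(p) L - p + 1L
  for (gi in seq_len(nrow(models))) {
    m <- models[gi, ]
    fm <- gene_models(m$gene, "1", if (m$strand == "+") "-" else "+",
                      flip_pos(m$tx_end), flip_pos(m$tx_start),
                      flip_pos(m$cds_end), flip_pos(m$cds_start),
                      list(rev(flip_pos(m$exon_ends[[1]]))),
                      list(rev(flip_pos(m$exon_starts[[1]]))))
    vs <- st$truth[!is.na(st$truth$gene) & st$truth$gene == m$gene &
                     nchar(st$truth$ref) == 1 & nchar(st$truth$alt) == 1, ]
    for (i in seq_len(nrow(vs))) {
      v <- vs[i, ]
      expect_equal(assign_region(flip_pos(v$pos), fm),
                   assign_region(v$pos, m))
      if (v$region == "cds")
        expect_equal(
          coding_effect(flip_pos(v$pos), unname(comp[v$ref]),
                        unname(comp[v$alt]), fm, rc_ref)$effect,
          coding_effect(v$pos, v$ref, v$alt, m, st$reference)$effect)
    }
  }
})

test_that("annotation without models is intergenic and deduplication is idempotent", {
  ref <- tiny_reference()
  v <- data.frame(chrom = "1", pos = c(5, 10), ref = "C", alt = "A")
  empty <- gene_models(character(0), character(0), character(0), integer(0),
                       integer(0), integer(0), integer(0), list(), list())
  ann <- annotate_catalogue(v, empty, ref)
  expect_true(all(ann$annotations$region == "intergenic"))
  ann2 <- annotate_catalogue(rbind(v, v), empty, ref)
  expect_equal(nrow(ann2$annotations), 2)
})
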