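# All generators are deterministic functions of their arguments and `seed`;
# each sets its own stream and restores the caller's RNG state, so adding a
# generator call never shifts another's output.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.numeric(seed) %% 2147483647)
  force(code)
}

#' Simulate a multi-generation pedigree with overlapping generations
#'
#' Founders are born over an initial window; each subsequent generation
#' consists of `floor(n_founders / 2)` matings producing
#' `round(offspring_rate)` offspring each, with sires and dams sampled from
#' all previously born animals of the right sex (so generations overlap).
#' Parents are always born before their offspring.
#'
#' @param n_founders number of founder animals (>= 2; both sexes present).
#' @param n_generations number of offspring generations (>= 1).
#' @param offspring_rate offspring per mating (rounded to an integer >= 1).
#' @param founder_year birth year of the first founder.
#' @param year_gap years between successive generations.
#' @param seed integer random seed (mandatory).
#' @return A `"pedigree"` object with an additional `sex` column
#'   (`"M"`/`"F"`).
#' @export
simulate_pedigree <- function(n_founders = 20, n_generations = 5,
                              offspring_rate = 2, founder_year = 1920,
                              year_gap = 3, seed) {
  if (n_founders < 2) stop("need at least two founders")
  if (n_generations < 1) stop("n_generations must be >= 1")
  n_off <- round(offspring_rate)
  if (n_off < 1) stop("offspring_rate must round to >= 1")
  with_seed(seed, {
    id <- sprintf("F%03d", seq_len(n_founders))
    sex <- rep(c("M", "F"), length.out = n_founders)
    year <- founder_year + (seq_len(n_founders) - 1L) %% 5L
    sire <- dam <- rep(NA_character_, n_founders)

    for (g in seq_len(n_generations)) {
      yg <- founder_year + 5L + g * year_gap
      eligible_m <- id[sex == "M" & year < yg]
      eligible_f <- id[sex == "F" & year < yg]
      if (!length(eligible_m) || !length(eligible_f))
        stop("infeasible parameters: no eligible parents in generation ", g)
      n_mat <- max(1L, n_founders %/% 2L)
      for (m in seq_len(n_mat)) {
        s <- sample(eligible_m, 1L)
        d <- sample(eligible_f, 1L)
        for (k in seq_len(n_off)) {
          id <- c(id, sprintf("G%d_%02d_%d", g, m, k))
          sex <- c(sex, sample(c("M", "F"), 1L))
          year <- c(year, yg + sample(0:2, 1L))
          sire <- c(sire, s); dam <- c(dam, d)
        }
      }
    }
    ped <- pedigree(id, sire, dam, year)
    ped$sex <- sex[match(ped$animal, id)]
    ped
  })
}

#' Gene dropping: genotypes consistent with pedigree transmission
#'
#' Founder chromosomes receive alternate alleles independently with the
#' given frequency; every offspring inherits one uniformly chosen allele
#' per parent per locus (an unknown parent side is a fresh phantom-founder
#' draw). With `track_ibd = TRUE`, founder-gamete labels are carried along
#' so realized identity-by-descent sharing can be computed; the expected
#' IBD fraction between two animals is half their numerator relationship.
#'
#' @param ped a `"pedigree"` object (parents precede offspring).
#' @param n_loci number of independent loci.
#' @param allele_freq alternate-allele frequency in (0, 1); scalar or one
#'   per locus.
#' @param seed integer random seed (mandatory).
#' @param track_ibd also return founder-gamete label matrices.
#' @return List with `genotypes` (animals x loci alt-allele dosage 0/1/2),
#'   `allele_freq`, and, when tracked, `label1`/`label2` (integer
#'   founder-gamete labels per inherited chromosome).
#' @export
gene_drop <- function(ped, n_loci, allele_freq = 0.5, seed,
                      track_ibd = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  if (any(allele_freq <= 0 | allele_freq >= 1))
    stop("allele frequencies must lie strictly within (0, 1)")
  q <- rep_len(allele_freq, n_loci)
  n <- nrow(ped)
  with_seed(seed, {
    A1 <- A2 <- matrix(0L, n, n_loci,
                       dimnames = list(ped$animal, NULL))
    L1 <- L2 <- matrix(0L, n, n_loci, dimnames = list(ped$animal, NULL))
    si <- match(ped$sire, ped$animal)
    di <- match(ped$dam, ped$animal)
    next_label <- 1L
    draw_founder_gamete <- function() {
      lab <- next_label
      next_label <<- next_label + 1L
      list(a = as.integer(stats::rbinom(n_loci, 1L, q)), lab = lab)
    }
    for (i in seq_len(n)) {
      if (is.na(si[i])) {
        gf <- draw_founder_gamete()
        A1[i, ] <- gf$a; L1[i, ] <- gf$lab
      } else {
        pick <- stats::runif(n_loci) < 0.5
        A1[i, ] <- ifelse(pick, A1[si[i], ], A2[si[i], ])
        L1[i, ] <- ifelse(pick, L1[si[i], ], L2[si[i], ])
      }
      if (is.na(di[i])) {
        gf <- draw_founder_gamete()
        A2[i, ] <- gf$a; L2[i, ] <- gf$lab
      } else {
        pick <- stats::runif(n_loci) < 0.5
        A2[i, ] <- ifelse(pick, A1[di[i], ], A2[di[i], ])
        L2[i, ] <- ifelse(pick, L1[di[i], ], L2[di[i], ])
      }
    }
    out <- list(genotypes = A1 + A2, allele_freq = q)
    if (track_ibd) { out$label1 <- L1; out$label2 <- L2 }
    out
  })
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

sample_safe <- function(pool, k) pool[sample.int(length(pool), k)]

# split total length L into k chunks, each >= min_len (stars and bars)
random_composition <- function(L, k, min_len = 8L) {
  if (k == 1L) return(L)
  stopifnot(L >= k * min_len)
  slack <- L - k * min_len
  bars <- sort(sample_safe(seq_len(slack + k - 1L), k - 1L))
  diff(c(0L, bars, slack + k)) - 1L + min_len
}

#' Simulate an annotated toy genome with planted variants of known effect
#'
#' Generates a single-chromosome reference, non-overlapping gene models
#' with 1-8 exons on both strands and clean open reading frames (initiator
#' ATG, no internal stop, terminal stop), and plants variants of known
#' region and coding effect: the substitution for each CDS truth label is
#' chosen at planting time to force the labelled effect. Gene footprints
#' (transcript + promoter) are spaced so no variant can overlap two genes,
#' making the truth labels exact.
#'
#' @param n_genes number of genes.
#' @param n_per_category named integer vector: planted variants per gene
#'   (or per gap, for `intergenic`) by truth label. Supported names:
#'   promoter, utr5, utr3, intron, splice_site, synonymous, missense,
#'   stop_gain, frameshift, inframe_indel, intergenic. Zero everywhere
#'   yields an empty variant set.
#' @param promoter_bp,splice_bp region parameters matching the annotator.
#' @param seed integer random seed (mandatory).
#' @return List with `reference` ([Biostrings::DNAStringSet], chromosome
#'   `"1"`), `models` (`"gene_models"`), `variants` (chrom/pos/ref/alt) and
#'   `truth` (variants plus `gene`, `region`, `effect`).
#' @export
simulate_annotation_truth <- function(n_genes = 20,
                                      n_per_category = c(
                                        promoter = 2, utr5 = 1, utr3 = 1,
                                        intron = 2, splice_site = 1,
                                        synonymous = 2, missense = 2,
                                        stop_gain = 1, frameshift = 1,
                                        inframe_indel = 1, intergenic = 1),
                                      promoter_bp = 1000, splice_bp = 2,
                                      seed) {
  cat0 <- c(promoter = 0, utr5 = 0, utr3 = 0, intron = 0, splice_site = 0,
            synonymous = 0, missense = 0, stop_gain = 0, frameshift = 0,
            inframe_indel = 0, intergenic = 0)
  bad <- setdiff(names(n_per_category), names(cat0))
  if (length(bad)) stop("unknown truth categories: ", paste(bad, collapse = ", "))
  cat0[names(n_per_category)] <- n_per_category
  npc <- cat0

  with_seed(seed, {
    gap <- 2L * as.integer(promoter_bp) + 200L  # footprints disjoint for any strand pairing
    genes <- vector("list", n_genes)
    chrom_parts <- character(0)
    cursor <- 0L                # bases emitted so far

    for (gi in seq_len(n_genes)) {
      n_exons <- sample(1:8, 1L, prob = c(1, rep(3, 5), 2, 1))
      n_codons <- sample(60:160, 1L)
      body <- sample(setdiff(all_codons(), STOP_CODONS),
                     n_codons - 2L, replace = TRUE)
      if (npc["stop_gain"] > 0)   # guarantee stop-mutable codons
        body[sample.int(length(body), min(npc["stop_gain"] + 1L,
                                          length(body)))] <- "TAT"
      cds <- paste0("ATG", paste(body, collapse = ""),
                    sample(STOP_CODONS, 1L))
      u5 <- sample(30:150, 1L); u3 <- sample(30:150, 1L)
      tx <- paste0(random_seq(u5), cds, random_seq(u3))
      L <- nchar(tx)
      exon_len <- random_composition(L, n_exons, min_len = 12L)
      intron_len <- if (n_exons > 1L)
        sample(30:150, n_exons - 1L, replace = TRUE) else integer(0)
      strand <- sample(c("+", "-"), 1L)

      # gap before the gene leaves room for the promoter on either strand
      gap_seq <- random_seq(gap)
      tx_start <- cursor + gap + 1L
      es <- integer(n_exons); ee <- integer(n_exons)
      pos <- tx_start
      for (e in seq_len(n_exons)) {
        es[e] <- pos; ee[e] <- pos + exon_len[e] - 1L
        pos <- ee[e] + 1L + if (e < n_exons) intron_len[e] else 0L
      }
      tx_end <- ee[n_exons]

      # plus-strand exonic sequence: transcript (or its reverse
      # complement) distributed over the exons in genomic order
      plus_tx <- if (strand == "+") tx else revcomp_chr(tx)
      exon_seqs <- character(n_exons)
      at <- 1L
      for (e in seq_len(n_exons)) {
        exon_seqs[e] <- substr(plus_tx, at, at + exon_len[e] - 1L)
        at <- at + exon_len[e]
      }
      gene_seq <- exon_seqs[1]
      if (n_exons > 1L) for (e in 2:n_exons) {
        intr <- random_seq(intron_len[e - 1L])
        if (intron_len[e - 1L] >= 4L) {
          donor <- if (strand == "+") "GT" else "CT"
          accep <- if (strand == "+") "AG" else "AC"
          substr(intr, 1L, 2L) <- donor
          substr(intr, nchar(intr) - 1L, nchar(intr)) <- accep
        }
        gene_seq <- paste0(gene_seq, intr, exon_seqs[e])
      }
      chrom_parts <- c(chrom_parts, gap_seq, gene_seq)
      cursor <- tx_end

      # CDS bounds in transcript coordinates -> genomic
      tmap <- transcript_to_genome(es, ee, strand)
      cds_t <- (u5 + 1L):(u5 + 3L * n_codons)
      genes[[gi]] <- list(gene = sprintf("GENE%03d", gi), strand = strand,
                          tx_start = tx_start, tx_end = tx_end,
                          cds_start = min(tmap[cds_t]),
                          cds_end = max(tmap[cds_t]),
                          es = es, ee = ee, u5 = u5, u3 = u3,
                          n_codons = n_codons, cds = cds, tmap = tmap)
    }
    chrom_parts <- c(chrom_parts, random_seq(gap))
    genome <- paste(chrom_parts, collapse = "")
    reference <- Biostrings::DNAStringSet(c("1" = genome))

    models <- gene_models(
      gene = vapply(genes, `[[`, character(1), "gene"),
      chrom = "1",
      strand = vapply(genes, `[[`, character(1), "strand"),
      tx_start = vapply(genes, `[[`, numeric(1), "tx_start"),
      tx_end = vapply(genes, `[[`, numeric(1), "tx_end"),
      cds_start = vapply(genes, `[[`, numeric(1), "cds_start"),
      cds_end = vapply(genes, `[[`, numeric(1), "cds_end"),
      exon_starts = lapply(genes, `[[`, "es"),
      exon_ends = lapply(genes, `[[`, "ee"))

    truth <- plant_variants(genes, genome, npc, promoter_bp, splice_bp,
                            nchar(genome))
    variants <- truth[, c("chrom", "pos", "ref", "alt")]
    list(reference = reference, models = models, variants = variants,
         truth = truth)
  })
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# genomic position of each transcript index (5'->3')
transcript_to_genome <- function(es, ee, strand) {
  pos <- unlist(mapply(seq.int, es, ee, SIMPLIFY = FALSE), use.names = FALSE)
  if (strand == "-") rev(pos) else pos
}

plant_variants <- function(genes, genome, npc, promoter_bp, splice_bp,
                           genome_len) {
  used <- integer(0)
  rows <- list()
  base_at <- function(p) substr(genome, p, p)
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  take <- function(pool, k) {
    pool <- setdiff(pool, c(used, used + 1L, used - 1L))
    if (length(pool) < k)
      stop("variant density too high: cannot place ", k,
           " non-overlapping variant(s) in a pool of ", length(pool))
    if (k == 0L) return(integer(0))
    sample_safe(pool, k)
  }
  add_snv <- function(p, gene, region, effect, alt = NULL) {
    ref <- base_at(p)
    if (is.null(alt)) alt <- other_base(ref)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = "1", pos = p, ref = ref, alt = alt, gene = gene,
      region = region, effect = effect, stringsAsFactors = FALSE)
    used <<- c(used, p)
  }

  code <- Biostrings::GENETIC_CODE
  for (g in genes) {
    exonic <- sort(unlist(mapply(seq.int, g$es, g$ee, SIMPLIFY = FALSE)))
    tmap <- g$tmap
    # region pools (genomic positions)
    prom <- if (g$strand == "+") (g$tx_start - promoter_bp):(g$tx_start - 1L)
            else (g$tx_end + 1L):(g$tx_end + promoter_bp)
    utr5_t <- seq_len(g$u5)
    utr3_t <- (g$u5 + 3L * g$n_codons + 1L):(g$u5 + 3L * g$n_codons + g$u3)
    n_ex <- length(g$es)
    splice <- intron <- integer(0)
    if (n_ex > 1L) {
      for (e in seq_len(n_ex - 1L)) {
        ib <- (g$ee[e] + 1L):(g$es[e + 1L] - 1L)
        sp <- c(utils::head(ib, splice_bp), utils::tail(ib, splice_bp))
        splice <- c(splice, sp)
        intron <- c(intron, setdiff(ib, sp))
      }
    }
    for (p in take(prom, npc["promoter"]))
      add_snv(p, g$gene, "promoter", "none")
    for (p in take(tmap[utr5_t], npc["utr5"]))
      add_snv(p, g$gene, "utr5", "none")
    for (p in take(tmap[utr3_t], npc["utr3"]))
      add_snv(p, g$gene, "utr3", "none")
    if (n_ex > 1L) {
      for (p in take(intron, npc["intron"]))
        add_snv(p, g$gene, "intron", "none")
      for (p in take(splice, npc["splice_site"]))
        add_snv(p, g$gene, "splice_site", "none")
    }

    # coding effects: pick a codon and substitution forcing each label
    planted_codons <- integer(0)
    plant_effect <- function(label, k) {
      for (rep in seq_len(k)) {
        found <- FALSE
        for (ci in sample(2:(g$n_codons - 1L))) {
          if (ci %in% planted_codons) next
          codon <- substr(g$cds, 3L * (ci - 1L) + 1L, 3L * ci)
          offs <- sample(1:3); done <- FALSE
          for (o in offs) {
            b <- substr(codon, o, o)
            for (nb in sample(setdiff(c("A", "C", "G", "T"), b))) {
              mut <- codon; substr(mut, o, o) <- nb
              ok <- switch(label,
                synonymous = code[mut] == code[codon] && code[mut] != "*",
                missense = code[mut] != code[codon] && code[mut] != "*",
                stop_gain = code[mut] == "*")
              if (ok) {
                t_idx <- g$u5 + 3L * (ci - 1L) + o
                p <- tmap[t_idx]
                if (p %in% c(used, used + 1L, used - 1L)) next
                alt_plus <- if (g$strand == "+") nb else comp_base(nb)
                add_snv(p, g$gene, "cds", label, alt = unname(alt_plus))
                planted_codons <<- c(planted_codons, ci)
                done <- TRUE; break
              }
            }
            if (done) break
          }
          if (done) { found <- TRUE; break }
        }
        if (!found)
          stop("could not plant a ", label, " variant in gene ", g$gene)
      }
    }
    plant_effect("synonymous", npc["synonymous"])
    plant_effect("missense", npc["missense"])
    plant_effect("stop_gain", npc["stop_gain"])

    # CDS InDels: anchor such that the affected bases stay inside one
    # coding exon (leftmost affected base = anchor + 1)
    plant_indel <- function(label, k) {
      del_len <- if (label == "frameshift") 1L else 3L
      cds_pos <- sort(tmap[(g$u5 + 4L):(g$u5 + 3L * (g$n_codons - 1L))])
      for (rep in seq_len(k)) {
        ok_anchor <- cds_pos[vapply(cds_pos, function(p)
          all((p + seq_len(del_len)) %in% cds_pos), logical(1))]
        p <- take(ok_anchor, 1L)
        ref <- substr(genome, p, p + del_len)
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = "1", pos = p, ref = ref, alt = substr(ref, 1L, 1L),
          gene = g$gene, region = "cds", effect = label,
          stringsAsFactors = FALSE)
        used <<- c(used, p:(p + del_len))
      }
    }
    plant_indel("frameshift", npc["frameshift"])
    plant_indel("inframe_indel", npc["inframe_indel"])
  }

  # intergenic: gaps outside every footprint, with a safety margin
  if (npc["intergenic"] > 0) {
    fp_start <- vapply(genes, function(g)
      if (g$strand == "+") g$tx_start - promoter_bp else g$tx_start,
      numeric(1))
    fp_end <- vapply(genes, function(g)
      if (g$strand == "+") g$tx_end else g$tx_end + promoter_bp, numeric(1))
    covered <- rep(FALSE, genome_len)
    for (i in seq_along(fp_start))
      covered[max(1, fp_start[i] - 2):min(genome_len, fp_end[i] + 2)] <- TRUE
    pool <- which(!covered)
    for (p in take(pool, npc["intergenic"] * length(genes)))
      add_snv(p, NA_character_, "intergenic", "none")
  }

  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), region = character(0),
                      effect = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate paired array and sequence genotype calls
#'
#' Degrades truth genotypes into two platforms. Array calls mimic a
#' high-accuracy genotyping chip: small per-genotype miscall and missing
#' rates, no quality scores. Sequence calls follow a binomial read-depth
#' model: per-site depth is Poisson around the animal's mean coverage,
#' alternate-read counts are binomial given the truth genotype and a
#' per-read error rate, the called genotype is the maximum-likelihood one
#' and its phred-scaled quality the likelihood gap to the second-best
#' genotype (capped at 60). Low coverage therefore yields both more errors
#' and lower qualities, coupling quality to error monotonically.
#'
#' @param truth_genotypes animals x loci alt-allele dosage matrix (0/1/2),
#'   e.g. from [gene_drop()].
#' @param coverage_tiers mean sequencing coverages; animals are assigned
#'   tiers in rotation. Defaults to the low-to-medium range typical of
#'   key-ancestor re-sequencing (about 4x to 25x, averaging around 7x).
#' @param read_error per-read base miscall rate.
#' @param array_miscall,array_missing array-platform error rates (the
#'   default missing rate matches a 99.26\% call rate).
#' @param positions,chrom site coordinates for the emitted call tables.
#' @param seed integer random seed (mandatory).
#' @return List with `array_calls` and `seq_calls` (long tables as from
#'   [genotype_calls()]), `coverage` (per-animal means), and the underlying
#'   `array_matrix`, `seq_matrix` (dosage with `NA` missing) and
#'   `quality_matrix`.
#' @export
simulate_genotyping <- function(truth_genotypes,
                                coverage_tiers = c(4.17, 7.46, 15, 24.98),
                                read_error = 0.01, array_miscall = 0.002,
                                array_missing = 0.0074, positions = NULL,
                                chrom = "1", seed) {
  if (length(coverage_tiers) == 0L) stop("coverage_tiers must be non-empty")
  g <- as.matrix(truth_genotypes)
  n <- nrow(g); L <- ncol(g)
  if (is.null(rownames(g))) rownames(g) <- sprintf("A%03d", seq_len(n))
  if (is.null(positions)) positions <- seq_len(L) * 1000L
  cov <- rep_len(coverage_tiers, n)
  names(cov) <- rownames(g)

  with_seed(seed, {
    # array platform
    arr <- g
    flip <- matrix(stats::runif(n * L) < array_miscall, n, L)
    if (any(flip)) {
      alt_state <- function(x) vapply(x, function(v)
        sample(setdiff(0:2, v), 1L), integer(1))
      arr[flip] <- alt_state(arr[flip])
    }
    arr[matrix(stats::runif(n * L) < array_missing, n, L)] <- NA

    # sequence platform: depth -> alt reads -> ML genotype + quality
    depth <- matrix(stats::rpois(n * L, rep(cov, L)), n, L)
    palt <- matrix(c(read_error, 0.5, 1 - read_error)[g + 1L], n, L)
    k <- matrix(stats::rbinom(n * L, depth, palt), n, L)
    l0 <- stats::dbinom(k, depth, read_error, log = TRUE)
    l1 <- stats::dbinom(k, depth, 0.5, log = TRUE)
    l2 <- stats::dbinom(k, depth, 1 - read_error, log = TRUE)
    call <- ifelse(l0 >= l1 & l0 >= l2, 0L, ifelse(l1 >= l2, 1L, 2L))
    best <- pmax(l0, l1, l2)
    second <- ifelse(call == 0L, pmax(l1, l2),
                     ifelse(call == 1L, pmax(l0, l2), pmax(l0, l1)))
    qual <- pmin(round(10 / log(10) * (best - second), 2), 60)
    call[depth == 0L] <- NA
    qual[depth == 0L] <- NA
    dimnames(call) <- dimnames(qual) <- list(rownames(g), NULL)

    dosage_to_gt <- function(x) c("hom_ref", "het", "hom_alt")[x + 1L]
    long <- function(mat, qmat = NULL) {
      genotype_calls(
        chrom = chrom,
        pos = rep(positions, each = n),
        animal = rep(rownames(g), L),
        gt = ifelse(is.na(as.vector(mat)), "missing",
                    dosage_to_gt(ifelse(is.na(as.vector(mat)), 0,
                                        as.vector(mat)))),
        quality = if (is.null(qmat)) NA_real_ else as.vector(qmat))
    }
    list(array_calls = long(arr), seq_calls = long(call, qual),
         coverage = cov, array_matrix = arr, seq_matrix = call,
         quality_matrix = qual, positions = positions)
  })
}

#' Simulate male X-chromosome genotypes with a planted PAR boundary
#'
#' Sites proximal of the boundary are hemizygous: diploid callers report
#' them as homozygous, so heterozygotes appear only through a small miscall
#' rate. Sites from the boundary to the distal chromosome end behave
#' diploid with Hardy-Weinberg heterozygosity at a per-site allele
#' frequency. Site positions are irregularly spaced.
#'
#' @param n_males number of male animals.
#' @param n_sites number of X-chromosome sites.
#' @param chrom_length chromosome length in bases.
#' @param par_boundary planted boundary position (PAR extends from here to
#'   the distal end); must lie within the chromosome.
#' @param maf_range per-site allele-frequency range (uniform draw).
#' @param het_miscall probability a hemizygous genotype is miscalled
#'   heterozygous.
#' @param missing_rate per-genotype missing rate.
#' @param seed integer random seed (mandatory).
#' @return List with `genotypes` (males x sites dosage, `NA` missing),
#'   `positions`, `par_boundary` and `chrom_length`.
#' @export
simulate_x <- function(n_males = 100, n_sites = 500, chrom_length = 149e6,
                       par_boundary = 137e6, maf_range = c(0.1, 0.5),
                       het_miscall = 0.005, missing_rate = 0.01, seed) {
  if (par_boundary <= 1 || par_boundary >= chrom_length)
    stop("par_boundary must lie within the chromosome")
  with_seed(seed, {
    positions <- sort(sample.int(chrom_length, n_sites))
    distal <- positions >= par_boundary
    q <- stats::runif(n_sites, maf_range[1], maf_range[2])
    G <- matrix(0L, n_males, n_sites)
    for (j in seq_len(n_sites)) {
      if (distal[j]) {
        G[, j] <- stats::rbinom(n_males, 2L, q[j])
      } else {
        hemi <- stats::rbinom(n_males, 1L, q[j]) * 2L
        mis <- stats::runif(n_males) < het_miscall
        hemi[mis] <- 1L
        G[, j] <- hemi
      }
    }
    G[matrix(stats::runif(n_males * n_sites) < missing_rate,
             n_males, n_sites)] <- NA
    rownames(G) <- sprintf("M%03d", seq_len(n_males))
    list(genotypes = G, positions = positions,
         par_boundary = par_boundary, chrom_length = chrom_length)
  })
}
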