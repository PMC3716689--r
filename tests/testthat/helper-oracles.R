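# Independent oracles used across the suite. Each re-derives the quantity by
# a different route than the implementation (enumeration, brute force, or
# full-sequence reconstruction).

# Kinship by exhaustive enumeration of every allele-transmission pattern:
# each known parent-offspring link contributes a binary choice; founder and
# phantom gametes carry fixed distinct labels. All probabilities are dyadic
# rationals, so double arithmetic is exact. Returns the kinship matrix; the
# numerator relationship matrix is twice this.
kinship_enumeration <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  links <- rbind(
    if (any(!is.na(si))) cbind(which(!is.na(si)), 1L),
    if (any(!is.na(di))) cbind(which(!is.na(di)), 2L))
  k <- if (is.null(links)) 0L else nrow(links)
  K <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (pattern in 0:(2^k - 1)) {
    bits <- if (k > 0) as.integer(intToBits(pattern))[seq_len(k)] else integer(0)
    L1 <- L2 <- integer(n)
    for (i in seq_len(n)) {
      if (is.na(si[i])) L1[i] <- 2L * i - 1L
      else {
        ch <- bits[which(links[, 1] == i & links[, 2] == 1L)]
        L1[i] <- if (ch == 0L) L1[si[i]] else L2[si[i]]
      }
      if (is.na(di[i])) L2[i] <- 2L * i
      else {
        ch <- bits[which(links[, 1] == i & links[, 2] == 2L)]
        L2[i] <- if (ch == 0L) L1[di[i]] else L2[di[i]]
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n))
      K[i, j] <- K[i, j] +
        ((L1[i] == L1[j]) + (L1[i] == L2[j]) +
         (L2[i] == L1[j]) + (L2[i] == L2[j])) / 4
  }
  K / 2^k
}

# brute-force best m-subset by captured diversity
best_subset_proportion <- function(A, cvec, m) {
  best <- -Inf; bestset <- NULL
  for (ss in utils::combn(names(cvec), m, simplify = FALSE)) {
    pr <- captured_diversity(A[ss, ss, drop = FALSE], cvec[ss])$proportion
    if (pr > best + 1e-12) { best <- pr; bestset <- ss }
  }
  list(proportion = best, set = bestset)
}

# naive two-loop binomial changepoint scan
seg_ll_oracle <- function(h, nn) {
  H <- sum(h); N <- sum(nn)
  if (N == 0) return(0)
  p <- H / N
  (if (H > 0) H * log(p) else 0) + (if (N - H > 0) (N - H) * log(1 - p) else 0)
}
naive_changepoint <- function(h, nn) {
  ns <- length(h); best <- -Inf; bi <- NA_integer_
  for (k in seq_len(ns - 1)) {
    ll <- seg_ll_oracle(h[1:k], nn[1:k]) +
      seg_ll_oracle(h[(k + 1):ns], nn[(k + 1):ns])
    if (ll > best) { best <- ll; bi <- k }
  }
  list(k = bi, ll = best)
}

# two-sided Fisher p by explicit choose() enumeration over all tables at
# the observed margins
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  if (c1 == 0 || c1 == N || r1 == 0 || r1 == N) return(1)
  dens <- function(x)
    choose(c1, x) * choose(N - c1, r1 - x) / choose(N, r1)
  xs <- max(0, r1 - (N - c1)):min(r1, c1)
  ps <- vapply(xs, dens, numeric(1))
  p_obs <- dens(tab[1, 1])
  min(1, sum(ps[ps <= p_obs * (1 + 1e-7)]))
}

# coding effect by full-sequence reconstruction: substitute the alternate
# allele into the chromosome, re-splice, translate both CDS copies and
# compare the protein sequences
coding_effect_oracle <- function(pos, ref, alt, model, reference) {
  chrom <- model$chrom
  mut_ref <- reference
  chrseq <- as.character(reference[[chrom]])
  stopifnot(substr(chrseq, pos, pos) == toupper(ref))
  substr(chrseq, pos, pos) <- toupper(alt)
  mut_ref[[chrom]] <- Biostrings::DNAString(chrseq)
  tr <- function(r) as.character(suppressWarnings(
    Biostrings::translate(cds_sequence(model, r), no.init.codon = TRUE)))
  aa0 <- tr(reference); aa1 <- tr(mut_ref)
  n <- nchar(aa0)
  if (aa0 == aa1) return("synonymous")
  d <- which(strsplit(aa0, "")[[1]] != strsplit(aa1, "")[[1]])[1]
  a0 <- substr(aa0, d, d); a1 <- substr(aa1, d, d)
  if (d == 1 && a0 == "M") "start_loss"
  else if (a1 == "*" && d < n) "stop_gain"
  else if (a0 == "*" && d == n) "stop_loss"
  else "missense"
}

# small deterministic pedigrees used in several files
ped_trio <- function() pedigree(c("S", "D", "O"), c(NA, NA, "S"),
                                c(NA, NA, "D"), c(1990, 1991, 1995))
ped_fullsib_mating <- function()
  pedigree(c("A", "B", "C", "D", "E"), c(NA, NA, "A", "A", "C"),
           c(NA, NA, "B", "B", "D"))
ped_halfsibs <- function()
  pedigree(c("S", "D1", "D2", "O1", "O2"), c(NA, NA, NA, "S", "S"),
           c(NA, NA, NA, "D1", "D2"))
ped_grandparent_loop <- function()
  pedigree(c("G1", "G2", "P1", "P2", "X"),
           c(NA, NA, "G1", "G1", "P1"), c(NA, NA, "G2", NA, "P2"))
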