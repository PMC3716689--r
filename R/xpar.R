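#' Male heterozygosity profile along the X chromosome
#'
#' Computes the per-site fraction of heterozygous males after call-rate
#' filtering: animals with a call rate below `min_call_rate` are removed
#' first, then sites with a call rate below `min_call_rate` over the
#' remaining animals. Hemizygous non-pseudoautosomal genotypes are expected
#' to be reported as homozygous by diploid callers, so heterozygosity rises
#' only in the pseudoautosomal region.
#'
#' @param genotypes matrix of diploid genotype calls, animals in rows and
#'   sites in columns: alt-allele dosage 0/1/2 with `NA` for missing.
#' @param positions strictly increasing 1-based site positions, one per
#'   column.
#' @param min_call_rate minimum fraction of called genotypes.
#' @param sex optional character vector per animal; any value other than
#'   `"M"` is an error (the profile is defined for males only).
#' @return `data.frame` of class `"het_profile"` with columns `position`,
#'   `n_called`, `n_het`, `het_fraction`.
#' @export
male_heterozygosity_profile <- function(genotypes, positions,
                                        min_call_rate = 0.9, sex = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(ncol(genotypes) == length(positions))
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (!is.null(sex) && any(sex != "M"))
    stop("non-male animal(s) in input: ",
         paste(which(sex != "M"), collapse = ", "))

  called <- !is.na(genotypes)
  keep_animal <- rowMeans(called) >= min_call_rate
  g <- genotypes[keep_animal, , drop = FALSE]
  called <- called[keep_animal, , drop = FALSE]
  keep_site <- colMeans(called) >= min_call_rate
  if (!any(keep_site)) stop("no sites survive call-rate filtering")
  g <- g[, keep_site, drop = FALSE]

  n_called <- colSums(!is.na(g))
  n_het <- colSums(g == 1, na.rm = TRUE)
  out <- data.frame(position = positions[keep_site], n_called = n_called,
                    n_het = n_het, het_fraction = n_het / n_called)
  rownames(out) <- NULL
  class(out) <- c("het_profile", "data.frame")
  out
}

binom_ll <- function(h, n) {
  H <- sum(h); N <- sum(n)
  if (N == 0) return(0)
  p <- H / N
  t1 <- if (H > 0) H * log(p) else 0
  t2 <- if (N - H > 0) (N - H) * log(1 - p) else 0
  t1 + t2
}

#' Detect the pseudoautosomal boundary from a heterozygosity profile
#'
#' Fits a single changepoint to the per-site heterozygote counts by an
#' exhaustive scan over all split positions, maximising the two-segment
#' binomial log-likelihood (each segment with its own heterozygosity rate).
#' The boundary is declared only when the log-likelihood-ratio against the
#' one-segment model exceeds `min_lr`; otherwise no pseudoautosomal region
#' is reported. The pseudoautosomal region is expected distal (higher
#' heterozygosity past the boundary); the reversed orientation is reported
#' with a warning.
#'
#' @param profile a `"het_profile"` with at least two sites.
#' @param min_lr significance gate in log-likelihood units.
#' @return List of class `"par_boundary"`: `detected`, `boundary` (midpoint
#'   between the flanking sites, `NA` if undetected), `split_index` (last
#'   site of the proximal segment), `proximal_het`, `distal_het`,
#'   `log_lr`, `par_side` (`"distal"`, `"proximal"` or `NA`).
#' @export
detect_par_boundary <- function(profile, min_lr = 10) {
  stopifnot(inherits(profile, "het_profile"), nrow(profile) >= 2L)
  h <- profile$n_het; n <- profile$n_called
  ns <- length(h)
  ll0 <- binom_ll(h, n)

  ch <- cumsum(h); cn <- cumsum(n)
  H <- ch[ns]; N <- cn[ns]
  ll_seg <- function(Hs, Ns) {
    out <- numeric(length(Hs))
    p <- ifelse(Ns > 0, Hs / Ns, 0)
    i <- Hs > 0; out[i] <- out[i] + Hs[i] * log(p[i])
    j <- Ns - Hs > 0; out[j] <- out[j] + (Ns - Hs)[j] * log(1 - p[j])
    out
  }
  k <- seq_len(ns - 1L)
  ll2 <- ll_seg(ch[k], cn[k]) + ll_seg(H - ch[k], N - cn[k])
  best <- which.max(ll2)
  log_lr <- ll2[best] - ll0

  if (!is.finite(log_lr) || log_lr < min_lr) {
    return(structure(list(detected = FALSE, boundary = NA_real_,
                          split_index = NA_integer_,
                          proximal_het = NA_real_, distal_het = NA_real_,
                          log_lr = log_lr, par_side = NA_character_),
                     class = "par_boundary"))
  }
  prox <- ch[best] / cn[best]
  dist <- (H - ch[best]) / (N - cn[best])
  side <- if (dist > prox) "distal" else "proximal"
  if (side == "proximal")
    warning("elevated heterozygosity proximal of the changepoint; ",
            "pseudoautosomal region reported on the proximal side")
  structure(list(detected = TRUE,
                 boundary = (profile$position[best] +
                               profile$position[best + 1L]) / 2,
                 split_index = best, proximal_het = prox, distal_het = dist,
                 log_lr = log_lr, par_side = side),
            class = "par_boundary")
}

#' @export
print.par_boundary <- function(x, ...) {
  if (!x$detected) {
    cat(sprintf("No pseudoautosomal boundary detected (log-LR = %.2f)\n",
                x$log_lr))
  } else {
    cat(sprintf(
      "Pseudoautosomal boundary at %.0f (log-LR = %.1f)\n  %s heterozygosity: proximal %.4f, distal %.4f; PAR on the %s side\n",
      x$boundary, x$log_lr, "male", x$proximal_het, x$distal_het, x$par_side))
  }
  invisible(x)
}
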