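---
title: "Methods: models, parameters and design choices in keyvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in keyvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyvar)
```

`keyvar` implements the computational stages of a key-ancestor
re-sequencing study. This vignette documents the underlying models and
assumptions, the tunable parameters with their defaults, what the
synthetic-data generators do and do not emulate, and the places where the
design was genuinely open and a choice had to be made.

## Pedigree diversity and key-animal selection

The additive (numerator) relationship matrix **A** is built by the tabular
method over a topologically ordered pedigree: for animal *i* with parents
*s*, *d*,
$$a_{ii} = 1 + \tfrac12 a_{sd}, \qquad a_{ij} = \tfrac12 (a_{js} + a_{jd})$$
with an unknown parent contributing zero. Founders (and phantom parents)
are assumed unrelated and non-inbred, so **A** is symmetric positive
semidefinite, equals twice the kinship matrix, and its diagonal is
$1 + F$ with $F$ the inbreeding coefficient. The test suite verifies
exact equality (all quantities are dyadic rationals, hence exactly
representable) against an independent oracle that enumerates every
possible allele-transmission pattern on pedigrees of up to eight animals.

For a selected set of $m$ animals, $\mathbf{c}_m$ holds their average
relationships to the reference population and
$\mathbf{p}_m = A_m^{-1}\mathbf{c}_m$ their diversity contributions. The
captured proportion is aggregated as $\sum_i p_i$ by default. The
aggregation was an open choice: the iterative formulation defines
$\mathbf{p}$ as per-animal proportions without stating how they combine;
summing contributions is the natural reading and yields the familiar
concave cumulative curve. The quadratic form
$\mathbf{c}^\top A^{-1}\mathbf{c}$ — the projection interpretation of the
same system — is exposed via `method = "quadratic"`. The two coincide in
neither ranking nor value in general (for a single animal they give
$c/a$ and $c^2/a$ respectively), and both are covered by tests.

Selection is greedy forward selection with full re-evaluation: at each
step every remaining candidate is scored by re-solving the enlarged
system, and the best is added. This re-evaluation (rather than one-off
ranking) was the second open choice; "iterative" selection with a changing
$A_m$ makes a static ranking incoherent. Ties are broken by earliest birth
year, then lexicographic id — older animals are the natural key-ancestor
candidates. If no candidate increases the captured proportion the
selection stops early with a message, which keeps the cumulative curve
non-decreasing by construction.

Greedy selection is *not* guaranteed to find the optimal $m$-subset, and
genuinely does not on a substantial fraction of small random pedigrees
(typical counterexample: the single best animal is a well-connected
descendant, while the best pair are its two founder parents). The tests
therefore assert optimality only where a brute-force subset search
confirms it, and otherwise assert that greedy beats the median random
subset of the same size; the acceptance script reports the observed
equality rate rather than presuming 100%.

Near-singular systems $A_m$ (duplicated or cloned individuals) are solved
by Moore–Penrose pseudoinverse when the condition number exceeds `1e8`,
with a warning naming the problem. Proportions outside $[0,1]$ by more
than `1e-8` warn and are clamped.

## Genotype concordance (NRS / NRD)

Genotype-level comparison of a sequence-derived call set against an
array-derived truth set at shared (site, animal) pairs. Sequence calls
below the phred threshold (`min_phred`, typically 10, i.e. ~90%
confidence) or missing are tallied as `missing_or_filtered`:

* **NRS** (non-reference sensitivity) = pairs with array ∈ {het, hom-alt}
  and sequence ∈ {het, hom-alt}, divided by pairs with array ∈ {het,
  hom-alt}. A missing/filtered sequence genotype at an array non-reference
  site *reduces* NRS — the study design evaluates genotyping completeness,
  so a lost genotype is a sensitivity failure.
* **NRD** (non-reference discrepancy) = discordant pairs among both-called
  pairs, divided by both-called pairs minus the concordant hom-ref cell.
  Removing the hom-ref/hom-ref mass from the denominator prevents the
  overwhelming majority of trivially concordant reference calls from
  masking errors.

Zero denominators yield `NA` ("undefined"), never 0. Sites present on only
one platform, and sites whose ref/alt alleles disagree between platforms,
are excluded and reported — never silently dropped. The array is treated
as truth; no reciprocal metric is computed.

## Variant catalogue

Classification is total on well-formed records and follows the VCF
left-anchored convention. Triallelic sites are counted but excluded from
Ti/Tv and from coding-effect annotation: how multi-allelic sites should
enter those summaries is genuinely underdetermined, and excluding 0.15%
of sites is the conservative choice. Ti/Tv uses transitions {A↔G, C↔T};
with no transversions (or no biallelic SNVs) the ratio is undefined
(`NA`). Uniform random substitutions give Ti/Tv → 0.5 (4 of 12 ordered
substitution types are transitions); real genomes sit well above this.
When a pseudoautosomal boundary is supplied, X-chromosome counts are
split into "X (non PAR)" and "X (PAR)" rows, the PAR extending from the
boundary to the distal end.

## Functional annotation

Gene models are single-transcript (one per gene; on duplicates the
longest CDS is kept). Models whose reference CDS length is not divisible
by three, or whose translation contains an internal stop codon, are
excluded with a reason — annotating against a broken frame would
misclassify every downstream variant.

Regions, assessed per model at the variant's leftmost affected base (for
left-anchored InDels this is the base after the anchor; a `spanning` flag
marks InDels crossing a boundary):

| region | definition | parameter |
|---|---|---|
| promoter | bases immediately upstream of the transcription start, strand-aware | `promoter_bp = 1000` |
| utr5 / utr3 | exonic transcript outside the CDS, oriented by strand | — |
| cds | exonic within the coding bounds | — |
| splice_site | first/last intronic bases of each intron | `splice_bp = 2` |
| intron | remaining intra-transcript | — |
| intergenic | everything else | — |

The splice-site width (2 bp, the canonical GT/AG dinucleotides) and the
precedence order splice_site > cds > UTR > promoter > intron were open
choices; both are parameters or documented constants rather than
hard-coded behaviour. Internally all coordinates are 1-based closed — the
natural convention in R/Bioconductor and in VCF and GFF3 — with BED12's
0-based half-open coordinates converted at the I/O boundary and covered
by round-trip tests.

Coding effects splice the CDS from the exon blocks (reverse-complementing
minus-strand models), locate the affected codon and translate with the
standard nuclear code. Any change to the initiator codon is a start loss;
a new internal stop is a stop gain; loss of the terminal stop is a stop
loss; InDels are frameshift or in-frame by length modulo 3. A guard
verifies the reference base at the variant position against the record's
ref allele, catching coordinate-convention bugs at the source. Two
independent oracles back this in the tests: full rebuild-and-translate of
the mutant CDS, and strand symmetry (annotating the reverse-complemented
genome with the mirrored model must give identical results).

## Pseudoautosomal boundary

Diploid callers report hemizygous male non-PAR genotypes as homozygous,
so male heterozygosity along X is near zero proximally and rises sharply
inside the PAR. After call-rate filtering (animals first, then sites;
default `min_call_rate = 0.9`), the boundary is the single changepoint
maximising the two-segment binomial log-likelihood of the per-site
heterozygote counts, found by exhaustive scan over all splits (the tests
check equivalence against a naive two-loop implementation). The original
visual determination is replaced by this likelihood criterion to make the
boundary reproducible; a likelihood-ratio gate (`min_lr = 10` log-units)
prevents fabricating a boundary on flat profiles — below the gate the
result is "no PAR detected". Residual proximal heterozygosity is treated
as caller noise, not an error; a profile with *higher* proximal
heterozygosity is reported with the PAR on the proximal side plus a
warning, since the changepoint model itself is symmetric.

## Disorder mapping

The per-SNP association test is Fisher's exact test on the 2×2
case/control allele-count table, computed by direct hypergeometric
enumeration: the two-sided p-value sums the probabilities of all tables
(at fixed margins) whose probability does not exceed the observed one,
with a relative tolerance of 1e-7 for floating-point ties. Missing
genotypes drop the animal at that SNP only; monomorphic SNPs get p = 1
and a flag. No multiple-testing correction is applied to the primary
p-values (raw Fisher p-values are the convention for this design); a
Bonferroni column is emitted for convenience. Under the null the exact
test is *super-uniform* (conservative) because of discreteness — the
tests assert P(p ≤ α) ≤ α rather than strict uniformity.

Autozygosity mapping reports maximal runs of at least `min_snps = 20`
consecutive SNPs at which every case is homozygous *for the same allele*
— the founder-haplotype interpretation of a shared autozygous segment.
Requiring identical alleles (rather than mere per-case homozygosity) was
an open choice; identical sharing is what a common ancestral haplotype
implies, and it is the default. A missing genotype disqualifies a SNP
unless `missing_tolerant = TRUE`. Segment bounds are the first and last
qualifying SNP positions, not interval midpoints. With a single case
every homozygous run qualifies — a documented degenerate behaviour.

## Synthetic data: what it emulates, and what it does not

All generators are deterministic functions of their arguments and a
mandatory integer seed, restore the caller's RNG state, and are
independent of call order.

* `simulate_pedigree()` builds overlapping-generation pedigrees (parents
  drawn from *all* previously born animals) with birth years from 1920
  on, echoing herdbook pedigrees reaching back a century. Defaults (20
  founders, 5 generations, 2 offspring per mating) give a population of
  the order of a hundred animals — large enough for selection curves,
  small enough for exhaustive oracles.
* `gene_drop()` transmits founder alleles down the pedigree, one
  uniformly chosen allele per parent per locus, with optional
  identity-by-descent labels. Loci are independent: there is no linkage,
  no mutation, no selection. Expected IBD sharing between two animals is
  half their numerator relationship, and the expected gene-content
  covariance is $a_{ij}\,2q(1-q)$ — both are exploited as Monte-Carlo
  oracles.
* `simulate_genotyping()` degrades truth genotypes into paired platforms.
  The array platform uses a small miscall rate (0.002) and a missing rate
  of 0.0074, matching a ~99.26% array call rate. The sequence platform
  draws per-site Poisson depth around the animal's coverage tier —
  default tiers 4.17, 7.46, 15 and 24.98, spanning the low-to-medium
  coverage range of key-ancestor re-sequencing — then binomial
  alternate-read counts (per-read error 0.01), calls the
  maximum-likelihood genotype and phred-scales the likelihood gap to the
  second-best genotype, capped at 60. This is a deliberately simple
  stand-in for a multi-sample caller: it produces the monotone coupling
  between coverage, quality and error that the concordance module needs,
  but no alignment artefacts, no imputation, no linkage-informed rescue
  of low-coverage sites.
* `simulate_annotation_truth()` generates a single-chromosome toy genome
  with non-overlapping genes (1–8 exons, both strands, valid ORFs) and
  plants variants whose region and coding effect are forced *by
  construction* at planting time; gene footprints are spaced so no
  variant can touch two genes. Truth recovery is therefore asserted at
  100% with no tolerance: annotator and generator must agree exactly.
* `simulate_x()` plants a pseudoautosomal boundary (default 137 Mb on a
  149 Mb chromosome) with hemizygous-as-homozygous proximal sites (het
  miscall 0.005) and Hardy–Weinberg diploid distal sites at per-site
  allele frequencies in 0.1–0.5.

Passing tests on these generators show the *algorithms* are correct under
idealised noise; they do not certify performance on real data with
linkage disequilibrium, alignment error, reference bias or population
structure.

## Problem sizes and numerical choices

The validation suite uses desk-scale problem sizes chosen so every oracle
remains exhaustive: transmission enumeration up to 8 animals (4^6
patterns), brute-force subset search on 12-animal pedigrees up to m = 3,
10,000 gene-drop loci for covariance checks, ~1,000 planted variants for
annotation, 200 replicate X profiles, Fisher enumeration up to grand
total 60. Tolerances are 3 Monte-Carlo standard errors for sampling
checks, 1e-12 for enumeration agreement, and exact equality where the
arithmetic is exact (relationship matrices, planted truth labels,
segment bounds).
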