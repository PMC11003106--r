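---
title: "Models and methods behind scifiatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scifiatac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scifiatac)
library(data.table)
```

## The problem

Droplet scATAC-seq platforms recover a small fraction of loaded nuclei
because the suspension must be dilute enough to keep two nuclei from
sharing a droplet. Combinatorial fluidic indexing removes that ceiling:
nuclei are first tagmented in a 96-well plate with *barcoded* Tn5 — a
5-nt barcode on each adapter side, 12 A-side ("row") barcodes crossed
with 8 B-side ("column") barcodes — and then deliberately overloaded
into the microfluidics device. Cell identity becomes the pair
*(16-bp bead barcode, Tn5 well)*: two nuclei in one droplet remain
distinguishable unless they also came from the same well.

This package implements the computational side of such an experiment:

1. a synthetic-experiment generator with complete ground truth;
2. demultiplexing of the combined barcodes with whitelist correction;
3. conversion of fragments to single-base Tn5 insertion sites and
   per-nucleus QC;
4. a binomial/Bayes genotype model that detects barcode collisions and
   quantifies index-hopping contamination;
5. an analytic droplet-occupancy ("birthday problem") model of
   collision rates;
6. pseudobulk accessibility scoring for annotation-style analyses.

## The synthetic experiment generator

`make_reference()` builds a miniature genome: by default two 5-Mb
nuclear chromosomes, two organelle scaffolds, 320 non-overlapping genes
laid out on a per-chromosome grid, 1600 ACRs of 500 bp, and homozygous
biallelic SNPs at 0.70/kb — the density typical of a diverse maize
panel, and the value at which the genotype model is designed to work.
Every SNP distinguishes at least two genotype labels.

`sim_design()` fixes the experimental conditions and
`simulate_experiment()` executes them with a single seeded RNG stream:

* **Droplet loading.** Nuclei per occupied droplet follow a
  zero-truncated Poisson. The default `lambda = 3.27` gives a mean
  occupancy of `r round(3.27/(1-exp(-3.27)), 2)` nuclei per droplet,
  the regime of a heavily multiplexed run; analyses in the test-suite
  use `lambda` 1–2, matching lighter overloading. Only the mean of the
  real occupancy distribution is observable at desk scale, and a
  truncated Poisson is the standard microfluidics loading model; the
  collision model consumes whatever occupancy distribution it is given,
  so this choice is not load-bearing.
* **Fragments.** Per-nucleus fragment counts are negative binomial
  (default mean 1000, size 4 — median depths in the low thousands of
  insertion sites with realistic overdispersion). Fragment sizes are a
  mixture of a nucleosome-free mode (N(80, 20), 60%) and a
  mononucleosome mode (N(200, 30), 40%), floored at 35 bp.
* **Genomic placement.** A fragment is organellar with probability
  0.08; otherwise its midpoint falls inside an ACR with probability
  `E·A / (E·A + (L − A))` (`E` = enrichment, default 5; `A` = total ACR
  length; `L` = nuclear genome length), uniformly otherwise over the
  non-ACR space. Sixty percent of ACRs are promoter-proximal (centred
  within ±1750 bp of a TSS, at most three per gene). Under the default
  geometry this gives an expected FRiP around 0.28 and TSS fraction
  around 0.24, so a typical simulated nucleus clears the QC thresholds
  the way a typical real nucleus does.
* **Index hopping.** Each read is, with probability `hopping_rate`
  (default 0.03), re-emitted under the bead barcode of *another*
  occupied droplet drawn in proportion to that droplet's fragment
  abundance — an index swap samples the library pool, so barcodes with
  more fragments both donate and receive more strays. The inline Tn5
  barcodes are untouched, which is exactly why the two-sided design can
  recognise most hopped reads: the stray read's well rarely matches a
  nucleus of the receiving droplet, so it surfaces as a trace
  (bead, well) combination that `filter_bead_well_combos()` flags.
  An abundance-proportional target (rather than a uniformly chosen
  droplet) also makes the pooled mismatch fraction among singlets equal
  `hopping_rate / 2` exactly in a two-genotype equal mixture; a uniform
  target would over-contaminate small cells relative to large ones.
* **Allele errors.** A read overlapping a SNP reports the wrong allele
  with probability `seq_error` (default 0.01 per informative read; the
  *model's* `epsilon = 0.05` is deliberately conservative relative to
  the generating process).

What the generator does **not** emulate: realistic sequence content
(bases outside barcodes are placeholders), base qualities, mappability
artefacts, chimeric reads, per-cell depth correlated with cell type,
or heavy-tailed occupancy beyond the truncated Poisson. Passing tests
therefore demonstrate the correctness of the algorithms under the
stated generative model, not robustness to every artefact of real
libraries.

## Demultiplexing and barcode correction

The default 5-nt barcode sets have minimum pairwise Hamming distance 3,
so single-substitution correction is always unambiguous;
`correct_barcode()` accepts the unique whitelist entry within
`max_mismatch` (default 1) and rejects ties — a conservative rule,
since a mis-corrected well barcode would masquerade downstream as
index hopping. Rejection reasons are enumerated (`bad_bead`, `bad_a`,
`bad_b`, `invalid_pair`) and reads are conserved: every input read is
assigned, flagged, or rejected.

A (bead, well) combination is promoted to a candidate nucleus when it
holds at least `min_reads = 100` reads *and* at least `min_frac = 0.05`
of its bead's reads. The thresholds are configurable; no published
value exists for them, and the defaults sit comfortably between trace
hopped combinations (a handful of reads) and genuine co-encapsulated
nuclei (hundreds).

## Insertion sites and nucleus QC

Fragments are converted to single-base Tn5 integration sites by the
canonical +4/−5 shift, applied in BED coordinates as `start + 4` and
`end − 5` (the source material states the shifts but not the dialect;
0-based half-open is this package's declared convention throughout).
Fragments shorter than 10 bp yield coincident or inverted sites and are
flagged degenerate rather than dropped. Only unique sites per cell are
retained.

Per-nucleus QC uses four inclusive thresholds: ≥ 1000 unique sites,
≥ 20% of sites within ±2 kb of a TSS (window inclusive at both ends),
≥ 20% of sites in ACRs, ≤ 30% of sites on organelle scaffolds. All
fractions are computed over **all** unique sites, organelle sites
included — whether the original workflow excluded organelle reads from
the denominators first is not documented, so the simpler convention is
used and stated.

## The genotype / collision model

For each candidate nucleus, reads covering homozygous biallelic SNPs
are counted per genotype (`count_alleles()`; a read contributes at its
first overlapped SNP, and an allele shared by several genotypes splits
the count equally so totals are conserved). With counts
\(n_1, \dots, n_G\), \(n = \sum_g n_g\), the model compares
\(G + 1\) hypotheses:

* **singlet of genotype g**: each read supports \(g\) with probability
  \(1 - \epsilon\), the error mass \(\epsilon\) spread evenly over the
  other genotypes;
* **collision**: the best equal mixture of two singlet distributions,
  \(p = \tfrac12 p^{(i)} + \tfrac12 p^{(j)}\) maximised over pairs
  \((i,j)\). With two genotypes this is the classical
  \(\mathrm{Binomial}(n, 0.5)\) collision kernel. (A formulation that
  assigns \((1-\epsilon)/2\) to each partner and splits the error over
  the rest does not define a probability vector at \(G = 2\); the
  mixture-of-singlets form is used instead and coincides with the
  binomial model in the two-genotype case.)

Posteriors follow from Bayes' theorem under flat priors (so the
posterior is the normalised likelihood), evaluated in log space —
informative-read counts can reach thousands and the binomial tails
underflow otherwise. Cells with \(n < 50\) are left unassigned, as are
exact posterior ties. Contamination of a singlet call is
\((n - n_{\text{call}})/n\), the mismatching-read fraction among reads
covering biallelic SNPs.

In multiplexed designs each well holds one sample, so the expected
genotype follows from the well map; reads not matching it are pooled
as "other" and the same machinery tests expected vs other vs collision
(`assign_expected_genotype()`). The error rate is applied per
informative read, not per base: with ~0.7 SNPs/kb a fragment rarely
covers more than one SNP, so the distinction is immaterial at this
density.

Two cohort-level facts are worth knowing when interpreting
contamination. First, with two equally mixed genotypes only half of
hopped reads land on a nucleus of the other genotype, so contamination
estimates hopping at rate \(h/2\). Second, that identity holds for the
*read-weighted* (pooled) mismatch fraction; an unweighted mean of
per-cell fractions is biased upward by small cells, which receive
hopped reads in proportion to the pool, not to their own size.

## The droplet-occupancy collision model

Observed occupancy \(k\) is the number of distinct retained wells per
bead barcode. For a droplet of \(k\) nuclei with well probabilities
\(p_w\):

* probability that at least two share a well (birthday problem):
  uniform wells, \(1 - \prod_{i=0}^{k-1}\frac{W-i}{W}\); general wells,
  \(1 - k!\, e_k(p)\) with \(e_k\) the elementary symmetric polynomial,
  computed exactly via Newton's identities for \(k \le 10\) and by
  seeded Monte-Carlo beyond;
* expected *fraction of nuclei* losing identity, by linearity of
  expectation: \(q(k) = 1 - \sum_w p_w (1-p_w)^{k-1}\), exact for every
  \(k\) (no enumeration needed);
* the dataset rate is the nucleus-weighted mixture
  \(\sum_k P(k)\,k\,q(k) / \sum_k P(k)\,k\), with \(P(k)\) the observed
  occupancy distribution and \(p_w\) estimated from per-well nucleus
  counts (loading across wells need not be uniform). A fixed-\(k\)
  figure (e.g. the four-nuclei droplet at mean occupancy 3.4) is
  available directly through `same_well_collision_prob()`.

The collision rate is defined at nucleus level — the fraction of
nuclei that share (droplet, well) with another — because recovered-
nuclei counts are the denominator in which such rates are reported.
Genotype-based detection sees only cross-genotype collisions; with
genotype fractions \(f_g\) the visible share is \(1 - \sum_g f_g^2\),
so `total_collision_from_observed()` rescales by its inverse — the
familiar ×2 for an equal two-genotype mixture:

```{r doubling}
total_collision_from_observed(c(4.87, 5.68), c(0.5, 0.5))
```

Two known approximations: nuclei that actually collide merge into one
observed combination, so the observed occupancy distribution slightly
underestimates loading (second-order at the ~2% collision rates of
interest); and bead multiplets (two beads in one droplet) are not
modelled.

## Pseudobulk accessibility

Gene accessibility counts insertion sites in the gene body plus 500 bp
upstream and 100 bp downstream, strand-relative (flank orientation is
a documented choice; "upstream" follows transcription). Counts are
CPM-normalised (via edgeR's `cpm`) and standardised per feature across
groups with the sample (n−1) standard deviation; zero-variance
features get Z = 0. ACR master lists take 500-bp summit-centred
windows, resolve overlaps greedily by descending summit signal (the
original unified-list script is unpublished; greedy-by-signal is the
standard iterative overlap removal), and drop windows below 3 CPM in
every group. Specificity calls use Z > 2, strictly; note that with
\(n\) groups the largest attainable Z for a single spiked group is
\((n-1)/\sqrt{n}\), so Z > 2 requires at least seven groups — consonant
with its use across many cell types. Library similarity is Spearman
correlation with average ranks on ties.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere; GRanges conversions
  add 1 internally. The TSS window is ±2000 bp inclusive of both
  endpoints.
* Likelihoods in log space; posterior ties → unassigned; `n = 0` →
  unassigned.
* Empty inputs return empty, typed tables (occupancy of no combos,
  QC of absent barcodes via the `barcodes` argument, fragment files
  with headers only).
* Elementary symmetric polynomials are exact to ~10⁻¹² against the
  uniform product formula for \(k \le 10\); beyond that the Monte-Carlo
  fallback is seeded for reproducibility.
* All generator draws come from one RNG stream keyed by
  `design$seed`; identical seeds give byte-identical experiments.

## Problem sizes used in the checks

The bundled checks run the generator at desk scale, chosen so each
check's Monte-Carlo error is small relative to what it measures:
occupancy goodness-of-fit on ≥ 10⁴ droplets; genotype calibration on
10⁴ singlets and 10⁴ balanced doublets (≥ 50 informative reads each);
contamination recovery at hopping rates 0.01/0.02/0.05 with 3000
nuclei × 800 fragments in a bead-barcode-only (single-well) design —
the configuration in which hopped reads land on real nuclei and the
\(h/2\) identity is observable, true singlet status taken from the
truth table; and end-to-end collision recovery with 20 000 nuclei at
λ = 2 over 96 uniform wells, comparing the model estimate against the
realised same-(droplet, well) fraction in the truth table within three
standard errors.

## Limitations

* The genotype model assumes a known SNP panel; de-novo genotype
  clustering is out of scope.
* Collision correction assumes independent genotype assignment across
  co-encapsulated nuclei; sample-to-well confounding in multiplexed
  designs is handled only through the expected-genotype route.
* The occupancy model ignores bead multiplets and assumes wells load
  independently of droplets.
* ACR discovery itself (peak calling) is an input, not a feature.
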