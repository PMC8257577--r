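---
title: "Chromatin states of the quiescent and regenerating liver: model, generator, and design notes"
author: "hepachrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin states of the quiescent and regenerating liver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepachrom)
library(dplyr)
```

## The model

hepachrom segments a genome into chromatin states from binarized epigenomic
tracks. The genome is tiled into fixed-width bins (200 bp by default, the
convention for this kind of segmentation); each bin carries an M-bit vector
saying which of M marks (here ATAC accessibility, H3K4me3, H2A.Z, H3K27me3,
H3K9me3) is present. A hidden Markov model with K states generates these
vectors: the state sequence is a first-order Markov chain with initial
distribution $\pi$ and transition matrix $A$, and conditional on the state
$k$ the marks are independent Bernoulli draws with presence probabilities
$p_{km}$ — the *emission parameters* whose state-by-mark heatmap is the
standard read-out of such a model. Fitting is by Baum–Welch EM on a scaled
forward–backward recursion (implemented in C++ for the inner loops);
decoding assigns each bin the state with maximal forward–backward posterior
(Viterbi decoding is available behind a flag but posterior decoding is the
convention this field uses). Chromosomes are independent sequences sharing
parameters; each restarts the chain at $\pi$.

The assumptions worth keeping in mind: marks are conditionally independent
given the state (no within-bin mark interactions beyond what states encode),
state runs are geometric in length (a first-order chain cannot encode domain
size distributions with heavy shoulders), and the binarization threshold is
global per mark (no local background correction, since no input/control
track is modelled).

### Numerical choices

* Emission probabilities are floored to $[10^{-6}, 1-10^{-6}]$ inside
  likelihood computations so degenerate parameters never produce $-\infty$;
  `emission_prob()` on a single observation honours exact zeros.
* EM stops when the log-likelihood gain drops below `tol` ($10^{-4}$ by
  default) or at `max_iter` (200). The trace is recorded and is
  non-decreasing (asserted to $10^{-8}$ slack in the test suite).
* Initialisation: emissions $\sim U(0.1, 0.9)$, transition rows uniform plus
  gamma jitter, uniform $\pi$; all seeded, so a fit is a pure function of
  (data, K, seed). Restarts (`n_restarts`) keep the best final likelihood.
* Label switching is resolved for display by sorting states on their mean
  emission over open-chromatin marks (names matching ATAC/H3K4/H2A), so
  active promoter-like states list first; `match_state_permutation()`
  resolves it against a reference parameterisation in validation work.
* State-number choice: `select_k()` fits a range of K and reports
  $\mathrm{BIC} = -2\,\mathrm{LL} + \big[(K-1) + K(K-1) + KM\big]\ln(\text{bins})$.
  BIC is this package's documented criterion; published liver maps fix a
  state count (six for the adult liver) without naming the criterion.
* Ties in majority-bp assignments (genes to states, peaks to elements)
  resolve to the lower state index / earlier element class, deterministically,
  and are flagged.
* `poisson_min_count(lambda, alpha)` is the smallest integer count whose
  Poisson upper tail is at most `alpha`; count 0 is never called present.
  Defaults (200 bp bins, $\alpha = 10^{-4}$, global per-mark mean as
  background rate) follow the established binarization convention for this
  kind of segmentation.

## Integration layers

Downstream of the segmentation the package integrates, in order: genomic
elements (promoter = 500 bp upstream of the TSS, strand-aware; precedence
promoter > exon > intron > intergenic makes the four-way partition disjoint
and exhaustive; the overlap rule is the package's choice, since the
four-way partition is conventionally reported without one); per-CpG methylation (methylated
$\beta > 0.8$, unmethylated $\beta < 0.2$, strict inequalities; CpGs take
the state of the bin containing them; coverage filter $\ge 5$ reads by
default); transposable elements (majority-bp state; RepeatMasker
Smith–Waterman score as the age proxy, higher = younger; simple repeats
excluded); expression (expressed iff FPKM > 1); and the regeneration
timecourse (TSS signal matrices at ±5 kb in 50 bp columns, k-means with
k = 3 on concatenated H3K4me3/H3K27me3 profiles, mean log(FPKM+1)
trajectories). Metaplots over TEs rescale each element to 40 equal bins,
strand-aware, and summarise each bin by the winsorized mean (1–99
percentile, linear-interpolation percentiles — the percentile method is the
package's choice).

Two statistical procedures deserve notes.

**Subsampled age test.** TE catalogues are large with high score variance,
so group-vs-reference age comparisons draw `reps = 100` subsamples of
`n = 1000` scores from each side and compare the replicate mean
distributions with a two-sided Welch t-test (a pooled-values variant is a
flag; "permuted sampling" is implemented as repeated random subsampling,
without replacement by default, with replacement behind a flag). This test
treats the realized catalogue as the population: its null is that the
group's score distribution equals the reference's, and the only randomness
is the subsampling. Under that null it is calibrated (verified by
simulation in the test suite: both replicate sets drawn from one shared
population). It is *not* calibrated against the stricter null in which the
group is an independent finite sample from the same distribution — there the
between-sample mean noise ($\sigma\sqrt{2/N}$) dwarfs the replicate-mean
standard error whenever $nR \gg N$ and the test over-rejects. That is an
inherent property of the subsample-then-test design; users comparing groups
that are not subsets of the reference catalogue should treat small p-values
with care.

**Gene-set enrichment.** Enrichment of a gene set within a state is the
upper-tail hypergeometric probability on (universe, state size, set size,
overlap), Benjamini–Hochberg adjusted across states; the hypergeometric is
the package's choice of test for this enrichment.

## The synthetic epigenome generator

Every downstream stage is exercised end-to-end on a synthetic epigenome
with known ground truth (`simulate_epigenome()`), so the whole pipeline is
testable without any sequencing data. The generator's defaults are the
study conditions the package documents:

* one synthetic chromosome of 50,000 bins × 200 bp (10 Mb; multiple
  chromosomes supported);
* six states whose stationary distribution mirrors the published liver
  genome fractions (88.5% empty state, ≈ 3–4% open states, ≈ 7.5%
  repressive states), with a switching rate of 0.015 per bin so state
  domains are multi-kb (mean ≈ 13 kb for the rare active states, longer for
  the large empty state) — geometric run lengths at this rate are what
  makes ±5 kb promoter windows recover their planted state;
* emission probabilities that qualitatively mirror the published heatmap
  (two ATAC+H3K4me3+H2A.Z states, an H2A.Z-dominant state, an empty state,
  an H3K9me3 state, an H3K27me3 state); exact values are package choices,
  not published values;
* 400 genes whose TSSs are planted at the *centres* of state domains
  (promoter chromatin is organised around the TSS in real data), with
  planting weights putting most genes in the active states and a fifth of
  active-state genes in the `bivalent_induced` trajectory class — silenced
  at baseline, induced 8-fold at 40–48 h after partial hepatectomy;
  repressive-state genes are mostly `repressed` (log-normal baseline FPKM
  with state-dependent meanlog; multiplicative log-normal noise per
  timepoint);
* 20,000 CpGs with state-dependent density (CpG-dense open states) and
  Beta-distributed methylation fractions: Beta(1,20) in active states,
  Beta(20,1) in the empty and H3K9me3 states, with the H3K9me3 track bit
  overriding the state (constitutive heterochromatin is methylated wherever
  H3K9me3 sits);
* 2,000 TEs whose per-TE state distribution matches the published one
  (88% / 6.5% / 3.2% in the empty / H3K9me3 / H3K27me3 states), with
  LINE+LTR-heavy class weights and a +3,500 mean Smith–Waterman score shift
  in the H3K9me3-like state (young TEs in constitutive heterochromatin),
  SINE-heavy weights in the open states;
* baseline peak sets per mark (merged runs of present bins, plus implanted
  H3K4me3+H3K27me3 peaks over bivalent TSSs — implanted at the peak level
  so the emitted track stays a pure draw from the ground-truth HMM) and a
  30 h H3K27me3 set that loses the bivalent-TSS peaks first, keeps 42% of
  its peaks on baseline loci, is ~15% smaller than baseline, and gains
  replacement peaks in empty-state territory (the
  promoter-to-intergenic redistribution).

What the generator does *not* emulate: read-level noise and mappability,
mark-specific peak shapes (a bin either is or is not present), correlated
biological replicates, CpG islands as contiguous sequence features (CpG
density varies by state but positions are otherwise uniform), TE
nesting/fragmentation, and any coupling between the fitted segmentation and
downstream tables beyond what the planted truth induces. A passing test
suite therefore demonstrates that the algorithms recover planted structure
under the stated noise model — not that the biology of any particular
tissue will behave as cleanly.

All generator randomness derives from one root seed through fixed named
substreams, so every artefact is byte-identical under a fixed seed.

## Problem sizes used in validation

The test suite runs entirely on synthetic data at desk scale: exhaustive
path enumeration validates the forward/backward recursions for sequences of
up to six bins and three states; parameter recovery uses a three-state,
well-separated emission configuration at 50,000 bins (emission mean
absolute error < 0.05 and ≥ 95% decoding accuracy after permutation
matching); BIC model selection uses twenty replicates of 3,000 bins;
resampling-test calibration uses 200 null datasets of 20,000 scores with
100 subsamples of 1,000; the end-to-end pipeline runs the full default
configuration (50,000 bins, six states, five marks). Published headline
counts for the adult liver (genome fractions to one decimal, gene counts
per state, cluster sizes) depend on deposited sequencing data, alignment
and annotation versions, and are not reproduction targets at these scales; the suite instead asserts the structural claims against
planted ground truth.

## Known limitations

* The Bernoulli HMM shares ChromHMM's modelling assumptions but not its
  information-based initialisation; with few random restarts, EM on rare
  states (a fraction of a percent of the genome) can merge or split them.
  The default pipeline run reports the fit trace and BIC so this is
  visible.
* The element partition is annotation-agnostic: it takes whatever gene
  models it is given and does not attempt to reconcile transcript isoforms
  beyond the BED12 blocks.
* `assign_genes_to_states()` exposes `exclude_unmarked` rather than
  deciding whether unmarked genes should be dropped before counting;
  published per-state gene counts typically exclude them from display,
  which is not quite the same thing.
* The subsampled age test's calibration caveat above.
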