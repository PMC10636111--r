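---
title: "Models and methods behind milkshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind milkshare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkshare)
```

## The problem

Human milk is a low-biomass sample: around $10^5$–$10^6$ bacterial cells per
ml, swamped by human cells and nutrients that interfere with DNA isolation.
Amplicon studies of milk therefore face three coupled problems that this
package addresses as one pipeline:

1. **Method comparison.** Different DNA-isolation kits and amplicon lengths
   (short-read 16S V3–V4, roughly 400–431 bp after denoising, versus
   long-read 16S-ITS-23S operons of 1900–3000 bp) distort the measured
   community differently. Compositional statistics — centred log-ratio (CLR)
   transforms, Aitchison distances, PCoA, PERMANOVA and per-genus linear
   models — quantify those distortions against mock communities of known
   composition.
2. **Contamination.** At low biomass, kit reagent bacteria contribute a
   visible fraction of reads. Negative controls carried through isolation
   and library preparation define potential contaminants: any ASV seen in
   both a biological sample and a corresponding control.
3. **Sharing.** With enough sequence resolution, identical amplicon sequence
   variants (ASVs) in a mother's milk and her infant's mouth or gut are
   evidence of bacterial transfer. The null comparison is the set of
   *unrelated* mother–infant pairings of the same samples.

Real cohort data of this kind is controlled-access, so the package ships a
synthetic-cohort generator whose ground truth makes every downstream stage
testable.

## Data model

The central object is the ASV count table: a non-negative integer matrix of
samples by ASVs. Around it sit per-sample metadata (family, body site,
isolation method, sequencing mode, replicate, DNA yield), ASV sequences
(normalized to uppercase DNA, U mapped to T, ambiguity codes rejected by
default because exact-identity sharing calls need an unambiguous alphabet),
an ASV-to-genus/species taxonomy, and a theoretical mock reference.

Missing DNA yields (empty metadata fields) are kept distinct from yields of
0, which encode measurements below the detection limit.

Published summary tables report per-kit read counts as `median (range)` over
1–3 replicates. `reconstruct_replicate_values()` inverts that convention:
one replicate is the median itself, two replicates are the range endpoints
(their midpoint must then match the printed median to within 0.5, a
consistency check on the reconstruction), three are the endpoints plus the
median. The n = 2 midpoint rule is a convention of this package, flagged as
such, because the printed tables carry no further information.

## The synthetic cohort generator

`simulate_cohort()` emulates the pilot design: `n_families = 14` families,
each with one milk, one infant oral, one infant faecal and one maternal
faecal sample, all isolated with one kit and sequenced in one mode
(default short). The generator is explicit about what it does and does not
emulate.

**Genus pools.** Each genus gets a random ancestor sequence at the mode's
amplicon length (420 bp short, 2500 bp long) and derives distinct pool ASVs
by per-site substitutions (default rate 0.02). Substitution-only evolution
means all pool sequences share one length, so Hamming distances are defined
without alignment and the recorded truth distances are exact; the MSA path
is exercised separately with indel-bearing inputs.

**Sharing model.** For each genus, every (family, sample type) owns one
private pool ASV, and every (family, milk-vs-other-site comparison) owns one
potential sharing ASV. With probability `p_share` (default 0.5) the sharing
ASV is planted in both members of the related pair — forcing presence, so
every truth-log event is detectable. One *cosmopolitan* ASV per genus is
carried by any sample with probability `p_bg` (default 0.02); this is the
only route to identical ASVs in unrelated pairs, so the unrelated
background sharing rate is approximately `p_bg^2` per pair. A literal
per-pair background probability is not realisable because pairs share
samples; the per-sample carriage model is the closest well-defined analogue.

**Abundances.** Present genera receive log-normal relative weights
(sd 1, echoing the strong dominance skew of real milk profiles), ASVs
within a genus receive log-normal weights, and read counts are one
multinomial draw at the type-specific depth (15 000–30 000 reads,
log-normal jitter sd 0.2 — the range of read counts reported for milk and
faecal amplicon libraries). Carried ASVs are floored at one read so the
truth log and the table never disagree.

**Negative controls and contamination.** Each isolation method owns a
disjoint pool of contaminant ASVs labelled with typical kit-contaminant
genera (*Cutibacterium*, *Enhydrobacter*, *Escherichia-Shigella*,
*Pelomonas*). Controls draw a uniform 0–5000 read depth (the printed
negative-control range tops out just under 5000 reads) spread over the
method's pool. Contaminant ASVs are injected into biological samples of the
same method with probability `injection_rate`; the injected read fraction
scales *inversely* with the sample's DNA yield (expected fraction
`contam_frac * median_yield / yield`, capped at 0.4), reproducing the
negative yield–contamination correlation reported for real milk samples.

**Mock communities.** One sample per method around an eight-genus
theoretical reference (the standard even-log bacterial community), with
multiplicative log-normal noise of sd `mock_dispersion`; at dispersion 0
the expected fractions equal the reference.

**Determinism.** Every stochastic step draws from a sub-seed derived by
hashing the config seed with a component key (`sample/F03_MILK`,
`pool/Rothia`, ...), so regeneration is bit-identical and insensitive to
evaluation order. RNG state of the caller is saved and restored.

What the generator does **not** model: sequencing error, chimeras, PCR
bias, read-level data, taxonomic misclassification, or compositional
correlation between genera. Passing tests on synthetic data therefore
demonstrate the correctness of the statistics, not the biological fidelity
of any particular parameter value; the generator parameters are stand-ins,
never estimates of a real cohort, and are echoed into every dataset header.

## Compositional analysis

Counts are aggregated to genus level; ASVs without genus classification
pool into `OTHER_UNCLASSIFIED`. Closure is over all retained reads by
default; a `closure = "classified"` flag restricts the denominator to
classified genera, since published figures are ambiguous about which
denominator was used.

CLR values are $\ln(x_{ij} / g(x_i))$ with $g$ the row geometric mean; rows
sum to zero by construction. Zeros are handled with a pseudocount of 0.5
added to genus counts before closure — the standard count-zero treatment,
chosen because it leaves technical replicates comparable; it is
configurable. The Aitchison distance is the Euclidean distance between CLR
rows.

PCoA is classical Gower scaling (via `stats::cmdscale` with eigenvalues
retained): axes ordered by decreasing eigenvalue, variance fractions over
positive eigenvalues, negative eigenvalues reported rather than clipped.
On Aitchison input the embedding reproduces the distance matrix to 1e-6.

PERMANOVA partitions the Gower-centred inner-product matrix by sequential
(type-I) sums of squares in user-given term order — so term order matters,
as in the classical distance-based ANOVA — with 999 unrestricted row
permutations by default and `p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})`. An
exhaustive mode enumerates all permutations for small n; tests verify exact
agreement with an independent within-group sum-of-squares oracle at n = 6
and a type-I error of about 0.045 at nominal 0.05 (the attainable level at
199 permutations). The permutation stream is seeded, so results are
reproducible.

Per-genus method effects are ordinary least squares on CLR abundances with
the milk sample as a fixed effect, a partial F test for the method term,
and Benjamini–Hochberg adjustment across genera. Univariate comparisons use
Kruskal–Wallis with Dunn's rank-based post hoc (z statistics with a tie
correction; BH over all pairwise comparisons within one Kruskal–Wallis
family — the adjustment scope the source tables imply but do not state),
Mann–Whitney U, Spearman correlation and Fisher's exact test.

Mock communities are evaluated against the theoretical reference: detected,
missing and unexpected genera (unexpected below 0.02% relative abundance
flagged as trace), per-genus log-ratio bias, and the Aitchison distance to
the reference with zero components replaced by a 1e-6 fraction. Prevalence
summaries use the ≥70% core-genus rule and the display filter (present in
≥2 samples and ≥2% in at least one; dominant at ≥15%).

## Contamination accounting

Detection is binary by design: an ASV with at least one read in a sample
and at least one read in a matched control is a potential contaminant. The
matching policy — all isolation controls of the same kit, plus all
library-preparation controls — is configurable and logged, because
"corresponding control" is underdetermined in the source design. No reads
are removed; the package only quantifies, reporting per-sample contaminated
read fractions, per-kit `median (range)` summaries, isolation- versus
library-preparation-attributed fractions, and the Spearman correlation of
contamination with DNA yield (missing yields dropped and counted; constant
vectors yield a missing rho with a warning rather than a spurious value).

## Sharing analysis

Pairs are enumerated exhaustively: every milk sample against every sample
of the other type, related iff same family. Families contributing more than
one sample of a type are an error unless replicates are collapsed by
summing first — the pilot design has exactly one sample per type per
family.

Candidate genera must be detected in both members of at least two related
pairs. A pair's call for a genus is `SHARED` iff some ASV of that genus has
an *identical* normalized sequence with at least one read in both samples —
an exact string criterion, deliberately alignment-free, since aligning
cannot change the equality of identical strings. The MSA and Hamming
machinery instead serves the non-zero distances: per-genus progressive
alignment (pairwise affine-gap Needleman–Wunsch–Gotoh, identity distances,
average-linkage guide tree, profile–profile merging; scores match +2,
mismatch −1, gap open −5, gap extend −2, configurable), Hamming matrices
where gap-versus-base counts as a difference and gap-versus-gap does not,
and neighbour-joining trees (Q-criterion; negative branches clamped to zero
with a log message; labels sorted so ties break by label order).

The per-genus test is Fisher's exact on related/unrelated × shared/
not-shared, two-sided by the probability-mass convention (summing
hypergeometric point probabilities ≤ the observed one, relative tolerance
1e-7), BH-adjusted within one body-site comparison — the per-panel family
that matches how significance stars are displayed; a global family is
available. Because the source does not state whether absent-in-either pairs
entered the denominator, both modes exist: the default counts all pairs
(the displayed percentages are over all pairs), `"present_both"` restricts
to pairs with the genus in both members.

## Numerical and design choices

* Read-count medians are reported rounded half away from zero, matching the
  printed convention (a pooled control median of 741.5 prints as 742).
* Fisher p-values are compared to enumeration with a relative tolerance of
  1e-7 to make the ≤ comparison robust to floating-point noise.
* `fisher_exact_2x2` odds ratios use the sample (cross-product) estimate
  with Inf/0 sentinels, NA for 0/0.
* Distance matrices are validated (symmetry, zero diagonal, non-negativity,
  labels) at every entry point.
* Guide-tree and clustering ties break by label order after sorting, so
  results are invariant to input row order.
* All generator and permutation seeds are recorded in outputs; the run
  manifest written by `run_pipeline()` reproduces any output file exactly.

## Problem sizes used in the test suite

The suite validates the exact 2×2 test against full hypergeometric
enumeration for all tables with margins ≤ 30; PERMANOVA size over 1000 null
simulations of 12 samples at 199 permutations plus exhaustive agreement at
n = 6; Hamming matrices on a 50 × 420 bp substitution-only pool; NJ
reconstruction of random additive metrics on 4–8 taxa; and parameter
recovery over 200 simulated 14-family cohorts (planted sharing 0.5,
background 0.02) plus a forced-sharing cohort in which every planted genus
must reach FDR < 0.05 with zero unrelated sharing. These sizes were chosen
as the smallest that make the checks sharp.

## Known limitations

* The generator's sharing model is presence-based; it does not model
  abundance-dependent detection, so power estimates on synthetic data are
  optimistic relative to real low-depth samples.
* Progressive MSA is a heuristic; for substitution-only inputs it provably
  returns the gap-free alignment, but with many indels the guide-tree
  order can affect gap placement (as with any progressive aligner).
* PERMANOVA uses unrestricted permutations; nested or repeated-measures
  designs would need restricted permutation schemes that the package does
  not provide.
* Neighbour joining is a distance method offered for desk-scale tree
  sketches; it does not replace likelihood phylogenetics for publication
  trees.
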