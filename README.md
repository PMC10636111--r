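# milkshare

Compositional analysis, contamination accounting and mother–infant ASV
sharing for low-biomass human-milk amplicon data.

## What problem this solves

Human milk carries ~10⁵–10⁶ bacterial cells per ml among overwhelming
amounts of human material, so milk microbiome results depend heavily on the
DNA-isolation kit, the amplicon (short-read 16S V3–V4 vs long-read
16S-ITS-23S operons) and the amount of reagent contamination. `milkshare`
implements the full post-denoising analysis for studies of this kind, for
microbiome researchers working from ASV count tables:

* **Compositional comparison of methods** — genus aggregation, centred
  log-ratio (CLR) transform `clr(x)_j = ln(x_j / g(x))`, Aitchison
  distances (Euclidean on CLR rows), PCoA with per-axis variance fractions,
  seeded PERMANOVA with sequential sums of squares and pseudo-F
  `F = (SS_term/df_term)/(SS_res/df_res)`, average-linkage clustering,
  mock-community evaluation against a theoretical reference, core-genus
  (≥70% prevalence) and display (≥2 samples, ≥2% abundance; dominant ≥15%)
  filters, per-genus CLR linear models with BH-FDR, and
  Kruskal–Wallis/Dunn, Mann–Whitney, Spearman and Fisher tests.
* **Contamination quantification** — an ASV present in both a sample and a
  matched negative control is a potential contaminant; the package reports
  contaminated read fractions, per-kit `median (range)` summaries,
  isolation- vs library-preparation attribution, and the yield–contamination
  Spearman correlation. Nothing is filtered, only quantified.
* **ASV sharing between related and unrelated mother–infant pairs** —
  exhaustive pair enumeration, candidate-genus selection (present in ≥2
  related pairs), exact-sequence-identity sharing calls, per-genus 2×2
  Fisher exact tests (probability-mass two-sided convention) with BH-FDR
  per body-site comparison, progressive MSA (Gotoh pairwise, guide tree,
  profile merging), Hamming matrices and neighbour-joining trees.
* **A synthetic cohort generator** — 14-family mother–infant cohorts with
  planted sharing at probability `p_share`, cosmopolitan background
  carriage `p_bg`, kit-specific contaminant pools injected into samples
  inversely to DNA yield, low-depth negative controls, mock communities and
  a machine-readable truth log, so the whole pipeline is testable without
  controlled-access human data.

## Worked example

```r
library(milkshare)

cfg <- sim_config(n_families = 14, p_share = 0.5, p_bg = 0.02, seed = 1)
ds  <- simulate_cohort(cfg)

pairs <- enumerate_pairs(ds$meta, "MILK", "INFANT_ORAL")
attr(pairs, "n_related"); attr(pairs, "n_unrelated")
#> [1] 14
#> [1] 182

cand  <- select_candidate_genera(ds$table, ds$taxonomy, pairs)
calls <- do.call(rbind, lapply(cand, classify_pair_sharing, pairs = pairs,
                               table = ds$table, records = ds$records,
                               taxonomy = ds$taxonomy))
sharing_tests(calls)[, c("genus", "related_shared", "related_total",
                         "unrelated_shared", "unrelated_total", "p", "fdr")]
#>                  genus related_shared related_total unrelated_shared unrelated_total            p          fdr
#> 1        Cutibacterium              2            14               26             182 1.000000e+00 1.000000e+00
#> 2        Enhydrobacter              3            14               33             182 7.245140e-01 9.315180e-01
#> 3 Escherichia-Shigella              4            14               68             182 5.791918e-01 8.687877e-01
#> 4              Gemella              8            14                0             182 6.425044e-11 2.891270e-10
#> 5            Pelomonas              2            14               28             182 1.000000e+00 1.000000e+00
#> 6               Rothia              4            14                0             182 1.678787e-05 3.021817e-05
#> 7       Staphylococcus              4            14                0             182 1.678787e-05 3.021817e-05
#> 8        Streptococcus              6            14                0             182 4.120060e-08 1.236018e-07
#> 9          Veillonella              9            14                0             182 2.050546e-12 1.845491e-11
```

Nine of fourteen related milk–infant-oral pairs share an identical
*Veillonella* ASV while zero of 182 unrelated pairs do; the exact test puts
that contrast at FDR ≈ 2e-11. The five genera with planted sharing at
probability 0.5 hover around 4–9 of 14 related pairs and all reach
FDR < 0.05. The kit-contaminant genera (*Cutibacterium*, *Enhydrobacter*,
*Escherichia-Shigella*, *Pelomonas*) are "shared" in many *unrelated* pairs
too — the same ASVs were injected kit-wide — so their tests are flat, which
is exactly the signature that distinguishes reagent contamination from
family-specific transmission.

The whole pipeline — simulation, validation, composition, contamination,
sharing, trees, run manifest — is one call:

```r
res <- run_pipeline(run_config(out_dir = "out", seed = 1), stages = "all")
```

which writes `genus_abundance.tsv`, `aitchison_distances.tsv`,
`permanova.tsv`, `contamination_report.tsv`,
`sharing_tests_milk_vs_*.tsv`, `nj_trees.tsv` and `run_manifest.tsv` under
`out/`. Re-running with the same config and seed reproduces every file
byte-for-byte.

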