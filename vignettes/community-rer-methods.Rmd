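---
title: "Methods: community relative evolutionary rates and their null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community relative evolutionary rates and their null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, estimators and numerical conventions
behind `rerate`, the assumptions they rest on, and the design choices made
where the method left the design genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. The rER model

Branch length in a rooted phylogeny accumulates sequence change. For a
marker-gene fragment placed on a reference tree, the root-to-query-tip
length `L_q` (root → attachment point along the edge, plus the pendant
branch) is compared to the median root-to-tip length `m_p` of the reference
taxa in the fragment's phylum. `rerate` defines

> rER = (L_q − m_p) / m_p.

**Why this form.** The underlying method is described only as a "branch
length variation" against the phylum median, without a formula. The
normalized deviation is scale-invariant (rescaling all branch lengths by
`c > 0` leaves it unchanged — a property test enforces this) and yields
values in the 0.1–0.3 range reported for real habitats. The absolute
difference `L_q − m_p` is available via `marker_rer(..., method =
"difference")` but is not the default: it carries units of
substitutions/site and is not comparable across trees.

Aggregation is fixed by the method: community rER = **median** of a
sample's marker rERs (robust to the heavy placement tails), habitat rER =
**mean** of its samples' community rERs. Medians of even-length vectors are
the mean of the two central values throughout.

**Assumptions and limits.** The phylum median is a fair baseline only if
the phylum is represented by several reference taxa (the tree model warns
on empty phyla and refuses a zero median); placements are taken at face
value (`best_placement` keeps the maximum like-weight-ratio record, ties to
the smaller edge number — the upstream method reports one placement per
fragment and no weighting scheme, so weight-averaging is deliberately not
the default).

### Midpoint rooting

Root placement changes every root-to-tip length, so it is part of the
contract: the root is the midpoint of the longest tip-to-tip path,
minimizing the maximum root-to-tip distance. When the midpoint falls inside
an edge, a degree-2 root splits it with lengths conserved; ties between
equally long tip pairs break on the lexicographically smallest (sorted)
label pair, making rooting — and everything downstream — deterministic.
The implementation is checked against an exact per-edge closed-form minimax
search and against `phangorn::midpoint` on random trees.

### jplace dialects

Producers disagree on whether `distal_length` measures the attachment's
distance from the proximal (root-facing) or distal end of the edge. The
reader normalizes to an internal proximal-offset convention under a switch
`offset_from = c("distal", "proximal")`; the default treats the file value
as the distal-side segment. The package's own writer emits the same
convention it reads, so synthetic round trips are exact to 1e-9 under
either setting; users ingesting third-party jplace should set the switch to
match their producer.

## 2. The composition-matched null

A habitat's samples may differ in rER only because they house different
phyla. The null model asks: *given this sample's phylum composition, and
the habitat-wide pool of marker records, what rER distribution would
random assembly produce?*

1. Pool all marker records (rER + phylum) of the habitat (≥ 2 samples).
2. Draw `n_min` records (size of the smallest member sample) stratified by
   phylum to match the focal sample's composition. Stratum counts use
   largest-remainder allocation (deterministic; remainder ties break on
   phylum name); sampling is without replacement within a stratum, falling
   back to with-replacement (and recording it) when a stratum is exhausted.
3. Repeat B times (default 1000; B = 200–500 in the timed test suite) with
   seeds chained as `derive_seed(master, replicate)`.
4. Compare the sample's observed marker-rER distribution against the
   pooled simulated draws with a two-sided two-sample Kolmogorov–Smirnov
   test; BH-correct across all samples of the run (α = 0.05).

A scalar community rER cannot feed a KS test; the only reading consistent
with a two-sample KS comparison is distribution-vs-distribution, so the
observed *marker-level* sample is tested against the simulated marker-level
draws. The per-replicate simulated community rERs (medians) are kept for
the signed deviation (observed − median expected). Exact KS p-values are
used where `stats::ks.test` provides them (small, tie-free samples) and the
asymptotic form otherwise; resampling ties make the test mildly
conservative, which the calibration test budget (BH rejection ≤ 0.08 at
α = 0.05 under the null) accounts for without being exceeded.

## 3. dN/dS by NG86 counting

The original analysis called an external ML codon package. Downstream use
is only a rank comparison of community medians, so the package implements
the fully specifiable Nei–Gojobori (1986) counting method instead (the
result table records `method = "NG86+JC"`):

* per-codon synonymous site fractions exclude mutations to stop codons
  from the denominator (so TGG has 0 synonymous sites, TTT has 1/3);
* multi-difference codons average over all mutational pathway orderings,
  excluding pathways through stop codons (if *every* pathway is blocked —
  rare — all pathways are used, steps through stops counted nonsynonymous);
* sites are averaged over the two sequences; `d = −(3/4)·ln(1 − 4p/3)`;
* codons with gaps or ambiguity in either sequence are dropped pairwise;
  `pX ≥ 3/4` flags saturation, `dS = 0` flags an undefined ratio; flagged
  pairs are excluded from the community median but tallied.

Counting is verified codon-by-codon against an independent recursive
enumeration oracle, and ω recovery is verified on generator output at
ω ∈ {0.2, 1.0} within 10%.

## 4. Companion estimators

* **Hit filter** — match length ≥ 100, identity ≥ 50%, coverage ≥ 50%,
  score ≥ 60 (all configurable); idempotent, with per-criterion tallies.
* **ACE** (rare threshold 10, the convention of the diversity pipeline the
  method relies on): `S_abund + S_rare/C + (F1/C)·γ²`; all-singleton rare
  classes fall back to Chao1, `N_rare ≤ 1` to observed richness, each with
  a warning. Cross-checked against `vegan::estimateR`.
* **AGS** — the original equation survives only as symbol definitions
  (`L_s`, `R_{m,s}`, `R_s`), so the package implements the marker-density
  reconstruction `AGS = marker_bp_per_genome / d`,
  `d = ΣR_m · L_s / R_s`, with `marker_bp_per_genome = 15000` bp
  (approximate summed length of the 31 single-copy markers in one genome).
  This constant is a **calibration parameter, prominently config-exposed**;
  absolute AGS values inherit its uncertainty, ratios between samples do
  not.
* **OGT** — exactly `937·F − 335` °C with F the IVYWREL residue fraction.
* **Transposase level** — flagged fraction of filtered genes, an input
  annotation flag rather than a homology search; `hgt_proxy_validation()`
  reproduces the supporting transposase↔HGT rank correlation on
  per-genome count tables.
* **Enrichment** — ln odds ratio per COG category, Haldane–Anscombe +0.5
  on zero cells, one-tailed Fisher p in the direction of the observed OR
  (stars at p < 0.01 / p < 0.001).
* **Clustering** — complete linkage on Euclidean distance of z-scored
  {rER, dN/dS, transposase, ACE} (the named tool's defaults; both are
  switchable), deterministic sample order, newick dendrogram export.

## 5. The synthetic world

`study_config()` encodes the stated world the generator emulates — six
habitats, three extreme (acid mine drainage, saline lake, hot spring) and
three normal (surface ocean, freshwater, soil):

| parameter | extreme | normal | why |
|---|---|---|---|
| rER deviation δ | 0.32 / 0.33 / 0.22 | 0.15 / 0.13 / 0.10 | group means ≈ 0.296 vs 0.133, hot spring lowest among extremes, soil lowest overall |
| dN/dS ω | 0.25 / 0.25 / 0.22 | 0.12 × 3 | purifying everywhere, more relaxed in extremes |
| transposase τ | 0.010 / 0.008 / 0.006 | 0.0006–0.002 | 1.0% (AMD) down to 0.06% (ocean) |
| richness S_true | 150 / 150 / 160 | 240 / 240 / 260 | ACE contrast ≈ 152 vs 240 |
| AGS | 2.72 Mb | 3.13 Mb | smaller genomes in extremes |
| OGT | 30 / 25 / **70** °C | 20 °C | only hot spring thermophilic (> 50 °C) |
| COG effect | ln 2 on L (AMD) | 0 | recombination/repair enrichment in acid communities |

Values not stated anywhere (per-fragment rER noise σ = 0.05, codon
divergence 0.3 per codon, lognormal sdlog = 1, depth 5000, 60 markers and
30 ortholog pairs per sample, Dirichlet-like phylum compositions with
shape 2) were chosen once as field-plausible magnitudes and are not tuned
against test outcomes.

Rate deviations are injected through placement geometry — the pendant and
attachment lengths are solved so a query's root-to-tip length equals
`(1 + δ + ε)·m_p` exactly — rather than by sequence simulation. That keeps
ground truth exact and the generator fast, at the price of realism: the
generator does **not** emulate placement error, alignment uncertainty,
chimeras, copy-number variation of markers, or taxonomic binning error. A
green end-to-end test therefore establishes that the *statistical
machinery* recovers injected effects, not that any upstream bioinformatics
is accurate.

## 6. Numerical conventions

* Seeds: every stochastic routine takes an explicit seed; replicate/sample
  seeds derive via a fixed LCG-style map kept below 2³¹. Identical config +
  seed reproduce byte-identical output files (tested via md5).
* Mann–Whitney: exact enumeration when the combined n ≤ 12 and tie-free,
  otherwise the tie-corrected normal approximation; one-tailed directions
  are always declared by the caller, never auto-selected.
* Permutation p-values use the +1 correction and can never be exactly 0.
* BH correction is applied across each family (habitat pairs; deviation
  tests of a run) at the per-analysis α (0.05 for the habitat and deviation
  tests, 0.001 reported for the extreme-vs-normal contrasts).
* ln-OR antisymmetry under focal/background swap holds exactly at the
  count level; floating-point `log()` reproduces it to ≤ 1e-12.
* The Spearman habitat-association test requires a user-supplied numeric
  habitat score: correlating a categorical label with rER is undefined
  without a coding, and choosing one silently would bake in a conclusion.
  With several samples per habitat the score column contains ties, so
  |rho| = 1 is unattainable by construction.

## 7. Known limitations

* Absolute rates, time calibration and effective population size are out
  of scope by design.
* The AGS constant and the rER formula are reconstructions of
  under-specified methods; both are config-exposed and flagged.
* Single-sample habitats cannot be tested against the null model (the pool
  is undefined); they are skipped with a warning.
* The KS deviation test inherits conservatism from resampling ties; its
  calibration is verified empirically rather than analytically.
* CLI stage subcommands recompute the deterministic pipeline and emit one
  stage's files; they are composable and bit-identical to `run`, but do not
  save time over a full run.
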