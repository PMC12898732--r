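---
title: "Bar-HRM species authentication: models, parameters and design choices"
author: "barhrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bar-HRM species authentication: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barhrm)
```

## The problem

Dried flowers (and root products) of *Panax ginseng* (PG) and
*P. notoginseng* (PN) are morphologically indistinguishable, and the price
gap between them invites substitution. Bar-HRM authentication resolves the
two species in a closed tube: a short PCR amplicon spanning
species-diagnostic barcode variants (in ITS/ITS2 or the plastid
*rbcL–accD* spacer) is melted on a fine temperature ramp, and the
fluorescence loss of a saturating intercalating dye is read as the duplex
dissociation curve. Sequence differences between species shift both the
melting temperature `Tm` (apex of the −dF/dT derivative) and the shape of
the normalized melt curve; both are used to call genotypes against
sequence-verified references.

`barhrm` implements every desk-side stage of that workflow — candidate
amplicon screening from aligned barcodes, thermodynamic Tm prediction,
melt-curve processing and genotype calling, and phylogenetic
cross-validation — together with a seeded simulator of melt-curve cohorts
that stands in for instrument data.

## Amplicon screening

Barcode sequences of the two species are globally aligned
(Needleman–Wunsch with affine gaps: match +1, mismatch −1, a gap of
length L scoring `gap_open + (L−1)·gap_extend` with defaults −2/−0.5).
Variant sites are substitution columns (SNPs) and maximal runs of gap
columns (InDels); ambiguity codes compatible with the opposing base are
not variants. Candidate amplicons are alignment windows whose degapped
per-species lengths fall in a configurable 100–250 bp band, contain at
least one variant, and offer at least `flank` (default 20) variant-free
columns at each end. The variant-free flank is a deliberate surrogate for
primer design: primers must bind identically in both species, and the
flank substrings are recorded as the primer sequences. Proper primer
optimization (3′-end stability, dimer checks) is out of scope.

Screening then applies two rules familiar from assay-development
practice: candidates must separate the species by more than 0.3 °C
(strict inequality), and candidates below 0.4 °C whose only variation is
a single SNP are excluded as unreliable. Survivors are ranked by

```
rank = 1.0·min(ΔTm, 1.5) + 0.5·[lengths in 100–200 bp]
     + 0.5·[GC of both amplicons in 40–60%] + 0.5·[> 1 variant]
```

with ties broken to the shorter amplicon and then the smallest name. The
weights are package defaults (all configurable): they encode that beyond
roughly 1.5 °C additional raw separation buys nothing, while a
GC-balanced 100–200 bp multi-polymorphic amplicon melts sharply at a high
Tm and is robust across matrices — which is why the rank rule prefers a
moderate-ΔTm, GC ≈ 60% candidate over AT-rich amplicons (GC ≈ 30%,
Tm ≈ 75 °C) with larger raw ΔTm. The "length in range" term requires both
species' amplicons in 100–200 bp; typical AT-rich distractor panels run
longer (up to ~246 bp), which is what the rule penalizes.

## Thermodynamic Tm prediction

`predict_tm_nn()` uses the unified oligonucleotide nearest-neighbor set
(SantaLucia 1998), summing per-dinucleotide stack enthalpies/entropies
plus both terminal initiation terms, with the symmetry entropy for
self-complementary strands, and

```
Tm = ΔH·1000 / (ΔS + R·ln(C_T / x)) − 273.15 + f([Na+])
```

- `C_T` — total strand concentration, default 5·10⁻⁸ mol/L (50 nM).
- `[Na+]` — sodium-equivalent ionic strength, default 0.05 mol/L.
- `x` — duplex symmetry factor: 4 for non-self-complementary duplexes,
  1 for palindromes. Formulations that write only `ln(C_T)` leave this
  factor implicit; making it explicit is a deliberate completion and is
  exercised against an independent summation oracle in the tests.
- `f` — salt correction. The default `celsius_additive` mode adds the
  classic empirical `16.6·log10([Na+])` °C, matching the additive
  structure of the equation above; an `entropic` mode
  (`ΔS + 0.368·(N−1)·ln[Na+]`) is available through
  `thermo_params()`.

Two caveats are intentional. The model is calibrated on short oligos;
applying it to 100–250 bp amplicons is the standard field extrapolation
and no long-duplex correction is applied silently. And measured HRM peaks
sit systematically above these predictions — typically by 0.7–1.5 °C —
because the saturating dye (and Mg²⁺ in the supermix) stabilizes the
duplex; `predicted_vs_observed()` reports that band but never asserts it.

`hairpin_screen()` replaces a full minimum-free-energy fold with an
exhaustive stem-loop enumeration: perfect reverse-complement stems of
≥ 4 bp around loops of ≥ 3 nt, scored as the sum of the stem's (stem_len
− 1) nearest-neighbor stack free energies at the evaluation temperature
plus a size-indexed loop penalty (+5.6, +5.6, +5.7, +5.4 kcal/mol for
loops of 3–6 nt, +6.0 beyond). Structures below −2 kcal/mol are flagged.
Only the sign and flagging behavior are load-bearing downstream; the
screen is verified against a brute-force enumerator. Note that under
this table a minimal 4-bp GC stem with a 3-nt loop lands slightly
*above* zero (3 × −1.83 + 5.6 ≈ +0.12 kcal/mol); five or more stacked
GC pairs are needed to go negative.

## The melt-curve model and simulator

Simulated curves follow a two-state logistic melt blended between linear
baselines:

```
F(T) = s · [ θ(T)·L_pre(T) + (1 − θ(T))·L_post(T) ] + ε(T),
θ(T) = Σ_d w_d / (1 + exp((T − Tm_d)/width_d))
```

This is the minimal model whose −dF/dT apex sits exactly at `Tm` for flat
baselines, matching how HRM software reads Tm. Defaults (chosen once as
plausible instrument-scale values and exposed in `melt_model()` /
`cohort_spec()`):

- grid 65–94 °C at 0.1 °C (291 points) — the acquisition ramp; real
  instruments oversample the same ramp to >1000 readings, which changes
  nothing downstream, so grid resolution is simply configurable;
- melt width 0.45 °C — reproduces the sharp, symmetric peaks of a
  GC-balanced 162 bp amplicon;
- baselines 100 → 5 RFU with slopes −0.3 / −0.05 RFU/°C;
- per-sample scale ~ LogNormal(0, 0.05), fluorescence noise
  sd 0.95 RFU (1% of the 95-RFU amplitude), per-sample Tm jitter
  sd 0.05 °C;
- `panax_cohort_spec()` encodes the validation-study conditions: 30
  samples, 24 drawn uniformly from the PG melting range 87.8–88.0 °C and
  6 from the PN range 88.4–88.6 °C, with 4 PN-model samples declared
  "PG" (label swaps never touch the generating model).

Negative noise deviates are clamped at zero so the non-negativity
invariant of `melt_curve()` can never be violated; at default noise this
is a > 5σ event confined to the post-melt tail. Each sample draws from a
counter-derived RNG substream, so enlarging one group never reshuffles
the curves of earlier samples.

What the simulator does **not** emulate: dye-binding kinetics and
redistribution, amplification (qPCR) efficiency differences,
heteroduplex/mixture melting, PCR inhibitors, or instrument-specific
optics. Passing tests on simulated cohorts therefore demonstrate that the
analysis recovers the structure this model generates — Tm separation,
shape differences, label swaps — not that any real matrix will behave.

## Melt-curve analysis

**Derivative peaks.** −dF/dT is estimated by local quadratic
least-squares (Savitzky–Golay) smoothing with the window expressed in °C
so results are grid-independent; `smooth_width_c` (default 0.5 °C) is the
*half*-width, giving an 11-point window at the default grid, and the
window must span at least 7 points. Peaks are local maxima at or above
`threshold_frac` (default 10%) of the tallest peak — the baseline-noise
threshold below which events are ignored. The apex is refined by a
least-squares parabola over the derivative points within
±1.4·`smooth_width_c` of the discrete maximum; this wide-stencil
parabolic interpolation replaces the classic 3-point formula because at
1% fluorescence noise the 3-point apex wobbles by ~0.05 °C while the
wide stencil keeps the mean absolute error near 0.015 °C (and its
noise-free bias below 0.01 °C). A curve whose derivative maximum does not
clear numerical dust (10⁻⁸ of the signal scale) has no melting event.

**Normalization.** Straight lines are fitted to a pre-melt and a
post-melt window and the curve is rescaled to 100%/0% between them.
Automatic placement looks for the first and last "quiet" runs of the
derivative — |−dF/dT| within 5% of its maximum, evaluated on a
median-filtered derivative with the threshold floored at 3× the robust
noise level of the outer 10% of points, so that noisy baselines still
read as quiet — and takes up to `window_width_c` (default 1.5 °C) at the
end of each run nearest the transition. The derivative's half-window edge
points (one-sided fits) are excluded from this search. Degenerate curves
whose pre-melt line does not exceed the post-melt line over the melt
region are rejected.

**Difference curves and calls.** Difference curves subtract the pointwise
mean of the reference-genotype normalized curves. Genotype calls minimize
the RMS deviation between a sample and each genotype centroid over the
analysis range — the inter-window span shrunk by 0.2 °C at both ends so
the normalization windows themselves never contribute. Temperature
shifting (overlaying curves by Tm before comparison) is deliberately
*off* by default: the assay's primary signal is the Tm shift itself,
which shifting would erase. Confidence is `100·max(0, r)` with `r` the
Pearson correlation between sample and assigned centroid over the
analysis range. This is an analogue of the proprietary per-cluster
confidence percentages reported by vendor software, not a reproduction of
them; under the default study conditions it exceeds 98 for well-separated
clusters, and it is reported alongside — never instead of — the
distance-based call. Distance ties break to the genotype whose centroid
Tm (read off the centroid curve's own derivative apex) is nearest the
sample Tm, then lexicographically.

**ΔTm and concordance.** Group ΔTm is the absolute difference of group
*mean* primary-peak Tm values (means, not extrema, of replicates).
`concordance()` reports percent agreement (one decimal, round-half-even),
the confusion matrix, discordant samples, and the mislabel list (samples
whose call contradicts their declared label).

## Phylogenetic validation

Barcode cross-validation uses K2P distances by default — the barcoding
convention; the model choice is a package default since assays rarely
state it — with p-distance available, gap/ambiguity columns excluded
pairwise, and saturation (log-domain violation) raised as an error rather
than returned as NaN. Neighbor joining is delegated to `ape::nj` with a
clamp-and-transfer post-pass: a negative branch is zeroed and its
(negative) length added to the sister branch, preserving the path length
through the shared node and the total tree length — the behavior common
in barcoding software. Bootstrap supports resample alignment columns,
rebuild the NJ tree per replicate, and count bipartition recovery
(seeded; 1000 replicates by default). `clade_check()` declares a group
monophyletic iff some bipartition separates exactly that group, with
singletons monophyletic by convention. ITS2 extraction from full ITS
(an annotation-service step) is out of scope; sequences are accepted
pre-trimmed.

## An end-to-end run

The full chain — sequences to screening to curves to calls to clades —
on synthetic data:

```{r end-to-end, eval = FALSE}
## 1. species pair with an AT-rich insertion, aligned and screened
pair <- make_species_pair_fasta(length = 400, n_snps = 3, indel_len = 12,
                                seed = 1)
aln <- align_global(pair$sequence[1], pair$sequence[2])
vars <- find_variant_sites(aln)
cands <- enumerate_amplicons(aln, vars)
screen <- screen_candidates(cands)
attr(screen, "nominated")

## 2. simulated validation cohort at the study conditions
sim <- simulate_cohort(panax_cohort_spec(seed = 1))
refs <- list(
  PG = head(sim$truth$sample_id[sim$truth$true_label == "PG"], 5),
  PN = sim$truth$sample_id[sim$truth$true_label == "PN" &
                             sim$truth$declared_label == "PN"])
res <- hrm_authenticate(sim$curves, refs, reference_label = "PG")
concordance(res$calls, setNames(sim$truth$true_label, sim$truth$sample_id))
```

## Problem sizes and reproducibility

The package's own validation (test suite and the acceptance script under
`scripts/`) runs cohorts of 30 samples × 291 grid points over ten seeds,
200-curve estimator sweeps, 100-oligo thermodynamic oracle comparisons,
and 200–1000-replicate bootstraps — sizes chosen so the whole battery
completes in well under a minute on one core while still exercising every
statistic at the scale the assay uses. All stochastic steps are seeded:
cohorts through `run_config(seed=)` with counter-derived per-sample
substreams, bootstraps through their `seed` argument.

## Known limitations

- The NN model extrapolates beyond its oligo calibration range on long
  amplicons; predictions are best used comparatively (ΔTm), not
  absolutely.
- The hairpin screen considers single perfect stems only; pseudoknots,
  bulged stems and multi-loop structures are invisible to it.
- Genotype calling assumes reference samples for every candidate
  genotype; there is no unsupervised cluster discovery, and mixtures
  (partial adulteration within one tube) are not deconvolved.
- The simulator's noise model is i.i.d. Gaussian; real instruments show
  correlated drift, plate-position effects and dye depletion that may
  widen the confidence/separation margins observed here.
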