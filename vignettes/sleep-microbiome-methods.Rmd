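---
title: "Methods: sleep architecture, diversity, and association analysis in sleepbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep architecture, diversity, and association analysis in sleepbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepbiome)
```

sleepbiome analyzes rodent studies that pair polysomnographic sleep scoring
with 16S gut-microbiome profiling and fecal bile-acid metabolomics. This
vignette documents the models and procedures the package implements, the
parameters that matter, the numerical choices made where conventions differ,
and what the synthetic-data generator does and does not emulate.

## Sleep architecture from scored epochs

The sleep-side input is a hypnogram: an ordered series of 10-second epochs
scored wake (W), NREM (N) or REM (R), anchored to Zeitgeber time (ZT; hours
since light onset under a 12:12 light:dark cycle). Automatic staging is
upstream of this package; `epoch_series()` only validates tokens and timing.

**Bouts.** A bout of a stage starts at the first pair of consecutive epochs
in that stage and ends when two consecutive epochs both fail to match it; a
*single* non-matching epoch of any stage is tolerated inside the bout. The
implementation (`detect_bouts()`) works on run-length encodings and is
checked exhaustively against a literal epoch-by-epoch state machine. Choices
that the rule itself does not fix:

* epoch indices are 0-based; bout intervals are closed `[start, end]`, so
  `duration = (end - start + 1) * epoch_length`;
* the terminating pair may immediately open a bout of another stage
  (abutting bouts are legal);
* a bout still open at the end of the recording closes at its last matching
  epoch — the termination rule defines termination, not truncation;
* single tolerated epochs inside a bout count toward its duration, because
  the bout is reported as an interval.

**Brief arousals** (`detect_brief_arousals()`) are single W epochs strictly
inside N or R bouts — a fragmentation index. By the termination rule such
epochs are always isolated, which the implementation re-checks.

**Summaries.** `stage_time_binned()` reports percent time per stage in
consecutive bins (default 3 h) starting at the recording's first epoch and
labeled by ZT; a partial trailing bin is dropped with a warning, and a bout
belongs to the bin of its *start* epoch so nothing is double-counted.
`bout_statistics()` uses the conventional interpolated median (mean of the
two middle values at even counts). `recovery_summary()` emits the standard
24-h recovery panel — total sleep, NREM and REM percent of the *full*
window, per-state bout counts and median durations, and the arousal count.
`location_index()` is `100 * t_moved / (t_moved + t_unmoved)`; 50 is chance.

## EEG band powers

Bands follow the rodent convention: delta 0.5–4, theta 4–8, alpha 8–11,
sigma 11–15, beta 15–30 Hz. Band intervals are half-open `[low, high)` with
the top band closed, so every shared edge is assigned deterministically
(4 Hz is theta; 30 Hz is beta). Relative power divides each band by the
total over the named bands only — power outside 0.5–30 Hz never enters the
denominator.

`periodogram()` is a Welch estimate: 2-s Hann-windowed segments, 50%
overlap, one-sided density scaling (so summed power times the bin width
tracks the signal variance). Only the band aggregates are contractual; the
window and segment length are conventional defaults. `nrem_delta_timecourse()`
averages per-epoch relative delta over the NREM epochs of each bin and
reports bins with no NREM sleep as missing, never zero. Delta is reported
as relative power without baseline normalization; callers who want
baseline-normalized timecourses can divide by their own baseline mean.

## Microbiome stages

`rarefy()` subsamples each sample without replacement to a common depth
(default 9,000 reads, the conventional choice for this design), removing —
with a named warning — samples below depth. `alpha_diversity()` offers
observed richness, Pielou's evenness `J = H'/ln S` (Shannon in nats; `NA`
when `S <= 1`), and Faith's phylogenetic diversity, computed as the branch
length of the minimal rooted subtree spanning the observed leaves *including
the path to the root* — the dominant implementation convention, verified
against picante.

`unifrac()` implements both variants. Unweighted UniFrac is unique branch
length over spanned branch length; weighted UniFrac is
`sum_b len(b) |p_a(b) - p_b(b)|` with `p` the fraction of a sample's reads
descending through branch `b`. The weighted default is the *unnormalized*
variant; `normalized = TRUE` divides by `sum_b len(b) (p_a + p_b)` to map
into `[0, 1]`. Both agree with phyloseq to numerical precision.

`permanova()` is the one-way pseudo-F permutation test on squared
distances, with `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)` under
free label permutation (no strata), matching one-factor use per timepoint.

`ancom()` counts, per feature, how many additive log-ratio tests against
the other features reject at level alpha (Mann–Whitney for two groups,
Kruskal–Wallis beyond), flagging features with `W >= 0.7 (m - 1)`. The
pseudocount is 1, there is no per-pair multiplicity correction, and all
three settings are arguments — these are the method's common defaults; the
original publications leave room for variants. A fully tied ratio yields no
test and contributes nothing to W, so a constant table gives all-zero W
without error.

`clr_transform()` subtracts the per-sample mean log abundance. The default
pseudocount 0.5 is added *only to zeros*; `all = TRUE` adds it everywhere.
The clr of a pseudocounted composition inverts exactly through a softmax,
which the tests exploit.

## Cross-domain statistics

`spearman_cor()` computes rho as the Pearson correlation of mid-ranks. For
`n < 10` — the realistic per-group size for within-diet correlations — the
p-value is the exact two-sided permutation probability over all `n!`
orderings; from `n = 10` the usual t-approximation is used. The exact branch
matches `cor.test`'s exact distribution.

`bh_adjust()` is the Benjamini–Hochberg step-up (via `p.adjust`). Note that
BH is *not* idempotent: re-adjusting adjusted values inflates them, so the
package never chains adjustments.

`build_network()` tests every (taxon, target) pair, adjusts the *full
family of pairs jointly*, and keeps `q < 0.05` edges with signed rho.
Taxa–taxa pairs are excluded: the network is bipartite by design.
Within-diet sleep correlations are computed per metric without cross-metric
correction, mirroring per-panel reporting; users wanting a joint family can
pool the inputs into one call.

`art_anova()` is the aligned rank transform: for each effect the response
is aligned by removing the unweighted cell-mean estimates of every other
effect, aligned values are mid-ranked, and a full factorial ANOVA on the
ranks supplies only that effect's F and p. On the aligned *unranked* data
the stripped effects' F statistics vanish to machine precision — the
standard correctness check, which the tests assert. Unbalanced cells are
aligned with unweighted cell means and flagged with a message. ART is not
invariant to monotone transforms of the response (alignment happens on the
raw scale); that is a property of the method, not a defect of the
implementation.

`normalize_bile_acids()` divides each sample by its internal-standard value
and then by its total ion count, so rows sum to 1 and any per-sample scale
cancels. `group_fold_change()` reports either the relative difference
`(mean_t - mean_c)/mean_c` (default) or the plain ratio, with a rank-sum p
and BH q per variable — both definitions are offered because published
fold-change columns are frequently ambiguous between them; neither is
asserted to be canonical.

## The synthetic-data generator

The generator produces study-shaped data so that every pipeline stage has a
self-contained test surface; it emulates structure, not biological realism.

**Design.** `study_design()` is the full 2x2x2 factorial — diet x sleep
disruption x social defeat — with 10 subjects per cell by default (80
subjects), four fecal timepoints T1–T4, 10-s epochs, and a 5-day disruption
protocol active 20 h/day (ZT6–ZT2).

**Hypnograms.** A first-order Markov chain over W/N/R at epoch scale with
one transition matrix per ZT hour (light vs dark by default). The default
matrices give roughly 64% sleep in the light phase and 25% in the dark, with
minute-scale NREM bouts, REM entered only from NREM and no direct
wake-to-REM transitions — rodent-typical structure. The chain is the
simplest model producing bouts, arousals and circadian structure;
semi-Markov dwell times are out of scope. Disruption is modeled as forced
wake during active windows with a per-epoch *escape probability* rising
across days 1–5 (defaults 0.010 to 0.060), reproducing the protocol's
declining efficacy; the rotating-bar mechanics are protocol metadata only.
Because sleep escapes are short and REM requires passage through NREM, REM
is suppressed more strongly than NREM early in the protocol — an emergent,
tested property. Recovery sleep multiplies wake-to-NREM entry by a rebound
gain (diet-specific defaults 1.8 control, 2.4 prebiotic).

**EEG.** Each epoch's signal is Gaussian noise spectrally shaped to the
state's relative-power targets, with a 0.5-Hz guard margin inside each band
edge so Welch-window leakage stays in-band; measured relative powers land
within about 0.02 of target on average.

**Microbiome.** Relative abundances are log-normal per feature (baseline
mean SD 1.5, per-sample noise SD 0.6) with multinomial counts at log-normal
depth (median ~12,000 reads; 5% of samples shrunk below 9,000 to exercise
rarefaction dropping). One feature blooms under the prebiotic diet with
fold factors 6.5, 7 and 5 at T2–T4 applied before renormalization. Each
subject also carries a persistent log-scale bloom deviation (SD 0.6);
`gen_study()` maps this deviation into the subject's recovery rebound gain
(1 gain unit per log unit, prebiotic group), which is what plants the
positive bloom-to-recovery-sleep correlation the end-to-end tests recover.
These two coupling constants were calibrated once so the planted structure
is recoverable at the design's group sizes, and are pinned in the tests.

**Metabolites.** Twenty acids by default; each log-intensity is a baseline
plus linked taxa's clr values times signed strengths plus noise, scaled by
a near-constant internal standard that `normalize_bile_acids()` removes.

**What passing these tests does not show.** The generator has no
overdispersion beyond the log-normal layer (a Dirichlet option exists), no
correlated taxa blocks, no EEG artifacts or non-stationarity, no
dropout/batch structure, and its sleep chain has geometric dwell times.
Recovery of planted effects here demonstrates the pipeline's correctness,
not expected power on real recordings.

## Problem sizes and numerical choices

The test suite and the reproduction script use: exhaustive bout
verification over all 59,049 length-10 stage sequences plus 10,000 random
length-1,000 hypnograms; 100 epochs per state for EEG recovery (tolerance
0.05); hand-computed 4- and 5-leaf trees at 1e-12 tolerance and 200 random
tables for UniFrac axioms; 200 replicates of a 24-sample null at 999
permutations for PERMANOVA calibration; 20 planted and 10 null microbiome
simulations at 20 samples/group for ANCOM; 2,000 Gaussian 2x2 replicates at
10/cell for ART type-I error; 100 seeds of the 4x20-variable network null
at n = 80; and the full 80-subject synthetic study for the end-to-end
check. Ties are handled by mid-ranks throughout; permutation p-values
always include the observed statistic in the numerator and denominator, so
the minimal attainable p is `1/(n_permutations + 1)`.

## Known limitations

* ANCOM variant and zero-handling differ across published implementations;
  results at other settings are reachable through the arguments but there
  is no canonical reference output.
* PERMANOVA permutes freely; repeated-measures designs need external
  strata handling.
* Mixed-effects inference (e.g. for longitudinal sleep panels) is out of
  scope — the package emits tidy per-subject tables for fitting elsewhere.
* The weighted-UniFrac default is unnormalized; compare only like with
  like across studies.
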