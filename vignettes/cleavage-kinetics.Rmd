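---
title: "Cleavage-kinetics analysis of cloned and fertilized mouse embryos: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavage-kinetics analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryokin)
library(dplyr)
```

`embryokin` analyses division-timing (morphokinetic) data of mouse
pre-implantation embryos, contrasting cloned embryos produced by somatic
cell nuclear transfer (NT) with fertilized controls produced by
intracytoplasmic sperm injection (ICSI). This vignette is the package's
methods account: the data model, the definitions behind every derived
quantity, the statistical and numerical choices, what the synthetic-data
generator does and does not emulate, and the known limitations.

## Data model

The unit of raw data is a *division record*: one annotated blastomere
with its lineage label (root `"1"`, daughters appending `.1`/`.2`),
birth and end times in decimal hours post activation (hpa; activation —
oocyte activation after nuclear transfer, or sperm injection — defines
t = 0), a fate (`divided`, `arrested`, `fused`, `censored`), and any
M-phase aberrancies observed at its division (`multipolar_spindle`,
`unipolar_spindle`, `nondisjunction`, `cell_fusion`,
`cytokinesis_failure`). Annotation conventions the package fixes:

- **One timestamp per division.** The division time is the moment the two
  daughters first exist; it is simultaneously the mother's `end_hpa` and
  both daughters' `birth_hpa`. Validation enforces the equality.
- **Aberrancy belongs to the mother.** An M-phase error is recorded on
  the cell that was dividing, not on its daughters.
- **Censoring.** Cells still alive at the observation horizon (default
  96 hpa, the end of recording) are `censored`; their cycle lengths are
  treated as missing, never truncated at the horizon.
- **Terminal divided cells.** A divided cell may have either two recorded
  daughters or none — annotation legitimately stops after the last timed
  division (e.g. tracking through the fourth round records the 16-cell
  divisions without following the 16 daughters). Exactly one recorded
  daughter is a structural error.
- **Lineage labels carry no biology.** `.1`/`.2` reflect annotation
  order; they matter only as a deterministic ordering for sister-pair
  statistics.

`parse_division_table()` / `as_division_table()` validate all of this and
return a tidy one-row-per-cell tibble; `build_lineage()` assembles a
single embryo's binary tree.

## Timing features

`compute_features()` reduces each lineage to the standard variable set.
Division times `div1, div2.1, div2.2, div3.1, div3.4, div4.1, div4.8`
are the times the embryo reaches 2, 3, 4, 5, 8, 9 and 16 cells. They are
computed as global order statistics of all observed division-completion
times: the k-th division anywhere in the embryo is the moment the embryo
has k + 1 cells. This definition is what the cell-count names mean, and
it makes the monotonicity `div2.1 ≤ div2.2 ≤ div3.1 ≤ …` structural
rather than empirical. (A per-round reading would differ only if
cleavage rounds overlapped in time, which the data model permits but
normal embryos rarely show.)

- `cck` is the per-embryo mean cycle length of the round-k cells, defined
  only when all 2^(k−1) cells of the round divided. Partial averages
  would bias slow embryos — an embryo whose slowest blastomere arrested
  would look faster than it was; a `partial_cc = TRUE` variant exists for
  exploratory use.
- `diffk` are the inter-stage durations — time spent at 3 cells
  (`div2.2 − div2.1`), 5–7 cells (`div3.4 − div3.1`) and 9–15 cells
  (`div4.8 − div4.1`) — the package's synchrony measures.
- `stagek_len` are entire cleavage-stage lengths measured last-exit to
  last-exit (`stage3_len = div3.4 − div2.2`). The alternative
  (first-entry to first-entry) differs by the adjacent inter-stages; the
  last-exit convention was adopted because it decomposes as
  `stagek_len = diffk +` (preceding synchronous span) and so never falls
  below `diffk`.
- `ck1` is the duration of the first cytokinesis,
  `div1 − cytokinesis_onset`. Whether the original annotation's onset is
  anaphase or furrow onset is unknowable from event tables; the package
  just subtracts whatever onset the table carries.

Any feature whose defining events were not observed is `NA`, never
imputed. Extraction is invariant to input row order (tested).

Speed classification at the three-cell transition uses `div2.1` against
the 35–41 hpa window: three-group mode labels `< 35` fast, `> 41` slow,
the closed interval between intermediate. For two-group analyses the
single cutoff defaults to the midpoint, 38 hpa — the source window is
stated as a range without a single threshold, so the symmetric midpoint
was chosen and left overridable (`cutoffs`, `mode`).

## Statistics

All tests return one-row tibbles (`estimate`, `statistic`, `p_value`,
`n`, `method`) so they stack into tidy tables via `stats_table()`.

- **Wilcoxon rank sum** (`wilcoxon_rank_sum()`): two-sided. The exact
  null distribution of the Mann–Whitney U statistic is computed by
  subset-sum dynamic programming over ranks; `auto` mode uses it when
  the combined n ≤ 20 and there are no ties, otherwise a normal
  approximation with tie and continuity corrections. The exact path is
  property-tested against full `combn()` enumeration, and both paths
  against `stats::wilcox.test()`. Degenerate inputs (all values
  identical) return p = 1 with a warning.
- **Fisher's exact test** (`fisher_exact_2x2()`): two-sided p by summing
  hypergeometric probabilities not exceeding the observed table's
  (relative tolerance 1e-7, matching common practice); estimate is the
  sample odds ratio with 0/∞ permitted. Zero-margin tables are
  degenerate: p = 1 with a warning.
- **Correlations** (`pearson_r2()`): squared Pearson r with a t-test on
  n − 2 degrees of freedom; the signed r is reported alongside because
  r² is sign-blind. Zero-variance input is flagged with a warning and
  `NA` rather than propagating `NaN`.
- **Group summaries**: median and the *unscaled* median absolute
  deviation (`median(|x − median(x)|)`). The robust spread is reported
  as-is, without the 1.4826 normal-consistency factor, because it is an
  error-bar descriptor here, not a sigma estimate.
- **Mother–daughter correlation**: each divided round-k cell is paired
  with each of its divided daughters, so a mother contributes two pairs.
  The per-mother daughter-mean variant is available
  (`method = "daughter_mean"`); the two differ only in weighting.
- **Sister statistics**: cycle-length correlation over sister pairs
  ordered by lineage label, and division concordance ("did the cell
  divide within the horizon" × "did its sister") as a Fisher test
  counted once per unordered pair.
- **Aberrancy logistic** (`aberrancy_logistic()`): maximum-likelihood
  logit P(aberrant) = b0 + b1·length via iteratively reweighted least
  squares (Newton steps, convergence at max |step| < 1e-10), Wald
  two-sided p. Complete separation on the single predictor is detected
  directly (a threshold separating the classes) and returned as a
  `separation` flag with a signed infinite estimate — never a silently
  huge finite coefficient. The fit is tested against both a
  likelihood-grid oracle and `glm()`.
- **Multiple testing**: none is applied; tests are reported per
  comparison, with `p < 0.01` significance markers in the report. Users
  wanting family-wise control can apply `p.adjust()` to the tidy table.

## The window predictor

The blastocyst predictor is an axis-aligned window rule on 1–3 timing
features: predict blastocyst iff every feature lies in its closed
interval. The direction (inside → blastocyst) follows the convention of
highlighting the region containing embryos that developed.

`best_window()` searches exhaustively. Candidate interval endpoints are
the midpoints between consecutive sorted unique values, flanked by ±∞ —
moving an endpoint between midpoints cannot change any embryo's
membership, so the grid is lossless. For one feature the search
exploits the fact that a window covers a contiguous run of sorted
values, scoring all O(m²) windows from cumulative counts; for 2–3
features it scores the Cartesian product of per-axis windows
(O(∏ mᵢ² · n)), with no pruning that could change the argmax. Ties are
broken deterministically: higher accuracy, then smaller window volume
(interval widths clipped to the data range, so infinite endpoints do not
dominate), then lexicographically smallest lower-bound vector.

The F-score is the precision/sensitivity harmonic mean
F = 2·pr·sn/(pr + sn), 0 when both are 0, with accuracy always reported
next to it. Evaluation is in-sample, matching how such prediction windows
are usually presented; this overstates generalization, which is why the
simulator's null preset (outcome independent of timing) is used in tests
to confirm that the achievable F stays near the predict-all baseline
2p/(1 + p) at prevalence p. Embryos missing a panel feature are excluded
per combination and counted (`n_excluded`), never imputed.

## Amino-acid turnover

Spent-media analysis covers the 18 amino acids measurable by OPA
derivatization (proline and cysteine are not detected). For each embryo
drop and its matched embryo-free control (which absorbs non-specific
degradation/appearance),

rate = (C_control − C_sample) [µmol/L] × V_drop [µL] / (n_embryos × t [h]),

in pmol·embryo⁻¹·h⁻¹; positive is depletion (consumption), negative is
appearance (release). *Turnover* of a profile is the sum of absolute
rates. Concentrations are assumed already corrected for any pre-assay
dilution; a `dilution` argument applies the correction (e.g. 12.5×) when
inputs are raw readings. Replicates are summarised per (group,
stage-window) cell as mean ± SEM with n.

Clustering follows the two-metric design: amino acids by 1 − Spearman ρ
across columns with complete linkage; group/stage columns by Euclidean
distance with Ward's minimum-variance method. Ward is implemented as the
squared-distance Lance–Williams criterion (`ward.D2`); the variant is
switchable (`ward = "ward.D"`) since the method name alone does not pin
it down. A constant amino-acid profile has an undefined rank
correlation; its distances are set to the maximum (2) with a warning.
Heatmap colours (consumption vs release) are presentation only — every
assertion in the package is on numbers.

## The synthetic-data generator

No raw time-lapse annotations or HPLC tables are publicly deposited, so
the package ships a stochastic generator whose defaults *are* the study
conditions, making every pipeline stage testable end to end.

**Cohorts** (`simulate_cohort()`): per embryo, cell k's cycle length is
log-normal,

log L = log(M_k) + e + h_k·v_mother + s_pair + c_cell,

where M_k is the group's round-k median, e ~ N(0, σ_e²) is an embryo
effect, v_mother the mother's own deviation scaled by a per-round
heritability h_k, s_pair a sister-shared mother effect, and c_cell an
individual term. The structure yields mother–daughter and sister
correlations (via e, h, s) and inter-stage asynchrony (via c). Third-round
cells draw an M-phase aberrancy from a logistic model in their own cycle
length; under the `nt_strict` arrest rule any such error precludes
blastocyst formation (as observed for cloned embryos), while `tolerant`
leaves the outcome model untouched (fertilized embryos reach blastocyst
despite such errors). Blastocyst formation is a logistic model in one
standardized timing feature (`cc1` for the fertilized preset — the first
cycle is the informative predictor there; the three-cell division time
`div2.1` for the cloned preset, the axis of the fast/slow contrast).
Cells running past the 96-hpa horizon are censored. Every embryo draws
from a deterministic substream of the seed, so cohorts are byte-identical
across runs and stable under subsetting.

**Calibration.** The published group contrasts fix only differences and
inter-stage medians, so the fertilized baseline medians are declared
assumptions: cc1 = 18, cc2 = 18, cc3 = 12.5, cc4 = 12 h — first division
near 18 hpa and an hour-scale 12–18 h cycle structure are standard for
mouse cleavage. The cloned preset adds the printed offsets (−0.4, +2.3,
+3.4, 0 h). The dispersion and outcome parameters were then tuned once,
against large held-out cohorts, in this order: (1) round-2/3 individual
cell noise to the inter-stage medians (1.0/1.7 h fertilized, 1.7/4.3 h
cloned); (2) embryo effect and heritabilities to the mother–daughter r²
ladder, with a negative round-3 heritability in the cloned preset
encoding the observed cc2–cc3 anticorrelation; (3) aberrancy intercepts
to ~2–3% per third-round cell (≈10% of embryos); (4) outcome
intercept/slope so the 38-hpa fast/slow split yields ≈48.9%/27.8%
blastocyst (cloned) and the overall rate ≈41.4% with first-cycle window
accuracy ≈66.7% (fertilized). The frozen values live in `sim_preset()`
and are not per-analysis knobs.

**What it does not emulate.** Spontaneous developmental arrest without a
visible M-phase error (failure is absorbed into the outcome model), cell
fusion, overlapping cleavage rounds, strain effects, imaging
phototoxicity, and measurement discretization — real recordings have a
20-minute frame interval, while simulated times are continuous (the
pipeline carries full precision either way and never assumes a grid).
Passing parameter-recovery tests therefore shows the pipeline's
correctness and the internal consistency of the published summary
statistics, not external validity on new recordings.

**Spent media** (`simulate_spent_media()`): the fertilized profile is an
invented 18 × 4 baseline with total turnover rising through development,
arginine increasingly depleted and alanine/glutamine/glycine released.
The cloned profile implements the metabolic lag — its 24–48 h column
equals the fertilized 0–24 h column exactly at zero noise — and the
arginine inversion (scaled below the fertilized value at 48–72 h, above
at 72–96 h). Drops use 20/15/10/5 embryos per stage, 17 h incubations in
5 µL, Gaussian concentration noise, and matched zero-mean controls.

## Numerical choices and degenerate inputs

- Times are carried at full double precision throughout; no rounding.
- Window-search tie tolerance is 1e-12 on scores (scores are ratios of
  small integers, so exact ties are exact in doubles).
- Exact Wilcoxon enumeration is limited to combined n ≤ 20 in `auto`
  mode (the DP itself is O(n·m·N²) and stays trivial there); forcing
  `exact` with ties falls back to the approximation with a warning.
- Degenerate inputs prefer flagged results over exceptions where a
  value is still well-defined (p = 1 for zero-margin tables and
  identical samples; separation flags for the logistic), and
  informative classed errors (`embryokin_*_error`) where it is not.

## Problem sizes

The test suite runs cohorts of 30–2000 embryos; the parameter-recovery
checks use 1000–2000 embryos per group, the sizes at which configured
medians and rates are recovered within the tolerances stated in the
tests (±0.2–0.3 h on medians, ±4–5 percentage points on rates). The
acceptance script uses the same sizes. A 2000-embryo cohort simulates
and validates in a few seconds on one core.

## Known limitations

- In-sample window scores are optimistic; the optional honest route is
  to split cohorts manually (no built-in cross-validation is enabled by
  default, matching how the windows are conventionally reported).
- The in-sample accuracy of the F-optimal first-cycle window at n = 500
  is an intrinsically noisy statistic (several percentage points of
  seed-to-seed spread): the F landscape near its optimum is flat, so the
  chosen window — and hence its accuracy — varies between cohorts.
- Censoring-aware survival models are out of scope: censored cycles are
  missing data, consistent with the feature definitions.
- The amino-acid baseline profile is synthetic; only its qualitative
  structure (rising turnover, lag, arginine inversion) is meaningful.
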