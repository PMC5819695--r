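---
title: "mirtriad: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirtriad: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

`mirtriad` implements a screening analysis for miRNA qPCR panels run on
pooled patient groups. The quantity of interest per well is the cycle
threshold CT: the PCR cycle at which fluorescence crosses detection. Under
ideal amplification efficiency one cycle corresponds to one doubling of
template, so linear abundance is proportional to $2^{-CT}$ and relative
expression follows the classic chain

$$\mathrm{dCT} = CT_\text{target} - CT_\text{housekeeper}, \qquad
\mathrm{ddCT} = \mathrm{dCT}_\text{sample} - \mathrm{dCT}_\text{reference}, \qquad
\mathrm{FC} = 2^{-\mathrm{ddCT}}.$$

The study design this package serves profiles the primary tumor of three
colorectal-cancer groups — liver metastasis (LM, n = 10), peritoneal
carcinomatosis (PER, n = 10), no metastasis (M0, n = 3) — on a 754-target
panel with three housekeeping small RNAs (RNU44, RNU48, U6) and a plant
miRNA negative control. Three patients per group are physically pooled onto
the array, so the screening stage has *one* sample per group and no
replication: screening calls are fold-change thresholds, not tests.
Inference happens afterwards, per patient, on selected assays.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `detection_ct_threshold` | 30, strict `<` | cycles | manufacturer guidance for "sufficiently expressed"; a tie at exactly 30 fails, by the literal reading of "lower than 30" |
| `detection_rule` | `ALL_SAMPLES` | — | the source protocol does not say in which samples CT < 30 must hold; requiring all scoped pools is conservative and guarantees every reported fold change is computable. `ANY_SAMPLE` is the escape hatch |
| `housekeeper_aggregation` | `MEAN_CT` | — | the normalization formula is written with a single "housekeeping gene" while three are present; the arithmetic mean CT (geometric mean abundance) is the standard multi-reference compromise, and `SINGLE:<id>` preserves the literal single-gene formula |
| `up_threshold` / `down_threshold` | 2.00 / 0.500, strict | fold change | the published screening cutoffs; reciprocal by design, so swapping a contrast's orientation maps UP and DOWN onto each other exactly |
| `alpha` | 0.05 | — | the declared significance level |
| `noise_sd` | 0.25 | cycles | a realistic per-well CT standard deviation for FFPE-derived TLDA data |
| `detection_ceiling` | 35 | cycles | typical instrument reporting limit; `Inf` disables it, the 40-cycle run length always applies |

## The synthetic world

`simulate_cohort()` draws, per target miRNA, a baseline CT shared by all
patients, uniform over 18–38 cycles — wide enough that the CT < 30 filter is
genuinely exercised (roughly half the panel fails it, comparable in spirit
to the ~36% detection rate of the motivating study). A planted effect
(assay, group, log2fc) lowers that group's CT by `log2fc` cycles relative to
the M0 baseline — one cycle per doubling. Housekeepers sit at fixed baselines
(19–21 cycles) with no group effect; the negative control never amplifies.
Gaussian noise of `noise_sd` cycles is added per well, and any CT beyond the
detection ceiling becomes non-detected.

Two deliberate conventions:

* **Planted effects live in the well-expressed regime.** Assays carrying a
  planted effect have their baseline redrawn from 18–26 cycles
  (`planted_baseline_range`). Without this, a uniform 18–38 baseline would
  place about half of all planted effects beyond the detection filter where
  no screening method could see them, and "recovery of planted truth" would
  measure the baseline lottery instead of the pipeline. Biologically this
  matches the screening situation: every published hit was, by construction,
  detectable. Effects are planted so that baseline + |log2fc| stays clear of
  the CT-30 filter in every group.
* **Pooling mixes molecules, not cycle numbers.** `pool_patients()` averages
  linear abundances, $CT_\text{pool} = -\log_2\left(\tfrac{1}{k}\sum_i
  2^{-CT_i}\right)$, rather than averaging CTs. A non-detected well
  contributes zero abundance; a well non-detected in every pooled patient
  (or a pooled CT beyond the 40-cycle run) stays non-detected. No ceiling
  imputation is offered — none is described for the source protocol, and the
  zero-abundance convention is the simplest defensible one.

Classifier status (the stem-cell immunophenotype) is an independent
Bernoulli per patient given the group, with default rates 1.0 / 0.2 / 0.0
for LM / PER / M0 — the marginal counts reported for the cohort (10/10,
2/10, 0/3). Only marginals are reported, so no within-group correlation
structure is modeled.

**What a green test establishes — and what it does not.** The generator
reproduces the *statistical skeleton* the analysis assumes: group structure,
detection censoring, planted multiplicative effects, homoscedastic Gaussian
CT noise. It does not emulate amplification efficiency ≠ 2, inter-card batch
effects, FFPE degradation profiles, or correlated miRNA co-regulation. Tests
against it therefore certify the *pipeline arithmetic and decision logic*,
not the biological validity of any particular published hit; the published
cascade counts (275 detected, 41/27/36 differential, 25 triple) are
properties of undeposited raw data and are reproduced structurally (as
report fields and planted-truth recovery), never asserted numerically.

## Statistical procedures

**Fisher's exact test** is two-sided by the probability-≤-observed rule: sum
the hypergeometric probabilities of every margin-preserving table no more
probable than the observed one (relative tie tolerance $1+10^{-7}$, the
convention shared by standard implementations). This rule reproduces the
published cohort p-values from their own printed counts — 0.003 for pT4
(7/10 vs 0/10), 0.001 for the classifier LM vs PER (10/10 vs 2/10), 0.003
for LM vs M0 (10/10 vs 0/3). Tables with an empty margin return p = 1 with a
note. The implementation is verified against exhaustive enumeration for
every 2×2 table with total ≤ 30.

**Student's t-test** is the pooled-variance form (df = nA + nB − 2), since
that is the test the source names; Welch is available via `welch = TRUE`.
Zero pooled variance yields p = 1 (equal means) or a flagged degenerate
p = 0 (unequal means).

**Whole-cohort validation** reports the fold change as the ratio of group
mean linear expressions ($2^{-\mathrm{dCT}}$), matching mean-±-SEM bar-plot
conventions, and runs the t-test on the linear scale by default with the dCT
scale one flag away (`scale = "dct"`). The underlying source states the test
but not its scale; with CT noise around 0.3 cycles the induced lognormal
skew is mild and both scales hold their nominal type-I level to within the
calibration band checked in the acceptance suite (~5% ± 2 pp at n = 10 vs
10). The reported "inverse correlation" of an assay with a binary phenotype
is implemented as the declared t-test of expression by phenotype status
(point-biserial equivalent); no correlation method was named, and this
choice is documented rather than guessed at.

## Numerical and degenerate-input choices

* Detection, UP and DOWN thresholds are all *strict* inequalities; boundary
  equality fails detection / is NS.
* Triple-differential membership is direction-agnostic: the published triple
  set itself contains assays induced in one contrast and repressed in
  another, so requiring sign agreement would contradict the definition.
* Missing dCT values (non-detected targets) propagate as omissions with a
  logged note, never as imputations.
* Candidate ranking orders by $|\log_2 \mathrm{FC}|$ descending with
  lexicographic assay-id tie-break, so a 4-fold induction and a 0.25-fold
  repression tie.
* Writers serialize CT and dCT values at full precision (17 significant
  digits) so read∘write is the identity; fold changes in result tables are
  display values at 3 significant digits, while calls round-trip exactly.
* Non-detected wells are serialized as `Undetermined`, the instrument
  convention of the inputs.
* Simulated CTs below one cycle (unreachable under default parameters) are
  clamped to 1 to keep the (0, 40] validity range.
* Seeds are mandatory for simulation and pooling — there is no wall-clock
  fallback — and identical config + seed yields byte-identical outputs.
* Run configs are JSON (via `jsonlite`); which three patients enter a pool
  is seed-driven, since the source does not say which were pooled.

## Known limitations

* No efficiency-corrected (Pfaffl-type) or absolute quantification.
* No multiple-testing correction at any stage — none is described for the
  source analysis, and the pooled screen has no p-values to correct.
* The pooled screen cannot separate biological from technical variation;
  that is inherent to pooling, not to the implementation.
* Calibration checks run the cohort t-test at a reduced panel size (4
  targets instead of 754 per simulated seed) to stay within test-time
  budgets; per-assay independence makes panel size irrelevant to per-assay
  error rates.
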