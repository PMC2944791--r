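---
title: "Models and methods behind germsoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind germsoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germsoma)
```

# The scientific question

Patients who develop many independent tumors — the motivating system is
organ-transplant recipients with multiple cutaneous squamous cell
carcinomas (SCC) — offer a natural experiment: if the germline genotype
shapes which somatic alterations a tumor acquires, then the copy-number
profiles of one patient's independent tumors should resemble each other
more than tumors from different patients, and recurrent allelic losses
within a patient should keep hitting the *same* parental allele.
`germsoma` implements both arms of that argument as a reusable, tested
pipeline:

1. **Concordance of copy-number profiles.** Array-CGH log2-ratio profiles
   are segmented, quality-controlled, and compared pairwise within and
   between patients, per chromosome arm and genome-wide; per-clone
   intraclass correlation quantifies how much copy-number variance patient
   identity explains.
2. **Preferential allelic imbalance.** Tumor/normal peak data at
   microsatellite and SNP loci are converted to allelic-imbalance ratios,
   classified, and tested per locus for skew toward one allele across a
   patient's tumors and across patients.

Because raw patient data of this kind are not publicly deposited, the
package ships a synthetic-cohort generator with known ground truth; every
downstream stage is exercised against it.

# The synthetic cohort generator

`sim_config()` collects all generative parameters; the three
`simulate_*_cohort()` functions emit analysis-ready tables plus separate
ground-truth tables that no analysis stage ever reads.

**Copy-number model.** Observed tumors of this type alter DNA mostly by
gaining or losing whole chromosome arms, so the generator simulates
whole-arm events only; focal events are a deliberate non-goal. Events
live on the liability scale: each patient draws one propensity shift per
arm, $\delta_{ia} \sim N(0, \sigma_{\text{patient}})$, and each tumor
independently gains the arm with probability
$\operatorname{logit}^{-1}(\operatorname{logit}(g_a) + \delta_{ia})$ and
loses it with probability
$\operatorname{logit}^{-1}(\operatorname{logit}(l_a) - \delta_{ia})$. An
aberrant arm shifts all its clones by $\pm s$ (default $s = 0.5$
log2-ratio units, roughly a single-copy change against a diploid
reference); clone-level Gaussian noise is added on top. Setting
$\sigma_{\text{patient}} = 0$ makes events independent across a patient's
tumors — the null regime for every concordance test — while large values
make the patient's tumors share the same gains and losses. Note that a
*pure-noise* cohort (zero event rates) is **not** a usable null for the
concordance tests: flat profiles are excluded by the informativeness
filter by design, so the calibration null keeps per-tumor events but
removes their patient-level sharing.

**Allelotype model.** Each patient is heterozygous at a marker with
probability `het_prob`; heterozygotes carry two alleles of distinct
fragment sizes, the larger labelled A. Peak heights have multiplicative
log-normal noise with coefficient of variation `peak_cv` — peak-height
assays are scale-noise dominated. An imbalance event multiplies the
retained allele's tumor peak by a dosage factor drawn log-uniformly in
$[1.8, 3.0]$; the published classification thresholds define what counts
as imbalance, not the effect size, so the factor is chosen to guarantee
the ratio clears those thresholds with margin at realistic noise. Allele
A is retained with probability `pref_loss_prob`; 0.5 is the null of
random loss. SNP cohorts follow the same model with two fixed bases per
locus, ordered lexicographically.

**Defaults as study conditions.** The defaults describe a desk-scale
cohort in the image of the motivating study: 25 patients with 3–6 tumors
each; 440 clones (10 per autosomal arm — a scaled-down BAC array; the
clone count is configurable and nothing is hard-coded to a physical
resolution); per-arm gain/loss rates 0.08/0.15, within the observed
per-arm frequency range for these tumors; clone noise sd 0.1 with 10% of
samples at 3× noise so that the MAD > 0.2 quality cut has real work to
do; `patient_effect_sd = 1.5` on the logit scale, which multiplies an
arm's event odds by $e^{\pm 1.5} \approx 4.5$ for a typical patient and
produces clearly visible intra-patient sharing; heterozygosity 0.7,
per-tumor imbalance probability 0.5, peak CV 0.1. No published effect
sizes exist for the arm-level shifts, so these are plausible choices, not
calibrations, and they are fixed once here.

**Seeding.** One master seed; per-patient streams derive their seeds by
deterministic label hashing, so enlarging a cohort never perturbs the
tumors already simulated, and identical configurations are byte-identical.

# aCGH processing

**Normalization.** `normalize_profiles()` regresses each sample's log2
ratios on supplied per-clone covariates (GC content, array geometry) with
a robust Huber fit (`MASS::rlm`) and keeps the residuals, median-centered;
with no covariates it median-centers only. GC computation from sequence
is out of scope — covariates are caller-supplied.

**Segmentation.** `segment_profiles()` implements circular binary
segmentation. Within a chromosome the candidate split is the pair of
complementary circular arcs maximizing the pooled two-sample
t-statistic, found by exhaustive $O(n^2)$ scan (a compiled kernel); its
significance is a within-segment permutation p-value, and accepted
splits (p < `alpha`, default 0.01, `n_perm` default 1000, `min_width` 2)
are refined recursively. Two numerical choices deserve note: a split
with zero pooled variance but unequal means is treated as infinitely
strong rather than skipped, so step-exact data segment correctly; and
the permutation loop stops early as soon as the exceedance count proves
the p-value cannot fall below `alpha`, which leaves accepted splits
untouched while making null chromosomes cheap. Permutations draw from
R's RNG, so `set.seed()` gives reproducible segmentations. A practical
floor: a permutation test on an $m$-clone chromosome cannot produce a
p-value below the probability that a random relabelling is perfectly
separated ($\approx m \, k!(m-k)!/m!$), so maps need roughly 7+ clones
per arm before arm-level events are detectable at `alpha` 0.01 — the
default map provides 10.

**Quality control.** The sample noise estimate is the scaled MAD,
`median(|observed − segmented|) × 1.4826`; `qc_filter()` excludes samples
with MAD strictly above 0.2 (a sample at exactly 0.2 is kept — the rule
is "greater than").

**Gain/loss calling.** `call_gains_losses()` merges segment levels
genome-wide per sample: repeatedly take the closest pair of level means
whose clone-value distributions a rank-sum test cannot distinguish at
`merge_p` (default 1e-4) and merge them, re-estimating the mean, until
all remaining levels differ. The cited merged-level procedure is more
elaborate; this simplification keeps its semantics (levels are merged
unless the data insist they differ) with one parameter. The level
nearest 0 is neutral — the reference channel defines diploid — with ties
broken toward the level with more clones; levels above/below are
gain/loss, and clones inherit their level's call. Missing values are
excluded from every statistic, never imputed.

# Concordance analysis

**Response values.** Both the correlation tests and the ICC model use
the same per-clone response: the segment mean, except where the clone
sits more than `outlier_k` (default 3; the source analysis does not
define "outlier") sample-MADs from its segment mean, in which case the
raw log2 ratio is kept.

**Pair filters.** Pearson correlations are computed per sample pair over
the scoped clones (one arm, or all autosomes). Intra-patient pairs come
only from patients with at least three tumors. A pair enters only if at
least one member is *informative* over the scope: at least 20% of its
clones beyond 2 sample-MADs in absolute value and at least 20% at or
below — both conditions on the same sample, which excludes flat and
saturated profiles alike. The informativeness scope follows the analysis
scope (arm for arm tests, genome for the genome-wide test). A scope is
*eligible* with ≥ 40 non-missing clones and ≥ 20 pairs in each group.

**Tests.** Group variances are compared with the Brown–Forsythe
(median-centered Levene) test; the pooled two-sided t-test is reported
only when variances are not significantly unequal at 0.05, and the Welch
t-test is always reported. Correlations are tested on the raw r scale
(no Fisher z) — at these sample sizes their distributions are near
normal, and this mirrors the procedure the package reimplements. Per-arm
p-values are Holm-adjusted across eligible arms (pooled and Welch
families separately). Pairs sharing a sample are treated as independent;
this deliberate simplification replicates the original procedure, and
the package's own calibration simulations (500 exchangeable-tumor
cohorts; Kolmogorov–Smirnov on the genome-wide p-values) measure rather
than assume its adequacy. No fixed list of excluded arms exists;
exclusion always emerges from the eligibility rule on the data at hand.

**ICC.** Per clone, the one-way random-effects model
$Y_{ij} = \mu + \alpha_i + \varepsilon_{ij}$ is fitted by ANOVA method
of moments with the unbalanced-design correction
$n_0 = (N - \sum_i n_i^2/N)/(a-1)$;
$\hat\sigma_\alpha^2 = \max\{0, (\text{MSB} - \text{MSW})/n_0\}$ and
$\text{ICC} = \hat\sigma_\alpha^2/(\hat\sigma_\alpha^2 + \hat\sigma_\varepsilon^2)$,
always in $[0, 1]$. The estimator is unnamed in the source; method of
moments is the standard default and is validated by parameter-recovery
simulation (true ICC 0.5 recovered within ±0.05 on average).

# Allelic imbalance and the preferential test

**Ratio and bands.** $R = (T_A/T_B)/(N_A/N_B)$ from the four peak
heights of a heterozygous marker. Imbalance when $R > 1.5$ or
$R < 0.66$; no imbalance when $0.85 \le R \le 1.25$; otherwise
uncertain. The published lower bound is 0.66 in one place and 0.67 in
another; 0.66 is the default and the band is configurable
(`ai_bands()`). The asymmetry with $1/1.5 = 0.6\overline{6}$ is
preserved as printed. The *favored* (relatively retained) allele is A
when $R > 1.5$, B when $R < 0.66$. Homozygous patients and tumors
missing either member of the matched normal/tumor pair are excluded;
uncertain calls contribute to neither count.

**Patient odds.** A patient with $n_j \ge 2$ imbalanced tumors, $k_j$
retaining allele A, gets the Bayes factor of random loss (point null
$p = 1/2$) against a preferential alternative with $p \sim$ Beta(1,1):
$$O_j = \frac{\binom{n_j}{k_j} 2^{-n_j}}
             {\int_0^1 \binom{n_j}{k_j} p^{k_j}(1-p)^{n_j-k_j}\,dp}
      = \binom{n_j}{k_j}\, 2^{-n_j}\, (n_j + 1).$$
The prior is configurable (Beta($a$,$b$)); the uniform default matches
the published semantics — small $O_j$ means the split is too lopsided
for random loss — and reproduces the published $\ln O_j < -1.5$ flag
threshold as a usable rule. $\ln O_j$ is symmetric in
$k_j \leftrightarrow n_j - k_j$, maximal at the balanced split, and is
verified in the tests against numerical integration of the binomial
marginal.

**Locus test.** The published procedure combines patient odds "into a
sample" for a frequentist Wilcoxon comparison without naming the
reference sample; here the comparison group is an explicitly simulated
null — for each observed patient's $n_j$, draw
$k \sim \text{Binomial}(n_j, 1/2)$ repeatedly (default 1000 replicates)
and record the log-odds. The rank-sum test is one-sided (observed
log-odds stochastically *smaller*: preferential imbalance can only
shrink them), using midranks with the normal approximation and tie
correction and no continuity correction — the null sample is massively
tied, and the continuity correction would make the test conservative.
Loci are reported at raw $p < 0.05$, replicating the original
(cross-locus Holm is available but off by default). Calibration and
power are measured by simulation in the test suite: type-I error at
nominal 0.05 stays within [0.025, 0.075], and power at
`pref_loss_prob = 0.9` with 10 informative patients of 4 imbalanced
tumors exceeds 0.8.

**SNP skew.** Across patients, heterozygous imbalanced tumors at a SNP
are counted by retained allele and tested against 50:50 with the
two-cell goodness-of-fit chi-square $X^2 = (a-b)^2/(a+b)$, df 1, no
continuity correction. The balanced worked example (3 vs 3) gives
$p = 1$ exactly. On the published skewed counts (28 vs 7) this statistic
gives $p \approx 4\times 10^{-4}$, not the printed 0.012 — the original
test variant or unit of analysis at that locus is unclear, and the
package implements the chi-square exactly as its methods describe.

# Problem sizes and what the tests show

The simulations in the test suite and acceptance script use desk-scale
cohorts chosen once: 10 patients × 3 tumors on a 352-clone map (8 per
arm) for the concordance power (100 replicates) and null-calibration
(500 replicates) studies, `n_perm = 200` for segmentation inside
replicate loops (p-value resolution 1/201, ample at `alpha` 0.01), and
500-replicate simulations for the preferential test's size and power.
The generator emulates whole-arm events, patient-level propensities, and
scale-noise on peaks; it does not emulate focal amplifications, stromal
contamination, marker-specific stutter, assay dropout beyond simple
missingness, or linkage between loci. Passing tests therefore show that
the statistical machinery is correct and calibrated under the stated
generative model — not that the model captures every feature of real
tumor data.

# Known limitations

- CBS here is a faithful but compact implementation (exhaustive arc
  scan, permutation acceptance, ternary recursion); it omits the
  reference implementation's hybrid tail approximation and undo
  heuristics.
- The merged-level procedure is a one-parameter simplification of the
  published method.
- Pair non-independence in the concordance t-tests is inherited from the
  original design; the package measures its calibration rather than
  correcting it. Measured effect at the default study conditions: null
  rejection rates at the 0.01 and 0.05 levels sit at or slightly below
  nominal, with a mild conservative shift in the middle of the p-value
  distribution (null medians around 0.52–0.55) that a 500-replicate
  Kolmogorov–Smirnov test can detect on some seeds.
- Table-2/Table-3-scale headline numbers from the motivating study
  derive from patient data that are not publicly available and are not
  reproducible here; the package reproduces the two printed quantities
  that are recomputable from printed inputs (the balanced SNP example
  exactly, the skewed one conservatively) and anchors everything else on
  property-based simulation.
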