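---
title: "Methods: pharmacogenomic scoring and cohort statistics in PGxCohort"
author: "PGxCohort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacogenomic scoring and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PGxCohort)
```

# The problem

Psychotropic prescribing fails on first attempt in roughly half of
patients, and pharmacogenomic testing — reading a patient's variants in
drug-metabolism (pharmacokinetic, PK) and drug-target (pharmacodynamic,
PD) genes — is one route to shortening the trial-and-error period.
PGxCohort implements, as reusable and tested code, a complete analysis
chain for studies of this kind: a 54-gene / 104-variant test panel;
translation of panel genotypes into CYP2D6 and CYP2C19 metabolizer
phenotypes; a composite 0–15 *genetic mutation score*; a questionnaire
based 1–10 *treatment-effectiveness score* (higher = worse); and the
cohort statistics linking them — a paired Wilcoxon signed-rank test with
effect size *r*, Spearman rank correlations, and a bootstrap-smoothed ROC
curve. Because patient-level data for such studies are generally not
shareable, the package includes a calibrated synthetic-cohort generator
so that every stage can be exercised end to end.

# The test panel

`loadDefaultPanel()` ships 107 (gene, site) entries over 54 gene symbols.
Three bookkeeping quirks of the published panel are preserved
deliberately:

* **rs2952768 appears under three genes** (an unlabeled row, OPRM1 and
  UGT2B15). It is stored once per gene context but deduplicated by rsID
  whenever variants are counted, so one physical variant is never scored
  twice. Net: 105 unique site keys, of which 104 are rs-numbered.
* **One row has no published gene symbol**; it is kept under the
  placeholder `UNASSIGNED_ROW8` (category `other_pd`) and surfaced by
  `validateCohort()` rather than silently invented or dropped.
* **The SLC6A4 promoter length polymorphism (5-HTTLPR)** has no rsID and
  cannot be carried in a VCF; it is modeled as the pseudo-site
  `SLC6A4_5HTTLPR` with alleles L/S, accepted by the tabular reader only.

Each entry carries a scoring category. The CYP450/UGT enzymes are
`pk_enzyme`; receptor genes (HTR1A/2A/2C, DRD1–3, ADRA2A, ADRB1/2,
CHRNB2, CNR1, MC4R, OPRD1, OPRM1, GRIA1, GRIK4) are `receptor`;
ABCB1, SLC6A4, SLC6A2 and SLCO1B1 are `transporter`; the remaining
neuropsychiatric PD genes (BDNF, COMT, TPH1/2, CACNA1C, FKBP5, ...) are
`other_pd`. Five genes with no plausible psychotropic PD role — F5,
VKORC1, APOE, MTHFR and HLA-B, which sit on the panel as haemostasis,
folate and drug-safety markers — are `non_scored`: they are neither
phenotyped nor counted. This split is a design decision of this package;
the source panel only fixes the enzyme, receptor and transporter
assignments.

Reference/alternate allele orientations and the per-site default allele
frequencies are a packaged, editable annotation: orientations follow
commonly documented dbSNP conventions for the star-allele defining sites
and plausible placeholders elsewhere (they only decide zygosity of
tabular input and drive the genotype-mode simulator; no downstream
statistic depends on which placeholder was chosen). Indel alleles use
array-style `D`/`I` codes.

# Phenotyping model

The translation table (`loadTranslationTable()`) restricts publicly
documented star-allele definitions to panel sites, one defining site per
allele: CYP2C19 \*2–\*8 (no function) and \*17 (increased function);
CYP2D6 \*2 (normal), \*3/\*4/\*6/\*7/\*8/\*11/\*12/\*15 (no function),
\*9/\*17/\*29/\*41/\*59 (0.5) and \*10 (0.25). The default \*1 allele
(activity 1.0) is implicit. The table is data, not code: studies using a
different interpreter can swap the file.

`callDiplotype()` turns per-site genotype classes into a diplotype: each
heterozygous defining site contributes one candidate allele copy, each
variant-homozygous site two. Genotypes are unphased, so when more than
two candidate copies exist the two retained alleles are chosen
*conservatively* — lowest activity first, then lowest star number —
which places two heterozygous no-function sites in trans. This maximizes
detected non-functionality, the cautious clinical reading; it is flagged
here as an assumption rather than an inference.

The activity score (sum of the two allele activities, scaled by
`copyNumber/2` for CYP2D6) maps to phenotype with the conventional
cutpoints: **poor** at 0, **intermediate** in (0, 1.25), **normal** in
[1.25, 2.25], **ultrarapid** above 2.25. Two gates refine this:

* CYP2C19 is ultrarapid when rs12248560 (\*17) is homozygous, regardless
  of the summed activity (a \*17/\*17 carrier sums to 2.0 under this
  table); heterozygous \*17 carriers stay normal.
* CYP2D6 can only be ultrarapid with a *declared* copy number above 2.
  SNP panels cannot see duplications, so without copy-number input
  CYP2D6 ultrarapid is unreachable and a note is logged. Copy number
  defaults to 2.

When no defining site has a usable call the phenotype is
**indeterminate**; everywhere downstream indeterminate behaves as normal
*with a warning*, so missing data can never raise a risk score or
manufacture a pharmacokinetic finding.

# The two scores

The **genetic mutation score** (0–15) is

$$ S_g \;=\; p(\mathrm{CYP2D6}) + p(\mathrm{CYP2C19}) +
   \min(\#\mathrm{PD\ variant\ sites},\,5), $$

where $p(\cdot)$ is 5 for an extreme phenotype (poor or ultra-rapid), 2
for intermediate, 0 for normal. A patient extreme in both genes scores
10 on the PK side; the PD tally adds one point per distinct variant site
in the receptor/transporter/other-PD categories, zygosity-insensitive,
capped at 5. Whether variants in PK enzymes *other than*
CYP2D6/CYP2C19 (e.g. CYP2C9) should enter the PD tally is ambiguous in
the source scoring description; this package counts only the three PD
categories and keeps the switch isolated in `countPdVariants()`.

The **treatment-effectiveness score** sums a mood-toward-work item
(1 = "I feel good", 2–3 = "I force myself to do work", 4–5 = "I am unable
to work"; the band interior is resolved by an explicit low/high severity
sub-level in the questionnaire) and a side-effect burden equal to the
number of distinct reported side effects capped at 5. Because mood is
answered on a 1–5 scale, totals live in [1, 10] even though the scale's
verbal anchor is "0 (Good)": the two statements conflict and the
attainable minimum of 1 was chosen. The count-based side-effect rule is
likewise the simplest reproducible reading of "a maximum score of 5" and
is isolated in `sideEffectPoints()` so it can be swapped.

# Statistical conventions

`wilcoxonPaired()` drops zero differences (logged), mid-ranks the
absolute differences, reports W = min(rank sums), and uses the
tie-corrected normal approximation *without* continuity correction. The
effect size defaults to $r = |Z|/\sqrt{2n}$ — standardized by the total
number of observations, two per pair. The alternative $|Z|/\sqrt{n}$
convention is one flag away (`rConvention = "pairs"`); under a
46-pair fully improving design the two give 0.62 and 0.87 respectively,
and the total-observations convention is the default because it matches
the effect size this design is expected to report. Effect sizes are
labeled with the usual 0.1/0.3/0.5 small/medium/large bands. An exact
mode enumerates all $2^n$ sign assignments for $n \le 16$ untied pairs.

`spearmanCorrelation()` is the Pearson correlation of mid-ranks with the
$t$ approximation on $n-2$ degrees of freedom. `rocBootstrapSmoothed()`
draws class-stratified bootstrap resamples, interpolates each resample's
empirical ROC on a fixed 101-point FPR grid, averages, applies a
monotone (cummax) cleanup and integrates by trapezoid; it converges to
the empirical AUC (= Mann–Whitney $U/(n_1 n_0)$) as resamples grow, and
is bit-reproducible given its seed (default 1000 resamples, seed
20180501). The ROC outcome label is "high effectiveness score",
dichotomized at a configurable threshold defaulting to 8 — an anchor
near the typical baseline mean, chosen by this package because no
published cutoff exists — and computed on the full analysed cohort by
default (`roc_cohort = "followup"` switches to the follow-up subset).
For the same reason the smoothed AUC is *not* a calibration anchor of
the generator: it depends on an unstated threshold and cohort choice.

Descriptive summaries use $n-1$ standard deviations and full-column
denominators for percentages (unreported categories make columns sum
below 100%). Report numbers are kept at full precision internally and
rounded only at render time.

# The synthetic-cohort generator

`generatorConfig()` defaults *are* the study conditions: 84 patients, 46
with follow-up, age 35.5 (SD 10.6), the published sex/ethnicity mix,
baseline effectiveness 8.39 (SD 1.22), follow-up 2.30 (SD 1.01), and a
genetic-score coupling targeting a Spearman correlation of about 0.281
at n = 84.

Per-gene phenotype probabilities (poor .07 / intermediate .35 / normal
.38 / ultra-rapid .20 for each of CYP2D6 and CYP2C19) and a
zero-inflated shifted-Poisson PD burden (no variants with probability
.22, otherwise $1+\mathrm{Pois}(4.8)$) were chosen once so that the
published prevalence figures emerge approximately: about two thirds of
patients with both PK and PD findings, about a fifth PK-only, and
phenotype prevalences near the published 14% poor / 37% ultra-rapid /
62% intermediate "of one or both genes". Exact matching is impossible —
the published profile counts sum to more than the cohort (93/84) and the
overlapping prevalence percentages exceed 100% — so the generator
parameterizes per-gene marginals and documents the approximation. The
implied genetic-score mean is ~7.6 (published 7.92) with a somewhat
wider spread; this is the price of honoring the profile-type mix.

Outcomes follow a latent-severity model: with $G_i$ the genetic score
computed by the *real* scoring code,

$$ T_i = \mu_b + \lambda\,(G_i - \bar G) + \varepsilon_i,
   \qquad \varepsilon_i \sim N(0,\ \sigma_b^2 - \lambda^2
   \widehat{\mathrm{Var}}(G)), $$

rounded and clipped into [1, 10], then split into mood
$= \lceil T/2 \rceil$ and side-effect $= \lfloor T/2 \rfloor$ components
— so every generated questionnaire record is a legal scoring input by
construction (side-effect points are realized as that many distinct
labels from a pool of common psychotropic side effects). The coupling
default $\lambda = 0.107$ was calibrated once by simulation (400 seeded
replicates) so the mean n = 84 Spearman correlation is 0.281⁠–⁠0.282.
Integer discretisation and clipping attenuate the configured moments
slightly — about −0.05 on the baseline mean, −0.07 on its SD — which is
documented rather than compensated, as it is far inside the stochastic
variability of an 84-patient cohort. Follow-up totals are drawn around
their own target mean, independently of $G$, and under the default
improvement guarantee are resampled until strictly below baseline (a
patient whose baseline total is 1 cannot strictly improve; the generator
warns, a case unreachable under the default calibration). A config with
follow-up mean at or above baseline mean is rejected outright. The
follow-up subset is uniform by default; `followup_male_bias` reproduces
the published sex-composition shift between the two study columns if
wanted.

Two generation modes exist. *Phenotype mode* (default) draws phenotypes
directly — fast and directly calibrated, appropriate because prevalences
(not genotype frequencies) are what such studies publish. *Genotype
mode* starts from independent Hardy–Weinberg draws at the panel's
default allele frequencies and routes through the real parsing,
diplotype-calling and counting stack with no shortcut, which is what the
end-to-end tests exercise. Everything derives sub-seeds deterministically
from one master seed (default 20180501); identical configs give
identical cohorts, and written cohorts (`writeCohort()`) re-ingest to
identical scores.

## What the generator does and does not emulate

It reproduces the marginal structure the analysis consumes: score
distributions, the genetic–baseline coupling, improvement at follow-up,
demographic mixes. It does **not** model medication identities or
prescription-change types, dropout mechanisms (selection into follow-up
is uniform unless biased explicitly), within-patient correlation of side
effects over time, or linkage disequilibrium between panel sites
(genotype mode samples sites independently, so real-world haplotype
structure such as \*4's two defining variants co-occurring is absent).
Passing tests therefore demonstrate that the pipeline's statistics
recover known generating parameters — not that any real cohort's numbers
were reproduced.

# Numerical choices and degenerate inputs

* Problem sizes in the test-suite: parameter recovery uses one
  5000-patient cohort; coupling recovery averages 200 replicate
  84-patient cohorts; Hardy–Weinberg recovery uses 2000 genotype-mode
  patients; the null-ROC check uses n = 2000 with 200 resamples. These
  sizes put Monte-Carlo error well below the asserted tolerances while
  keeping the default run under a minute.
* All-zero paired differences, zero-variance correlation input and
  single-class ROC labels raise errors at the statistic level; the
  pipeline catches the follow-up-free and single-class cases and marks
  those report sections not-computed instead of failing the run.
* Exact Wilcoxon enumeration is limited to $n \le 16$ (memory), and
  refuses tied magnitudes rather than approximating.
* Duplicate conflicting genotype rows are an error naming the conflict;
  unknown genotype strings and sites degrade to `no_call` with warnings;
  missingness flags patients without dropping them.
* Spec-level tie-breaks: with more than two candidate allele copies the
  retained pair minimizes activity then star number; `approx(ties =
  max)` resolves vertical ROC segments; mid-ranks resolve rank ties.

# Known limitations

The allele annotation is deliberately minimal (single defining site per
star allele, no suballeles, no phasing, no CYP2D6 hybrid alleles);
copy-number must be declared, never inferred; the PD tally treats all
variant sites as exchangeable one-point contributions, which is exactly
what the composite score prescribes but discards effect-size information
the underlying literature contains. The ROC threshold and cohort choice
are package defaults, not reproduced study facts, so smoothed AUC values
should be compared across configurations, not against published values.
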