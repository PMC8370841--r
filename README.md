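# PGxCohort

Pharmacogenomics-guided cohort analysis of treatment effectiveness in
mental-health prescribing.

Studies of pharmacogenomic (PGx) testing in psychiatry typically genotype
patients on a fixed variant panel, translate CYP2D6/CYP2C19 genotypes into
metabolizer phenotypes (poor / intermediate / normal / ultra-rapid), fold
phenotypes and pharmacodynamic variant burden into a composite genetic
risk score, score treatment effectiveness from patient questionnaires
before and after a prescription change, and relate the two with
non-parametric statistics. PGxCohort implements that entire chain as a
tested R package for analysts who want to run, audit or re-calibrate this
kind of study — including a seeded synthetic-cohort generator, because
patient-level data from such studies are rarely shareable.

## What it computes

**Genetic mutation score (0–15).** With p(poor) = p(ultra-rapid) = 5,
p(intermediate) = 2, p(normal) = 0 per gene,

    S_g = p(CYP2D6) + p(CYP2C19) + min(# PD variant sites, 5)

where the pharmacodynamic (PD) tally counts distinct variant sites in the
panel's receptor / transporter / other-PD categories, regardless of
zygosity. Phenotypes come from star-allele diplotypes via the activity
score convention (poor = 0, intermediate (0, 1.25), normal [1.25, 2.25],
ultra-rapid > 2.25, with a CYP2C19 \*17/\*17 gate and a CYP2D6
copy-number gate).

**Treatment-effectiveness score (1–10, higher = worse).** Mood toward
work (1–5, from the questionnaire's three bands plus a severity
sub-level) plus distinct reported side effects capped at 5.

**Cohort statistics.** Paired Wilcoxon signed-rank test (tie-corrected
normal approximation, no continuity correction, optional exact 2^n mode)
with effect size r = |Z|/sqrt(2n); Spearman rank correlation (mid-ranks,
t approximation); bootstrap-smoothed ROC (class-stratified resamples
averaged on a fixed 101-point FPR grid, trapezoidal AUC); and the
descriptive study table.

The methods vignette (`vignettes/pgxcohort-methods.Rmd`) documents every
model assumption, default and tie-break, and what the synthetic generator
does and does not emulate.

## Worked example

```r
library(PGxCohort)

loadDefaultPanel()
#> PgxPanel (panel-1.0): 54 genes, 107 gene-site entries (105 unique sites)
#>   categories: non_scored=8, other_pd=23, pk_enzyme=45, receptor=25, transporter=6
```

The panel's 54 genes carry 104 rs-numbered variants plus the 5-HTTLPR
pseudo-site; rs2952768 is listed under three genes but scored once.
Calling a CYP2C19 diplotype for a rs4244285 heterozygote:

```r
callDiplotype("CYP2C19", c(rs4244285 = "heterozygous"),
              loadTranslationTable())
#> $diplotype
#> [1] "*1/*2"
#> $activity
#> [1] 1
```

Activity 1 is an intermediate metabolizer (2 points). Scoring two
constructed profiles — a CYP2D6-poor patient carrying 7 PD variants, and
an all-normal patient:

```r
prof <- phenotypeProfile(c("poor", "normal"), c("intermediate", "normal"),
                         c(7, 0), patientId = c("P1", "P2"))
geneticMutationScore(prof)
#>   patient_id pk_points_2d6 pk_points_2c19 pd_points total
#> 1         P1             5              2         5    12
#> 2         P2             0              0         0     0
```

P1 scores 5 (poor CYP2D6) + 2 (intermediate CYP2C19) + 5 (PD burden
capped at five) = 12 of 15. Running the whole pipeline on a simulated
default cohort (84 patients, 46 followed up):

```r
rep <- runPipeline(runConfig(simulate = generatorConfig(seed = 7)))
rep
#> Cohort summary: 84 patients, 46 with follow-up
#>   ... (descriptive table) ...
#> Paired Wilcoxon signed-rank test (normal approximation, tie-corrected,
#>   no continuity correction)
#>   n = 46 pairs (0 zero differences dropped)
#>   W = 0.0, Z = 5.936, p = 2.919e-09, effect size r = 0.619
#> Full cohort Spearman rank correlation: rho = 0.130, p = 0.2376, n = 84
#> Follow-up subset Spearman rank correlation: rho = 0.057, p = 0.7085, n = 46
#> Bootstrap-smoothed ROC: AUC = 0.580 (1000 resamples, seed 20180501)
```

Every follow-up score improved (W = 0), giving the large effect size
r ≈ 0.62 that a 46-pair fully improving design implies. A single
84-patient cohort's Spearman correlation is noisy (SE ≈ 0.11); the
generator's coupling is calibrated in expectation, so averages over many
seeds land near 0.281 (see below). `writeReport(rep, "out/")` writes
`report.json`, `table2.csv`, `scores.csv`, `profiles.csv` and optional
plots. A command-line wrapper with `simulate` / `score` / `analyze` /
`report` subcommands is installed at
`system.file("scripts", "pgx-pipeline.R", package = "PGxCohort")`.

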