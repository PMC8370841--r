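.SIDE_EFFECT_POOL <- c("fatigue", "dizziness", "insomnia",
                       "sexual dysfunction", "weight gain", "nausea",
                       "headache", "tremor")

#' Generator configuration for synthetic cohorts
#'
#' Returns the configuration list driving [generateCohort()] and
#' [generateGenotypeMode()]. The defaults ARE the study conditions the
#' package is calibrated to: 84 patients of whom 46 complete follow-up, the
#' published demographic mix, per-gene CYP2D6/CYP2C19 phenotype
#' probabilities and a Poisson pharmacodynamic variant burden chosen to
#' reproduce the published phenotype prevalences and genetic-score mean
#' approximately, baseline effectiveness 8.39 (SD 1.22), follow-up 2.30
#' (SD 1.01), and a latent coupling coefficient lambda calibrated so the
#' n = 84 Spearman correlation between genetic score and baseline
#' effectiveness is about 0.281 in expectation.
#'
#' @param n_total cohort size.
#' @param n_followup number of patients with follow-up records
#'   (<= n_total).
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param age_mean,age_sd age distribution (years).
#' @param sex_probs,ethnicity_probs named probability vectors (may include
#'   an "Unreported" mass; must sum to <= 1 each before the implicit
#'   remainder is added).
#' @param phenotype_probs list with named probability vectors for CYP2D6
#'   and CYP2C19 over poor/intermediate/normal/ultrarapid.
#' @param pd_zero_prob probability of carrying no pharmacodynamic variant
#'   at all (the zero-inflation mass; these patients can only be
#'   pharmacokinetic-profile or none).
#' @param pd_count_mean mean of the pharmacodynamic variant count among
#'   carriers (a shifted Poisson: 1 + Poisson(pd_count_mean - 1)).
#' @param lambda latent coupling: baseline latent severity is
#'   \code{baseline_mean + lambda * (G - mean(G)) + noise}.
#' @param baseline_mean,baseline_sd,followup_mean,followup_sd target
#'   moments of the effectiveness totals (latent scale; integer
#'   discretisation attenuates them by about 0.02, far inside the
#'   generator's stochastic variability).
#' @param improvement_guarantee if TRUE every follow-up total is strictly
#'   below its baseline total.
#' @param followup_male_bias log-odds weight favouring males in the
#'   follow-up subset (0 = uniform selection; positive values reproduce
#'   the published sex-composition shift between the two columns).
#' @param allele_freqs optional named vector of alternate-allele
#'   frequencies overriding the panel defaults (genotype mode only).
#' @return a list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(n_total = 84L, n_followup = 46L,
                            seed = 20180501,
                            age_mean = 35.5, age_sd = 10.6,
                            sex_probs = c(Female = 45 / 84, Male = 38 / 84),
                            ethnicity_probs = c(Asian = 5 / 84,
                                                Caucasian = 58 / 84,
                                                Other = 3 / 84),
                            phenotype_probs = list(
                              CYP2D6 = c(poor = 0.07, intermediate = 0.35,
                                         normal = 0.38, ultrarapid = 0.20),
                              CYP2C19 = c(poor = 0.07, intermediate = 0.35,
                                          normal = 0.38, ultrarapid = 0.20)),
                            pd_zero_prob = 0.22,
                            pd_count_mean = 5.8,
                            lambda = 0.107,
                            baseline_mean = 8.39, baseline_sd = 1.22,
                            followup_mean = 2.30, followup_sd = 1.01,
                            improvement_guarantee = TRUE,
                            followup_male_bias = 0,
                            allele_freqs = NULL) {
  cfg <- list(n_total = as.integer(n_total),
              n_followup = as.integer(n_followup), seed = seed,
              age_mean = age_mean, age_sd = age_sd,
              sex_probs = sex_probs, ethnicity_probs = ethnicity_probs,
              phenotype_probs = phenotype_probs,
              pd_zero_prob = pd_zero_prob,
              pd_count_mean = pd_count_mean, lambda = lambda,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              followup_mean = followup_mean, followup_sd = followup_sd,
              improvement_guarantee = improvement_guarantee,
              followup_male_bias = followup_male_bias,
              allele_freqs = allele_freqs)
  .validateGeneratorConfig(cfg)
  structure(cfg, class = c("GeneratorConfig", "list"))
}

.validateGeneratorConfig <- function(cfg) {
  if (cfg$n_followup > cfg$n_total)
    stop("config error: n_followup exceeds n_total")
  for (p in list(cfg$sex_probs, cfg$ethnicity_probs,
                 cfg$phenotype_probs$CYP2D6, cfg$phenotype_probs$CYP2C19)) {
    if (any(p < 0 | p > 1) || sum(p) > 1 + 1e-9)
      stop("config error: probabilities must lie in [0,1] and sum to <= 1")
  }
  for (g in c("CYP2D6", "CYP2C19")) {
    ph <- cfg$phenotype_probs[[g]]
    if (!all(c("poor", "intermediate", "normal", "ultrarapid") %in%
               names(ph)))
      stop("config error: phenotype_probs$", g,
           " must name poor/intermediate/normal/ultrarapid")
  }
  if (cfg$pd_zero_prob < 0 || cfg$pd_zero_prob > 1)
    stop("config error: pd_zero_prob must lie in [0,1]")
  if (cfg$pd_count_mean < 1)
    stop("config error: pd_count_mean (carrier mean) must be >= 1")
  if (cfg$improvement_guarantee && cfg$followup_mean >= cfg$baseline_mean)
    stop("config error: follow-up mean must be below baseline mean ",
         "when the improvement guarantee is on")
  if (!is.null(cfg$allele_freqs) &&
      any(cfg$allele_freqs < 0 | cfg$allele_freqs > 1))
    stop("config error: allele frequencies must lie in [0,1]")
  invisible(TRUE)
}

.simCategorical <- function(n, probs, unreported = "Unreported") {
  rest <- 1 - sum(probs)
  lv <- c(names(probs), if (rest > 1e-9) unreported)
  pr <- c(probs, if (rest > 1e-9) rest)
  sample(lv, n, replace = TRUE, prob = pr)
}

.simDemographics <- function(cfg) {
  n <- cfg$n_total
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = pmin(pmax(round(stats::rnorm(n, cfg$age_mean, cfg$age_sd)), 18),
               70),
    sex = .simCategorical(n, cfg$sex_probs),
    ethnicity = .simCategorical(n, cfg$ethnicity_probs),
    stringsAsFactors = FALSE)
}

## mood/side components from an integer total in 1..10; mood = ceiling(t/2)
## and side = floor(t/2) keep both components in range by construction
.componentsFromTotal <- function(total) {
  mood <- as.integer(ceiling(total / 2))
  data.frame(mood_points = mood, side_points = as.integer(total - mood))
}

.moodCategoryFromPoints <- function(mood) {
  cat <- c("feel_good", "force_myself", "force_myself", "unable",
           "unable")[mood]
  sub <- c(NA, "low", "high", "low", "high")[mood]
  data.frame(mood_category = cat, mood_sublevel = sub,
             stringsAsFactors = FALSE)
}

.questionnaireRows <- function(ids, totals, timepoint) {
  comp <- .componentsFromTotal(totals)
  moodQ <- .moodCategoryFromPoints(comp$mood_points)
  se <- vapply(comp$side_points, function(k)
    paste(sample(.SIDE_EFFECT_POOL, k), collapse = ";"), character(1))
  data.frame(patient_id = ids, timepoint = rep(timepoint, length(ids)),
             mood_category = moodQ$mood_category,
             mood_sublevel = moodQ$mood_sublevel,
             side_effects = se, stringsAsFactors = FALSE)
}

## latent-severity outcome model shared by both generator modes
.simOutcomes <- function(demographics, geneticTotals, cfg) {
  n <- cfg$n_total
  G <- geneticTotals
  noiseSd <- sqrt(max(cfg$baseline_sd^2 -
                        cfg$lambda^2 * stats::var(G), 0.05))
  latent <- cfg$baseline_mean + cfg$lambda * (G - mean(G)) +
    stats::rnorm(n, 0, noiseSd)
  baseline <- pmin(pmax(round(latent), 1L), 10L)

  w <- rep(1, n)
  if (cfg$followup_male_bias != 0)
    w[demographics$sex == "Male"] <- exp(cfg$followup_male_bias)
  fuIdx <- sample(n, cfg$n_followup, prob = w)
  followupFlag <- seq_len(n) %in% fuIdx

  fu <- rep(NA_integer_, n)
  draw <- function(k) pmin(pmax(round(
    stats::rnorm(k, cfg$followup_mean, cfg$followup_sd)), 1L), 10L)
  fu[fuIdx] <- draw(length(fuIdx))
  if (cfg$improvement_guarantee) {
    for (i in fuIdx) {
      tries <- 0
      while (fu[i] >= baseline[i] && tries < 1000) {
        fu[i] <- draw(1)
        tries <- tries + 1
      }
      if (fu[i] >= baseline[i]) {
        fu[i] <- max(1L, baseline[i] - 1L)
        if (fu[i] >= baseline[i])
          warning("improvement guarantee unattainable for patient ",
                  demographics$patient_id[i], " (baseline total 1)")
      }
    }
  }
  list(baseline = baseline, followup = fu, followupFlag = followupFlag)
}

.assembleCohort <- function(demographics, profiles, genotypes, out, cfg) {
  demographics$followup <- out$followupFlag
  q <- rbind(
    .questionnaireRows(demographics$patient_id, out$baseline, "baseline"),
    .questionnaireRows(demographics$patient_id[out$followupFlag],
                       out$followup[out$followupFlag], "followup"))
  new("SyntheticCohort", demographics = demographics, questionnaire = q,
      profiles = profiles, genotypes = genotypes,
      config = unclass(cfg))
}

#' Generate a synthetic cohort (phenotype mode)
#'
#' Draws a fully synthetic study cohort: demographics, per-gene CYP2D6 and
#' CYP2C19 metabolizer phenotypes, a Poisson pharmacodynamic variant count,
#' and questionnaire records whose effectiveness totals follow the latent
#' model \code{baseline_mean + lambda * (G - mean(G)) + noise}, where G is
#' each patient's genetic mutation score computed by the real scoring code.
#' Totals are discretized into valid mood (1-5) and side-effect (0-5)
#' components, so every generated record is a legal scoring input by
#' construction. Follow-up totals are drawn around their own target mean
#' and, under the improvement guarantee, resampled until strictly below
#' baseline. Fully reproducible for a given seed.
#'
#' @param config a [generatorConfig()] list.
#' @return a [SyntheticCohort-class].
#' @examples
#' ch <- generateCohort(generatorConfig(seed = 1))
#' ch
#' @export
generateCohort <- function(config = generatorConfig()) {
  .validateGeneratorConfig(config)
  withSeed(subSeed(config$seed, 1), {
    demo <- .simDemographics(config)
    n <- config$n_total
    ph <- lapply(config$phenotype_probs, function(p)
      sample(names(p), n, replace = TRUE, prob = p))
    carrier <- stats::runif(n) >= config$pd_zero_prob
    pdCount <- ifelse(carrier,
                      1L + stats::rpois(n, config$pd_count_mean - 1), 0L)
    profiles <- phenotypeProfile(ph$CYP2D6, ph$CYP2C19, pdCount,
                                 patientId = demo$patient_id)
    G <- geneticMutationScore(profiles)$total
    out <- .simOutcomes(demo, G, config)
    .assembleCohort(demo, profiles, NULL, out, config)
  })
}

.hwGenotypeClass <- function(nAlt) {
  c("ref_homozygous", "heterozygous", "variant_homozygous")[nAlt + 1L]
}

#' Generate a synthetic cohort (genotype mode)
#'
#' Like [generateCohort()] but starts one level lower: per-site genotypes
#' are drawn under independent Hardy-Weinberg sampling at the panel's
#' alternate-allele frequencies (overridable via
#' \code{config$allele_freqs}), then routed through the real panel
#' validation and phenotyping stack — diplotype calling, activity mapping
#' and PD variant counting — with no phenotype shortcut, guaranteeing
#' end-to-end exercise of the calling code.
#'
#' @param config a [generatorConfig()] list.
#' @param panel a [PgxPanel-class].
#' @param table an [AlleleTranslationTable-class].
#' @return a [SyntheticCohort-class] with genotype calls attached.
#' @export
generateGenotypeMode <- function(config = generatorConfig(),
                                 panel = loadDefaultPanel(),
                                 table = loadTranslationTable()) {
  .validateGeneratorConfig(config)
  withSeed(subSeed(config$seed, 2), {
    demo <- .simDemographics(config)
    n <- config$n_total
    sites <- panelSites(panel)
    sites <- sites[!duplicated(sites$rsid), , drop = FALSE]
    af <- sites$default_af
    names(af) <- sites$rsid
    if (!is.null(config$allele_freqs)) {
      unknown <- setdiff(names(config$allele_freqs), names(af))
      if (length(unknown))
        stop("config error: allele_freqs for non-panel site(s): ",
             paste(unknown, collapse = ", "))
      af[names(config$allele_freqs)] <- config$allele_freqs
    }
    nSites <- nrow(sites)
    nAlt <- matrix(stats::rbinom(n * nSites, 2, rep(af, each = n)),
                   nrow = n)
    allele1 <- ifelse(nAlt >= 1, rep(sites$alt, each = n),
                      rep(sites$ref, each = n))
    allele2 <- ifelse(nAlt == 2, rep(sites$alt, each = n),
                      rep(sites$ref, each = n))
    calls <- data.frame(
      patient_id = rep(demo$patient_id, times = nSites),
      rsid = rep(sites$rsid, each = n),
      genotype_class = .hwGenotypeClass(as.vector(nAlt)),
      alleles = paste(pmin(allele1, allele2), pmax(allele1, allele2),
                      sep = "/"),
      stringsAsFactors = FALSE)
    cn <- rep(2, n); names(cn) <- demo$patient_id
    genotypes <- new("GenotypeCohort", calls = calls, copyNumber = cn)
    profiles <- buildProfile(genotypes, panel, table)
    G <- geneticMutationScore(profiles)$total
    out <- .simOutcomes(demo, G, config)
    .assembleCohort(demo, profiles, genotypes, out, config)
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort in exactly the formats the ingestion functions read:
#' \code{questionnaire.csv}, \code{demographics.csv}, \code{profiles.csv},
#' \code{genotypes.tsv} (genotype mode only), and \code{manifest.yaml}
#' recording the generator configuration (including the seed) and panel
#' version.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- c(questionnaire = file.path(dir, "questionnaire.csv"),
             demographics = file.path(dir, "demographics.csv"),
             profiles = file.path(dir, "profiles.csv"),
             manifest = file.path(dir, "manifest.yaml"))
  tryCatch({
    utils::write.csv(cohortQuestionnaire(cohort), paths["questionnaire"],
                     row.names = FALSE, na = "")
    utils::write.csv(cohortDemographics(cohort), paths["demographics"],
                     row.names = FALSE)
    writeProfiles(cohortProfiles(cohort), paths["profiles"])
    if (!is.null(cohortGenotypes(cohort))) {
      paths <- c(paths, genotypes = file.path(dir, "genotypes.tsv"))
      writeGenotypeTable(cohortGenotypes(cohort), paths["genotypes"])
    }
    cfg <- cohortConfig(cohort)
    cfg$allele_freqs <- as.list(cfg$allele_freqs)
    yaml::write_yaml(list(generator_config = unclass(cfg),
                          seed = cfg$seed,
                          package_version =
                            as.character(utils::packageVersion("PGxCohort"))),
                     paths["manifest"])
  }, error = function(e)
    stop("failed writing cohort to ", dir, ": ", conditionMessage(e)))
  invisible(paths)
}
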