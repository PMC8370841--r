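#' Assemble a run configuration
#'
#' Exactly one of \code{simulate} or \code{inputs} must be given.
#' \code{inputs} is a named list of file paths: \code{questionnaire}
#' (required), \code{demographics} (required), and either \code{genotypes}
#' (tabular genotype file, phenotyped on the fly) or \code{profiles} (a
#' pre-computed profile CSV). Statistical options: \code{r_convention}
#' ("total" or "pairs"), \code{threshold} (dichotomization cut for the ROC
#' outcome, default 8), \code{n_boot}, \code{roc_seed}, \code{roc_cohort}
#' ("all", the default, or "followup").
#'
#' @param simulate a [generatorConfig()] list, or NULL.
#' @param inputs named list of input paths, or NULL.
#' @param options named list of statistical options (defaults filled in).
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(simulate = NULL, inputs = NULL, options = list()) {
  if (is.null(simulate) == is.null(inputs))
    stop("exactly one of simulate mode or real-input mode must be active")
  opts <- utils::modifyList(
    list(r_convention = "total", threshold = 8, n_boot = 1000,
         roc_seed = 20180501, roc_cohort = "all"), options)
  if (!is.null(inputs)) {
    miss <- setdiff(c("questionnaire", "demographics"), names(inputs))
    if (length(miss))
      stop("inputs must name: ", paste(miss, collapse = ", "))
    if (is.null(inputs$genotypes) && is.null(inputs$profiles))
      stop("inputs must name either genotypes or profiles")
  }
  structure(list(simulate = simulate, inputs = inputs, options = opts),
            class = c("RunConfig", "list"))
}

#' Read a run configuration from YAML
#' @param path YAML file with top-level keys \code{simulate} or
#'   \code{inputs}, plus optional \code{options}.
#' @return list of class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) {
    if (isTRUE(y$simulate)) generatorConfig()
    else do.call(generatorConfig, y$simulate)
  }
  runConfig(simulate = sim, inputs = y$inputs,
            options = y$options %||% list())
}

.readProfilesCsv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  p$pd_variant_count <- as.integer(p$pd_variant_count)
  phenotypeProfile(p$cyp2d6, p$cyp2c19, p$pd_variant_count,
                   patientId = p$patient_id)
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest -> phenotype -> score -> statistics -> report.
#' Patients lacking a baseline questionnaire are excluded from the
#' statistics (with a logged count) but retained in the phenotype output.
#' The paired Wilcoxon test runs on the follow-up-complete subset only;
#' Spearman correlations are computed for both the full analysed cohort
#' and the follow-up subset; the ROC uses the genetic score against the
#' dichotomized baseline effectiveness. Sections whose inputs are
#' degenerate (no follow-up records, single-class ROC labels) are marked
#' not-computed rather than failing the run.
#'
#' @param config a [runConfig()] list.
#' @return list of class \code{"AnalysisReport"}: \code{summary},
#'   \code{wilcoxon}, \code{spearman_all}, \code{spearman_followup},
#'   \code{roc}, \code{scores}, \code{profiles}, \code{exclusions},
#'   \code{provenance}.
#' @examples
#' rep <- runPipeline(runConfig(simulate = generatorConfig(seed = 7)))
#' rep$spearman_all
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig"))
    stop("config must come from runConfig()/readRunConfig()")
  opts <- config$options
  panel <- loadDefaultPanel()
  table <- loadTranslationTable()

  if (!is.null(config$simulate)) {
    pgxLog("pipeline", "simulate mode, seed ", config$simulate$seed)
    cohort <- generateCohort(config$simulate)
    demo <- cohortDemographics(cohort)
    quest <- cohortQuestionnaire(cohort)
    profiles <- cohortProfiles(cohort)
  } else {
    ins <- config$inputs
    for (p in unlist(ins))
      if (!file.exists(p)) stop("input file not found: ", p)
    quest <- readQuestionnaire(ins$questionnaire)
    demo <- utils::read.csv(ins$demographics, stringsAsFactors = FALSE)
    profiles <- if (!is.null(ins$genotypes)) {
      pgxLog("pipeline", "phenotyping genotype table ", ins$genotypes)
      buildProfile(parseGenotypeTable(ins$genotypes, panel), panel, table)
    } else .readProfilesCsv(ins$profiles)
  }

  genetic <- geneticMutationScore(profiles)
  scored <- scoreQuestionnaire(quest)
  scores <- scoreTable(genetic, scored)

  noBaseline <- is.na(scores$baseline_total)
  if (any(noBaseline))
    pgxLog("pipeline", "excluding ", sum(noBaseline),
           " patient(s) without baseline questionnaire from statistics")
  ana <- scores[!noBaseline, , drop = FALSE]
  exclusions <- list(n_input = nrow(scores),
                     n_analyzed = nrow(ana),
                     n_excluded_no_baseline = sum(noBaseline))

  fu <- ana[!is.na(ana$followup_total), , drop = FALSE]
  wil <- if (nrow(fu) >= 5) {
    wilcoxonPaired(fu$baseline_total, fu$followup_total,
                   rConvention = opts$r_convention)
  } else {
    pgxLog("pipeline", "follow-up subset too small (", nrow(fu),
           "); Wilcoxon section not computed")
    NULL
  }

  spAll <- spearmanCorrelation(ana$genetic_total, ana$baseline_total)
  spFu <- if (nrow(fu) >= 4)
    spearmanCorrelation(fu$genetic_total, fu$baseline_total) else NULL

  rocData <- if (identical(opts$roc_cohort, "followup")) fu else ana
  labels <- dichotomizeEffectiveness(rocData$baseline_total,
                                     opts$threshold)
  roc <- if (length(unique(labels)) == 2) {
    rocBootstrapSmoothed(rocData$genetic_total, labels,
                         nBoot = opts$n_boot, seed = opts$roc_seed)
  } else {
    pgxLog("pipeline", "dichotomized labels are single-class; ",
           "ROC section not computed")
    NULL
  }

  demo2 <- demo[match(ana$patient_id, demo$patient_id), , drop = FALSE]
  ptab <- profileTable(profiles)
  cohortTable <- data.frame(
    patient_id = ana$patient_id,
    age = demo2$age, sex = demo2$sex, ethnicity = demo2$ethnicity,
    profile_type = ptab$profile_type[match(ana$patient_id,
                                           ptab$patient_id)],
    genetic_total = ana$genetic_total,
    baseline_total = ana$baseline_total,
    followup_total = ana$followup_total,
    stringsAsFactors = FALSE)

  provenance <- list(
    config_hash = .configHash(unclass(config)),
    seeds = list(simulate = config$simulate$seed, roc = opts$roc_seed),
    panel_version = panelVersion(panel),
    package_version = as.character(utils::packageVersion("PGxCohort")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  structure(list(summary = summarizeCohort(cohortTable),
                 wilcoxon = wil, spearman_all = spAll,
                 spearman_followup = spFu, roc = roc,
                 scores = scores, profiles = ptab,
                 cohort_table = cohortTable,
                 exclusions = exclusions, provenance = provenance),
            class = "AnalysisReport")
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport\n==============\n")
  print(x$summary)
  if (!is.null(x$wilcoxon)) print(x$wilcoxon)
  else cat("Wilcoxon: not computed\n")
  cat("Full cohort ")
  print(x$spearman_all)
  if (!is.null(x$spearman_followup)) {
    cat("Follow-up subset ")
    print(x$spearman_followup)
  }
  if (!is.null(x$roc)) print(x$roc) else cat("ROC: not computed\n")
  invisible(x)
}

.reportJsonPayload <- function(report, timestamp = NULL) {
  prov <- report$provenance
  if (!is.null(timestamp)) prov$timestamp <- timestamp
  num <- function(r, fields) if (is.null(r)) "not computed" else r[fields]
  list(
    provenance = prov,
    exclusions = report$exclusions,
    summary = list(
      n_all = report$summary$all$n,
      n_followup = report$summary$followup$n,
      baseline_mean = report$summary$all$baseline[["mean"]],
      baseline_sd = report$summary$all$baseline[["sd"]],
      followup_subset_baseline_mean =
        report$summary$followup$baseline[["mean"]],
      followup_subset_baseline_sd =
        report$summary$followup$baseline[["sd"]],
      followup_mean = report$summary$followup$followup[["mean"]],
      followup_sd = report$summary$followup$followup[["sd"]],
      genetic_mean = report$summary$all$genetic[["mean"]],
      genetic_sd = report$summary$all$genetic[["sd"]]),
    wilcoxon = num(report$wilcoxon,
                   c("n_pairs", "W_statistic", "Z", "p_value",
                     "effect_size_r")),
    spearman_all = num(report$spearman_all, c("rho", "p_value", "n")),
    spearman_followup = num(report$spearman_followup,
                            c("rho", "p_value", "n")),
    roc = if (is.null(report$roc)) "not computed" else
      list(auc = report$roc$auc, n_boot = report$roc$n_boot,
           seed = report$roc$seed))
}

#' Write an analysis report to disk
#'
#' Emits \code{report.json} (full-precision numbers), \code{table2.csv}
#' (the formatted descriptive table), \code{scores.csv},
#' \code{profiles.csv} and optionally base-graphics \code{roc.png} /
#' \code{prepost.png}. With a fixed \code{timestamp} the output is
#' byte-identical across reruns of the same config and seeds.
#'
#' @param report an \code{AnalysisReport} from [runPipeline()].
#' @param dir output directory (created if needed).
#' @param plots also write the ROC and pre/post distribution plots.
#' @param timestamp optional fixed timestamp string recorded in the JSON
#'   provenance instead of the run's wall-clock time.
#' @return named vector of written paths, invisibly.
#' @export
writeReport <- function(report, dir, plots = FALSE, timestamp = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- c(report = file.path(dir, "report.json"),
             table2 = file.path(dir, "table2.csv"),
             scores = file.path(dir, "scores.csv"),
             profiles = file.path(dir, "profiles.csv"))
  jsonlite::write_json(.reportJsonPayload(report, timestamp),
                       paths["report"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(report$summary$table2, paths["table2"],
                   row.names = FALSE)
  utils::write.csv(report$scores, paths["scores"], row.names = FALSE,
                   na = "")
  utils::write.csv(report$profiles, paths["profiles"], row.names = FALSE)
  if (plots) {
    paths <- c(paths, roc = file.path(dir, "roc.png"),
               prepost = file.path(dir, "prepost.png"))
    if (!is.null(report$roc)) {
      grDevices::png(paths["roc"], width = 600, height = 600)
      plot(report$roc$fpr_grid, report$roc$mean_tpr, type = "l",
           xlab = "False positive rate", ylab = "True positive rate",
           main = sprintf("Bootstrap-smoothed ROC (AUC = %.3f)",
                          report$roc$auc))
      graphics::abline(0, 1, lty = 2)
      grDevices::dev.off()
    }
    ct <- report$cohort_table
    grDevices::png(paths["prepost"], width = 700, height = 500)
    graphics::boxplot(list(baseline = ct$baseline_total,
                           `follow-up` =
                             ct$followup_total[!is.na(ct$followup_total)]),
                      ylab = "Treatment effectiveness score")
    grDevices::dev.off()
  }
  invisible(paths)
}
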