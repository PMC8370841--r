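#' @import methods
NULL

.GENOTYPE_CLASSES <- c("ref_homozygous", "heterozygous", "variant_homozygous",
                       "no_call")
.PANEL_CATEGORIES <- c("pk_enzyme", "receptor", "transporter", "other_pd",
                       "non_scored")
.PHENOTYPES <- c("poor", "intermediate", "normal", "ultrarapid",
                 "indeterminate")
.PROFILE_TYPES <- c("pharmacokinetic", "pharmacodynamic", "both", "none")

#' PgxPanel: a pharmacogenomic test panel
#'
#' Container for a test panel: one row per (gene, site) entry with the gene
#' symbol, rsID (or pseudo-site key), scoring category, reference and
#' alternate alleles, optional star-allele tag and a default alternate-allele
#' frequency used by the genotype-mode simulator. The same rsID may appear
#' under several genes (the packaged panel lists rs2952768 under three), but
#' never twice under the same gene.
#'
#' @slot sites data.frame with columns \code{gene}, \code{rsid},
#'   \code{category}, \code{ref}, \code{alt}, \code{star}, \code{default_af}.
#' @slot version single character string identifying the panel build.
#' @seealso [loadDefaultPanel()]
#' @exportClass PgxPanel
setClass("PgxPanel",
         representation(sites = "data.frame", version = "character"))

setValidity("PgxPanel", function(object) {
  msg <- character()
  need <- c("gene", "rsid", "category", "ref", "alt")
  if (!all(need %in% names(object@sites)))
    msg <- c(msg, paste("sites must have columns:",
                        paste(setdiff(need, names(object@sites)),
                              collapse = ", ")))
  else {
    if (anyDuplicated(object@sites[, c("gene", "rsid")]))
      msg <- c(msg, "duplicate (gene, rsid) entries")
    bad <- setdiff(unique(object@sites$category), .PANEL_CATEGORIES)
    if (length(bad))
      msg <- c(msg, paste("unknown category:", paste(bad, collapse = ", ")))
    if (any(!nzchar(object@sites$gene)) || any(is.na(object@sites$gene)))
      msg <- c(msg, "empty gene symbols")
  }
  if (length(object@version) != 1L)
    msg <- c(msg, "version must be a single string")
  if (length(msg)) msg else TRUE
})

#' AlleleTranslationTable: star-allele definitions with activity values
#'
#' Maps defining variant sites to named star alleles of CYP2D6/CYP2C19 and
#' assigns each allele a non-negative activity value plus a function label.
#' The default allele (*1, activity 1.0) is implicit: it applies to every
#' haplotype copy on which no defining variant is observed.
#'
#' @slot alleles data.frame with columns \code{gene}, \code{star_allele},
#'   \code{rsid}, \code{state}, \code{activity}, \code{function_label}.
#' @seealso [loadTranslationTable()], [callDiplotype()]
#' @exportClass AlleleTranslationTable
setClass("AlleleTranslationTable", representation(alleles = "data.frame"))

setValidity("AlleleTranslationTable", function(object) {
  msg <- character()
  need <- c("gene", "star_allele", "rsid", "state", "activity")
  if (!all(need %in% names(object@alleles)))
    msg <- c(msg, paste("alleles must have columns:",
                        paste(setdiff(need, names(object@alleles)),
                              collapse = ", ")))
  else {
    if (any(object@alleles$activity < 0, na.rm = TRUE))
      msg <- c(msg, "negative activity values")
    if (any(is.na(object@alleles$activity)))
      msg <- c(msg, "missing activity values")
    if (any(object@alleles$star_allele == "*1"))
      msg <- c(msg, "*1 is the implicit default allele; do not define it")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeCohort: per-patient genotype calls at panel sites
#'
#' Long-format container of genotype calls for one or more patients. Each
#' call carries the classified genotype state at a panel site plus the raw
#' allele string when available. CYP2D6 copy number is an optional explicit
#' per-patient annotation (SNP panels cannot see duplications); it defaults
#' to 2 copies.
#'
#' @slot calls data.frame with columns \code{patient_id}, \code{rsid},
#'   \code{genotype_class}, \code{alleles}.
#' @slot copyNumber named numeric vector of CYP2D6 copy numbers, one entry
#'   per patient.
#' @seealso [parseGenotypeTable()], [parseVcf()], [validateCohort()]
#' @exportClass GenotypeCohort
setClass("GenotypeCohort",
         representation(calls = "data.frame", copyNumber = "numeric"))

setValidity("GenotypeCohort", function(object) {
  msg <- character()
  need <- c("patient_id", "rsid", "genotype_class", "alleles")
  if (!all(need %in% names(object@calls)))
    msg <- c(msg, paste("calls must have columns:",
                        paste(setdiff(need, names(object@calls)),
                              collapse = ", ")))
  else {
    bad <- setdiff(unique(object@calls$genotype_class), .GENOTYPE_CLASSES)
    if (length(bad))
      msg <- c(msg, paste("unknown genotype_class:",
                          paste(bad, collapse = ", ")))
    if (any(!nzchar(object@calls$patient_id)))
      msg <- c(msg, "empty patient_id")
    if (anyDuplicated(object@calls[, c("patient_id", "rsid")]))
      msg <- c(msg, "duplicate (patient_id, rsid) calls")
  }
  if (any(object@copyNumber < 0))
    msg <- c(msg, "negative copy number")
  if (length(msg)) msg else TRUE
})

#' PhenotypeProfiles: per-patient metabolizer phenotypes and variant burden
#'
#' One row per patient: CYP2D6 and CYP2C19 metabolizer phenotypes, the count
#' of pharmacodynamic variant sites carried (receptor / transporter /
#' other-PD panel categories, each rsID counted once, zygosity-insensitive),
#' and the derived profile type. The profile type is \code{both} when a
#' non-normal PK phenotype co-occurs with PD variants, \code{pharmacokinetic}
#' or \code{pharmacodynamic} when only one side is affected, \code{none}
#' otherwise; indeterminate phenotypes count as normal for this purpose.
#'
#' @slot profiles data.frame with columns \code{patient_id}, \code{cyp2d6},
#'   \code{cyp2c19}, \code{pd_variant_count}, \code{profile_type}.
#' @seealso [buildProfile()], [phenotypeProfile()]
#' @exportClass PhenotypeProfiles
setClass("PhenotypeProfiles", representation(profiles = "data.frame"))

setValidity("PhenotypeProfiles", function(object) {
  p <- object@profiles
  msg <- character()
  need <- c("patient_id", "cyp2d6", "cyp2c19", "pd_variant_count",
            "profile_type")
  if (!all(need %in% names(p)))
    return(paste("profiles must have columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  if (!all(p$cyp2d6 %in% .PHENOTYPES) || !all(p$cyp2c19 %in% .PHENOTYPES))
    msg <- c(msg, "unknown phenotype value")
  if (any(p$pd_variant_count < 0))
    msg <- c(msg, "negative pd_variant_count")
  if (!all(p$profile_type %in% .PROFILE_TYPES))
    msg <- c(msg, "unknown profile_type")
  else if (nrow(p)) {
    expect <- .profileType(p$cyp2d6, p$cyp2c19, p$pd_variant_count)
    if (!identical(as.character(p$profile_type), expect))
      msg <- c(msg, "profile_type inconsistent with phenotypes and counts")
  }
  if (length(msg)) msg else TRUE
})

setClassUnion("GenotypeCohortOrNULL", c("GenotypeCohort", "NULL"))

#' SyntheticCohort: a simulated patient cohort
#'
#' Bundles everything one study cohort provides to the analysis pipeline:
#' demographics, questionnaire records (baseline for everyone, follow-up for
#' the follow-up subset), phenotype profiles, optionally the raw genotype
#' calls (genotype mode), and the generator configuration that produced it.
#'
#' @slot demographics data.frame: \code{patient_id}, \code{age}, \code{sex},
#'   \code{ethnicity}, \code{followup} (logical).
#' @slot questionnaire data.frame in the questionnaire-CSV layout:
#'   \code{patient_id}, \code{timepoint}, \code{mood_category},
#'   \code{mood_sublevel}, \code{side_effects}.
#' @slot profiles a [PhenotypeProfiles-class] object.
#' @slot genotypes a [GenotypeCohort-class] object, or NULL in phenotype mode.
#' @slot config the [generatorConfig()] list used.
#' @seealso [generateCohort()], [generateGenotypeMode()], [writeCohort()]
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
         representation(demographics = "data.frame",
                        questionnaire = "data.frame",
                        profiles = "PhenotypeProfiles",
                        genotypes = "GenotypeCohortOrNULL",
                        config = "list"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- object@demographics$patient_id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate patient ids")
  q <- object@questionnaire
  if (!all(q$patient_id %in% ids))
    msg <- c(msg, "questionnaire rows for unknown patients")
  if (!all(q$timepoint %in% c("baseline", "followup")))
    msg <- c(msg, "unknown timepoint")
  fu <- sum(object@demographics$followup)
  if (sum(q$timepoint == "followup") != fu)
    msg <- c(msg, "follow-up questionnaire rows do not match follow-up flags")
  if (length(msg)) msg else TRUE
})

## ---- generics & accessors ---------------------------------------------

#' Patient identifiers stored in an object
#' @param x a GenotypeCohort, PhenotypeProfiles or SyntheticCohort.
#' @return character vector of unique patient ids, in first-seen order.
#' @export
setGeneric("patientIDs", function(x) standardGeneric("patientIDs"))

#' @describeIn patientIDs patients with at least one genotype call
#' @export
setMethod("patientIDs", "GenotypeCohort",
          function(x) unique(x@calls$patient_id))

#' @describeIn patientIDs profiled patients
#' @export
setMethod("patientIDs", "PhenotypeProfiles",
          function(x) x@profiles$patient_id)

#' @describeIn patientIDs simulated patients
#' @export
setMethod("patientIDs", "SyntheticCohort",
          function(x) x@demographics$patient_id)

#' Panel accessors
#' @param x a [PgxPanel-class] object.
#' @return \code{panelSites}: the site table; \code{panelGenes}: unique gene
#'   symbols; \code{panelVersion}: the version string.
#' @export
setGeneric("panelSites", function(x) standardGeneric("panelSites"))
#' @rdname panelSites
#' @export
setMethod("panelSites", "PgxPanel", function(x) x@sites)

#' @rdname panelSites
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))
#' @rdname panelSites
#' @export
setMethod("panelGenes", "PgxPanel", function(x) unique(x@sites$gene))

#' @rdname panelSites
#' @export
setGeneric("panelVersion", function(x) standardGeneric("panelVersion"))
#' @rdname panelSites
#' @export
setMethod("panelVersion", "PgxPanel", function(x) x@version)

#' Genotype-call accessors
#' @param x a [GenotypeCohort-class] object.
#' @return \code{genotypeCalls}: long data.frame of calls;
#'   \code{cyp2d6CopyNumber}: named numeric vector of copy numbers.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "GenotypeCohort", function(x) x@calls)

#' @rdname genotypeCalls
#' @export
setGeneric("cyp2d6CopyNumber",
           function(x) standardGeneric("cyp2d6CopyNumber"))
#' @rdname genotypeCalls
#' @export
setMethod("cyp2d6CopyNumber", "GenotypeCohort", function(x) x@copyNumber)

#' Profile table accessor
#' @param x a [PhenotypeProfiles-class] object.
#' @return data.frame of per-patient profiles.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
#' @rdname profileTable
#' @export
setMethod("profileTable", "PhenotypeProfiles", function(x) x@profiles)

#' Synthetic-cohort accessors
#' @param x a [SyntheticCohort-class] object.
#' @return the corresponding component.
#' @export
setGeneric("cohortDemographics",
           function(x) standardGeneric("cohortDemographics"))
#' @rdname cohortDemographics
#' @export
setMethod("cohortDemographics", "SyntheticCohort",
          function(x) x@demographics)

#' @rdname cohortDemographics
#' @export
setGeneric("cohortQuestionnaire",
           function(x) standardGeneric("cohortQuestionnaire"))
#' @rdname cohortDemographics
#' @export
setMethod("cohortQuestionnaire", "SyntheticCohort",
          function(x) x@questionnaire)

#' @rdname cohortDemographics
#' @export
setGeneric("cohortProfiles", function(x) standardGeneric("cohortProfiles"))
#' @rdname cohortDemographics
#' @export
setMethod("cohortProfiles", "SyntheticCohort", function(x) x@profiles)

#' @rdname cohortDemographics
#' @export
setGeneric("cohortGenotypes", function(x) standardGeneric("cohortGenotypes"))
#' @rdname cohortDemographics
#' @export
setMethod("cohortGenotypes", "SyntheticCohort", function(x) x@genotypes)

#' @rdname cohortDemographics
#' @export
setGeneric("cohortConfig", function(x) standardGeneric("cohortConfig"))
#' @rdname cohortDemographics
#' @export
setMethod("cohortConfig", "SyntheticCohort", function(x) x@config)

## ---- show methods ------------------------------------------------------

setMethod("show", "PgxPanel", function(object) {
  s <- object@sites
  cat("PgxPanel (", object@version, "): ",
      length(unique(s$gene)), " genes, ", nrow(s), " gene-site entries (",
      length(unique(s$rsid)), " unique sites)\n", sep = "")
  tab <- table(s$category)
  cat("  categories:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "AlleleTranslationTable", function(object) {
  a <- object@alleles
  cat("AlleleTranslationTable:", nrow(a), "defining sites for",
      length(unique(a$gene)), "gene(s)\n")
  for (g in unique(a$gene))
    cat("  ", g, ": ",
        paste(unique(a$star_allele[a$gene == g]), collapse = " "),
        "\n", sep = "")
})

setMethod("show", "GenotypeCohort", function(object) {
  cat("GenotypeCohort:", length(patientIDs(object)), "patient(s),",
      nrow(object@calls), "calls\n")
  nc <- sum(object@calls$genotype_class == "no_call")
  if (nc) cat("  no-call entries:", nc, "\n")
})

setMethod("show", "PhenotypeProfiles", function(object) {
  p <- object@profiles
  cat("PhenotypeProfiles:", nrow(p), "patient(s)\n")
  if (nrow(p)) {
    cat("  profile types:",
        paste(names(table(p$profile_type)), table(p$profile_type),
              sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@demographics), "patients (",
      sum(object@demographics$followup), "with follow-up ),",
      if (is.null(object@genotypes)) "phenotype mode" else "genotype mode",
      "\n  seed:", object@config$seed, "\n")
})
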