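#' Load a star-allele translation table
#'
#' The packaged table encodes publicly documented single-site star-allele
#' definitions restricted to panel rsIDs: CYP2C19 *2-*8 (no function) and
#' *17 (increased function), CYP2D6 *2 (normal), *3/*4/*6/*7/*8/*11/*12/*15
#' (no function) and *9/*10/*17/*29/*41/*59 (decreased function). The
#' default allele *1 (activity 1.0) is implicit. Users may supply a
#' replacement table with the same columns.
#'
#' @param path optional path to a replacement TSV.
#' @return an [AlleleTranslationTable-class].
#' @export
loadTranslationTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "allele_translation.tsv",
                        package = "PGxCohort", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("AlleleTranslationTable", alleles = tab)
}

.starNumber <- function(star) {
  as.numeric(sub("^\\*([0-9]+).*$", "\\1", star))
}

#' Call a CYP2D6/CYP2C19 diplotype and its activity score
#'
#' Matches a patient's genotype states at the gene's defining sites against
#' the translation table. Each heterozygous defining site contributes one
#' copy of its star allele, each variant-homozygous site two copies. With
#' more than two candidate copies (unphased data), the two retained alleles
#' are chosen conservatively: lowest activity first, then lowest star-allele
#' number; two heterozygous defining sites are thereby placed in trans. With
#' fewer than two copies the implicit *1 (activity 1.0) fills the diplotype.
#' The activity score is the sum of the two allele activities; for CYP2D6 it
#' is scaled by \code{copyNumber/2} when the declared copy number differs
#' from 2.
#'
#' @param gene \code{"CYP2D6"} or \code{"CYP2C19"}.
#' @param calls named character vector: genotype class per rsID for one
#'   patient (names are rsIDs; values in ref_homozygous / heterozygous /
#'   variant_homozygous / no_call). Sites absent from the vector count as
#'   missing data.
#' @param table an [AlleleTranslationTable-class].
#' @param copyNumber declared CYP2D6 copy number (default 2; ignored for
#'   other genes).
#' @return list with \code{diplotype} (e.g. \code{"*1/*2"}),
#'   \code{activity}, and \code{indeterminate} (TRUE when no defining site
#'   had a usable call, in which case activity is NA).
#' @examples
#' tab <- loadTranslationTable()
#' callDiplotype("CYP2C19", c(rs4244285 = "heterozygous"), tab)
#' @export
callDiplotype <- function(gene, calls, table = loadTranslationTable(),
                          copyNumber = 2) {
  defs <- table@alleles[table@alleles$gene == gene, , drop = FALSE]
  if (!nrow(defs)) stop("no translation entries for gene ", gene)
  state <- calls[defs$rsid]
  usable <- !is.na(state) & state != "no_call"
  if (!any(usable))
    return(list(diplotype = NA_character_, activity = NA_real_,
                indeterminate = TRUE))
  copies <- rep(seq_len(nrow(defs)),
                ifelse(is.na(state), 0L,
                       ifelse(state == "heterozygous", 1L,
                              ifelse(state == "variant_homozygous", 2L, 0L))))
  stars <- defs$star_allele[copies]
  acts <- defs$activity[copies]
  if (length(stars) > 2L) {
    ord <- order(acts, .starNumber(stars))[1:2]
    stars <- stars[ord]; acts <- acts[ord]
  }
  while (length(stars) < 2L) {
    stars <- c(stars, "*1"); acts <- c(acts, 1)
  }
  ord <- order(.starNumber(stars))
  activity <- sum(acts)
  if (gene == "CYP2D6" && copyNumber != 2)
    activity <- activity * copyNumber / 2
  list(diplotype = paste(stars[ord], collapse = "/"),
       activity = activity, indeterminate = FALSE)
}

#' Map an activity score to a metabolizer phenotype
#'
#' Uses the conventional activity-score cutpoints: poor at activity 0,
#' intermediate in (0, 1.25), normal in [1.25, 2.25], ultrarapid above
#' 2.25. Two gene-specific gates apply: CYP2C19 is additionally called
#' ultrarapid when rs12248560 (*17) is variant-homozygous, and CYP2D6 can
#' only be ultrarapid when a declared copy number above 2 backs the
#' increased activity (SNP-only panels cannot see duplications, so without
#' copy-number input CYP2D6 ultrarapid is unreachable).
#'
#' @param gene gene symbol (gates apply to CYP2C19/CYP2D6).
#' @param activity non-negative activity score (NA gives indeterminate).
#' @param copyNumber declared CYP2D6 copy number.
#' @param rs12248560State genotype class at rs12248560, for the CYP2C19
#'   *17 homozygote gate.
#' @param thresholds numeric length-2: upper-exclusive intermediate bound
#'   and upper-inclusive normal bound (default \code{c(1.25, 2.25)}).
#' @return one of \code{"poor"}, \code{"intermediate"}, \code{"normal"},
#'   \code{"ultrarapid"}, \code{"indeterminate"}.
#' @export
phenotypeFromActivity <- function(gene, activity, copyNumber = 2,
                                  rs12248560State = "ref_homozygous",
                                  thresholds = c(1.25, 2.25)) {
  if (is.na(activity)) return("indeterminate")
  if (activity < 0) stop("activity must be non-negative")
  if (gene == "CYP2C19" && identical(rs12248560State, "variant_homozygous"))
    return("ultrarapid")
  if (activity == 0) return("poor")
  if (activity < thresholds[1]) return("intermediate")
  if (activity <= thresholds[2]) return("normal")
  if (gene == "CYP2D6" && copyNumber <= 2) {
    message("[phenotyping] CYP2D6 activity ", activity,
            " above the normal range without copy number > 2; ",
            "calling normal (ultrarapid requires declared duplications)")
    return("normal")
  }
  "ultrarapid"
}

#' Count pharmacodynamic variant sites carried by a patient
#'
#' Counts panel sites in the receptor, transporter and other-PD categories
#' whose genotype is heterozygous or variant-homozygous. Each rsID is
#' counted once even if the panel lists it under several genes
#' (rs2952768), and zygosity does not matter: one point per variant site
#' carried. No-call and missing sites contribute 0. PK-enzyme genes other
#' than CYP2D6/CYP2C19 (e.g. CYP2C9) are deliberately not counted: they are
#' neither phenotyped for the score nor tallied as pharmacodynamic burden.
#'
#' @param calls named character vector of genotype classes (names = rsIDs)
#'   for one patient.
#' @param panel a [PgxPanel-class].
#' @return integer count (uncapped; the genetic score caps it at 5 later).
#' @export
countPdVariants <- function(calls, panel = loadDefaultPanel()) {
  sites <- panelSites(panel)
  pd <- unique(sites$rsid[sites$category %in%
                            c("receptor", "transporter", "other_pd")])
  state <- calls[pd]
  sum(!is.na(state) & state %in% c("heterozygous", "variant_homozygous"))
}

## profile-type rule shared by the constructor and the class validity
.profileType <- function(cyp2d6, cyp2c19, pdCount) {
  d6 <- ifelse(cyp2d6 == "indeterminate", "normal", cyp2d6)
  c19 <- ifelse(cyp2c19 == "indeterminate", "normal", cyp2c19)
  pkHit <- d6 != "normal" | c19 != "normal"
  ifelse(pkHit & pdCount > 0, "both",
         ifelse(pkHit, "pharmacokinetic",
                ifelse(pdCount > 0, "pharmacodynamic", "none")))
}

#' Construct phenotype profiles directly
#'
#' Builds a [PhenotypeProfiles-class] from given phenotype values and PD
#' variant counts, deriving the profile type; vectorized over patients.
#' Indeterminate phenotypes are treated as normal for profile typing (with
#' a warning) so that missing data never manufactures a pharmacokinetic
#' finding.
#'
#' @param cyp2d6,cyp2c19 phenotype values (see
#'   [phenotypeFromActivity()]).
#' @param pdVariantCount non-negative integer vector.
#' @param patientId patient identifiers (default P1, P2, ...).
#' @return a [PhenotypeProfiles-class].
#' @examples
#' phenotypeProfile("ultrarapid", "poor", 0)
#' @export
phenotypeProfile <- function(cyp2d6, cyp2c19, pdVariantCount,
                             patientId = paste0("P", seq_along(cyp2d6))) {
  if (any(cyp2d6 == "indeterminate" | cyp2c19 == "indeterminate"))
    warning("indeterminate phenotype treated as normal for profile typing")
  prof <- data.frame(
    patient_id = patientId,
    cyp2d6 = cyp2d6, cyp2c19 = cyp2c19,
    pd_variant_count = as.integer(pdVariantCount),
    profile_type = .profileType(cyp2d6, cyp2c19, pdVariantCount),
    stringsAsFactors = FALSE)
  new("PhenotypeProfiles", profiles = prof)
}

#' Build phenotype profiles from genotype calls
#'
#' Runs the full translation for every patient in a cohort: CYP2D6 and
#' CYP2C19 diplotype calling ([callDiplotype()]), activity-to-phenotype
#' mapping ([phenotypeFromActivity()]) honouring declared CYP2D6 copy
#' numbers and the CYP2C19 *17 homozygote gate, and the PD variant tally
#' ([countPdVariants()]).
#'
#' @param genotypes a [GenotypeCohort-class].
#' @param panel a [PgxPanel-class].
#' @param table an [AlleleTranslationTable-class].
#' @return a [PhenotypeProfiles-class].
#' @export
buildProfile <- function(genotypes, panel = loadDefaultPanel(),
                         table = loadTranslationTable()) {
  calls <- genotypeCalls(genotypes)
  cn <- cyp2d6CopyNumber(genotypes)
  ids <- patientIDs(genotypes)
  byPatient <- split(calls, calls$patient_id)[ids]
  rows <- lapply(ids, function(id) {
    mine <- byPatient[[id]]
    v <- mine$genotype_class
    names(v) <- mine$rsid
    d6 <- callDiplotype("CYP2D6", v, table, copyNumber = cn[id])
    c19 <- callDiplotype("CYP2C19", v, table)
    phD6 <- phenotypeFromActivity("CYP2D6", d6$activity,
                                  copyNumber = cn[id])
    phC19 <- phenotypeFromActivity(
      "CYP2C19", c19$activity,
      rs12248560State = if ("rs12248560" %in% names(v))
        v[["rs12248560"]] else "ref_homozygous")
    data.frame(patient_id = id, cyp2d6 = phD6, cyp2c19 = phC19,
               pd_variant_count = countPdVariants(v, panel),
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  nInd <- sum(prof$cyp2d6 == "indeterminate" |
                prof$cyp2c19 == "indeterminate")
  if (nInd)
    warning(nInd, " patient(s) with indeterminate metabolizer phenotype; ",
            "treated as normal for profile typing")
  prof$profile_type <- .profileType(prof$cyp2d6, prof$cyp2c19,
                                    prof$pd_variant_count)
  prof$pd_variant_count <- as.integer(prof$pd_variant_count)
  new("PhenotypeProfiles", profiles = prof)
}

#' Write phenotype profiles to CSV
#' @param profiles a [PhenotypeProfiles-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  utils::write.csv(profileTable(profiles), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
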