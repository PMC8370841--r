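#' Per-gene score points for a metabolizer phenotype
#'
#' Extreme phenotypes (poor or ultra-rapid) contribute the maximum 5 points,
#' intermediate 2, normal 0. Indeterminate contributes 0 with a warning:
#' missing data must never raise a risk score.
#'
#' @param phenotype character vector of phenotype values.
#' @return integer vector of points in \{0, 2, 5\}.
#' @examples
#' pkPhenotypePoints(c("poor", "ultrarapid", "intermediate", "normal"))
#' @export
pkPhenotypePoints <- function(phenotype) {
  bad <- setdiff(phenotype, .PHENOTYPES)
  if (length(bad))
    stop("unknown phenotype value(s): ", paste(bad, collapse = ", "))
  if (any(phenotype == "indeterminate"))
    warning("indeterminate phenotype scored as 0 points")
  unname(c(poor = 5L, ultrarapid = 5L, intermediate = 2L, normal = 0L,
           indeterminate = 0L)[phenotype])
}

#' Genetic mutation score (0-15)
#'
#' The composite genetic score: up to 5 points per gene for the CYP2D6 and
#' CYP2C19 metabolizer phenotypes (5 extreme / 2 intermediate / 0 normal,
#' so a patient extreme in both genes scores 10), plus one point per
#' pharmacodynamic variant site carried, capped at 5. Totals therefore lie
#' in [0, 15] and the PK component sum in \{0, 2, 4, 5, 7, 10\}.
#'
#' @param profiles a [PhenotypeProfiles-class].
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{pk_points_2d6}, \code{pk_points_2c19}, \code{pd_points},
#'   \code{total}.
#' @examples
#' geneticMutationScore(phenotypeProfile("ultrarapid", "poor", 0))$total  # 10
#' @export
geneticMutationScore <- function(profiles) {
  p <- profileTable(profiles)
  d6 <- pkPhenotypePoints(p$cyp2d6)
  c19 <- pkPhenotypePoints(p$cyp2c19)
  pd <- pmin(p$pd_variant_count, 5L)
  data.frame(patient_id = p$patient_id,
             pk_points_2d6 = d6, pk_points_2c19 = c19,
             pd_points = as.integer(pd),
             total = as.integer(d6 + c19 + pd),
             stringsAsFactors = FALSE)
}

#' Mood points from the questionnaire answer
#'
#' The mood-toward-work item is answered as a category with, for the two
#' upper bands, a severity sub-level: "I feel good" scores 1, "I force
#' myself to do work" 2 (low) or 3 (high), "I am unable to work" 4 (low)
#' or 5 (high).
#'
#' @param category character vector in \code{feel_good}, \code{force_myself},
#'   \code{unable}.
#' @param sublevel \code{low} or \code{high}; ignored for \code{feel_good}.
#' @return integer vector in 1..5.
#' @export
moodPoints <- function(category, sublevel = NA_character_) {
  if (length(sublevel) == 1L) sublevel <- rep(sublevel, length(category))
  bad <- !category %in% c("feel_good", "force_myself", "unable")
  if (any(bad))
    stop("unknown mood category: ",
         paste(unique(category[bad]), collapse = ", "))
  needsSub <- category != "feel_good"
  if (any(needsSub & !sublevel %in% c("low", "high")))
    stop("mood sub-level must be 'low' or 'high' for banded categories")
  base <- c(feel_good = 1L, force_myself = 2L, unable = 4L)[category]
  unname(base + ifelse(needsSub & sublevel == "high", 1L, 0L))
}

#' Side-effect points
#'
#' One point per distinct reported side effect (case-insensitive,
#' whitespace-trimmed), capped at the maximum of 5.
#'
#' @param sideEffects a character vector of side-effect labels for one
#'   patient, a single semicolon-separated string, or a list of either (one
#'   element per patient).
#' @return integer vector of points in 0..5.
#' @examples
#' sideEffectPoints("fatigue;dizziness;fatigue")  # 2
#' @export
sideEffectPoints <- function(sideEffects) {
  if (!is.list(sideEffects)) sideEffects <- list(sideEffects)
  vapply(sideEffects, function(x) {
    if (length(x) == 1L && (is.na(x) || !nzchar(x))) return(0L)
    labels <- unlist(strsplit(x, ";", fixed = TRUE))
    labels <- tolower(trimws(labels))
    labels <- labels[nzchar(labels)]
    min(length(unique(labels)), 5L)
  }, integer(1))
}

#' Treatment-effectiveness score (1-10)
#'
#' Sum of the mood points (1-5) and side-effect points (0-5); higher is
#' worse. Because mood is answered on a 1-5 scale, the minimum attainable
#' total is 1: the scale's "0 (Good)" anchor labels the good end but is not
#' a reachable value.
#'
#' @param moodPoints integer vector in 1..5.
#' @param sideEffectPoints integer vector in 0..5.
#' @param timepoint \code{"baseline"} or \code{"followup"}.
#' @return data.frame with \code{mood_points}, \code{side_effect_points},
#'   \code{total}, \code{timepoint}.
#' @export
effectivenessScore <- function(moodPoints, sideEffectPoints,
                               timepoint = "baseline") {
  if (any(moodPoints < 1 | moodPoints > 5))
    stop("mood points must lie in 1..5")
  if (any(sideEffectPoints < 0 | sideEffectPoints > 5))
    stop("side-effect points must lie in 0..5")
  if (!all(timepoint %in% c("baseline", "followup")))
    stop("timepoint must be 'baseline' or 'followup'")
  data.frame(mood_points = as.integer(moodPoints),
             side_effect_points = as.integer(sideEffectPoints),
             total = as.integer(moodPoints + sideEffectPoints),
             timepoint = timepoint,
             stringsAsFactors = FALSE)
}

#' Read a questionnaire CSV
#'
#' Expected columns: \code{patient_id}, \code{timepoint} (baseline or
#' followup), \code{mood_category}, \code{mood_sublevel},
#' \code{side_effects} (semicolon-separated labels, may be empty).
#'
#' @param path path to the CSV.
#' @return data.frame of raw questionnaire records.
#' @export
readQuestionnaire <- function(path) {
  q <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("patient_id", "timepoint", "mood_category", "mood_sublevel",
            "side_effects")
  miss <- setdiff(need, names(q))
  if (length(miss))
    stop("questionnaire is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(q)) stop("empty questionnaire file: ", path)
  q
}

#' Score questionnaire records
#'
#' Applies [moodPoints()], [sideEffectPoints()] and [effectivenessScore()]
#' to every record of a questionnaire table.
#'
#' @param questionnaire data.frame as returned by [readQuestionnaire()].
#' @return data.frame: \code{patient_id}, \code{timepoint},
#'   \code{mood_points}, \code{side_effect_points}, \code{total}.
#' @export
scoreQuestionnaire <- function(questionnaire) {
  mp <- moodPoints(questionnaire$mood_category, questionnaire$mood_sublevel)
  sp <- sideEffectPoints(as.list(questionnaire$side_effects))
  sc <- effectivenessScore(mp, sp, questionnaire$timepoint)
  cbind(data.frame(patient_id = questionnaire$patient_id,
                   stringsAsFactors = FALSE),
        sc[, c("timepoint", "mood_points", "side_effect_points", "total")])
}

#' Assemble the per-patient score table
#'
#' Joins genetic mutation scores with baseline and (where present)
#' follow-up effectiveness totals into the flat score table the statistics
#' stage consumes.
#'
#' @param genetic data.frame from [geneticMutationScore()].
#' @param scored data.frame from [scoreQuestionnaire()].
#' @return data.frame with one row per patient: genetic score components
#'   and \code{baseline_total} / \code{followup_total} (NA when absent).
#' @export
scoreTable <- function(genetic, scored) {
  base <- scored[scored$timepoint == "baseline", c("patient_id", "total")]
  names(base)[2] <- "baseline_total"
  fu <- scored[scored$timepoint == "followup", c("patient_id", "total")]
  names(fu)[2] <- "followup_total"
  g <- genetic
  names(g)[names(g) == "total"] <- "genetic_total"
  out <- merge(g, base, by = "patient_id", all.x = TRUE)
  out <- merge(out, fu, by = "patient_id", all.x = TRUE)
  out <- out[match(g$patient_id, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
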