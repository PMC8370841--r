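#' Load the packaged default test panel
#'
#' Reads the packaged 54-gene pharmacogenomic panel: 107 (gene, site)
#' entries covering 104 unique rsIDs plus the 5-HTTLPR length polymorphism
#' (pseudo-site key \code{SLC6A4_5HTTLPR}, alleles L/S, which has no rsID and
#' can only be supplied through the tabular reader). rs2952768 is listed
#' under three genes; per-patient variant counting deduplicates it. One
#' panel row has no published gene symbol and is kept under the placeholder
#' \code{UNASSIGNED_ROW8}, flagged by [validateCohort()].
#'
#' Reference/alternate allele orientations and the default allele
#' frequencies are an editable packaged annotation (dbSNP conventions where
#' commonly documented, plausible placeholders otherwise); they decide
#' zygosity in [parseGenotypeTable()] and drive [generateGenotypeMode()].
#'
#' @param path optional path to an alternative panel file (TSV with the same
#'   columns); defaults to the packaged panel.
#' @param version version label attached to the returned panel.
#' @return a [PgxPanel-class] object.
#' @examples
#' panel <- loadDefaultPanel()
#' length(panelGenes(panel))  # 54
#' @export
loadDefaultPanel <- function(path = NULL, version = "panel-1.0") {
  if (is.null(path))
    path <- system.file("extdata", "panel_sites.tsv", package = "PGxCohort",
                        mustWork = TRUE)
  sites <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  sites$default_af <- as.numeric(sites$default_af)
  new("PgxPanel", sites = sites, version = version)
}

## classify one allele pair against panel ref/alt
.classifyAlleles <- function(a1, a2, ref, alt) {
  if (a1 == "." || a2 == "." || is.na(ref) || is.na(alt)) return("no_call")
  known <- c(ref, alt)
  if (!(a1 %in% known) || !(a2 %in% known)) return(NA_character_)
  nAlt <- (a1 == alt) + (a2 == alt)
  c("ref_homozygous", "heterozygous", "variant_homozygous")[nAlt + 1L]
}

#' Read a patient genotype table
#'
#' Parses a UTF-8 delimited file (TSV or CSV, auto-detected) with header
#' columns \code{patient_id}, \code{rsid}, \code{genotype} and optionally
#' \code{cyp2d6_copy_number}. Genotypes are slash-separated allele pairs
#' (\code{G/A}), \code{./.} for missing; the 5-HTTLPR row uses rsid
#' \code{SLC6A4_5HTTLPR} with alleles \code{L}/\code{S}. Zygosity is decided
#' against the panel's reference/alternate annotation; genotype strings that
#' do not match the annotated alleles, and sites unknown to the panel whose
#' orientation therefore cannot be decided, become \code{no_call} with a
#' warning.
#'
#' @param path path to the genotype table.
#' @param panel a [PgxPanel-class]; defaults to the packaged panel.
#' @return a [GenotypeCohort-class] object.
#' @export
parseGenotypeTable <- function(path, panel = loadDefaultPanel()) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty genotype table: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", strip.white = TRUE)
  need <- c("patient_id", "rsid", "genotype")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("genotype table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(tab)) stop("empty genotype table: ", path)

  tab <- unique(tab[, intersect(c(need, "cyp2d6_copy_number"), names(tab))])
  key <- paste(tab$patient_id, tab$rsid, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("conflicting duplicate genotype rows for: ",
         paste(gsub("\r", "/", dup), collapse = ", "))
  }

  sites <- panelSites(panel)
  ord <- match(tab$rsid, sites$rsid)  # first gene context is enough: ref/alt shared
  parts <- strsplit(tab$genotype, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    warning(sum(bad), " genotype string(s) not of the form X/Y set to no_call")
    parts[bad] <- list(c(".", "."))
  }
  cls <- vapply(seq_len(nrow(tab)), function(i) {
    j <- ord[i]
    if (is.na(j)) {
      if (parts[[i]][1] == ".") "no_call" else NA_character_
    } else .classifyAlleles(parts[[i]][1], parts[[i]][2],
                            sites$ref[j], sites$alt[j])
  }, character(1))
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning(sum(unknown),
            " genotype(s) with alleles unknown to the panel set to no_call")
    cls[unknown] <- "no_call"
  }

  calls <- data.frame(patient_id = tab$patient_id, rsid = tab$rsid,
                      genotype_class = cls, alleles = tab$genotype,
                      stringsAsFactors = FALSE)
  ids <- unique(calls$patient_id)
  cn <- rep(2, length(ids)); names(cn) <- ids
  if ("cyp2d6_copy_number" %in% names(tab)) {
    given <- suppressWarnings(as.numeric(tab$cyp2d6_copy_number))
    for (id in ids) {
      v <- unique(given[tab$patient_id == id & !is.na(given)])
      if (length(v) > 1)
        stop("conflicting cyp2d6_copy_number for patient ", id)
      if (length(v) == 1) cn[id] <- v
    }
  }
  new("GenotypeCohort", calls = calls, copyNumber = cn)
}

#' Write a genotype table
#'
#' Inverse of [parseGenotypeTable()]; re-parsing the written file reproduces
#' the same calls.
#'
#' @param genotypes a [GenotypeCohort-class].
#' @param path output file path (written as TSV).
#' @return the path, invisibly.
#' @export
writeGenotypeTable <- function(genotypes, path) {
  calls <- genotypeCalls(genotypes)
  cn <- cyp2d6CopyNumber(genotypes)
  out <- data.frame(patient_id = calls$patient_id, rsid = calls$rsid,
                    genotype = calls$alleles,
                    cyp2d6_copy_number = cn[calls$patient_id],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read panel genotypes from a VCF
#'
#' Extracts per-sample genotype calls at panel sites from a VCF (v4.x, GT
#' subfield required), matching sites to the panel by the ID column rsID.
#' Non-panel sites are ignored with a logged count. Genotype classes follow
#' GT semantics: all-reference alleles give \code{ref_homozygous}, a mix of
#' reference and alternate \code{heterozygous}, all-alternate
#' \code{variant_homozygous}, missing \code{no_call}. Requires the
#' VariantAnnotation package.
#'
#' @param path path to a VCF file.
#' @param panel a [PgxPanel-class].
#' @return a [GenotypeCohort-class] object.
#' @export
parseVcf <- function(path, panel = loadDefaultPanel()) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("parseVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt) || ncol(gt) == 0L)
    stop("VCF has no sample genotype (GT) columns: ", path)
  ids <- rownames(gt)
  inPanel <- ids %in% panelSites(panel)$rsid
  if (any(!inPanel))
    message("[genotype_panel] ignoring ", sum(!inPanel),
            " non-panel site(s) in VCF")
  if (!any(inPanel))
    warning("VCF contains no panel sites; patients have zero calls")
  gt <- gt[inPanel, , drop = FALSE]
  if (nrow(gt) == 0L) {
    calls <- data.frame(patient_id = character(0), rsid = character(0),
                        genotype_class = character(0),
                        alleles = character(0), stringsAsFactors = FALSE)
    cn <- rep(2, ncol(gt)); names(cn) <- colnames(gt)
    return(new("GenotypeCohort", calls = calls, copyNumber = cn))
  }
  cls <- apply(gt, c(1, 2), function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (!length(al) || any(al == ".")) return("no_call")
    nAlt <- sum(al != "0")
    if (nAlt == 0) "ref_homozygous"
    else if (nAlt == length(al)) "variant_homozygous"
    else "heterozygous"
  })
  calls <- data.frame(
    patient_id = rep(colnames(gt), each = nrow(gt)),
    rsid = rep(rownames(gt), times = ncol(gt)),
    genotype_class = as.vector(cls),
    alleles = as.vector(gt),
    stringsAsFactors = FALSE)
  cn <- rep(2, ncol(gt)); names(cn) <- colnames(gt)
  new("GenotypeCohort", calls = calls, copyNumber = cn)
}

#' Validate a genotype cohort against a panel
#'
#' Report-only quality check: per patient, the panel sites with no data, the
#' no-call fraction, any rsIDs absent from the panel, and flags. Patients
#' whose missing + no-call fraction exceeds \code{missingnessThreshold} are
#' flagged, not dropped; a patient with no usable CYP2D6 call gets a
#' \code{"CYP2D6 uncallable"} flag (likewise CYP2C19). Calls at the
#' placeholder row \code{UNASSIGNED_ROW8} are flagged as such.
#'
#' @param genotypes a [GenotypeCohort-class].
#' @param panel a [PgxPanel-class].
#' @param missingnessThreshold flag patients whose fraction of panel sites
#'   without a usable call exceeds this (default 0.2).
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{n_missing_sites}, \code{no_call_fraction}, \code{unknown_rsids}
#'   (comma-separated), \code{flags} (semicolon-separated), \code{flagged}.
#' @export
validateCohort <- function(genotypes, panel, missingnessThreshold = 0.2) {
  sites <- panelSites(panel)
  panelKeys <- unique(sites$rsid)
  calls <- genotypeCalls(genotypes)
  res <- lapply(patientIDs(genotypes), function(id) {
    mine <- calls[calls$patient_id == id, ]
    missing <- setdiff(panelKeys, mine$rsid)
    onPanel <- mine$rsid %in% panelKeys
    unknown <- unique(mine$rsid[!onPanel])
    nNoCall <- sum(mine$genotype_class[onPanel] == "no_call")
    frac <- (length(missing) + nNoCall) / length(panelKeys)
    flags <- character()
    for (g in c("CYP2D6", "CYP2C19")) {
      gs <- sites$rsid[sites$gene == g]
      usable <- mine$rsid %in% gs & mine$genotype_class != "no_call"
      if (!any(usable)) flags <- c(flags, paste(g, "uncallable"))
    }
    if (frac > missingnessThreshold)
      flags <- c(flags, sprintf("missingness %.2f above threshold", frac))
    if (any(mine$rsid %in% sites$rsid[sites$gene == "UNASSIGNED_ROW8"]))
      flags <- c(flags, "call at unassigned panel row (UNASSIGNED_ROW8)")
    data.frame(patient_id = id, n_missing_sites = length(missing),
               no_call_fraction = nNoCall / length(panelKeys),
               unknown_rsids = paste(unknown, collapse = ","),
               flags = paste(flags, collapse = ";"),
               flagged = frac > missingnessThreshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
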