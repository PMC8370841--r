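## shared fixtures, built in code at test time

`%||%` <- function(a, b) if (is.null(a)) b else a

fixPanel <- loadDefaultPanel()
fixTable <- loadTranslationTable()

## write a genotype table for the given (patient, rsid, genotype) rows
writeGenotypeFixture <- function(rows, path = tempfile(fileext = ".tsv"),
                                 sep = "\t") {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(patient_id = r[1], rsid = r[2], genotype = r[3],
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

## a minimal VCF 4.2 body; gts: named list sample -> character vector of GTs
writeVcfFixture <- function(ids, gts, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", names(gts)), collapse = "\t"))
  body <- vapply(seq_along(ids), function(i)
    paste(c("1", as.character(1000 + i), ids[i], "G", "A", ".", ".", ".",
            "GT", vapply(gts, `[`, character(1), i)), collapse = "\t"),
    character(1))
  writeLines(c(hdr, body), path)
  path
}

## genotype class vector with every panel site reference-homozygous
allRefCalls <- function(panel = fixPanel) {
  sites <- unique(panelSites(panel)$rsid)
  v <- rep("ref_homozygous", length(sites))
  names(v) <- sites
  v
}

## a small deterministic questionnaire data.frame
questionnaireFixture <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3", "P1"),
    timepoint = c("baseline", "baseline", "baseline", "followup"),
    mood_category = c("unable", "force_myself", "feel_good", "feel_good"),
    mood_sublevel = c("high", "low", "", ""),
    side_effects = c("fatigue;dizziness;insomnia", "fatigue", "", ""),
    stringsAsFactors = FALSE)
}

## independent brute-force diplotype matcher: exhaustive search over allele
## pairs, maximizing represented variant copies, then minimal activity,
## then lowest star numbers
bruteDiplotype <- function(gene, calls, table = fixTable) {
  defs <- table@alleles[table@alleles$gene == gene, , drop = FALSE]
  state <- calls[defs$rsid]
  usable <- !is.na(state) & state != "no_call"
  if (!any(usable)) return(list(diplotype = NA_character_,
                                activity = NA_real_))
  dosage <- ifelse(is.na(state), 0L,
                   ifelse(state == "heterozygous", 1L,
                          ifelse(state == "variant_homozygous", 2L, 0L)))
  alleles <- rbind(defs[, c("star_allele", "activity")],
                   data.frame(star_allele = "*1", activity = 1))
  starNum <- as.numeric(sub("^\\*([0-9]+).*$", "\\1",
                            alleles$star_allele))
  best <- NULL
  for (i in seq_len(nrow(alleles))) for (j in i:nrow(alleles)) {
    pair <- alleles$star_allele[c(i, j)]
    nCopies <- vapply(defs$star_allele, function(s) sum(pair == s),
                      numeric(1))
    if (any(nCopies > dosage)) next        # can't assign uncarried alleles
    represented <- sum(pmin(nCopies, dosage))
    key <- c(-represented, alleles$activity[i] + alleles$activity[j],
             sort(starNum[c(i, j)]))
    if (is.null(best) || .lexLess(key, best$key))
      best <- list(pair = pair, key = key,
                   activity = alleles$activity[i] + alleles$activity[j])
  }
  ord <- order(as.numeric(sub("^\\*([0-9]+).*$", "\\1", best$pair)))
  list(diplotype = paste(best$pair[ord], collapse = "/"),
       activity = best$activity)
}

.lexLess <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

## brute-force exact two-sided signed-rank p over all 2^n sign masks
bruteExactWilcoxonP <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    w <- sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
    if (abs(w - mu) >= abs(wObs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}

## brute-force AUC by pair counting (ties count 1/2)
bruteAuc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

## brute-force mid-rank Spearman: average ranks computed by hand
bruteSpearmanRho <- function(x, y) {
  midrank <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v))
      out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    out
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
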