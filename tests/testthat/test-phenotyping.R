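test_that("diplotype calling handles reference, het, hom and missing input", {
  allRef <- allRefCalls()
  d <- callDiplotype("CYP2C19", allRef, fixTable)
  expect_equal(d$diplotype, "*1/*1")
  expect_equal(d$activity, 2)

  het2 <- allRef; het2["rs4244285"] <- "heterozygous"
  d <- callDiplotype("CYP2C19", het2, fixTable)
  expect_equal(d$diplotype, "*1/*2")
  expect_equal(d$activity, 1)

  hom4 <- allRef; hom4["rs3892097"] <- "variant_homozygous"
  d <- callDiplotype("CYP2D6", hom4, fixTable)
  expect_equal(d$diplotype, "*4/*4")
  expect_equal(d$activity, 0)

  # unphased het/het at two no-function sites goes in trans (conservative)
  two <- allRef
  two[c("rs4244285", "rs12248560")] <- "heterozygous"
  d <- callDiplotype("CYP2C19", two, fixTable)
  expect_equal(d$diplotype, "*2/*17")

  noCall <- allRef
  noCall[fixTable@alleles$rsid[fixTable@alleles$gene == "CYP2C19"]] <-
    "no_call"
  d <- callDiplotype("CYP2C19", noCall, fixTable)
  expect_true(d$indeterminate)

  # CYP2D6 copy-number scaling of the activity score
  d <- callDiplotype("CYP2D6", allRef, fixTable, copyNumber = 3)
  expect_equal(d$activity, 3)
})

test_that("diplotype calls match an exhaustive brute-force matcher", {
  # all genotype combinations at three defining sites per gene
  states <- c("ref_homozygous", "heterozygous", "variant_homozygous")
  cases <- expand.grid(s1 = states, s2 = states, s3 = states,
                       stringsAsFactors = FALSE)
  siteSets <- list(
    CYP2C19 = c("rs4244285", "rs4986893", "rs12248560"),
    CYP2D6 = c("rs3892097", "rs28371725", "rs16947"))
  for (gene in names(siteSets)) {
    for (i in seq_len(nrow(cases))) {
      calls <- allRefCalls()
      calls[siteSets[[gene]]] <- unlist(cases[i, ])
      got <- callDiplotype(gene, calls, fixTable)
      want <- bruteDiplotype(gene, calls, fixTable)
      expect_equal(got$diplotype, want$diplotype,
                   info = paste(gene, paste(cases[i, ], collapse = "/")))
      expect_equal(got$activity, want$activity,
                   info = paste(gene, paste(cases[i, ], collapse = "/")))
    }
  }
})

test_that("activity maps to phenotype with the documented cutpoints", {
  expect_equal(phenotypeFromActivity("CYP2C19", 0), "poor")
  expect_equal(phenotypeFromActivity("CYP2C19", 1.0), "intermediate")
  expect_equal(phenotypeFromActivity("CYP2C19", 1.25), "normal")
  expect_equal(phenotypeFromActivity("CYP2C19", 2.0), "normal")
  expect_equal(phenotypeFromActivity("CYP2C19", 2.25), "normal")
  expect_equal(phenotypeFromActivity("CYP2C19", 2.5), "ultrarapid")
  expect_equal(phenotypeFromActivity("CYP2C19", NA), "indeterminate")
  expect_error(phenotypeFromActivity("CYP2C19", -1), "non-negative")

  # CYP2C19 *17 homozygote gate
  expect_equal(
    phenotypeFromActivity("CYP2C19", 2.0,
                          rs12248560State = "variant_homozygous"),
    "ultrarapid")

  # CYP2D6 ultrarapid needs declared duplications
  expect_message(
    ph <- phenotypeFromActivity("CYP2D6", 3, copyNumber = 2),
    "copy number")
  expect_equal(ph, "normal")
  expect_equal(phenotypeFromActivity("CYP2D6", 3, copyNumber = 3),
               "ultrarapid")
})

test_that("every CYP2C19 phenotype class is reachable from panel genotypes", {
  mk <- function(rsid, state) {
    calls <- allRefCalls()
    calls[rsid] <- state
    c19 <- callDiplotype("CYP2C19", calls, fixTable)
    phenotypeFromActivity("CYP2C19", c19$activity,
                          rs12248560State = calls[["rs12248560"]])
  }
  expect_equal(mk("rs4244285", "variant_homozygous"), "poor")
  expect_equal(mk("rs4244285", "heterozygous"), "intermediate")
  expect_equal(mk("rs4244285", "ref_homozygous"), "normal")
  expect_equal(mk("rs12248560", "variant_homozygous"), "ultrarapid")
})

test_that("PD variant counting is zygosity-insensitive and deduplicated", {
  calls <- allRefCalls()
  expect_equal(countPdVariants(calls, fixPanel), 0)

  calls[c("rs6265", "rs4680")] <- "heterozygous"
  expect_equal(countPdVariants(calls, fixPanel), 2)

  calls <- allRefCalls()
  calls["rs1045642"] <- "variant_homozygous"
  expect_equal(countPdVariants(calls, fixPanel), 1)

  # rs2952768 appears under three panel genes but counts once
  calls <- allRefCalls()
  calls["rs2952768"] <- "heterozygous"
  expect_equal(countPdVariants(calls, fixPanel), 1)

  # PK-enzyme and non-scored variants never enter the PD tally
  calls <- allRefCalls()
  calls[c("rs1799853", "rs6025", "rs4244285")] <- "variant_homozygous"
  expect_equal(countPdVariants(calls, fixPanel), 0)

  # no-call sites contribute nothing; adding a variant never decreases it
  calls <- allRefCalls()
  pd <- c("rs6265", "rs4680", "rs6295", "rs1045642", "rs5443")
  prev <- countPdVariants(calls, fixPanel)
  for (site in pd) {
    calls[site] <- "heterozygous"
    now <- countPdVariants(calls, fixPanel)
    expect_gte(now, prev)
    prev <- now
  }
  calls[pd] <- "no_call"
  expect_equal(countPdVariants(calls, fixPanel), 0)
})

test_that("profiles assemble phenotypes, counts and profile type", {
  rows <- list(
    # PK-only: CYP2C19 *1/*2 intermediate, no PD variants
    c("PK", "rs4244285", "G/A"),
    # PD-only: all PK normal, three PD variants
    c("PD", "rs6265", "G/A"), c("PD", "rs4680", "A/A"),
    c("PD", "rs1045642", "C/T"),
    # both: CYP2D6 poor plus two PD variants
    c("BO", "rs3892097", "A/A"), c("BO", "rs6265", "G/A"),
    c("BO", "rs4680", "G/A"),
    # none: a lone reference call
    c("NO", "rs4244285", "G/G"))
  # patients lacking calls for one of the PK genes are indeterminate there,
  # which buildProfile flags and treats as normal
  prof <- profileTable(suppressWarnings(buildProfile(parseGenotypeTable(
    writeGenotypeFixture(rows)), fixPanel, fixTable)))
  rownames(prof) <- prof$patient_id
  expect_equal(prof["PK", "cyp2c19"], "intermediate")
  expect_equal(prof["PK", "profile_type"], "pharmacokinetic")
  expect_equal(prof["PD", "pd_variant_count"], 3L)
  expect_equal(prof["PD", "profile_type"], "pharmacodynamic")
  expect_equal(prof["BO", "cyp2d6"], "poor")
  expect_equal(prof["BO", "profile_type"], "both")
  expect_equal(prof["NO", "profile_type"], "none")

  # determinism: identical genotypes give identical profiles
  prof2 <- profileTable(suppressWarnings(buildProfile(parseGenotypeTable(
    writeGenotypeFixture(rows)), fixPanel, fixTable)))
  rownames(prof2) <- prof2$patient_id
  expect_identical(prof, prof2)
})

test_that("indeterminate phenotypes degrade to normal with a warning", {
  expect_warning(p <- phenotypeProfile("indeterminate", "poor", 2),
                 "indeterminate")
  expect_equal(profileTable(p)$profile_type, "both")
  expect_warning(p2 <- phenotypeProfile("indeterminate", "normal", 0),
                 "indeterminate")
  expect_equal(profileTable(p2)$profile_type, "none")
})
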