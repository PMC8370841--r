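test_that("the paired Wilcoxon test matches stats::wilcox.test conventions", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    b <- round(rnorm(n, 8, 1.5), 2)
    f <- round(rnorm(n, 3, 1.5), 2)
    keep <- b != f
    b <- b[keep]; f <- f[keep]
    if (length(b) < 5) next
    got <- wilcoxonPaired(b, f)
    ref <- suppressWarnings(stats::wilcox.test(b, f, paired = TRUE,
                                               exact = FALSE,
                                               correct = FALSE))
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
    # V is the positive rank sum; W is the smaller of the two sums
    d <- b - f
    r <- rank(abs(d))
    expect_equal(got$W_statistic, min(sum(r[d > 0]), sum(r[d < 0])))
  }
})

test_that("degenerate and zero-difference pairs are handled as specified", {
  expect_error(wilcoxonPaired(c(5, 4, 3, 2, 1), c(5, 4, 3, 2, 1)),
               "degenerate")
  expect_message(res <- wilcoxonPaired(c(5, 4, 3, 2, 1, 9),
                                       c(5, 1, 1, 1, 0, 2)),
                 "zero-difference")
  expect_equal(res$n_pairs, 5)
  expect_equal(res$n_zero_dropped, 1)
})

test_that("exact-mode p equals the brute-force 2^n sign enumeration", {
  # six pairs with a single sign flip
  b <- c(9, 8, 9, 10, 7, 8)
  f <- c(3, 4, 2, 7, 8, 3)     # one negative difference, untied magnitudes
  got <- wilcoxonPaired(b, f, exact = TRUE)
  expect_equal(got$p_value, bruteExactWilcoxonP(b - f))
  ref <- stats::wilcox.test(b, f, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, unname(ref$p.value))

  set.seed(7)
  for (i in 1:5) {
    d <- sample(1:50, 8) * sample(c(-1, 1), 8, replace = TRUE)
    got <- wilcoxonPaired(d, rep(0, 8), exact = TRUE)
    expect_equal(got$p_value, bruteExactWilcoxonP(d))
  }
})

test_that("normal and exact Wilcoxon p agree on rejection for small n", {
  set.seed(42)
  agree <- 0; total <- 200
  for (i in seq_len(total)) {
    n <- sample(6:10, 1)
    d <- sample(1:100, n) * sample(c(-1, 1), n, replace = TRUE,
                                   prob = c(0.35, 0.65))
    pN <- wilcoxonPaired(d, rep(0, n))$p_value
    pE <- wilcoxonPaired(d, rep(0, n), exact = TRUE)$p_value
    agree <- agree + ((pN < 0.05) == (pE < 0.05))
  }
  expect_gte(agree / total, 0.95)
})

test_that("one-signed untied designs give the closed-form effect size", {
  for (n in c(5, 10, 46, 100)) {
    b <- 10 * seq_len(n)
    f <- b - seq_len(n)          # distinct positive differences
    res <- wilcoxonPaired(b, f)
    zClosed <- (n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    expect_equal(abs(res$Z), zClosed, tolerance = 1e-12)
    expect_equal(res$effect_size_r, zClosed / sqrt(2 * n),
                 tolerance = 1e-12)
    # the "pairs" convention divides by sqrt(n) instead
    expect_equal(wilcoxonPaired(b, f,
                                rConvention = "pairs")$effect_size_r,
                 zClosed / sqrt(n), tolerance = 1e-12)
  }
})

test_that("Spearman correlation equals the mid-rank oracle and cor.test", {
  expect_equal(spearmanCorrelation(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearmanCorrelation(1:4, c(4, 3, 2, 1))$rho, -1)
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "zero variance")

  set.seed(5)
  for (i in 1:10) {
    x <- sample(1:5, 8, replace = TRUE)   # heavy ties
    y <- sample(1:4, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearmanCorrelation(x, y)
    expect_equal(got$rho, bruteSpearmanRho(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- rnorm(30); y <- x + rnorm(30)
  base <- spearmanCorrelation(x, y)$rho
  expect_equal(spearmanCorrelation(exp(x), y)$rho, base)
  expect_equal(spearmanCorrelation(x, y^3 + 5 * y)$rho, base)
  expect_equal(spearmanCorrelation(rank(x), y)$rho, base)
})

test_that("empirical AUC equals brute-force pair counting", {
  scores <- c(1, 2, 2, 3, 5, 5, 6, 7, 7, 9)
  labels <- c(0, 0, 1, 0, 1, 0, 1, 0, 1, 1)
  expect_equal(empiricalAuc(scores, labels), bruteAuc(scores, labels))
  # and with a tied mass plus perfect separation corner cases
  expect_equal(empiricalAuc(rep(3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(empiricalAuc(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1)), 1)
  set.seed(12)
  for (i in 1:5) {
    s <- sample(1:6, 30, replace = TRUE)
    l <- rbinom(30, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(empiricalAuc(s, l), bruteAuc(s, l))
  }
})

test_that("empirical AUC agrees with pROC on a fixture", {
  set.seed(3)
  s <- rnorm(50)
  l <- rbinom(50, 1, plogis(s))
  ref <- suppressMessages(pROC::auc(pROC::roc(l, s, quiet = TRUE)))
  expect_equal(empiricalAuc(s, l), as.numeric(ref), tolerance = 1e-12)
})

test_that("bootstrap-smoothed ROC is reproducible and converges", {
  s <- c(1, 3, 2, 8, 9, 4, 7, 6, 5, 10, 2, 9)
  l <- c(0, 0, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0)
  r1 <- rocBootstrapSmoothed(s, l, nBoot = 50, seed = 99)
  r2 <- rocBootstrapSmoothed(s, l, nBoot = 50, seed = 99)
  expect_identical(r1, r2)
  expect_false(identical(
    r1$mean_tpr, rocBootstrapSmoothed(s, l, nBoot = 50, seed = 100)$mean_tpr))
  # curve sanity: monotone, anchored, trapezoid-consistent
  expect_true(all(diff(r1$mean_tpr) >= 0))
  expect_equal(r1$auc, sum(diff(r1$fpr_grid) *
                             (head(r1$mean_tpr, -1) +
                                tail(r1$mean_tpr, -1)) / 2))

  # perfect separation survives resampling
  expect_equal(rocBootstrapSmoothed(c(1, 2, 3, 11, 12, 13),
                                    c(0, 0, 0, 1, 1, 1),
                                    nBoot = 25, seed = 1)$auc, 1)

  # convergence to the empirical AUC as resamples grow
  emp <- empiricalAuc(s, l)
  d10 <- abs(rocBootstrapSmoothed(s, l, nBoot = 10, seed = 5)$auc - emp)
  d1000 <- abs(rocBootstrapSmoothed(s, l, nBoot = 1000, seed = 5)$auc - emp)
  expect_lt(d1000, d10)

  expect_error(rocBootstrapSmoothed(1:5, rep(1, 5), 10, 1), "degenerate")
})

test_that("the smoothed AUC is near 0.5 when labels carry no signal", {
  set.seed(2024)
  s <- rnorm(2000)
  l <- rbinom(2000, 1, 0.5)
  res <- rocBootstrapSmoothed(s, l, nBoot = 200, seed = 77)
  expect_lt(abs(res$auc - 0.5), 0.03)
})

test_that("dichotomization applies the threshold rule", {
  expect_equal(dichotomizeEffectiveness(c(9, 7, 8), 8), c(1L, 0L, 1L))
  expect_equal(dichotomizeEffectiveness(c(4, 9), 1), c(1L, 1L))
  expect_equal(dichotomizeEffectiveness(c(4, 9), 10), c(0L, 0L))
  expect_error(dichotomizeEffectiveness(5, 0), "threshold")
})

test_that("the cohort summary reports counts, means and SDs as displayed", {
  tab <- data.frame(
    patient_id = c("A", "B"),
    age = c(30, 40), sex = c("Female", "Female"),
    ethnicity = c("Asian", "Caucasian"),
    profile_type = c("both", "pharmacokinetic"),
    genetic_total = c(10, 6),
    baseline_total = c(9, 8), followup_total = c(NA, NA),
    stringsAsFactors = FALSE)
  s <- summarizeCohort(tab)
  expect_equal(unname(s$all$age[["mean"]]), 35)
  expect_equal(unname(s$all$age[["sd"]]), sd(c(30, 40)))
  expect_equal(s$all$sex$n[s$all$sex$level == "Female"], 2)
  expect_equal(s$all$sex$pct[s$all$sex$level == "Female"], 100)
  # empty follow-up subset renders as missing markers
  expect_equal(s$followup$n, 0)
  expect_true(all(s$table2$followup_subset[9:12] == "-"))

  one <- summarizeCohort(tab[1, , drop = FALSE])
  expect_equal(one$all$sex$n, c(1, 0))
  expect_equal(one$all$sex$pct, c(100, 0))
})
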