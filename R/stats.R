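#' Paired Wilcoxon signed-rank test with effect size r
#'
#' Compares paired baseline and follow-up measurements. Zero differences
#' are dropped before ranking (signed-rank convention, with a logged
#' count); absolute differences are mid-ranked. The reported statistic W is
#' the smaller of the positive and negative rank sums. The normal
#' approximation uses the tie-corrected variance and no continuity
#' correction; the two-sided p-value follows. The effect size is by default
#' r = |Z| / sqrt(2 n), i.e. standardized by the total number of
#' observations (two per pair); \code{rConvention = "pairs"} switches to
#' |Z| / sqrt(n).
#'
#' With \code{exact = TRUE} (no ties among the absolute differences,
#' n <= 16) the two-sided p-value is computed by full enumeration of all
#' 2^n sign assignments instead of the normal approximation.
#'
#' @param baseline,followup equal-length numeric vectors (>= 5 pairs).
#' @param rConvention \code{"total"} (default) or \code{"pairs"}.
#' @param exact use exact enumeration for the p-value.
#' @return list of class \code{"WilcoxonResult"}: \code{n_pairs} (non-zero
#'   differences), \code{n_zero_dropped}, \code{W_statistic}, \code{Z},
#'   \code{p_value}, \code{effect_size_r}, \code{method}.
#' @examples
#' wilcoxonPaired(c(8, 9, 7, 10, 9, 8), c(3, 2, 2, 4, 1, 3))
#' @export
wilcoxonPaired <- function(baseline, followup, rConvention = c("total",
                                                               "pairs"),
                           exact = FALSE) {
  rConvention <- match.arg(rConvention)
  if (length(baseline) != length(followup))
    stop("baseline and followup must have equal length")
  if (length(baseline) < 5)
    stop("need at least 5 pairs")
  d <- baseline - followup
  nZero <- sum(d == 0)
  if (nZero) {
    message("[cohort_stats] dropping ", nZero, " zero-difference pair(s)")
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0)
    stop("degenerate input: all paired differences are zero")
  r <- rank(abs(d))
  wPlus <- sum(r[d > 0])
  wMinus <- sum(r[d < 0])
  W <- min(wPlus, wMinus)
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  Z <- (wPlus - mu) / sqrt(sigma2)
  if (exact) {
    if (any(duplicated(abs(d))))
      stop("exact p-value requires untied absolute differences")
    if (n > 16) stop("exact enumeration limited to n <= 16 pairs")
    p <- .wilcoxonExactP(r[d > 0], n)
    method <- "exact enumeration"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
    method <- "normal approximation, tie-corrected, no continuity correction"
  }
  er <- abs(Z) / sqrt(if (rConvention == "total") 2 * n else n)
  structure(list(n_pairs = n, n_zero_dropped = nZero, W_statistic = W,
                 Z = Z, p_value = p, effect_size_r = er, method = method),
            class = "WilcoxonResult")
}

## exact two-sided p by enumerating all 2^n sign assignments of ranks 1..n
.wilcoxonExactP <- function(posRanks, n) {
  wObs <- sum(posRanks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- as.vector(signs %*% seq_len(n))
  mu <- n * (n + 1) / 4
  min(1, mean(abs(wAll - mu) >= abs(wObs - mu) - 1e-9))
}

#' @export
print.WilcoxonResult <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d pairs (%d zero differences dropped)\n",
              x$n_pairs, x$n_zero_dropped))
  cat(sprintf("  W = %.1f, Z = %.3f, p = %.4g, effect size r = %.3f\n",
              x$W_statistic, x$Z, x$p_value, x$effect_size_r))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' p-value from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @return list of class \code{"SpearmanResult"}: \code{rho},
#'   \code{p_value}, \code{n}.
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "SpearmanResult")
}

#' @export
print.SpearmanResult <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %.4g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

## empirical ROC points (fpr, tpr) over decreasing score thresholds
.empiricalRocPoints <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # one point per threshold
  data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                          utils::tail(y, -1)) / 2)

#' Empirical ROC AUC
#'
#' Trapezoidal area under the empirical ROC curve (ties produce diagonal
#' segments), which equals the Mann-Whitney U statistic divided by
#' n1 * n0.
#'
#' @param scores numeric predictor.
#' @param labels binary 0/1 outcome vector.
#' @return AUC in [0, 1].
#' @export
empiricalAuc <- function(scores, labels) {
  .checkBinary(labels)
  pts <- .empiricalRocPoints(scores, labels)
  .trapz(pts$fpr, pts$tpr)
}

.checkBinary <- function(labels) {
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2)
    stop("degenerate input: both classes must be present")
}

#' Bootstrap-smoothed ROC curve
#'
#' Draws class-stratified bootstrap resamples, computes each resample's
#' empirical ROC, linearly interpolates its TPR on a fixed 101-point FPR
#' grid, and averages across resamples. The smoothed AUC is the trapezoidal
#' area of the averaged curve (after a monotone cummax cleanup). Fully
#' reproducible for a given seed; as n_boot grows the smoothed AUC
#' converges to the empirical AUC of the data.
#'
#' @param scores numeric predictor.
#' @param labels binary 0/1 outcome vector (both classes required).
#' @param nBoot number of bootstrap resamples (>= 1; default 1000).
#' @param seed RNG seed (default 20180501).
#' @return list of class \code{"RocResult"}: \code{auc}, \code{fpr_grid},
#'   \code{mean_tpr}, \code{n_boot}, \code{seed}.
#' @export
rocBootstrapSmoothed <- function(scores, labels, nBoot = 1000,
                                 seed = 20180501) {
  .checkBinary(labels)
  if (nBoot < 1) stop("nBoot must be >= 1")
  grid <- seq(0, 1, length.out = 101)
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  tprMat <- matrix(NA_real_, nrow = nBoot, ncol = length(grid))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  for (b in seq_len(nBoot)) {
    idx <- c(i1[sample.int(length(i1), replace = TRUE)],
             i0[sample.int(length(i0), replace = TRUE)])
    pts <- .empiricalRocPoints(scores[idx], labels[idx])
    tprMat[b, ] <- stats::approx(pts$fpr, pts$tpr, xout = grid,
                                 ties = max, rule = 2)$y
  }
  meanTpr <- cummax(colMeans(tprMat))
  structure(list(auc = .trapz(grid, meanTpr), fpr_grid = grid,
                 mean_tpr = meanTpr, n_boot = nBoot, seed = seed),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf(
    "Bootstrap-smoothed ROC: AUC = %.3f (%d resamples, seed %d)\n",
    x$auc, x$n_boot, x$seed))
  invisible(x)
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Dichotomize effectiveness scores
#'
#' Labels a score "high" (1) when it reaches the threshold, default 8
#' (the configurable anchor near the typical baseline mean); used to build
#' the binary outcome for the ROC analysis.
#'
#' @param scores numeric vector of effectiveness totals.
#' @param threshold cut point in [1, 10]; label 1 iff score >= threshold.
#' @return integer 0/1 vector.
#' @export
dichotomizeEffectiveness <- function(scores, threshold = 8) {
  if (threshold < 1 || threshold > 10)
    stop("threshold must lie in [1, 10]")
  as.integer(scores >= threshold)
}

.meanSd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
  c(mean = mean(x), sd = stats::sd(x), n = length(x))
}

.countPct <- function(values, levels, denom) {
  n <- vapply(levels, function(l) sum(values == l, na.rm = TRUE),
              numeric(1))
  data.frame(level = levels, n = n,
             pct = if (denom > 0) 100 * n / denom else rep(0, length(n)),
             stringsAsFactors = FALSE)
}

#' Descriptive cohort summary
#'
#' Produces the study-table layout for the full cohort and the follow-up
#' subset side by side: counts and percentages by sex, ethnicity and
#' pharmacogenomic profile type (denominator = full column size, so
#' unreported categories make columns sum below 100%), and mean/SD (n - 1
#' denominator) of age, genetic mutation score and the baseline/follow-up
#' effectiveness totals.
#'
#' @param cohortTable data.frame with one row per patient and columns
#'   \code{patient_id}, \code{age}, \code{sex}, \code{ethnicity},
#'   \code{profile_type}, \code{genetic_total}, \code{baseline_total},
#'   \code{followup_total} (NA when not followed up).
#' @return list of class \code{"CohortSummary"}: \code{all} and
#'   \code{followup} sub-lists (counts tables and mean/SD entries) plus
#'   \code{table2}, a flat formatted data.frame.
#' @export
summarizeCohort <- function(cohortTable) {
  one <- function(d) {
    denom <- nrow(d)
    list(n = denom,
         sex = .countPct(d$sex, c("Female", "Male"), denom),
         ethnicity = .countPct(d$ethnicity,
                               c("Asian", "Caucasian", "Other"), denom),
         profile = .countPct(d$profile_type,
                             c("both", "pharmacodynamic",
                               "pharmacokinetic", "none"), denom),
         age = .meanSd(d$age),
         genetic = .meanSd(d$genetic_total),
         baseline = .meanSd(d$baseline_total),
         followup = .meanSd(d$followup_total))
  }
  all <- one(cohortTable)
  fu <- one(cohortTable[!is.na(cohortTable$followup_total), , drop = FALSE])
  fmtN <- function(s, lev) {
    i <- match(lev, s$level)
    sprintf("%d (%.1f)", s$n[i], s$pct[i])
  }
  fmtM <- function(m) if (m[["n"]] == 0) "-" else
    sprintf("%.2f (%.2f)", m[["mean"]], m[["sd"]])
  rows <- c(paste0(c("Female", "Male"), ", n (%)"),
            paste0(c("Asian", "Caucasian", "Other"), ", n (%)"),
            paste0(c("Both", "Pharmacodynamic", "Pharmacokinetic"),
                   ", n (%)"),
            "Age in years, Mean (SD)", "Genetic mutation score, Mean (SD)",
            "Baseline effectiveness, Mean (SD)",
            "Follow-up effectiveness, Mean (SD)")
  col <- function(s)
    c(fmtN(s$sex, c("Female", "Male")),
      fmtN(s$ethnicity, c("Asian", "Caucasian", "Other")),
      fmtN(s$profile, c("both", "pharmacodynamic", "pharmacokinetic")),
      fmtM(s$age), fmtM(s$genetic), fmtM(s$baseline), fmtM(s$followup))
  table2 <- data.frame(characteristic = rows,
                       all_patients = col(all),
                       followup_subset = col(fu),
                       stringsAsFactors = FALSE)
  structure(list(all = all, followup = fu, table2 = table2),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d patients, %d with follow-up\n",
              x$all$n, x$followup$n))
  print(x$table2, row.names = FALSE)
  invisible(x)
}
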