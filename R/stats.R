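# Classification metrics and cohort statistics: exact binomial intervals,
# one-vs-rest multiclass ROC-AUC, and the paired/unpaired tests used to
# compare models and cross-validation cohorts.  Test results are returned
# as base-R `htest` objects.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact beta-quantile interval for a binomial proportion: the lower bound
#' is 0 when `k = 0` and the upper bound 1 when `k = n`.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials.
#' @param level confidence level in (0, 1).
#' @return object of class `binomial_ci`: `k`, `n`, `level`, `estimate`,
#'   `lower`, `upper`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k))
    stop("invalid k/n")
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  structure(list(k = k, n = n, level = level, estimate = k / n,
                 lower = lower, upper = upper),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f (%.0f%% CI: %.3f, %.3f), Clopper-Pearson\n",
              x$k, x$n, x$estimate, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from a confusion table
#'
#' For a `K x K` confusion table (rows = true stage, columns = predicted):
#' accuracy is `trace/total` with a Clopper-Pearson interval; sensitivity
#' and specificity are macro-averages of the per-stage one-vs-rest recall
#' and true-negative rate.  Stages absent from the cohort are dropped from
#' the macro averages with a warning.
#'
#' @param table square integer matrix of counts.
#' @param level confidence level for the accuracy interval.
#' @return list with `acc`, `acc_ci` ([clopper_pearson()]), `sen`, `spe`,
#'   and per-class vectors `sen_class`, `spe_class`.
#' @export
acc_sen_spe <- function(table, level = 0.95) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == ncol(table), all(table >= 0))
  total <- sum(table)
  if (total == 0) stop("empty confusion table")
  correct <- sum(diag(table))
  acc <- correct / total
  K <- nrow(table)
  sen_c <- spe_c <- rep(NA_real_, K)
  for (cl in seq_len(K)) {
    pos <- sum(table[cl, ])
    tp <- table[cl, cl]
    fp <- sum(table[-cl, cl])
    tn <- total - pos - fp
    if (pos > 0) sen_c[cl] <- tp / pos
    spe_c[cl] <- tn / (total - pos)
  }
  if (anyNA(sen_c))
    warning("empty class excluded from macro averages")
  list(acc = acc, acc_ci = clopper_pearson(correct, total, level),
       sen = mean(sen_c, na.rm = TRUE), spe = mean(spe_c, na.rm = TRUE),
       sen_class = sen_c, spe_class = spe_c)
}

# mid-rank AUC of scores for a binary indicator
.auc_rank <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("degenerate class counts")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest multiclass ROC-AUC
#'
#' Micro-average: a single AUC on the flattened one-vs-rest
#' indicator/score pairs (every class of every case contributes one pair).
#' Macro-average: the unweighted mean of the per-class one-vs-rest AUCs.
#' Ties are handled by mid-ranks.
#'
#' @param stage_probs numeric matrix, cases x classes.
#' @param labels integer class per case (1-based).
#' @param average `"micro"` or `"macro"`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc_ovr <- function(stage_probs, labels, average = c("micro", "macro")) {
  average <- match.arg(average)
  stage_probs <- as.matrix(stage_probs)
  K <- ncol(stage_probs)
  ind <- matrix(0L, nrow(stage_probs), K)
  ind[cbind(seq_along(labels), labels)] <- 1L
  if (average == "micro") {
    .auc_rank(as.numeric(stage_probs), as.numeric(ind) == 1L)
  } else {
    aucs <- vapply(seq_len(K), function(cl) {
      if (sum(ind[, cl]) == 0L || sum(ind[, cl]) == nrow(ind))
        stop("macro average requires every class present")
      .auc_rank(stage_probs[, cl], ind[, cl] == 1L)
    }, numeric(1))
    mean(aucs)
  }
}

# DeLong structural components: per-case placement values and the
# variance/covariance of correlated AUCs.
.delong_components <- function(scores, labels) {
  pos <- which(labels); neg <- which(!labels)
  m <- length(pos); n <- length(neg)
  x <- scores[pos]; y <- scores[neg]
  v10 <- vapply(x, function(xi)
    (sum(xi > y) + 0.5 * sum(xi == y)) / n, numeric(1))
  v01 <- vapply(y, function(yj)
    (sum(x > yj) + 0.5 * sum(x == yj)) / m, numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

# variance of a single AUC from its structural components
.delong_var <- function(comp) {
  stats::var(comp$v10) / comp$m + stats::var(comp$v01) / comp$n
}

#' DeLong test for two correlated AUCs
#'
#' Compares the ROC-AUCs of two score vectors evaluated on the same cases
#' using the asymptotic normal difference with structural-component
#' covariance.
#'
#' @param scores_a,scores_b paired per-case scores.
#' @param binary_labels logical (or 0/1) outcome per case; at least two
#'   cases per class.
#' @return an `htest` with the z statistic, two-sided p-value, and the two
#'   AUCs as estimates.
#' @export
delong_test <- function(scores_a, scores_b, binary_labels) {
  lab <- as.logical(binary_labels)
  if (sum(lab) < 2 || sum(!lab) < 2)
    stop("degenerate class counts: need >= 2 cases per class")
  ca <- .delong_components(scores_a, lab)
  cb <- .delong_components(scores_b, lab)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  d <- ca$auc - cb$auc
  if (d == 0 || vd <= 0) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(auc_a = ca$auc, auc_b = cb$auc),
                 method = "DeLong test for two correlated ROC curves",
                 data.name = "paired scores"),
            class = "htest")
}

#' McNemar test on paired correct/incorrect outcomes
#'
#' Exact binomial test on the discordant pairs when there are fewer than
#' 25 of them, continuity-corrected chi-square otherwise.  Zero discordant
#' pairs give p = 1.
#'
#' @param correct_a,correct_b paired logical outcome vectors.
#' @return an `htest`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  a <- as.logical(correct_a); b <- as.logical(correct_b)
  stopifnot(length(a) == length(b))
  n10 <- sum(a & !b)
  n01 <- sum(!a & b)
  nd <- n10 + n01
  if (nd == 0) {
    stat <- c(discordant = 0); p <- 1
    meth <- "McNemar exact binomial test (no discordant pairs)"
  } else if (nd < 25) {
    p <- min(1, 2 * stats::pbinom(min(n10, n01), nd, 0.5))
    stat <- c(discordant = nd)
    meth <- "McNemar exact binomial test"
  } else {
    chi <- (abs(n10 - n01) - 1)^2 / nd
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
    stat <- c(`X-squared` = chi)
    meth <- "McNemar chi-square test with continuity correction"
  }
  structure(list(statistic = stat, p.value = p, method = meth,
                 parameter = c(b = n10, c = n01),
                 data.name = "paired outcomes"),
            class = "htest")
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped.  Exact null enumeration (signrank
#' distribution) when the remaining n is at most 25 and the absolute
#' differences are untied; tie- and continuity-corrected normal
#' approximation otherwise.
#'
#' @param x,y paired numeric vectors.
#' @return an `htest`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(statistic = c(V = 0), p.value = 1,
                          method = "Wilcoxon signed rank test",
                          data.name = "paired samples"),
                     class = "htest"))
  }
  if (n < 5) stop("need >= 5 nonzero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        stats::psignrank(V - 1, n, lower.tail = FALSE)))
    meth <- "Wilcoxon signed rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tt <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)   # continuity corrected
    p <- 2 * stats::pnorm(-abs(z))
    meth <- "Wilcoxon signed rank test (normal approximation)"
  }
  structure(list(statistic = c(V = V), p.value = p, method = meth,
                 data.name = "paired samples"),
            class = "htest")
}

#' Mann-Whitney U test
#'
#' Exact enumeration (Wilcoxon rank-sum distribution) when the smaller
#' sample has at most 8 untied observations; tie- and continuity-corrected
#' normal approximation otherwise.
#'
#' @param x,y independent numeric samples.
#' @return an `htest` with U computed for `x` (number of (x, y) pairs with
#'   `x > y`, ties counting one half).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(n1, n2) <= 8 && !ties) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    meth <- "Mann-Whitney U test (exact)"
  } else {
    N <- n1 + n2
    tt <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)   # continuity corrected
    p <- 2 * stats::pnorm(-abs(z))
    meth <- "Mann-Whitney U test (normal approximation)"
  }
  structure(list(statistic = c(U = U), p.value = p, method = meth,
                 data.name = "two samples"),
            class = "htest")
}

#' Compare two cross-validation runs case by case
#'
#' Pairs the pooled out-of-fold predictions of two [run_cv()] results on
#' their shared cases and runs the model-comparison tests: DeLong on the
#' micro-average one-vs-rest AUC construction (stacked class indicators),
#' McNemar on per-case staging correctness, and Wilcoxon signed-rank on
#' the per-case DSC and ASD values.
#'
#' @param cv_a,cv_b `mt_cv` objects over the same cohort.
#' @return list of `htest` results: `delong`, `mcnemar`, `wilcoxon_dsc`,
#'   `wilcoxon_asd`.
#' @export
compare_cv <- function(cv_a, cv_b) {
  a <- cv_a$pooled; b <- cv_b$pooled
  b <- b[match(a$case_id, b$case_id), ]
  if (anyNA(b$case_id)) stop("runs do not share the same cases")
  K <- 4L
  ind <- matrix(0L, nrow(a), K)
  ind[cbind(seq_len(nrow(a)), a$stage)] <- 1L
  pc <- c("p1", "p2", "p3", "p4")
  dl <- delong_test(as.numeric(as.matrix(a[, pc])),
                    as.numeric(as.matrix(b[, pc])),
                    as.numeric(ind) == 1L)
  mc <- mcnemar_test(a$pred_stage == a$stage, b$pred_stage == b$stage)
  safe_wilcox <- function(x, y)
    tryCatch(wilcoxon_signed_rank(x, y), error = function(e) NULL)
  wd <- safe_wilcox(a$dsc, b$dsc)
  ok <- !is.na(a$asd_mm) & !is.na(b$asd_mm)
  wa <- if (sum(ok) >= 5) safe_wilcox(a$asd_mm[ok], b$asd_mm[ok]) else NULL
  list(delong = dl, mcnemar = mc, wilcoxon_dsc = wd, wilcoxon_asd = wa)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction,
#' `df = (r - 1)(c - 1)`, upper-tail p-value.
#'
#' @param table r x c matrix of counts (all expected counts positive).
#' @return an `htest`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(res$expected <= 0)) stop("non-positive expected count")
  res$data.name <- "contingency table"
  res
}
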