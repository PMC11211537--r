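test_that("Clopper-Pearson interval reproduces printed clinical values", {
  ci <- clopper_pearson(225, 320, 0.95)
  expect_equal(round(ci$lower, 2), 0.65)
  expect_equal(round(ci$upper, 2), 0.75)
  expect_equal(round(ci$estimate, 1), 0.7)
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  expect_error(clopper_pearson(11, 10), "invalid")
})

test_that("Clopper-Pearson intervals are nested across levels", {
  for (k in c(3, 17, 42)) {
    c90 <- clopper_pearson(k, 60, 0.90)
    c95 <- clopper_pearson(k, 60, 0.95)
    c99 <- clopper_pearson(k, 60, 0.99)
    expect_true(c99$lower <= c95$lower && c95$lower <= c90$lower)
    expect_true(c90$upper <= c95$upper && c95$upper <= c99$upper)
  }
})

test_that("accuracy, sensitivity, specificity follow the one-vs-rest reductions", {
  ident <- diag(c(10L, 20L, 15L, 5L))
  r <- acc_sen_spe(ident)
  expect_equal(r$acc, 1); expect_equal(r$sen, 1); expect_equal(r$spe, 1)
  # early-stage printed accuracy: 126 of 166 -> 76%
  expect_equal(round(100 * 126 / 166), 76)
  expect_equal(round(100 * 99 / 154), 64)
  # uniform random predictions on balanced classes
  set.seed(2)
  truth <- rep(1:4, each = 1000)
  pred <- sample(1:4, 4000, TRUE)
  cm <- as.matrix(table(truth, pred))
  r2 <- acc_sen_spe(cm)
  expect_equal(r2$acc, 0.25, tolerance = 0.03)
  expect_equal(r2$spe, 0.75, tolerance = 0.03)
  expect_warning(acc_sen_spe(rbind(c(5, 1), c(0, 0))), "empty class")
})

test_that("one-vs-rest AUC matches exhaustive pair counting", {
  set.seed(3)
  probs <- matrix(runif(6 * 4), 6, 4)
  probs <- probs / rowSums(probs)
  labels <- c(1, 2, 2, 3, 4, 4)
  ind <- matrix(0L, 6, 4); ind[cbind(1:6, labels)] <- 1L
  expect_equal(roc_auc_ovr(probs, labels, "micro"),
               auc_pairs(as.numeric(probs), as.numeric(ind) == 1L))
  macro <- mean(vapply(1:4, function(cl)
    auc_pairs(probs[, cl], ind[, cl] == 1L), numeric(1)))
  expect_equal(roc_auc_ovr(probs, labels, "macro"), macro)
  # perfect separation and chance level
  sep <- ind + 0
  expect_equal(roc_auc_ovr(sep, labels, "micro"), 1)
  expect_equal(roc_auc_ovr(sep, labels, "macro"), 1)
  set.seed(4)
  big <- matrix(runif(4000), 1000, 4)
  expect_equal(roc_auc_ovr(big, sample(1:4, 1000, TRUE), "micro"), 0.5,
               tolerance = 0.03)
  expect_error(roc_auc_ovr(probs, rep(1L, 6), "macro"), "class")
})

test_that("DeLong test is symmetric, null-calibrated and cross-checks", {
  set.seed(5)
  lab <- rep(c(TRUE, FALSE), each = 40)
  s1 <- rnorm(80) + lab
  expect_equal(delong_test(s1, s1, lab)$p.value, 1)
  s2 <- rnorm(80) + 0.5 * lab
  t12 <- delong_test(s1, s2, lab)
  t21 <- delong_test(s2, s1, lab)
  expect_equal(unname(t12$statistic), -unname(t21$statistic))
  expect_equal(t12$p.value, t21$p.value)
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(lab, s1, quiet = TRUE),
                        pROC::roc(lab, s2, quiet = TRUE), method = "delong")
  expect_equal(t12$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("DeLong variance agrees with a bootstrap of the AUC", {
  env <- asNamespace("gtvstage")
  set.seed(6)
  lab <- rep(c(TRUE, FALSE), each = 100)
  sc <- rnorm(200) + 0.8 * lab
  v_struct <- env$.delong_var(env$.delong_components(sc, lab))
  boot <- replicate(2000, {
    i <- c(sample(which(lab), replace = TRUE),
           sample(which(!lab), replace = TRUE))
    r <- rank(sc[i]); pos <- lab[i]
    (sum(r[pos]) - 100 * 101 / 2) / (100 * 100)
  })
  expect_lt(abs(v_struct - var(boot)) / var(boot), 0.15)
})

test_that("McNemar test uses exact discordant-pair enumeration", {
  a <- c(rep(TRUE, 30), rep(FALSE, 10))
  expect_equal(mcnemar_test(a, a)$p.value, 1)
  # equal discordants: exact symmetric p = 1
  a2 <- c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 10))
  b2 <- c(FALSE, FALSE, TRUE, TRUE, rep(TRUE, 10))
  expect_equal(mcnemar_test(a2, b2)$p.value, 1)
  # discordants (12, 2): doubled binomial tail
  a3 <- c(rep(TRUE, 12), rep(FALSE, 2), rep(TRUE, 20))
  b3 <- c(rep(FALSE, 12), rep(TRUE, 2), rep(TRUE, 20))
  expect_equal(mcnemar_test(a3, b3)$p.value, 2 * pbinom(2, 14, 0.5))
})

test_that("Wilcoxon signed-rank matches exhaustive sign enumeration", {
  x <- c(1.2, -0.4, 2.5, 0.8, -1.9, 3.1)
  y <- c(0.3, 0.1, 1.1, -0.2, -0.6, 1.4)
  got <- wilcoxon_signed_rank(x, y)$p.value
  d <- x - y
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  # enumerate all 2^6 sign assignments under the null
  Vs <- vapply(0:63, function(bits) {
    signs <- as.integer(intToBits(bits))[1:6]
    sum(r[signs == 1])
  }, numeric(1))
  mu <- mean(Vs)
  p_exact <- mean(abs(Vs - mu) >= abs(V_obs - mu) - 1e-12)
  expect_equal(got, p_exact)
  expect_equal(wilcoxon_signed_rank(x, x)$p.value, 1)
  # strong shift is detected
  set.seed(7)
  xs <- rnorm(20)
  expect_lt(wilcoxon_signed_rank(xs, xs + 1)$p.value, 0.01)
})

test_that("Mann-Whitney U matches enumeration and its symmetry law", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1 / 3)
  tied <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(tied$statistic), 4.5)   # n1 n2 / 2
  set.seed(8)
  x <- rnorm(7); y <- rnorm(9)
  ra <- mann_whitney_u(x, y); rb <- mann_whitney_u(y, x)
  expect_equal(unname(ra$statistic), 63 - unname(rb$statistic))
  expect_equal(ra$p.value, rb$p.value)
  expect_error(mann_whitney_u(numeric(0), y), "empty")
})

test_that("exact and approximate p-values agree near the switchovers", {
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(8); y <- rnorm(8)
    p_exact <- mann_whitney_u(x, y)$p.value
    r <- rank(c(x, y)); U <- sum(r[1:8]) - 36
    z <- (U - 32 - sign(U - 32) * 0.5) / sqrt(64 / 12 * 17)
    expect_lt(abs(p_exact - 2 * pnorm(-abs(z))), 0.02)
  }
  for (i in 1:50) {
    x <- rnorm(25); y <- rnorm(25)
    p_exact <- wilcoxon_signed_rank(x, y)$p.value
    d <- x - y; r <- rank(abs(d)); V <- sum(r[d > 0]); n <- 25
    z <- (V - n * (n + 1) / 4 - sign(V - n * (n + 1) / 4) * 0.5) /
      sqrt(n * (n + 1) * (2 * n + 1) / 24)
    expect_lt(abs(p_exact - 2 * pnorm(-abs(z))), 0.02)
  }
})

test_that("chi-square reproduces the printed cohort comparisons", {
  sex_c1_c2 <- rbind(c(77, 28), c(73, 32))
  expect_equal(round(chi_square_test(sex_c1_c2)$p.value, 3), 0.541)
  t_c1_c2 <- rbind(c(8, 47, 28, 22), c(8, 47, 28, 22))
  r <- chi_square_test(t_c1_c2)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  t_c1_c3 <- rbind(c(8, 47, 28, 22), c(10, 46, 31, 23))
  expect_equal(round(chi_square_test(t_c1_c3)$p.value, 3), 0.962)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "marginal")
})
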