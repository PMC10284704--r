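# Testing battery: tail probabilities, t tests, Levene, ANOVA, multiple
# comparisons, multivariate LRT, BH FDR.

test_that("t and F tail probabilities reproduce printed legend statistics", {
  # paired comparisons of pre vs post preference at P98
  expect_equal(round(t_to_p(-3.741, 14), 3), 0.002)   # psilocybin
  expect_lt(t_to_p(-7.095, 8), 0.001)                 # LSD
  expect_lt(t_to_p(-3.826, 17), 0.002)                # ketamine
  expect_equal(round(t_to_p(-2.690, 11), 2), 0.02)    # ibogaine
  expect_equal(round(t_to_p(-0.441, 16), 3), 0.665)   # saline
  # unpaired drug-vs-saline comparisons (normalized scores)
  expect_equal(round(t_to_p(-2.800, 30), 3), 0.009)
  expect_equal(round(t_to_p(-3.558, 21), 3), 0.002)
  # one-way ANOVA across the eight treatment groups (frequency / amplitude)
  expect_equal(signif(f_to_p(5.99, 7, 31), 1), 0.0002)
  expect_equal(round(f_to_p(1.09, 7, 31), 2), 0.39)
})

test_that("tail probabilities have the right edge cases and validation", {
  expect_equal(t_to_p(0, 5), 1)
  expect_equal(t_to_p(0, 500), 1)
  expect_equal(f_to_p(0, 3, 10), 1)
  expect_error(t_to_p(1, 0), "positive")
  expect_error(f_to_p(-1, 3, 10), "non-negative")
})

test_that("tail probabilities match numerical quadrature of the densities", {
  p_t <- integrate(function(x) dt(x, 10), 2, Inf, rel.tol = 1e-12)$value * 2
  expect_equal(t_to_p(2, 10), p_t, tolerance = 1e-8)
  p_f <- integrate(function(x) df(x, 3, 20), 2.5, Inf,
                   rel.tol = 1e-12)$value
  expect_equal(f_to_p(2.5, 3, 20), p_f, tolerance = 1e-8)
})

test_that("tail probabilities are monotone and t converges to the normal", {
  ts <- seq(0, 5, by = 0.25)
  expect_true(all(diff(t_to_p(ts, 7)) < 0))
  expect_true(all(diff(f_to_p(seq(0.1, 8, by = 0.5), 4, 20)) < 0))
  for (t in c(0.5, 1.5, 2.5))
    expect_equal(t_to_p(t, 1e6), 2 * (1 - pnorm(t)), tolerance = 1e-3)
})

test_that("t tests agree with hand-coded formula oracles", {
  set.seed(10)
  for (i in 1:10) {
    x <- rnorm(12, 1, 0.5); y <- rnorm(9, 1.2, 0.8)
    w <- unpaired_t(x, y, welch = TRUE); wo <- welch_oracle(x, y)
    expect_equal(w$statistic, wo$t, tolerance = 1e-10)
    expect_equal(w$df, wo$df, tolerance = 1e-10)
    expect_equal(w$p_value, wo$p, tolerance = 1e-10)
    pl <- unpaired_t(x, y[1:12 %% 9 + 1], welch = FALSE)
    po <- pooled_oracle(x, y[1:12 %% 9 + 1])
    expect_equal(pl$statistic, po$t, tolerance = 1e-10)
    expect_equal(pl$p_value, po$p, tolerance = 1e-10)
    z <- rnorm(12)
    pr <- paired_t(x, z); pro <- paired_oracle(x, z)
    expect_equal(pr$statistic, pro$t, tolerance = 1e-10)
    expect_equal(pr$p_value, pro$p, tolerance = 1e-10)
  }
})

test_that("degenerate and null comparisons give P = 1, never NaN", {
  x <- c(1, 2, 3)
  p <- paired_t(x, x)
  expect_equal(p$statistic, 0)
  expect_equal(p$p_value, 1)
  u <- unpaired_t(x, x)
  expect_equal(u$statistic, 0)
  expect_equal(u$p_value, 1)
  cc <- unpaired_t(c(2, 2, 2), c(2, 2))   # zero variance, equal means
  expect_equal(cc$p_value, 1)
  dd <- unpaired_t(c(2, 2, 2), c(3, 3))   # zero variance, unequal means
  expect_equal(dd$p_value, 0)
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("Welch equals the pooled test when variances and sizes match", {
  x <- c(1, 2, 3, 4, 5)
  y <- x + 0.7  # identical variance, equal n
  w <- unpaired_t(x, y, welch = TRUE)
  p <- unpaired_t(x, y, welch = FALSE)
  expect_equal(w$statistic, p$statistic, tolerance = 1e-12)
  expect_equal(w$df, p$df, tolerance = 1e-9)
})

test_that("Levene's test matches the mean-centred reference implementation", {
  skip_if_not_installed("car")
  set.seed(20)
  x <- rnorm(15, 0, 1); y <- rnorm(20, 0, 2.5)
  res <- levene(x, y)
  v <- c(x, y); g <- factor(rep(1:2, c(15, 20)))
  ref <- car::leveneTest(v, g, center = mean)
  expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # degenerate equal-constant groups
  expect_equal(levene(c(1, 1, 1), c(1, 1))$p_value, 1)
})

test_that("one-way ANOVA handles identical groups and keeps df bookkeeping", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- one_way_anova(g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-10)
  expect_error(one_way_anova(list(1:3, numeric(0))), "empty")
  # eight treatment groups, 39 cells in total -> F df (7, 31)
  set.seed(30)
  eight <- lapply(c(8, 6, 4, 4, 4, 5, 4, 4), function(n) rnorm(n))
  expect_equal(one_way_anova(eight)$df, c(7, 31))
})

test_that("pairwise Holm-Sidak comparisons control familywise error", {
  set.seed(40)
  fw_raw <- fw_adj <- logical(300)
  pairs <- list(c("a", "base"), c("b", "base"), c("c", "base"),
                c("d", "base"))
  for (i in 1:300) {
    groups <- list(base = rnorm(6), a = rnorm(6), b = rnorm(6),
                   c = rnorm(6), d = rnorm(6))
    mc <- multiple_comparisons(groups, pairs)
    fw_raw[i] <- any(mc$p_value <= 0.05)
    fw_adj[i] <- any(mc$p_adjusted <= 0.05)
    expect_true(all(mc$p_adjusted >= mc$p_value - 1e-12))
  }
  expect_lte(mean(fw_adj), 0.08)       # ~0.05 familywise
  expect_gt(mean(fw_raw), mean(fw_adj))  # adjustment actually bites
})

test_that("a planted group shift is flagged by the adjusted comparisons", {
  set.seed(41)
  groups <- list(base = rnorm(8, 0, 0.5), a = rnorm(8, 0, 0.5),
                 b = rnorm(8, 2.5, 0.5))
  mc <- multiple_comparisons(groups, list(c("a", "base"), c("b", "base")))
  expect_lt(mc$p_adjusted[mc$group1 == "b"], 0.001)
  expect_gt(mc$p_adjusted[mc$group1 == "a"], 0.05)
  tk <- multiple_comparisons(groups, list(c("b", "base")), method = "tukey")
  expect_lt(tk$p_adjusted, 0.01)
  expect_equal(tk$estimate, mean(groups$b) - mean(groups$base),
               tolerance = 1e-9)
})

test_that("multivariate LRT is null for an empty contrast and matches Wilks", {
  set.seed(50)
  n <- 40
  fac <- data.frame(treatment = sample(c("sal", "drug"), n, TRUE),
                    age = sample(c("48h", "2wk"), n, TRUE),
                    structure = sample(c("NAc", "mPFC"), n, TRUE))
  Y <- cbind(freq = rnorm(n, 2), amp = rnorm(n, 15))
  # same design in full and reduced: statistic 0, P 1
  same <- manova_lrt(Y, transform(fac, treatment = "sal"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # Wilks' Lambda agrees with the stats::manova cross-check (treatment
  # entered last so the sequential SS match the marginal drop)
  res <- manova_lrt(Y, fac)
  mfit <- stats::manova(Y ~ age + structure + treatment, data = fac)
  wl <- summary(mfit, test = "Wilks")$stats["treatment", "Wilks"]
  expect_equal(res$wilks_lambda, wl, tolerance = 1e-8)
})

test_that("multivariate LRT detects a frequency-only treatment effect and is
           calibrated under label permutation", {
  set.seed(51)
  n <- 40
  fac <- data.frame(treatment = rep(c("sal", "drug"), each = n / 2),
                    age = rep(c("48h", "2wk"), n / 2),
                    structure = rep(c("NAc", "NAc", "mPFC", "mPFC"), n / 4))
  hits <- 0
  for (i in 1:40) {
    Y <- cbind(freq = rnorm(n, ifelse(fac$treatment == "drug", 1.2, 2), 0.4),
               amp = rnorm(n, 15, 2))
    hits <- hits + (manova_lrt(Y, fac)$p_value <= 0.05)
  }
  expect_gte(hits / 40, 0.9)
  # permutation null
  Y <- cbind(freq = rnorm(n, 2, 0.4), amp = rnorm(n, 15, 2))
  perm_p <- vapply(1:200, function(i) {
    f2 <- fac; f2$treatment <- sample(f2$treatment)
    manova_lrt(Y, f2)$p_value
  }, numeric(1))
  rate <- mean(perm_p <= 0.05)
  expect_lt(rate, 0.12)  # ~alpha, small-n chi-square slack allowed
})

test_that("BH q-values follow the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q_values,
               rep(0.04, 4))
  expect_equal(bh_fdr(0.03)$q_values, 0.03)
  set.seed(60)
  for (i in 1:10) {
    p <- runif(50)^2
    res <- bh_fdr(p, q_threshold = 0.1)
    expect_equal(res$q_values, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_equal(res$significant, bh_stepup_oracle(p) <= 0.1)
    # monotone non-decreasing after sorting by p
    expect_true(all(diff(res$q_values[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.1, NA)), "missing")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH keeps the realized false discovery rate at its level under the null", {
  set.seed(61)
  any_rej <- vapply(1:200, function(i)
    any(bh_fdr(runif(2000), 0.1)$significant), logical(1))
  # under a global null, E[FDR] = P(any rejection) <= q (= 0.1 here);
  # bound allows ~3 binomial standard errors
  expect_lte(mean(any_rej), 0.16)
})
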