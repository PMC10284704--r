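# Hypothesis-testing battery: t and F tail probabilities, paired/unpaired t,
# Levene's test, one-way ANOVA with pairwise multiple comparisons, a
# multivariate likelihood-ratio test, and Benjamini-Hochberg FDR control.

crit_test <- function(statistic, df, p_value, method, two_tailed = TRUE,
                      extra = list()) {
  structure(c(list(statistic = unname(statistic), df = unname(df),
                   p_value = unname(p_value), method = method,
                   two_tailed = two_tailed), extra),
            class = "crit_test")
}

#' @export
print.crit_test <- function(x, ...) {
  dfs <- paste(format(signif(x$df, 5)), collapse = ", ")
  cat(sprintf("%s%s\n  statistic = %.4g, df = (%s), P = %.4g\n",
              x$method, if (x$two_tailed) " (two-tailed)" else "",
              x$statistic, dfs, x$p_value))
  invisible(x)
}

#' Two-tailed P value from a t statistic
#'
#' @param t t statistic (sign is irrelevant).
#' @param df degrees of freedom (> 0).
#' @return two-tailed tail probability of the Student t distribution.
#' @examples
#' t_to_p(-3.741, 14)   # 0.002 to the precision figure legends print
#' @export
t_to_p <- function(t, df) {
  if (any(df <= 0)) stop("df must be positive", call. = FALSE)
  2 * stats::pt(-abs(t), df)
}

#' Upper-tail P value from an F statistic
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return upper-tail probability of the F distribution.
#' @examples
#' f_to_p(5.99, 7, 31)  # 0.0002
#' @export
f_to_p <- function(f, df1, df2) {
  if (any(f < 0)) stop("F statistic must be non-negative", call. = FALSE)
  if (any(df1 <= 0) || any(df2 <= 0)) stop("df must be positive", call. = FALSE)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

# Two-group zero-variance degenerate cases: equal constants compare as equal
# (t = 0, P = 1) rather than NaN.
degenerate_two_group <- function(delta, method) {
  if (delta == 0) crit_test(0, NA_real_, 1, method)
  else crit_test(sign(delta) * Inf, NA_real_, 0, method)
}

#' Paired two-tailed t-test
#'
#' @param x,y paired measurement vectors (equal length, n >= 2).
#' @return a `crit_test` with the t statistic, df and two-tailed P value.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length",
                                   call. = FALSE)
  if (length(x) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) return(degenerate_two_group(mean(d), "paired t-test"))
  tt <- stats::t.test(x, y, paired = TRUE)
  crit_test(tt$statistic, tt$parameter, tt$p.value, "paired t-test")
}

#' Unpaired two-tailed t-test
#'
#' @param x,y group measurement vectors (each n >= 2).
#' @param welch apply Welch's correction for unequal variances
#'   (Welch-Satterthwaite df); `FALSE` gives the pooled-variance test.
#' @return a `crit_test`.
#' @export
unpaired_t <- function(x, y, welch = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need n >= 2 per group", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(degenerate_two_group(mean(x) - mean(y),
                                if (welch) "Welch t-test" else
                                  "pooled t-test"))
  tt <- stats::t.test(x, y, var.equal = !welch)
  crit_test(tt$statistic, tt$parameter, tt$p.value,
            if (welch) "Welch t-test" else "pooled t-test")
}

#' Levene's test for equality of variances
#'
#' Classic Levene: one-way ANOVA on the absolute deviations from each group's
#' mean.
#'
#' @param ... two or more group vectors, or a single list of groups.
#' @return a `crit_test` (F statistic, df pair, P value).
#' @export
levene <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1L]])) groups <- groups[[1L]]
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) stop("need n >= 2 per group", call. = FALSE)
  absdev <- unlist(lapply(groups, function(g) abs(g - mean(g))))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::sd(absdev) == 0)
    return(crit_test(0, c(length(groups) - 1L,
                          length(absdev) - length(groups)), 1,
                     "Levene's test"))
  an <- stats::anova(stats::lm(absdev ~ g))
  crit_test(an$`F value`[1L], c(an$Df[1L], an$Df[2L]), an$`Pr(>F)`[1L],
            "Levene's test", two_tailed = FALSE)
}

#' One-way analysis of variance
#'
#' @param groups named or unnamed list of group vectors (>= 2 groups, each
#'   n >= 2).
#' @return a `crit_test` with the F statistic, `(df1, df2)` and P value, plus
#'   `group_means` in the result.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least 2 group vectors", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("empty group(s): ",
         paste(which(lengths(groups) == 0L), collapse = ", "), call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("need n >= 2 per group", call. = FALSE)
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups); n <- length(v)
  if (stats::sd(v) == 0)
    return(crit_test(0, c(k - 1L, n - k), 1, "one-way ANOVA",
                     two_tailed = FALSE,
                     extra = list(group_means = vapply(groups, mean,
                                                      numeric(1)))))
  an <- stats::anova(stats::lm(v ~ g))
  crit_test(an$`F value`[1L], c(an$Df[1L], an$Df[2L]), an$`Pr(>F)`[1L],
            "one-way ANOVA", two_tailed = FALSE,
            extra = list(group_means = vapply(groups, mean, numeric(1)),
                         mse = an$`Mean Sq`[2L]))
}

# Holm-Sidak step-down adjustment over m pairwise P values.
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1L)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise multiple comparisons after one-way ANOVA
#'
#' Pairwise t comparisons for the named pairs (each drug against its own
#' baseline, rather than all pairs), using the ANOVA pooled error with
#' `N - k` degrees of freedom, adjusted by the Holm-Sidak step-down method
#' (default) or Tukey's HSD.
#'
#' @param groups named list of group vectors.
#' @param pairs list of length-2 character vectors (or a 2-column matrix) of
#'   group names to compare.
#' @param method `"holm-sidak"` or `"tukey"`.
#' @return data frame with one row per pair: `group1`, `group2`, `estimate`
#'   (mean difference), `statistic`, `p_value` (unadjusted; `NA` for Tukey)
#'   and `p_adjusted`.
#' @export
multiple_comparisons <- function(groups, pairs,
                                 method = c("holm-sidak", "tukey")) {
  method <- match.arg(method)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a fully named list", call. = FALSE)
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1L)
  bad <- setdiff(unique(unlist(pairs)), names(groups))
  if (length(bad))
    stop("unknown group(s) in pairs: ", paste(bad, collapse = ", "),
         call. = FALSE)
  an <- one_way_anova(groups)
  mse <- an$mse %||% 0
  df_err <- an$df[2L]
  k <- length(groups)

  if (method == "tukey") {
    v <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
    tk <- stats::TukeyHSD(stats::aov(v ~ g))$g
    out <- do.call(rbind, lapply(pairs, function(pr) {
      key <- c(paste(pr[2L], pr[1L], sep = "-"),
               paste(pr[1L], pr[2L], sep = "-"))
      hit <- key[key %in% rownames(tk)][1L]
      est <- tk[hit, "diff"] * if (hit == key[1L]) -1 else 1
      data.frame(group1 = pr[1L], group2 = pr[2L], estimate = est,
                 statistic = NA_real_, p_value = NA_real_,
                 p_adjusted = tk[hit, "p adj"])
    }))
    rownames(out) <- NULL
    return(out)
  }

  res <- lapply(pairs, function(pr) {
    x <- groups[[pr[1L]]]; y <- groups[[pr[2L]]]
    se <- sqrt(mse * (1 / length(x) + 1 / length(y)))
    tstat <- if (se == 0) 0 else (mean(x) - mean(y)) / se
    data.frame(group1 = pr[1L], group2 = pr[2L],
               estimate = mean(x) - mean(y), statistic = tstat,
               p_value = if (se == 0) 1 else t_to_p(tstat, df_err))
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- holm_sidak_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Multivariate likelihood-ratio test (frequency, amplitude)
#'
#' Likelihood-ratio test for a treatment effect on a bivariate response
#' (mEPSC frequency and amplitude), comparing the full multivariate linear
#' model `response ~ treatment + age + structure` to the reduced model
#' `response ~ age + structure`.  The statistic is
#' \eqn{-n \log(|\hat\Sigma_{full}| / |\hat\Sigma_{reduced}|)} with a
#' chi-square reference on (number of responses) x (parameters dropped)
#' degrees of freedom.  Wilks' \eqn{\Lambda} is reported alongside.
#'
#' @param responses numeric matrix with one column per response variable
#'   (typically frequency and amplitude) and one row per cell.
#' @param factors data frame of explanatory variables, same rows.
#' @param full character vector of factor names in the full model.
#' @param drop factor name(s) removed in the reduced model.
#' @return a `crit_test` with `wilks_lambda` in the result.
#' @export
manova_lrt <- function(responses, factors,
                       full = c("treatment", "age", "structure"),
                       drop = "treatment") {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (n != nrow(factors))
    stop("responses and factors must have the same number of rows",
         call. = FALSE)
  check_columns(factors, full, "factors")
  if (!all(drop %in% full)) stop("`drop` must be a subset of `full`",
                                 call. = FALSE)
  keep <- setdiff(full, drop)

  build <- function(vars) {
    if (!length(vars)) return(matrix(1, n, 1L))
    mf <- factors[vars]
    # single-level factors carry no information; drop them
    mf <- mf[vapply(mf, function(v) length(unique(v)) > 1L, logical(1))]
    if (!length(mf)) return(matrix(1, n, 1L))
    stats::model.matrix(~ ., data = mf)
  }
  Xf <- build(full); Xr <- build(keep)
  qf <- qr(Xf); qr_ <- qr(Xr)
  if (qf$rank < ncol(Xf))
    stop("rank-deficient full design (confounded factors)", call. = FALSE)
  if (n <= qf$rank + ncol(responses))
    stop("too few rows for the full model", call. = FALSE)
  Ef <- crossprod(stats::residuals(stats::lm.fit(Xf, responses)))
  Er <- crossprod(stats::residuals(stats::lm.fit(Xr, responses)))
  q_dropped <- qf$rank - qr_$rank
  if (q_dropped == 0L)
    return(crit_test(0, 0, 1, "multivariate LRT",
                     extra = list(wilks_lambda = 1)))
  lambda <- det(Ef) / det(Er)
  statistic <- -n * log(lambda)
  df <- ncol(responses) * q_dropped
  crit_test(statistic, df,
            stats::pchisq(statistic, df, lower.tail = FALSE),
            "multivariate LRT", two_tailed = FALSE,
            extra = list(wilks_lambda = lambda))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up BH q-values with a significance mask at the chosen threshold.
#'
#' @param p_values vector of P values in \[0, 1\] (no missing values).
#' @param q_threshold FDR level for the mask (default 0.1).
#' @return list with `q_values` and logical `significant`
#'   (`q <= q_threshold`).
#' @export
bh_fdr <- function(p_values, q_threshold = 0.1) {
  if (anyNA(p_values)) stop("missing P values", call. = FALSE)
  if (any(p_values < 0 | p_values > 1))
    stop("P values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, significant = q <= q_threshold)
}
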