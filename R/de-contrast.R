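# Open-vs-closed differential-expression contrast.
#
# The contrast compares conditions in which the critical period is open
# (48 h and 2 weeks after LSD, 48 h after ketamine, 48 h after MDMA) against
# conditions where it remains in or returns to the closed state (saline and
# cocaine at both timepoints, ketamine at 2 weeks).  Time never enters the
# design; batch does.  Per gene, a likelihood-ratio test compares the full
# Gaussian log-abundance model (intercept + batch + state) to the reduced
# model (intercept + batch), with BH FDR control across genes.
#
# With a few dozen samples the asymptotic chi-square reference for the LRT is
# noticeably anticonservative, which inflates the realized FDR; the default
# P value therefore comes from the exact finite-sample null distribution of
# the LRT under the Gaussian model (its monotone F transform,
# F = (n - p) (exp(LRT / n) - 1)), with the asymptotic chi-square available
# as an option.  The two agree as n grows.

open_closed_map <- c(
  "LSD.48h" = "open", "LSD.2wk" = "open", "ketamine.48h" = "open",
  "MDMA.48h" = "open",
  "saline.48h" = "closed", "saline.2wk" = "closed",
  "cocaine.48h" = "closed", "cocaine.2wk" = "closed",
  "ketamine.2wk" = "closed")

#' Assign open/closed (or treated/untreated) state labels to samples
#'
#' Maps each sample's condition and timepoint to the contrast label.  For
#' `open_vs_closed`, LSD (48 h, 2 wk), ketamine (48 h) and MDMA (48 h) are
#' open; saline and cocaine (both timepoints) and ketamine (2 wk) are
#' closed.  For `treated_vs_untreated`, saline is untreated and every drug
#' condition (cocaine included) is treated.  Timepoint is only used to look
#' up the open/closed label — it never enters the design as a covariate.
#'
#' @param samples sample sheet with `condition_label`, `timepoint_label`
#'   (`"48h"` or `"2wk"`) and `batch_id`.
#' @param contrast_name `"open_vs_closed"` or `"treated_vs_untreated"`.
#' @return list of class `state_design`: `state` (factor per sample),
#'   `batch` (factor), `contrast_name`.
#' @examples
#' sheet <- default_expression_design()
#' table(assign_state_labels(sheet, "open_vs_closed")$state)
#' @export
assign_state_labels <- function(samples,
                                contrast_name = c("open_vs_closed",
                                                  "treated_vs_untreated")) {
  contrast_name <- match.arg(contrast_name)
  check_columns(samples, c("condition_label", "timepoint_label", "batch_id"),
                "sample sheet")
  key <- paste(samples$condition_label, samples$timepoint_label, sep = ".")
  if (contrast_name == "open_vs_closed") {
    state <- open_closed_map[key]
    if (anyNA(state))
      stop("condition-timepoint pair(s) with no defined open/closed label: ",
           paste(unique(key[is.na(state)]), collapse = ", "),
           "; defined pairs: ", paste(names(open_closed_map),
                                      collapse = ", "), call. = FALSE)
    state <- factor(state, levels = c("closed", "open"))
  } else {
    known <- c("saline", "cocaine", "ketamine", "LSD", "MDMA",
               "psilocybin", "ibogaine")
    bad <- !samples$condition_label %in% known |
      !samples$timepoint_label %in% c("48h", "2wk")
    if (any(bad))
      stop("unknown condition/timepoint pair(s): ",
           paste(unique(key[bad]), collapse = ", "), call. = FALSE)
    state <- factor(ifelse(samples$condition_label == "saline",
                           "untreated", "treated"),
                    levels = c("untreated", "treated"))
  }
  structure(list(state = state, batch = factor(samples$batch_id),
                 contrast_name = contrast_name), class = "state_design")
}

#' Per-gene likelihood-ratio test for a state effect
#'
#' Gaussian likelihood on `log(abundance + pseudocount)`: for each gene the
#' full model (intercept + batch + state) is compared to the reduced model
#' (intercept + batch) by the likelihood-ratio statistic
#' \eqn{n \log(RSS_{reduced} / RSS_{full})}; q-values are BH across genes.
#' By default the P value uses the exact finite-sample null distribution of
#' this statistic under the Gaussian model (the monotone transform
#' \eqn{F = (n - p)(e^{LRT/n} - 1)} is F(1, n - p) under the null), which
#' keeps the realized FDR at its nominal level at typical sample sizes; the
#' asymptotic chi-square(1) reference is available via
#' `null_dist = "chisq"`.  A negative-binomial option (`method = "nb"`)
#' fits per-gene NB regressions on rounded abundances instead.
#'
#' @param study an `expression_study` (or a list with `abundance` matrix and
#'   `samples` sheet).
#' @param design optional [assign_state_labels()] result; built from
#'   `study$samples` and `contrast_name` when `NULL`.
#' @param contrast_name contrast to test (see [assign_state_labels()]).
#' @param pseudocount added to abundances before the log transform
#'   (default 0.5).
#' @param q_threshold FDR level for the significance mask (default 0.1 for
#'   the open-vs-closed contrast; the treated-vs-untreated contrast is
#'   conventionally read at 0.15).
#' @param method `"gaussian"` (default) or `"nb"`.
#' @param null_dist `"f"` (exact finite-sample reference, default) or
#'   `"chisq"` (asymptotic); Gaussian method only.
#' @return data frame of class `de_result`: `gene`, `lrt_stat`, `p_value`,
#'   `q_value`, `direction` (sign of the state coefficient), `significant`.
#' @export
gene_lrt <- function(study, design = NULL,
                     contrast_name = "open_vs_closed", pseudocount = 0.5,
                     q_threshold = if (contrast_name == "open_vs_closed")
                       0.1 else 0.15,
                     method = c("gaussian", "nb"),
                     null_dist = c("f", "chisq")) {
  method <- match.arg(method)
  null_dist <- match.arg(null_dist)
  abundance <- study$abundance
  if (is.null(abundance) || any(abundance < 0))
    stop("`study$abundance` must be a non-negative matrix", call. = FALSE)
  design <- design %||% assign_state_labels(study$samples, contrast_name)
  state <- design$state
  batch <- design$batch
  if (length(state) != ncol(abundance))
    stop("sample sheet does not cover the abundance columns", call. = FALSE)
  if (min(table(state)) < 2L)
    stop("need >= 2 samples per state", call. = FALSE)

  Xf <- stats::model.matrix(~ batch + state)
  Xr <- stats::model.matrix(~ batch)
  if (qr(Xf)$rank < ncol(Xf))
    stop("batch is perfectly confounded with state: effect inestimable",
         call. = FALSE)
  n <- ncol(abundance)

  if (method == "gaussian") {
    Y <- t(log(abundance + pseudocount))
    ff <- stats::lm.fit(Xf, Y)
    fr <- stats::lm.fit(Xr, Y)
    rss_f <- colSums(as.matrix(ff$residuals)^2)
    rss_r <- colSums(as.matrix(fr$residuals)^2)
    lrt <- n * log(pmax(rss_r, .Machine$double.xmin) /
                     pmax(rss_f, .Machine$double.xmin))
    lrt[rss_r < 1e-12 & rss_f < 1e-12] <- 0  # constant gene: no evidence
    coef_state <- as.matrix(ff$coefficients)[ncol(Xf), ]
    if (null_dist == "f") {
      df2 <- n - ncol(Xf)
      fstat <- df2 * (exp(lrt / n) - 1)
      p <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
    } else {
      p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    }
  } else {
    counts <- round(abundance)
    res <- apply(counts, 1L, function(y) {
      fit_f <- tryCatch(MASS::glm.nb(y ~ batch + state),
                        error = function(e) NULL)
      fit_r <- tryCatch(MASS::glm.nb(y ~ batch), error = function(e) NULL)
      if (is.null(fit_f) || is.null(fit_r)) return(c(0, 0))
      c(max(0, 2 * (stats::logLik(fit_f) - stats::logLik(fit_r))),
        stats::coef(fit_f)[["stateopen"]] %||% 0)
    })
    lrt <- res[1L, ]
    coef_state <- res[2L, ]
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }

  fdr <- bh_fdr(p, q_threshold)
  out <- data.frame(
    gene = rownames(abundance) %||% sprintf("gene%05d", seq_along(p)),
    lrt_stat = unname(lrt),
    p_value = unname(p),
    q_value = fdr$q_values,
    direction = sign(unname(coef_state)),
    significant = fdr$significant
  )
  class(out) <- c("de_result", "data.frame")
  attr(out, "contrast_name") <- design$contrast_name
  attr(out, "q_threshold") <- q_threshold
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Differential expression (%s): %d of %d genes at q <= %g\n",
              attr(x, "contrast_name"), sum(x$significant), nrow(x),
              attr(x, "q_threshold")))
  NextMethod()
}

#' Expression ratios to the average saline baseline
#'
#' For each requested gene and each condition-timepoint group, the mean
#' abundance divided by that gene's mean over all saline samples (both
#' timepoints) — the per-drug expression ratio display for top-scoring
#' genes.
#'
#' @param study an `expression_study`.
#' @param gene_set character vector of gene identifiers (possibly empty).
#' @return data frame with `gene`, `condition_label`, `timepoint_label`,
#'   `ratio`.
#' @export
ratio_to_saline <- function(study, gene_set) {
  abundance <- study$abundance
  samples <- study$samples
  check_columns(samples, c("sample_id", "condition_label", "timepoint_label"),
                "sample sheet")
  if (!length(gene_set))
    return(data.frame(gene = character(0), condition_label = character(0),
                      timepoint_label = character(0), ratio = numeric(0)))
  missing <- setdiff(gene_set, rownames(abundance))
  if (length(missing))
    stop("gene(s) not in study: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sal <- samples$condition_label == "saline"
  if (!any(sal)) stop("no saline samples in study", call. = FALSE)
  baseline <- rowMeans(abundance[gene_set, sal, drop = FALSE])
  if (any(baseline == 0))
    stop("zero saline mean for gene(s): ",
         paste(gene_set[baseline == 0], collapse = ", "), call. = FALSE)
  groups <- unique(samples[c("condition_label", "timepoint_label")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- samples$condition_label == groups$condition_label[i] &
      samples$timepoint_label == groups$timepoint_label[i]
    data.frame(gene = gene_set,
               condition_label = groups$condition_label[i],
               timepoint_label = groups$timepoint_label[i],
               ratio = rowMeans(abundance[gene_set, sel, drop = FALSE]) /
                 baseline)
  }))
  rownames(out) <- NULL
  out
}
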