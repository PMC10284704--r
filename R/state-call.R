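# Open/closed state classification via nested-model mean-shift testing.
#
# A treated cohort is compared against the reference developmental timecourse
# by fitting, on the pooled data, a full linear model (natural-spline basis in
# age + experiment indicator + cohort condition offset) against the reduced
# model without the condition offset.  The nested-model F test P value for the
# offset is the mean-shift P value; the cohort is called "open" when
# P <= alpha_open (default 0.1, the convention that comparisons with the
# spline model are not significant at P > 0.1).

#' Classify a cohort as open- or closed-state
#'
#' Tests whether a cohort's normalized social preference shows a mean shift
#' away from the closed-state developmental trajectory fitted to the
#' reference timecourse.  Full model: spline basis in age + experiment
#' indicator + cohort offset; reduced model drops the offset.  The offset's
#' nested-model F test (exact under Gaussian errors) is the default; a
#' likelihood-ratio chi-square is available via `test = "LRT"`.
#'
#' The experiment indicator absorbs batch differences between the reference
#' experiments.  An experiment label that occurs only in the cohort is
#' indistinguishable from the cohort's condition offset, so such labels are
#' mapped to the reference's modal experiment before fitting.
#'
#' @param reference data frame with `age_days`, `normalized_score` and
#'   optionally `experiment_id` (the reference developmental timecourse).
#' @param cohort the treated cohort: a data frame with `age_days` and
#'   `normalized_score` (plus optional `experiment_id`), or a `scored_cohort`
#'   from [score_cohort()] whose records carry `age_days`.
#' @param spec [spline_spec()] for the trajectory basis.
#' @param alpha_open significance level for the open call (default 0.1).
#' @param test `"F"` for the nested-model F test, `"LRT"` for the
#'   likelihood-ratio chi-square.
#' @param cohort_label label stored in the call (defaults to the cohort's
#'   `condition_label` if present).
#' @param age_margin days beyond the reference age range still accepted
#'   before extrapolation is refused.
#' @return object of class `state_call`: `cohort_label`, `shift_estimate`
#'   (normalized preference units), `se`, `p_value`, `call`
#'   (`"open"`/`"closed"`), `alpha_open`, `method`, `n_cohort`,
#'   `n_reference`.
#' @examples
#' ref <- timecourse_from_records(generate_reference_timecourse(
#'   ages = seq(21, 112, by = 7), n_per_age = 10, seed = 1))
#' coh <- timecourse_from_records(generate_scpp_cohort(
#'   n_mice = 15, age_days = 98, open_shift = 0.3,
#'   condition_label = "psilocybin", seed = 2))
#' classify_cohort(ref, coh)
#' @export
classify_cohort <- function(reference, cohort, spec = spline_spec(),
                            alpha_open = 0.1, test = c("F", "LRT"),
                            cohort_label = NULL, age_margin = 7) {
  test <- match.arg(test)
  check_columns(reference, c("age_days", "normalized_score"), "reference")
  if (inherits(cohort, "scored_cohort"))
    cohort <- timecourse_from_records(cohort$records)
  check_columns(cohort, c("age_days", "normalized_score"), "cohort")
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  cohort_label <- cohort_label %||%
    as.character(cohort$condition_label[1L] %||% "cohort")

  rng <- range(reference$age_days)
  if (all(cohort$age_days < rng[1] - age_margin |
          cohort$age_days > rng[2] + age_margin))
    stop(sprintf("cohort ages (%.3g-%.3g) lie entirely outside the reference age range (%.3g-%.3g): extrapolation refused",
                 min(cohort$age_days), max(cohort$age_days), rng[1], rng[2]),
         call. = FALSE)

  ref_exp <- as.character(reference$experiment_id %||%
                            rep("reference", nrow(reference)))
  coh_exp <- as.character(cohort$experiment_id %||% rep("cohort", nrow(cohort)))
  modal <- names(sort(table(ref_exp), decreasing = TRUE))[1L]
  coh_exp[!coh_exp %in% unique(ref_exp)] <- modal

  pooled <- data.frame(
    age_days = c(reference$age_days, cohort$age_days),
    normalized_score = c(reference$normalized_score, cohort$normalized_score),
    experiment = factor(c(ref_exp, coh_exp)),
    in_cohort = rep(c(0, 1), c(nrow(reference), nrow(cohort)))
  )
  use_exp <- nlevels(pooled$experiment) > 1L
  basis_fml <- model_formula("natural_spline", spec, pooled$age_days)
  rhs_red <- paste(as.character(basis_fml)[3L],
                   if (use_exp) "+ experiment" else "")
  full <- stats::lm(stats::as.formula(paste("normalized_score ~", rhs_red,
                                            "+ in_cohort")), data = pooled)
  reduced <- stats::lm(stats::as.formula(paste("normalized_score ~", rhs_red)),
                       data = pooled)
  if (anyNA(stats::coef(full)))
    stop("singular full model; collinear column(s): ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "), call. = FALSE)

  if (test == "F") {
    an <- stats::anova(reduced, full)
    statistic <- an$F[2L]
    p_value <- an$`Pr(>F)`[2L]
    method <- "nested-model F test"
  } else {
    n <- nrow(pooled)
    rss_f <- sum(stats::residuals(full)^2)
    rss_r <- sum(stats::residuals(reduced)^2)
    statistic <- n * log(rss_r / rss_f)
    p_value <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
    method <- "likelihood-ratio chi-square"
  }
  est <- stats::coef(summary(full))["in_cohort", ]

  structure(list(
    cohort_label = cohort_label,
    shift_estimate = unname(est["Estimate"]),
    se = unname(est["Std. Error"]),
    statistic = statistic,
    p_value = p_value,
    call = if (p_value <= alpha_open) "open" else "closed",
    alpha_open = alpha_open,
    method = method,
    n_cohort = nrow(cohort),
    n_reference = nrow(reference),
    full_fit = full,
    reduced_fit = reduced
  ), class = "state_call")
}

#' @export
print.state_call <- function(x, ...) {
  cat(sprintf("State call for '%s': %s\n", x$cohort_label, toupper(x$call)))
  cat(sprintf("  mean shift vs closed-state trajectory: %+.3f (s.e. %.3f)\n",
              x$shift_estimate, x$se))
  cat(sprintf("  %s: P = %.4g (open if P <= %.3g)\n",
              x$method, x$p_value, x$alpha_open))
  cat(sprintf("  n = %d cohort, %d reference mice\n",
              x$n_cohort, x$n_reference))
  invisible(x)
}

#' Age-binned control check against the reference timecourse
#'
#' Two-tailed two-sample t-test of a cohort's normalized scores against the
#' reference records in the age bin matched to the cohort's mean age — the
#' sanity check that new control data sit on the fitted curve.
#'
#' @inheritParams classify_cohort
#' @param bin_width width (days) of the matched reference age bin, centred on
#'   the cohort's mean age.
#' @param welch use Welch's correction (default `TRUE`).
#' @return a `crit_test` result (see [unpaired_t()]).
#' @export
binned_control_check <- function(reference, cohort, bin_width = 14,
                                 welch = TRUE) {
  check_columns(reference, c("age_days", "normalized_score"), "reference")
  if (inherits(cohort, "scored_cohort"))
    cohort <- timecourse_from_records(cohort$records)
  check_columns(cohort, c("age_days", "normalized_score"), "cohort")
  if (nrow(cohort) < 2L)
    stop("need at least 2 cohort records for the binned t-test", call. = FALSE)
  centre <- mean(cohort$age_days)
  in_bin <- abs(reference$age_days - centre) <= bin_width / 2
  if (sum(in_bin) < 2L) {
    nearest <- reference$age_days[which.min(abs(reference$age_days - centre))]
    stop(sprintf("reference age bin %.3g +/- %.3g days holds %d record(s); nearest populated reference age is %.3g",
                 centre, bin_width / 2, sum(in_bin), nearest), call. = FALSE)
  }
  unpaired_t(cohort$normalized_score, reference$normalized_score[in_bin],
             welch = welch)
}
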