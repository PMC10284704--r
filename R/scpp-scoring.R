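# sCPP scoring: preference scores and inclusion rules.
#
# A preference record is one mouse's time (seconds) in the social-assigned
# bedding zone during the 30-min pre-conditioning and post-conditioning trials.
# In an 1800-s session a pre-conditioning social-zone time of 900 s means the
# mouse split its time equally between the two beddings; 1800 s means it spent
# the whole session on the (future) social cue.

#' Score a social conditioned place preference record
#'
#' Converts pre/post social-zone occupancy times into the three standard
#' preference scores and applies the pre-conditioning inclusion rule:
#' \describe{
#'   \item{normalized}{post-conditioning social-zone time divided by
#'     pre-conditioning social-zone time (dimensionless; 1 = no change).}
#'   \item{subtracted}{post minus pre social-zone time, in seconds.}
#'   \item{pre_preference}{pre-conditioning social-zone time divided by half
#'     the session length, so that 1 is an unbiased mouse, 0.5 is 25\%
#'     occupancy and 1.5 is 75\% occupancy.}
#' }
#' A mouse is excluded when its pre-conditioning preference score is above 1.5
#' or below 0.5, i.e. when it already spent more than three quarters or less
#' than one quarter of the baseline session on the social-assigned bedding.
#' Exclusion is decided from the pre-conditioning trial only.
#'
#' @param pre_social_s seconds in the social-assigned zone, pre-conditioning.
#' @param post_social_s seconds in the social-assigned zone, post-conditioning.
#' @param session_s session length in seconds (default 1800 = 30 min).
#' @return A data frame with columns `normalized`, `subtracted`,
#'   `pre_preference` and `excluded` (one row per record).  When
#'   `pre_social_s` is 0 the normalized ratio is undefined: it is returned as
#'   `NA` with a warning (such records are always excluded, since their
#'   pre-preference of 0 falls below 0.5); the subtracted score is still
#'   returned.
#' @examples
#' score_record(900, 1350)             # normalized 1.5, not excluded
#' score_record(1400, 900)             # pre_preference 1.56 -> excluded
#' @export
score_record <- function(pre_social_s, post_social_s, session_s = 1800) {
  check_positive_scalar(session_s[1L], "session_s")
  n <- max(length(pre_social_s), length(post_social_s))
  pre <- rep_len(as.numeric(pre_social_s), n)
  post <- rep_len(as.numeric(post_social_s), n)
  sess <- rep_len(as.numeric(session_s), n)
  if (any(!is.finite(pre)) || any(!is.finite(post)))
    stop("zone times must be finite numbers", call. = FALSE)
  if (any(pre < 0 | pre > sess) || any(post < 0 | post > sess))
    stop("zone times must lie in [0, session_s]", call. = FALSE)
  normalized <- ifelse(pre > 0, post / pre, NA_real_)
  if (anyNA(normalized))
    warning("pre_social_s is 0 for ", sum(is.na(normalized)),
            " record(s): normalized ratio undefined (returned as NA); ",
            "these records are excluded by the pre-preference rule",
            call. = FALSE)
  pre_preference <- pre / (sess / 2)
  data.frame(
    normalized = normalized,
    subtracted = post - pre,
    pre_preference = pre_preference,
    excluded = pre_preference > 1.5 | pre_preference < 0.5
  )
}

#' Score a cohort of preference records and apply exclusions
#'
#' Scores every record with [score_record()], flags excluded mice, and
#' summarises the cohort (mean and s.e.m. of the normalized and subtracted
#' scores) over the included records only.
#'
#' @param records data frame with columns `pre_social_s`, `post_social_s` and
#'   optionally `session_s` (default 1800), plus any identifier columns
#'   (`mouse_id`, `age_days`, `condition_label`, `experiment_id`), which are
#'   carried through.
#' @param keep_excluded if `TRUE`, excluded records stay in the returned table
#'   (always flagged); they never enter the summary statistics.
#' @return A list of class `scored_cohort` with elements `records` (the input
#'   plus score columns and the `excluded` flag) and `summary` (one-row data
#'   frame: `n` after exclusion, `n_excluded`, mean/s.e.m. of normalized and
#'   subtracted scores).
#' @seealso [classify_cohort()], which accepts a `scored_cohort` directly.
#' @export
score_cohort <- function(records, keep_excluded = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data frame", call. = FALSE)
  check_columns(records, c("pre_social_s", "post_social_s"), "cohort table")
  sess <- records$session_s %||% 1800
  scores <- score_record(records$pre_social_s, records$post_social_s, sess)
  out <- cbind(records, scores)
  if (all(out$excluded))
    stop("all ", nrow(out), " records excluded by the pre-conditioning ",
         "preference rule (score > 1.5 or < 0.5)", call. = FALSE)
  inc <- out[!out$excluded, , drop = FALSE]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- data.frame(
    n = nrow(inc),
    n_excluded = sum(out$excluded),
    mean_normalized = mean(inc$normalized),
    sem_normalized = sem(inc$normalized),
    mean_subtracted = mean(inc$subtracted),
    sem_subtracted = sem(inc$subtracted)
  )
  if (!keep_excluded) out <- inc
  structure(list(records = out, summary = summary), class = "scored_cohort")
}

#' @export
print.scored_cohort <- function(x, ...) {
  s <- x$summary
  cat("sCPP cohort:", s$n, "mice included,", s$n_excluded, "excluded\n")
  cat(sprintf("  normalized preference: %.3f +/- %.3f (mean +/- s.e.m.)\n",
              s$mean_normalized, s$sem_normalized))
  cat(sprintf("  subtracted preference: %.1f +/- %.1f s\n",
              s$mean_subtracted, s$sem_subtracted))
  invisible(x)
}

#' Build a timecourse table from scored preference records
#'
#' Convenience bridge from a cohort table of raw zone times to the
#' `(age_days, normalized_score)` format consumed by [fit_trajectory()] and
#' [classify_cohort()].  Excluded records are dropped.
#'
#' @param records data frame as for [score_cohort()], with an `age_days`
#'   column.
#' @return data frame with `age_days`, `normalized_score`, and, when present,
#'   `experiment_id` and `condition_label`.
#' @export
timecourse_from_records <- function(records) {
  check_columns(records, "age_days", "timecourse input")
  sc <- score_cohort(records, keep_excluded = FALSE)$records
  out <- data.frame(age_days = sc$age_days, normalized_score = sc$normalized)
  for (col in c("experiment_id", "condition_label"))
    if (!is.null(sc[[col]])) out[[col]] <- sc[[col]]
  out
}
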