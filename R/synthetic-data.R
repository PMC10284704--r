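# Seeded synthetic-data generators for the three data modalities:
# sCPP cohorts, mEPSC recordings, and expression studies.  Every generator
# routes all randomness through one seed and restores the caller's RNG state,
# so identical spec + seed gives bit-identical output.

#' Generate an sCPP cohort
#'
#' Draws one preference record per mouse.  The normalized preference is
#' Gaussian on the normalized scale: mean `trajectory(age_days) + open_shift`,
#' s.d. `noise_sd`.  It is mapped back to zone times holding the
#' pre-conditioning social-zone time at its expected value (`session_s / 2`),
#' so the two zone times of each trial sum to the session length and the
#' post/pre ratio reproduces the drawn normalized score exactly.  A mean
#' implying a post-conditioning zone time outside `[0, session_s]` is an
#' error (never silently clipped); individual noise draws are taken from the
#' normal truncated to the feasible range `[0, 2]` (occupancy cannot exceed
#' the session), whose truncation mass is below 1e-3 at the default noise
#' level, leaving the expected preference equal to the configured mean to
#' numerical precision.
#'
#' @param n_mice number of mice.
#' @param age_days postnatal age of the cohort (days).
#' @param condition_label treatment label (saline, psilocybin, LSD, ketamine,
#'   ibogaine, MDMA, cocaine, ...).
#' @param open_shift additive shift (normalized preference units) applied
#'   when the treatment holds the critical period open; 0 for the closed
#'   state.
#' @param noise_sd between-mouse s.d. of normalized preference (default 0.19,
#'   the residual scale of the reference trajectory fit).
#' @param session_s trial length in seconds (default 1800).
#' @param seed RNG seed.
#' @param trajectory closed-state mean function of age (default
#'   [developmental_trajectory()]).
#' @param experiment_id experiment/batch label.
#' @return data frame of preference records: `mouse_id`, `age_days`,
#'   `condition_label`, `experiment_id`, `pre_social_s`, `post_social_s`,
#'   `session_s`.
#' @export
generate_scpp_cohort <- function(n_mice, age_days, condition_label = "saline",
                                 open_shift = 0, noise_sd = 0.19,
                                 session_s = 1800, seed = 1,
                                 trajectory = developmental_trajectory,
                                 experiment_id = "reference") {
  check_positive_scalar(n_mice, "n_mice")
  check_positive_scalar(age_days, "age_days")
  check_positive_scalar(noise_sd, "noise_sd")
  check_positive_scalar(session_s, "session_s")
  mu0 <- trajectory(age_days)
  if (!is.finite(mu0))
    stop("trajectory is not defined at age ", age_days, call. = FALSE)
  mu <- mu0 + open_shift
  if (mu < 0 || mu > 2)
    stop("trajectory + open_shift implies a mean zone time outside ",
         "[0, session_s]; clipping is an error — reduce open_shift or the ",
         "trajectory level", call. = FALSE)
  scores <- with_seed(seed, {
    lo <- stats::pnorm(0, mu, noise_sd)
    hi <- stats::pnorm(2, mu, noise_sd)
    stats::qnorm(stats::runif(n_mice, lo, hi), mu, noise_sd)
  })
  pre <- session_s / 2
  post <- scores * pre
  data.frame(
    mouse_id = sprintf("%s_P%g_m%02d", condition_label, age_days,
                       seq_len(n_mice)),
    age_days = age_days,
    condition_label = condition_label,
    experiment_id = experiment_id,
    pre_social_s = pre,
    post_social_s = post,
    session_s = session_s
  )
}

#' Generate a reference developmental timecourse
#'
#' Cohorts at each age, stacked into the developmental dataset the trajectory
#' model is fitted on.  The default conditions emulate a published
#' timecourse: juvenile ages below P35 through adult ages beyond P98, with
#' the closed-state trajectory mean and no treatment shift.
#'
#' @param ages vector of at least 4 distinct ages; should span juvenile
#'   (< 35) to adult (> 98) ages for the spline to be well identified (a
#'   warning is issued otherwise).
#' @param n_per_age mice per age (recycled over ages; every entry must be
#'   positive).
#' @param open_shift shift per age (recycled; default 0 everywhere).
#' @inheritParams generate_scpp_cohort
#' @return data frame of preference records over all ages.
#' @export
generate_reference_timecourse <- function(ages, n_per_age, seed = 1,
                                          open_shift = 0, noise_sd = 0.19,
                                          session_s = 1800,
                                          trajectory = developmental_trajectory,
                                          condition_label = "control",
                                          experiment_id = "reference") {
  if (length(unique(ages)) < 4L)
    stop("need at least 4 distinct ages (spline unidentifiable)",
         call. = FALSE)
  n_per_age <- rep_len(n_per_age, length(ages))
  if (any(n_per_age <= 0))
    stop("`n_per_age` must be positive at every age", call. = FALSE)
  open_shift <- rep_len(open_shift, length(ages))
  if (!any(ages < 35) || !any(ages > 98))
    warning("reference ages should span below P35 and above P98",
            call. = FALSE)
  with_seed(seed, {
    out <- lapply(seq_along(ages), function(i)
      generate_scpp_cohort(n_per_age[i], ages[i],
                           condition_label = condition_label,
                           open_shift = open_shift[i], noise_sd = noise_sd,
                           session_s = session_s,
                           seed = stats::runif(1) * 2^30,
                           trajectory = trajectory,
                           experiment_id = experiment_id))
    do.call(rbind, out)
  })
}

# ---- mEPSC generation -----------------------------------------------------

# Normalized biexponential kernel g(t) = (exp(-t/td) - exp(-t/tr)) / peak,
# peak value 1 at t_peak.
biexp_peak_time <- function(tau_r, tau_d) {
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

biexp_kernel <- function(t, tau_r, tau_d) {
  tp <- biexp_peak_time(tau_r, tau_d)
  peak <- exp(-tp / tau_d) - exp(-tp / tau_r)
  ifelse(t < 0, 0, (exp(-t / tau_d) - exp(-t / tau_r)) / peak)
}

# 10-90% rise time of the biexponential kernel (same time units as taus).
kernel_rise_1090 <- function(tau_r, tau_d) {
  tp <- biexp_peak_time(tau_r, tau_d)
  cross <- function(level)
    stats::uniroot(function(t) biexp_kernel(t, tau_r, tau_d) - level,
                   lower = 0, upper = tp, tol = 1e-12)$root
  cross(0.9) - cross(0.1)
}

# (tau_rise, tau_decay) giving a target 10-90% rise.  The biexponential's
# rise cannot exceed roughly half its decay constant, so the decay is
# lengthened when a slower rise is requested than tau_d admits.
solve_tau_rise <- function(rise, tau_d) {
  max_rise <- kernel_rise_1090(tau_d * 0.999, tau_d)
  if (rise >= max_rise) tau_d <- tau_d * rise / max_rise * 1.05
  tau_r <- stats::uniroot(function(tr) kernel_rise_1090(tr, tau_d) - rise,
                          lower = tau_d * 1e-4, upper = tau_d * 0.999,
                          tol = 1e-10)$root
  list(tau_r = tau_r, tau_d = tau_d)
}

# Truncated-normal draws (exact inverse-CDF truncation at `lower`).
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(mean, n))
  stats::qnorm(stats::runif(n, stats::pnorm(lower, mean, sd), 1), mean, sd)
}

# Draw a Poisson event train with per-event amplitudes and rise times.
# Assumes the RNG is already seeded by the caller.
draw_mepsc_events <- function(rate_hz, trace_s, amp_mean_pa, amp_sd_pa,
                              rise_ms_mean, rise_ms_sd) {
  times <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1L, rate_hz)
    if (t > trace_s) break
    times <- c(times, t)
  }
  n <- length(times)
  data.frame(
    onset_s = times,
    amplitude_pa = rnorm_trunc(n, amp_mean_pa, amp_sd_pa, lower = 1),
    rise_ms = rnorm_trunc(n, rise_ms_mean, rise_ms_sd, lower = 0.2)
  )
}

#' Generate a synthetic mEPSC current trace with ground truth
#'
#' Event onsets follow a homogeneous Poisson process; each event is a
#' biexponential current (fast rise, slow exponential decay with time
#' constant `tau_decay_ms`) scaled to its drawn peak amplitude, and Gaussian
#' noise is added per sample.  Under oxytocin in an open-state condition the
#' event rate is multiplied by `oxytocin_freq_ratio`; the amplitude
#' distribution is never changed (the oxytocin effect is presynaptic,
#' frequency-only).  The returned ground truth records each event's true
#' onset, peak amplitude and 10-90\% rise time (computed from its kernel).
#'
#' @param rate_hz true mEPSC frequency before any oxytocin effect.
#' @param trace_s trace duration (s).
#' @param amp_mean_pa,amp_sd_pa amplitude distribution (pA; truncated normal,
#'   positive magnitudes).
#' @param rise_ms_mean,rise_ms_sd 10-90\% rise-time distribution (ms).
#' @param tau_decay_ms decay time constant of the event kernel (ms).
#' @param oxytocin oxytocin applied?
#' @param state_open is the critical period open in this condition?  The
#'   frequency ratio only applies when `oxytocin && state_open`.
#' @param oxytocin_freq_ratio multiplier in (0, 1] on the event rate under
#'   oxytocin in the open state (default 0.5).
#' @param sample_rate_hz sampling rate (must resolve the rise over >= 3
#'   samples).
#' @param noise_sd_pa per-sample Gaussian noise s.d. (default 1.5 pA,
#'   a typical whole-cell recording noise floor).
#' @param seed RNG seed.
#' @param events optional data frame (`onset_s`, `amplitude_pa`, `rise_ms`)
#'   of planted events, overriding random generation (noise is still added
#'   unless `noise_sd_pa = 0`).
#' @param cell_id,condition_label identifiers for the trace.
#' @return list with `trace` (a [current_trace()]), `truth` (event table),
#'   `rate_effective_hz`, `expected_events` and `low_rate` (`TRUE` when
#'   fewer than one event is expected over the trace).
#' @export
generate_mepsc_trace <- function(rate_hz = 1, trace_s = 60,
                                 amp_mean_pa = 15, amp_sd_pa = 2,
                                 rise_ms_mean = 1.5, rise_ms_sd = 0.15,
                                 tau_decay_ms = 5,
                                 oxytocin = FALSE, state_open = TRUE,
                                 oxytocin_freq_ratio = 0.5,
                                 sample_rate_hz = 10000, noise_sd_pa = 1.5,
                                 seed = 1, events = NULL,
                                 cell_id = "cell",
                                 condition_label = "saline") {
  check_positive_scalar(rate_hz, "rate_hz")
  check_positive_scalar(trace_s, "trace_s")
  check_positive_scalar(sample_rate_hz, "sample_rate_hz")
  check_positive_scalar(noise_sd_pa, "noise_sd_pa", strict = FALSE)
  if (oxytocin_freq_ratio <= 0 || oxytocin_freq_ratio > 1)
    stop("`oxytocin_freq_ratio` must be in (0, 1]", call. = FALSE)
  if (rise_ms_mean / 1000 * sample_rate_hz < 3)
    stop("sample rate too low: the mean rise time must span >= 3 samples",
         call. = FALSE)

  rate_eff <- rate_hz * if (oxytocin && state_open) oxytocin_freq_ratio else 1
  expected <- rate_eff * trace_s

  with_seed(seed, {
    if (is.null(events)) {
      events <- draw_mepsc_events(rate_eff, trace_s, amp_mean_pa, amp_sd_pa,
                                  rise_ms_mean, rise_ms_sd)
    } else {
      check_columns(events, c("onset_s", "amplitude_pa", "rise_ms"),
                    "planted events")
    }
    n_samp <- round(trace_s * sample_rate_hz)
    y <- if (noise_sd_pa > 0) stats::rnorm(n_samp, 0, noise_sd_pa) else
      numeric(n_samp)
    tt <- seq_len(n_samp) / sample_rate_hz
    tau_d <- tau_decay_ms / 1000
    rise_true <- numeric(nrow(events))
    for (i in seq_len(nrow(events))) {
      taus <- solve_tau_rise(events$rise_ms[i] / 1000, tau_d)
      rise_true[i] <- kernel_rise_1090(taus$tau_r, taus$tau_d) * 1000
      i0 <- floor(events$onset_s[i] * sample_rate_hz) + 1L
      i1 <- min(n_samp, i0 + ceiling(8 * taus$tau_d * sample_rate_hz))
      if (i0 > n_samp) next
      idx <- i0:i1
      y[idx] <- y[idx] + events$amplitude_pa[i] *
        biexp_kernel(tt[idx] - events$onset_s[i], taus$tau_r, taus$tau_d)
    }
    truth <- data.frame(onset_s = events$onset_s,
                        amplitude_pa = events$amplitude_pa,
                        rise_ms = rise_true)
    list(trace = current_trace(y, sample_rate_hz, cell_id = cell_id,
                               condition_label = condition_label,
                               oxytocin = oxytocin),
         truth = truth,
         rate_effective_hz = rate_eff,
         expected_events = expected,
         low_rate = expected < 1)
  })
}

#' Generate per-cell mEPSC summaries for a set of conditions
#'
#' Event-table-level generation (no raw traces): for each cell, a true rate
#' and amplitude mean are drawn with modest between-cell lognormal
#' variability, the Poisson event train is drawn, and the cell is summarised
#' with [summarize_cell()].  The oxytocin frequency ratio applies only to
#' cells in conditions flagged both `oxytocin` and `state_open`; amplitude
#' parameters are identical in all conditions.
#'
#' @param conditions data frame with columns `condition_label`, `n_cells`,
#'   `oxytocin` (logical), `state_open` (logical).
#' @param cell_cv lognormal coefficient of variation of the per-cell true
#'   rate (default 0.2) and, scaled by a third, of the per-cell amplitude
#'   mean.
#' @inheritParams generate_mepsc_trace
#' @return data frame of cell summaries (one row per cell, see
#'   [bind_cell_summaries()]).
#' @export
generate_mepsc_summaries <- function(conditions, rate_hz = 2, trace_s = 60,
                                     amp_mean_pa = 15, amp_sd_pa = 2,
                                     rise_ms_mean = 1.5, rise_ms_sd = 0.15,
                                     oxytocin_freq_ratio = 0.5,
                                     cell_cv = 0.2, seed = 1, cap = 200) {
  check_columns(conditions,
                c("condition_label", "n_cells", "oxytocin", "state_open"),
                "conditions")
  with_seed(seed, {
    rows <- list()
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      ratio <- if (cond$oxytocin && cond$state_open) oxytocin_freq_ratio else 1
      for (k in seq_len(cond$n_cells)) {
        cell_rate <- rate_hz * ratio *
          stats::rlnorm(1L, -0.5 * log(1 + cell_cv^2),
                        sqrt(log(1 + cell_cv^2)))
        cv_a <- cell_cv / 3
        cell_amp <- amp_mean_pa *
          stats::rlnorm(1L, -0.5 * log(1 + cv_a^2), sqrt(log(1 + cv_a^2)))
        ev <- draw_mepsc_events(cell_rate, trace_s, cell_amp, amp_sd_pa,
                                rise_ms_mean, rise_ms_sd)
        s <- summarize_cell(ev, trace_s, cap = cap,
                            cell_id = sprintf("%s_c%02d",
                                              cond$condition_label, k),
                            condition_label = cond$condition_label)
        rows[[length(rows) + 1L]] <- s
      }
    }
    bind_cell_summaries(rows)
  })
}

# ---- expression generation ------------------------------------------------

#' Default expression-study sample sheet
#'
#' The nine defined condition-timepoint pairs (saline, cocaine, ketamine and
#' LSD at 48 h and 2 weeks, plus MDMA at 48 h) with `n_reps` replicates each;
#' replicate r of every condition is assigned to batch r, so batches cut
#' across conditions and are never confounded with the open/closed contrast.
#'
#' @param n_reps replicates per condition-timepoint pair (default 3).
#' @return data frame: `sample_id`, `condition_label`, `timepoint_label`,
#'   `batch_id`.
#' @export
default_expression_design <- function(n_reps = 3) {
  pairs <- rbind(
    expand.grid(condition_label = c("saline", "cocaine", "ketamine", "LSD"),
                timepoint_label = c("48h", "2wk"),
                stringsAsFactors = FALSE),
    data.frame(condition_label = "MDMA", timepoint_label = "48h"))
  out <- pairs[rep(seq_len(nrow(pairs)), each = n_reps), ]
  out$batch_id <- paste0("batch", rep(seq_len(n_reps), nrow(pairs)))
  out$sample_id <- sprintf("%s_%s_r%d", out$condition_label,
                           out$timepoint_label, rep(seq_len(n_reps),
                                                    nrow(pairs)))
  rownames(out) <- NULL
  out[c("sample_id", "condition_label", "timepoint_label", "batch_id")]
}

#' Generate a synthetic expression study with planted state genes
#'
#' Gene-by-sample abundance matrix on a TPM-like positive scale.  Per-gene
#' baselines are lognormal; gene-specific batch offsets (log2 s.d.
#' `batch_log2fc_sd`) are applied independently of the open/closed labels; a
#' random set of `n_state_genes` genes carries a state effect of
#' `state_log2fc` log2 units (random sign per gene) in open-state samples
#' only; residual noise is Gaussian on the log2 scale with s.d. `dispersion`.
#' Open/closed truth per sample comes from [assign_state_labels()] on the
#' sample sheet.
#'
#' @param n_genes number of genes.
#' @param samples sample sheet (see [default_expression_design()]).
#' @param n_state_genes number of genes with a planted state effect.
#' @param state_log2fc magnitude (log2) of the planted open-vs-closed effect.
#' @param dispersion s.d. of log2 abundance noise (default 0.35, i.e. ~25\%
#'   biological CV).
#' @param batch_log2fc_sd s.d. (log2) of gene-specific batch offsets;
#'   requires >= 2 batches when positive.
#' @param baseline_log2_mean,baseline_log2_sd baseline log2 abundance
#'   distribution across genes.
#' @param seed RNG seed.
#' @return object of class `expression_study`: `abundance` (genes x samples
#'   matrix), `samples` (sheet), `truth` (data frame `gene`, `log2fc` for the
#'   planted genes), `state` (per-sample open/closed factor).
#' @export
generate_expression_study <- function(n_genes = 2000,
                                      samples = default_expression_design(),
                                      n_state_genes = 50, state_log2fc = 1,
                                      dispersion = 0.35,
                                      batch_log2fc_sd = 0.3,
                                      baseline_log2_mean = 5,
                                      baseline_log2_sd = 2, seed = 1) {
  check_positive_scalar(n_genes, "n_genes")
  check_positive_scalar(dispersion, "dispersion")
  check_positive_scalar(batch_log2fc_sd, "batch_log2fc_sd", strict = FALSE)
  check_columns(samples,
                c("sample_id", "condition_label", "timepoint_label",
                  "batch_id"), "sample sheet")
  if (n_state_genes < 0 || n_state_genes > n_genes)
    stop("`n_state_genes` must be in [0, n_genes]", call. = FALSE)
  design <- assign_state_labels(samples, "open_vs_closed")
  batches <- unique(samples$batch_id)
  if (batch_log2fc_sd > 0 && length(batches) < 2L)
    stop("need >= 2 batches when batch_log2fc_sd > 0", call. = FALSE)
  n_s <- nrow(samples)

  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    baseline <- stats::rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
    batch_fx <- matrix(stats::rnorm(n_genes * length(batches), 0,
                                    batch_log2fc_sd),
                       n_genes, length(batches),
                       dimnames = list(NULL, batches))
    state_genes <- sort(sample.int(n_genes, n_state_genes))
    fc <- numeric(n_genes)
    if (n_state_genes > 0)
      fc[state_genes] <- state_log2fc *
        sample(c(-1, 1), n_state_genes, replace = TRUE)
    open <- design$state == "open"
    log2x <- matrix(baseline, n_genes, n_s) +
      batch_fx[, samples$batch_id, drop = FALSE] +
      outer(fc, as.numeric(open)) +
      matrix(stats::rnorm(n_genes * n_s, 0, dispersion), n_genes, n_s)
    abundance <- 2^log2x
    dimnames(abundance) <- list(genes, samples$sample_id)
    structure(list(
      abundance = abundance,
      samples = samples,
      truth = data.frame(gene = genes[state_genes],
                         log2fc = fc[state_genes]),
      state = design$state
    ), class = "expression_study")
  })
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study: %d genes x %d samples (%d open, %d closed); %d planted state gene(s)\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(x$state == "open"), sum(x$state == "closed"),
              nrow(x$truth)))
  invisible(x)
}
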