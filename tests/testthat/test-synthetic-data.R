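# Seeded generators: determinism, law-of-large-numbers behaviour, and the
# statistical structure the downstream analyses assume.

test_that("all generators are bit-identical under a repeated seed", {
  a <- generate_scpp_cohort(12, 98, open_shift = 0.2, seed = 5)
  b <- generate_scpp_cohort(12, 98, open_shift = 0.2, seed = 5)
  expect_identical(a, b)
  r1 <- generate_reference_timecourse(seq(21, 112, by = 7), 5, seed = 6)
  r2 <- generate_reference_timecourse(seq(21, 112, by = 7), 5, seed = 6)
  expect_identical(r1, r2)
  e1 <- generate_mepsc_trace(seed = 7, trace_s = 5)
  e2 <- generate_mepsc_trace(seed = 7, trace_s = 5)
  expect_identical(e1, e2)
  x1 <- generate_expression_study(n_genes = 50, seed = 8)
  x2 <- generate_expression_study(n_genes = 50, seed = 8)
  expect_identical(x1, x2)
  # and the RNG state of the session is left untouched
  set.seed(123); before <- .Random.seed
  invisible(generate_scpp_cohort(5, 98, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("sCPP cohort honours the trajectory mean and zone-time invariants", {
  # null-effect degenerate case: flat unit trajectory, vanishing noise
  flat <- generate_scpp_cohort(10, 98, open_shift = 0, noise_sd = 1e-12,
                               seed = 1, trajectory = function(a) 1)
  expect_equal(flat$post_social_s, flat$pre_social_s, tolerance = 1e-6)
  # zone times within the session, both trials
  coh <- generate_scpp_cohort(200, 30, open_shift = 0.3, seed = 2)
  expect_true(all(coh$pre_social_s >= 0 & coh$pre_social_s <= 1800))
  expect_true(all(coh$post_social_s >= 0 & coh$post_social_s <= 1800))
  # two zone times per trial sum to the session length (pre zone pair)
  expect_equal(coh$pre_social_s + (coh$session_s - coh$pre_social_s),
               coh$session_s)
})

test_that("cohort mean converges to trajectory + open_shift (law of large numbers)", {
  big <- generate_scpp_cohort(10000, 98, open_shift = 0.2, seed = 4)
  expect_equal(mean(score_cohort(big)$records$normalized), 1.2,
               tolerance = 0.01)
})

test_that("sCPP generator rejects invalid specifications", {
  expect_error(generate_scpp_cohort(10, 98, session_s = 0), "session_s")
  expect_error(generate_scpp_cohort(10, 98, noise_sd = 0), "noise_sd")
  expect_error(generate_scpp_cohort(10, 98, open_shift = 1.5),
               "outside")  # mean 2.5 > feasible ratio 2
  expect_error(generate_scpp_cohort(10, 98,
                                    trajectory = function(a) NA_real_),
               "not defined")
})

test_that("reference timecourse validates its design", {
  expect_error(generate_reference_timecourse(c(21, 35, 98), 5),
               "4 distinct ages")
  expect_error(generate_reference_timecourse(seq(21, 112, 7), 0),
               "positive")
  expect_warning(generate_reference_timecourse(c(40, 50, 60, 70), 5),
                 "span")
})

test_that("flat reference yields a flat line; peaked reference favours the spline", {
  flat <- timecourse_from_records(generate_reference_timecourse(
    seq(21, 112, by = 7), 10, seed = 11, trajectory = function(a) 1))
  lfit <- fit_trajectory(flat, "linear", loocv = FALSE)
  expect_lt(abs(coef(lfit)[2]), 0.002)  # slope ~ 0 score units per day
  peaked <- timecourse_from_records(generate_reference_timecourse(
    seq(21, 112, by = 7), 10, seed = 12, trajectory = peaked_trajectory))
  expect_lt(fit_trajectory(peaked, "natural_spline", loocv = FALSE)$rmse,
            fit_trajectory(peaked, "linear", loocv = FALSE)$rmse)
})

test_that("mEPSC event trains are Poisson with strictly increasing times", {
  counts <- vapply(1:100, function(s)
    nrow(generate_mepsc_trace(rate_hz = 4, trace_s = 60, seed = s,
                              noise_sd_pa = 0)$truth), numeric(1))
  # mean of 100 Poisson(240) draws: s.e. ~ 1.55
  expect_equal(mean(counts), 240, tolerance = 5 / 240)
  g <- generate_mepsc_trace(rate_hz = 4, trace_s = 60, seed = 3)
  expect_true(all(diff(g$truth$onset_s) > 0))
})

test_that("a single noiseless planted event reproduces its amplitude", {
  g <- generate_mepsc_trace(trace_s = 3, noise_sd_pa = 0, seed = 1,
                            events = data.frame(onset_s = 1,
                                                amplitude_pa = 15,
                                                rise_ms = 1))
  expect_equal(max(g$trace$samples) - median(g$trace$samples), 15,
               tolerance = 0.02 * 15)
})

test_that("oxytocin halves event frequency but leaves amplitudes untouched", {
  n_ctl <- n_oxt <- amp_ctl <- amp_oxt <- numeric(30)
  for (s in 1:30) {
    ctl <- generate_mepsc_trace(rate_hz = 2, trace_s = 60, seed = 400 + s,
                                oxytocin = FALSE, noise_sd_pa = 0)
    oxt <- generate_mepsc_trace(rate_hz = 2, trace_s = 60, seed = 700 + s,
                                oxytocin = TRUE, state_open = TRUE,
                                oxytocin_freq_ratio = 0.5, noise_sd_pa = 0)
    n_ctl[s] <- nrow(ctl$truth); n_oxt[s] <- nrow(oxt$truth)
    amp_ctl[s] <- mean(ctl$truth$amplitude_pa)
    amp_oxt[s] <- mean(oxt$truth$amplitude_pa)
  }
  expect_equal(mean(n_oxt) / mean(n_ctl), 0.5, tolerance = 0.08)
  expect_gt(t.test(amp_ctl, amp_oxt)$p.value, 0.05)
  # closed state: oxytocin has no frequency effect either
  closed <- generate_mepsc_trace(rate_hz = 2, trace_s = 60, seed = 5,
                                 oxytocin = TRUE, state_open = FALSE)
  expect_equal(closed$rate_effective_hz, 2)
})

test_that("amplitude distributions stay indistinguishable at 200 events per cell", {
  nonsig <- logical(20)
  for (s in 1:20) {
    a <- generate_mepsc_trace(rate_hz = 4, trace_s = 50, seed = 900 + s,
                              noise_sd_pa = 0)$truth$amplitude_pa
    b <- generate_mepsc_trace(rate_hz = 2, trace_s = 100, seed = 950 + s,
                              oxytocin = TRUE, noise_sd_pa = 0,
                              oxytocin_freq_ratio = 0.5)$truth$amplitude_pa
    nonsig[s] <- t.test(a[1:200], b[1:200])$p.value > 0.05
  }
  expect_gte(sum(nonsig), 16)  # ~95% expected at alpha 0.05
})

test_that("trace generation flags sub-unity expected event counts", {
  g <- generate_mepsc_trace(rate_hz = 0.05, trace_s = 10, seed = 1)
  expect_true(g$low_rate)
  expect_lt(g$expected_events, 1)
  expect_error(generate_mepsc_trace(sample_rate_hz = 1000), ">= 3 samples")
})

test_that("expression generator plants exactly the recorded state genes", {
  st <- generate_expression_study(n_genes = 300, n_state_genes = 25,
                                  seed = 13)
  expect_equal(nrow(st$truth), 25)
  expect_true(all(st$truth$gene %in% rownames(st$abundance)))
  expect_true(all(abs(st$truth$log2fc) == 1))
  expect_true(all(st$abundance > 0))
  # no planted genes: open and closed expectations coincide
  null_st <- generate_expression_study(n_genes = 2000, n_state_genes = 0,
                                       dispersion = 0.2, seed = 14)
  open <- null_st$state == "open"
  diffs <- rowMeans(log2(null_st$abundance[, open])) -
    rowMeans(log2(null_st$abundance[, !open]))
  expect_lt(abs(mean(diffs)), 0.02)
  expect_equal(nrow(null_st$truth), 0)
})

test_that("a planted unit log2 fold change doubles open-state means", {
  sheet <- default_expression_design(n_reps = 30)
  st <- generate_expression_study(n_genes = 60, samples = sheet,
                                  n_state_genes = 10, state_log2fc = 1,
                                  batch_log2fc_sd = 0, seed = 15)
  open <- st$state == "open"
  for (i in seq_len(nrow(st$truth))) {
    g <- st$truth$gene[i]
    ratio <- mean(st$abundance[g, open]) / mean(st$abundance[g, !open])
    expect_equal(ratio, 2^st$truth$log2fc[i], tolerance = 0.12)
  }
})

test_that("expression generator validates its sample sheet", {
  bad <- default_expression_design()
  bad$timepoint_label[1] <- "96h"
  expect_error(generate_expression_study(n_genes = 20, n_state_genes = 0,
                                         samples = bad),
               "no defined open/closed label")
  one_batch <- default_expression_design()
  one_batch$batch_id <- "batch1"
  expect_error(generate_expression_study(n_genes = 20, n_state_genes = 0,
                                         samples = one_batch,
                                         batch_log2fc_sd = 0.3),
               ">= 2 batches")
})
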