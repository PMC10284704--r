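# Event detection, per-cell summaries, condition comparison, ECDF.

test_that("a flat trace yields no events and short traces are refused", {
  flat <- current_trace(rep(0, 20000), 10000)
  expect_equal(nrow(detect_events(flat)), 0)
  expect_error(detect_events(current_trace(rep(0, 100), 10000)),
               "baseline window")
  expect_error(detect_events(current_trace(rep(0, 20000), 1000)),
               "2 kHz")
})

test_that("noiseless planted events are recovered exactly with accurate amplitudes", {
  planted <- data.frame(onset_s = seq(0.5, 9.5, by = 1),
                        amplitude_pa = 15, rise_ms = 1)
  g <- generate_mepsc_trace(trace_s = 10.5, noise_sd_pa = 0, seed = 1,
                            events = planted)
  ev <- detect_events(g$trace)
  expect_equal(nrow(ev), 10)
  expect_lt(max(abs(ev$amplitude_pa - 15)) / 15, 0.05)
  expect_lt(max(abs(ev$onset_s - planted$onset_s)), 0.003)
  expect_true(all(ev$rise_ms < 3))
  expect_true(all(diff(ev$onset_s) > 0))
})

test_that("the 5 pA and 3 ms acquisition filters reject planted violations", {
  bad <- data.frame(onset_s = c(1, 3, 5),
                    amplitude_pa = c(4, 15, 15),   # sub-threshold first
                    rise_ms = c(1, 5, 1))          # slow-rise second
  g <- generate_mepsc_trace(trace_s = 7, noise_sd_pa = 0, seed = 1,
                            events = bad)
  ev <- detect_events(g$trace)
  expect_equal(nrow(ev), 1)   # only the 15 pA / 1 ms event survives
  expect_equal(ev$onset_s, 5, tolerance = 0.01)
})

test_that("negative-going raw traces are rectified at ingest", {
  planted <- data.frame(onset_s = c(1, 2.5), amplitude_pa = 12, rise_ms = 1)
  g <- generate_mepsc_trace(trace_s = 4, noise_sd_pa = 0, seed = 1,
                            events = planted)
  neg <- current_trace(-g$trace$samples, g$trace$sample_rate_hz)
  ev <- detect_events(neg)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$amplitude_pa, c(12, 12), tolerance = 0.05 * 12)
})

test_that("detector recall and precision reach 0.95 on realistic traces", {
  stats_ <- t(vapply(1:4, function(s) {
    g <- generate_mepsc_trace(rate_hz = 1, trace_s = 60, seed = s)
    ev <- detect_events(g$trace)
    hit <- outer(ev$onset_s, g$truth$onset_s,
                 function(a, b) abs(a - b) < 0.005)
    c(recall = sum(apply(hit, 2, any)) / nrow(g$truth),
      precision = sum(apply(hit, 1, any)) / nrow(ev))
  }, numeric(2)))
  expect_gte(mean(stats_[, "recall"]), 0.95)
  expect_gte(mean(stats_[, "precision"]), 0.95)
})

test_that("cell summaries compute frequency, IEIs, and the 200-event cap", {
  ev <- data.frame(onset_s = 1:10, amplitude_pa = 8, rise_ms = 1)
  s <- summarize_cell(ev, duration_s = 10)
  expect_equal(s$frequency_hz, 1)
  expect_equal(s$ieis_s, rep(1, 9))
  expect_equal(s$n_events_used, 10)

  many <- data.frame(onset_s = sort(runif(250, 0, 10)),
                     amplitude_pa = 8, rise_ms = 1)
  s2 <- summarize_cell(many, duration_s = 10, cap = 200)
  expect_equal(s2$n_events_used, 200)
  expect_equal(length(s2$ieis_s), 199)
  # frequency over the time needed to collect the capped events
  expect_equal(s2$frequency_hz, 200 / sort(many$onset_s)[200])

  none <- summarize_cell(empty_event <- data.frame(onset_s = numeric(0),
                                                   amplitude_pa = numeric(0)),
                         duration_s = 10)
  expect_true(none$no_events)
  expect_equal(none$frequency_hz, 0)
  expect_equal(length(none$ieis_s), 0)
})

test_that("inter-event intervals of a Poisson train follow the exponential law", {
  d <- vapply(1:10, function(s) {
    g <- generate_mepsc_trace(rate_hz = 4, trace_s = 300, seed = 50 + s,
                              noise_sd_pa = 0)
    cs <- summarize_cell(g$truth, 300, cap = 1000)
    as.numeric(ks.test(cs$ieis_s, pexp, rate = 4)$statistic)
  }, numeric(1))
  # mean KS distance to the true Exp(rate) shrinks like 0.87/sqrt(n)
  expect_lt(mean(d), 0.05)
})

test_that("condition comparison dissociates frequency from amplitude", {
  conds <- data.frame(condition_label = c("saline_oxt", "lsd_oxt"),
                      n_cells = 8, oxytocin = TRUE,
                      state_open = c(FALSE, TRUE))
  sm <- generate_mepsc_summaries(conds, rate_hz = 2,
                                 oxytocin_freq_ratio = 0.5, seed = 33)
  cc <- condition_comparison(sm)
  expect_lt(cc$frequency$p_value, 0.05)
  expect_gt(cc$amplitude$p_value, 0.05)
  expect_equal(cc$frequency$df, c(1, 14))
  # identical summaries in both conditions: both tests null
  dup <- data.frame(condition_label = rep(c("a", "b"), each = 4),
                    frequency_hz = rep(c(1, 2, 1.5, 1.8), 2),
                    mean_amplitude_pa = rep(c(14, 15, 16, 15.5), 2))
  cc2 <- condition_comparison(dup)
  expect_equal(cc2$frequency$p_value, 1, tolerance = 1e-9)
  expect_equal(cc2$amplitude$p_value, 1, tolerance = 1e-9)
})

test_that("single-cell conditions are excluded with a warning record", {
  sm <- data.frame(condition_label = c("a", "a", "a", "b", "b", "lone"),
                   frequency_hz = c(1, 2, 1.5, 1.2, 1.8, 9),
                   mean_amplitude_pa = c(15, 16, 14, 15, 15, 30))
  expect_warning(cc <- condition_comparison(sm), "lone")
  expect_equal(cc$excluded_conditions, "lone")
  expect_equal(sort(cc$group_means$condition_label), c("a", "b"))
})

test_that("permuted condition labels reject at about the nominal rate", {
  conds <- data.frame(condition_label = c("x", "y"), n_cells = 8,
                      oxytocin = FALSE, state_open = FALSE)
  sm <- generate_mepsc_summaries(conds, rate_hz = 2, seed = 44)
  set.seed(45)
  sig <- vapply(1:60, function(i) {
    p <- sm; p$condition_label <- sample(p$condition_label)
    condition_comparison(p)$frequency$p_value <= 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.15)
})

test_that("the empirical CDF is right-continuous and reaches 1", {
  cd <- cumulative_distribution(c(1, 2, 3))
  expect_equal(cd$cumulative_probability[cd$value == 2], 2 / 3)
  expect_equal(max(cd$cumulative_probability), 1)
  dup <- cumulative_distribution(c(1, 1, 2))
  expect_equal(dup$cumulative_probability[dup$value == 1], c(2 / 3, 2 / 3))
  expect_error(cumulative_distribution(numeric(0)), "empty")
  # DKW: a large uniform sample stays near the identity CDF
  set.seed(46)
  u <- runif(2000)
  cdu <- cumulative_distribution(u)
  expect_lt(max(abs(cdu$cumulative_probability - cdu$value)), 0.05)
})
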