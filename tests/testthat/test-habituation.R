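test_that("window detection finds peak 8 s / return 18 s on clean input", {
  cfg <- noiseless_cfg()
  run <- simulate_roi_run(cfg, -0.1, 10, seed = 1)
  win <- detect_window(run$left$signal, cfg$tr_seconds)
  expect_equal(win$t_peak_s, 8)
  expect_equal(win$t_return_s, 18)
  expect_equal(win$duration_s, 10)
  expect_identical(win$start_index, 4L)
  expect_identical(win$end_index, 9L)
})

test_that("window detection rejects degenerate series", {
  tr <- 2
  # strictly decreasing from onset: peak at t = 0 has no novelty rise
  expect_error(detect_window(seq(10, 0, length.out = 15), tr),
               "onset")
  # never returns to baseline
  expect_error(detect_window(c(0, 5, 10, rep(9, 12)), tr),
               "return to baseline")
  # peak at the final volume: no decay segment
  expect_error(detect_window(seq(0, 10, length.out = 15), tr,
                             max_return_s = 30), "final volume")
  # too short to cover 20 s post-onset
  expect_error(detect_window(c(0, 5, 10, 5, 0), tr), "20 s")
})

test_that("window detection refuses windows containing target onsets", {
  cfg <- noiseless_cfg()
  run <- simulate_roi_run(cfg, -0.1, 10, seed = 1)
  expect_error(detect_window(run$left$signal, cfg$tr_seconds,
                             target_onsets = c(12)), "target onsets")
  win <- detect_window(run$left$signal, cfg$tr_seconds,
                       target_onsets = c(2, 40))
  expect_equal(win$duration_s, 10)
})

test_that("novelty amplitude reads the window-start signal", {
  cfg <- noiseless_cfg()
  run <- simulate_roi_run(cfg, -0.1, 10, seed = 1)
  win <- default_window()
  expect_equal(novelty_amplitude(run$left, win), 10)
  expect_equal(novelty_amplitude(rep(0, 30), win), 0)
  # short average at window start: volumes 4 and 5 hold 10 and 8
  expect_equal(novelty_amplitude(run$left, win, width = 2), 9)
})

test_that("novelty estimate is unbiased under symmetric noise", {
  cfg <- sim_config(noise_sd = 1, outlier_rate = 0)
  win <- default_window()
  est <- vapply(1:500, function(i) {
    run <- simulate_roi_run(cfg, -0.1, 10, seed = 1000L + i)
    novelty_amplitude(run$left, win)
  }, numeric(1))
  expect_lt(abs(mean(est) - 10), 3 * sd(est) / sqrt(500))
})

test_that("slope estimation matches the analytic line and the OLS oracle", {
  win <- default_window()
  # constant signal: zero slope, zero normalized slope
  h <- habituation_slope(rep(4, 30), win, tr_seconds = 2)
  expect_equal(h$raw_slope_b, 0)
  expect_equal(h$b_prime, 0)
  # noiseless decline from 10 at 8 s to 0 at 18 s
  cfg <- noiseless_cfg()
  run <- simulate_roi_run(cfg, -0.1, 10, seed = 1)
  h <- habituation_slope(run$left, win)
  expect_equal(h$raw_slope_b, -1)
  expect_equal(h$b_prime, -0.1)
  expect_identical(h$n_window_volumes, 6L)
  # randomized fixtures against the normal-equations oracle
  set.seed(77)
  for (rep in 1:5) {
    sig <- rnorm(30, sd = 3) + 5
    h <- habituation_slope(sig, win, tr_seconds = 2)
    t_win <- (4:9) * 2
    expect_lt(abs(h$raw_slope_b - oracle_slope(t_win, sig[5:10])), 1e-10)
  }
})

test_that("slope estimation validates its window", {
  win <- default_window()
  expect_error(habituation_slope(rnorm(8), win, tr_seconds = 2),
               "beyond the series")
  expect_error(habituation_slope(c(rnorm(29), NaN), win, tr_seconds = 2),
               "non-finite")
  narrow <- habituation_window(8, 10, 4)  # volumes 2..2 at TR 4
  expect_error(habituation_slope(rnorm(30), narrow, tr_seconds = 4),
               "at least 3")
})

test_that("normalized slope is invariant to positive rescaling", {
  win <- default_window()
  set.seed(123)
  sig <- rnorm(30) + 6
  b1 <- habituation_slope(sig, win, tr_seconds = 2)$b_prime
  for (c in c(0.25, 3, 1e4)) {
    b2 <- habituation_slope(c * sig, win, tr_seconds = 2)$b_prime
    expect_lt(abs(b1 - b2), 1e-12)
  }
})

test_that("steeper decay strictly decreases the estimated slope", {
  cfg <- noiseless_cfg()
  win <- default_window()
  slopes <- c(-0.02, -0.05, -0.08, -0.1)
  est <- vapply(slopes, function(b) {
    habituation_slope(simulate_roi_run(cfg, b, 10, seed = 1)$left,
                      win)$b_prime
  }, numeric(1))
  expect_true(all(diff(est) < 0))
  expect_equal(est, slopes)
})

test_that("near-zero novelty flags b_prime unreliable but keeps raw slope", {
  win <- default_window()
  set.seed(55)
  sig <- rnorm(30, sd = 2)
  sig[5] <- 1e-4  # window-start amplitude far below the guard
  h <- habituation_slope(sig, win, tr_seconds = 2)
  expect_true(h$unreliable)
  expect_true(is.na(h$b_prime))
  expect_true(is.finite(h$raw_slope_b))
})

test_that("parameter recovery: mean estimated b' approaches truth", {
  cfg <- sim_config(noise_sd = 1, outlier_rate = 0)
  win <- default_window()
  truth <- -0.12
  est <- vapply(1:500, function(i) {
    run <- simulate_roi_run(cfg, truth, 10, seed = 5000L + i,
                            enforce_range = FALSE)
    habituation_slope(average_hemispheres(run$left,
                                          run$right)$series, win)$b_prime
  }, numeric(1))
  expect_lt(abs(mean(est) - truth), 2 * sd(est) / sqrt(500))
  # RMSE shrinks as noise vanishes
  est_low <- vapply(1:100, function(i) {
    run <- simulate_roi_run(sim_config(noise_sd = 0.1, outlier_rate = 0),
                            truth, 10, seed = 8000L + i,
                            enforce_range = FALSE)
    habituation_slope(run$left, win)$b_prime
  }, numeric(1))
  expect_lt(sqrt(mean((est_low - truth)^2)),
            sqrt(mean((est - truth)^2)))
})

test_that("percent-slower re-expresses the group beta in points", {
  expect_equal(percent_slower(0.11), 11)
  expect_equal(percent_slower(0), 0)
  expect_equal(percent_slower(0.16), 16)
  expect_error(percent_slower(NA_real_))
})

test_that("compute_slopes maps cells of a tidy table", {
  cfg <- noiseless_cfg(n_control = 2, n_patient = 1)
  sim <- simulate_cohort(cfg)
  avg <- hemi_average_table(sim$timeseries)
  sl <- compute_slopes(avg, default_window(), cfg$tr_seconds)
  expect_identical(nrow(sl), nrow(unique(
    avg[, c("participant_id", "visit", "region")])))
  gt <- sim$ground_truth$slopes
  m <- merge(sl, gt, by = c("participant_id", "visit", "region"))
  expect_equal(m$b_prime, m$true_b_prime, tolerance = 1e-8)
})
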