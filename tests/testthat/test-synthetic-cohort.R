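test_that("trial schedule never places targets in the first 10 s", {
  cfg <- sim_config()
  for (seed in c(1L, 17L, 2024L)) {
    sched <- build_trial_schedule(cfg, seed)
    expect_false(any(sched$is_target[sched$onset_s < 10]))
    expect_equal(sched$onset_s, seq(0, 119, by = 1))
  }
})

test_that("trial schedule respects the target rate and the seed", {
  cfg <- sim_config()
  expect_false(any(build_trial_schedule(sim_config(target_fraction = 0),
                                        5L)$is_target))
  # long run, one seed: binomial 95% band around 0.10 among eligible trials
  long <- sim_config(run_duration_s = 2400)
  sched <- build_trial_schedule(long, 11L)
  eligible <- sched$onset_s >= 10
  rate <- mean(sched$is_target[eligible])
  band <- 1.96 * sqrt(0.1 * 0.9 / sum(eligible))
  expect_lt(abs(rate - 0.10), band + 1e-12)
  expect_identical(build_trial_schedule(cfg, 7L),
                   build_trial_schedule(cfg, 7L))
})

test_that("noiseless run follows the piecewise-linear shape", {
  cfg <- noiseless_cfg()
  # zero slope: constant at the novelty amplitude across the window
  run <- simulate_roi_run(cfg, 0, 10, seed = 1)
  tt <- (seq_along(run$left$signal) - 1) * cfg$tr_seconds
  inwin <- tt >= 8 & tt <= 18
  expect_equal(run$left$signal[inwin], rep(10, sum(inwin)))
  expect_identical(run$left$signal, run$right$signal)
  # full linear return to baseline: 10 at 8 s, slope -0.1/s -> 0 at 18 s
  run <- simulate_roi_run(cfg, -0.1, 10, seed = 1)
  expect_equal(run$left$signal[tt == 18], 0)
  expect_equal(run$left$signal[tt == 8], 10)
  expect_equal(run$left$signal[tt == 12], 6)
})

test_that("undershoot guard errors and names the offending parameters", {
  cfg <- noiseless_cfg()
  expect_error(simulate_roi_run(cfg, -0.15, 10, seed = 1),
               "true_b_prime.*true_novelty")
  expect_silent(simulate_roi_run(cfg, -0.15, 10, seed = 1,
                                 enforce_range = FALSE))
})

test_that("left/right noise correlation matches the configured value", {
  cfg <- sim_config(run_duration_s = 1200, noise_sd = 1,
                    hemi_correlation = 0.8, outlier_rate = 0)
  run <- simulate_roi_run(cfg, -0.1, 10, seed = 42)
  nv <- length(run$left$signal)
  late <- seq(floor(30 / cfg$tr_seconds), nv)  # noise-dominated segment
  r <- cor(run$left$signal[late], run$right$signal[late])
  expect_lt(abs(r - 0.8), 0.05)
})

test_that("simulated slope draws match the configured cell distribution", {
  cfg <- sim_config(n_control = 500, n_patient = 500,
                    regions = "anterior_hippocampus")
  st <- simulate_slope_table(cfg, seed = 3)
  cell <- st[st$group == "control" & st$visit == "baseline", "b_prime"]
  expect_length(cell, 500)
  expect_lt(abs(mean(cell) + 0.16), 2 * sd(cell) / sqrt(500))
  expect_lt(abs(sd(cell) - 0.3), 0.3 / sqrt(2 * (500 - 1)) * 3)
})

test_that("cohort simulation is deterministic and honors group structure", {
  cfg <- quiet_cfg(seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$runs, b$runs)
  expect_identical(a$ground_truth$slopes, b$ground_truth$slopes)

  ctl_only <- simulate_cohort(sim_config(n_control = 4, n_patient = 0,
                                         outlier_rate = 0))
  expect_true(all(ctl_only$cohort$group == "control"))
  expect_true(all(is.na(ctl_only$cohort$panss_total)))
  expect_true(all(is.na(ctl_only$cohort$cpz_mg)))
})

test_that("cohort invariants: clinical fields only for patients, in range", {
  sim <- simulate_cohort(quiet_cfg(seed = 2))
  co <- sim$cohort
  pat <- co$group == "patient"
  expect_true(all(is.na(co$panss_total[!pat])))
  expect_true(all(co$panss_positive[pat] >= 7))
  expect_true(all(co$panss_negative[pat] >= 7))
  expect_true(all(co$ham_d[pat] >= 0))
  expect_true(all(co$cpz_mg[pat] >= 0))
  expect_true(all(co$cpz_mg[pat][!co$on_antipsychotic[pat]] == 0))
  expect_setequal(unique(co$visit), c("baseline", "followup"))
})

test_that("NIfTI fixture round-trips through extraction", {
  skip_if_not_installed("RNifti")
  cfg <- noiseless_cfg(run_duration_s = 40)
  run <- simulate_roi_run(cfg, -0.1, 10, seed = 1)
  paths <- write_nifti_fixture(run, dir = tempdir(), prefix = "rt")
  img <- RNifti::readNifti(paths$image)
  mskL <- RNifti::readNifti(paths$mask_left)
  expect_equal(extract_roi_timeseries(img, mskL), run$left$signal,
               tolerance = 1e-6)
  # single-voxel mask equals that voxel's series
  p1 <- write_nifti_fixture(run, left_voxels = cbind(2, 2, 2),
                            right_voxels = cbind(5, 5, 2),
                            dir = tempdir(), prefix = "vox1")
  img1 <- RNifti::readNifti(p1$image)
  expect_equal(extract_roi_timeseries(img1, RNifti::readNifti(p1$mask_left)),
               run$left$signal, tolerance = 1e-6)
})

test_that("voxel averaging reduces extraction noise like sigma/sqrt(m)", {
  cfg <- noiseless_cfg(run_duration_s = 400)
  run <- simulate_roi_run(cfg, 0, 0.5, seed = 1)
  m <- 16
  vox <- as.matrix(expand.grid(2:5, 2:5, 2))
  set.seed(11)
  paths <- write_nifti_fixture(run, dim_xyz = c(8, 8, 4), left_voxels = vox,
                               right_voxels = cbind(7, 7, 3),
                               voxel_noise_sd = 1, dir = tempdir(),
                               prefix = "avg")
  ext <- extract_roi_timeseries(RNifti::readNifti(paths$image),
                                RNifti::readNifti(paths$mask_left))
  noise <- ext - run$left$signal
  expect_lt(abs(sd(noise) - 1 / sqrt(m)), 3 * (1 / sqrt(m)) / sqrt(2 * 199))
})

test_that("overlapping or empty fixture masks are rejected", {
  cfg <- noiseless_cfg(run_duration_s = 40)
  run <- simulate_roi_run(cfg, 0, 1, seed = 1)
  expect_error(write_nifti_fixture(run, left_voxels = cbind(2, 2, 2),
                                   right_voxels = cbind(2, 2, 2)),
               "overlap")
  expect_error(write_nifti_fixture(run,
                                   left_voxels = matrix(0, 0, 3),
                                   right_voxels = cbind(2, 2, 2)),
               "empty mask")
})
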