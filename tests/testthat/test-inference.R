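test_that("one-sample habituation test matches the closed form", {
  # symmetric values: t = 0, one-sided p exactly 0.5
  r <- one_sample_habituation_test(c(-1, 0, 1))
  expect_identical(r$t, 0)
  expect_identical(r$p, 0.5)
  # all values near -c: p approaches 0
  set.seed(2)
  r2 <- one_sample_habituation_test(-0.5 + rnorm(40, sd = 1e-3))
  expect_lt(r2$p, 1e-10)
  # seed-fixed draw vs the brute-force formula
  set.seed(64)
  x <- rnorm(64, -0.1, 0.3)
  r3 <- one_sample_habituation_test(x)
  t_hand <- mean(x) / (sd(x) / sqrt(64))
  expect_lt(abs(r3$t - t_hand), 1e-10)
  expect_lt(abs(r3$p - pt(t_hand, 63)), 1e-10)
  expect_identical(r3$df, 63)
  expect_error(one_sample_habituation_test(rep(-1, 10)), "variance")
  expect_error(one_sample_habituation_test(c(-1, 1)), "at least 3")
})

test_that("one-sided p values of sign-flipped data sum to 1", {
  set.seed(9)
  for (rep in 1:5) {
    x <- rnorm(20, -0.1, 0.2)
    p1 <- one_sample_habituation_test(x)$p
    p2 <- one_sample_habituation_test(-x)$p
    expect_equal(p1 + p2, 1)
  }
})

test_that("mixed model reduces to two-factor least squares when balanced", {
  # balanced complete data simulated with zero participant-level variance
  set.seed(42)
  n <- 40
  d <- expand.grid(participant_id = sprintf("P%02d", 1:n),
                   visit = c("baseline", "followup"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("P", "", d$participant_id)) <= n / 2,
                    "control", "patient")
  d$b_prime <- -0.1 + 0.1 * (d$group == "patient") -
    0.05 * (d$visit == "followup") + rnorm(nrow(d), sd = 0.2)
  fit <- fit_group_time_model(d, region = "r")
  ols <- lm(b_prime ~ group + visit, data = d)
  expect_lt(abs(fit$beta[fit$effect == "group"] -
                  coef(ols)["grouppatient"]), 1e-8)
  expect_lt(abs(fit$beta[fit$effect == "time"] -
                  coef(ols)["visitfollowup"]), 1e-8)
  # between-within denominator df for the group effect: subjects - 2
  expect_equal(fit$df_den[fit$effect == "group"], n - 2)
  expect_equal(fit$percent_slower[fit$effect == "group"],
               100 * fit$beta[fit$effect == "group"])
})

test_that("mixed model recovers a simulated group difference", {
  cfg <- sim_config(n_control = 300, n_patient = 300,
                    regions = "anterior_hippocampus")
  st <- simulate_slope_table(cfg, seed = 5)
  fit <- fit_group_time_model(st, region = "anterior_hippocampus")
  g <- fit[fit$effect == "group", ]
  delta_true <- mean(c(-0.06 - -0.16, 0.00 - -0.11))  # configured cells
  expect_lt(abs(g$beta - delta_true), 2 * g$se)
  expect_gt(g$F, 0)
})

test_that("mixed model keeps participants with a single visit", {
  cfg <- sim_config(n_control = 30, n_patient = 30,
                    regions = "anterior_hippocampus")
  st <- simulate_slope_table(cfg, seed = 8)
  # drop the follow-up visit for a third of participants
  drop <- unique(st$participant_id)[1:20]
  st <- st[!(st$participant_id %in% drop & st$visit == "followup"), ]
  fit <- fit_group_time_model(st, region = "anterior_hippocampus")
  expect_identical(nrow(fit), 2L)
  expect_true(all(is.finite(fit$p)))
  expect_equal(fit$df_den[fit$effect == "group"], 60 - 2)
})

test_that("mixed model validates its input", {
  cfg <- sim_config(n_control = 10, n_patient = 0,
                    regions = "anterior_hippocampus")
  st <- simulate_slope_table(cfg, seed = 1)
  expect_error(fit_group_time_model(st), "both groups")
  expect_error(fit_group_time_model(st[0, ]), "no usable")
})

test_that("Cohen's d follows the default formula and stays pluggable", {
  expect_equal(cohen_d_from_model(t = 0, df = 50), 0)
  expect_equal(cohen_d_from_model(F = 4, df = 100), 0.4)
  expect_equal(cohen_d_from_model(F = 11.92, df = 136),
               2 * sqrt(11.92) / sqrt(136))
  alt <- function(t, df) t * sqrt(2 / df)
  expect_equal(cohen_d_from_model(t = 3, df = 50, formula = alt),
               3 * sqrt(2 / 50))
  expect_error(cohen_d_from_model(df = 10), "supply t or F")
})

test_that("Spearman screen matches rank-then-Pearson and handles ties", {
  set.seed(17)
  d <- data.frame(group = "patient", visit = "baseline", region = "r",
                  b_prime = c(rnorm(8), 1.5, 1.5),  # tied values
                  m1 = rnorm(10), m2 = rnorm(10))
  res <- spearman_screen(d, measures = c("m1", "m2"))
  expect_lt(abs(res$rho[res$measure == "m1"] -
                  oracle_spearman(d$b_prime, d$m1)), 1e-12)
  # perfectly monotone pair
  d2 <- data.frame(group = "g", visit = "v", region = "r",
                   b_prime = 1:10, m1 = (1:10)^3)
  expect_equal(spearman_screen(d2, "m1")$rho, 1)
})

test_that("Spearman screen flags constant columns instead of dropping them", {
  d <- data.frame(group = "g", visit = "v", region = "r",
                  b_prime = rnorm(10), m1 = rep(2, 10), m2 = rnorm(10))
  res <- spearman_screen(d, c("m1", "m2"))
  expect_true(is.na(res$rho[res$measure == "m1"]))
  expect_match(res$note[res$measure == "m1"], "constant")
  expect_true(is.finite(res$rho[res$measure == "m2"]))
  expect_identical(unique(res$family_size), 1L)
})

test_that("Holm correction never lowers p and equals raw p alone", {
  set.seed(30)
  d <- data.frame(group = "g", visit = "v", region = "r",
                  b_prime = rnorm(20),
                  m1 = rnorm(20), m2 = rnorm(20), m3 = rnorm(20))
  res <- spearman_screen(d, c("m1", "m2", "m3"))
  expect_true(all(res$p_fwe >= res$p_raw))
  solo <- spearman_screen(d, "m1")
  expect_equal(solo$p_fwe, solo$p_raw)
})

test_that("familywise false-positive rate stays at or below alpha", {
  # n = 12 pairs keeps the Spearman null distribution exact (tie-free),
  # so the Holm familywise guarantee applies without approximation error
  set.seed(77)
  n_rep <- 400
  fp <- 0L
  for (i in seq_len(n_rep)) {
    d <- data.frame(group = "g", visit = "v", region = "r",
                    b_prime = rnorm(12))
    for (j in 1:8) d[[paste0("m", j)]] <- rnorm(12)
    res <- spearman_screen(d, paste0("m", 1:8))
    fp <- fp + any(res$significant)
  }
  rate <- fp / n_rep
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("chi-square test equals the brute-force loop and handles edge cases", {
  set.seed(12)
  for (rep in 1:5) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    r <- categorical_group_test(tab)
    expect_lt(abs(r$statistic - oracle_chisq(tab)), 1e-12)
    expect_identical(r$df, 2L)
  }
  # identical row proportions: statistic 0
  expect_equal(categorical_group_test(rbind(c(10, 30), c(5, 15)))$statistic,
               0)
  expect_error(categorical_group_test(rbind(c(0, 0), c(5, 15))),
               "zero marginal")
  expect_error(categorical_group_test(matrix(1:3, 1)), "2x2")
})

test_that("counts reconstruct from printed percentages", {
  expect_identical(reconstruct_counts(72, 68)[["count"]], 49L)
  expect_identical(reconstruct_counts(84, 64)[["count"]], 54L)
  expect_identical(reconstruct_counts(0, 50)[["count"]], 0L)
  expect_identical(sum(reconstruct_counts(77, 70)), 70L)
  # ties round half up
  expect_identical(reconstruct_counts(50, 5)[["count"]], 3L)
})

test_that("two-sample power follows the noncentral t distribution", {
  expect_equal(two_sample_power(0, 20, 20), 0.05, tolerance = 1e-10)
  expect_gt(two_sample_power(5, 20, 20), 0.999)
  # monotone in effect size and sample size
  expect_gt(two_sample_power(0.6, 50, 50), two_sample_power(0.4, 50, 50))
  expect_gt(two_sample_power(0.4, 80, 80), two_sample_power(0.4, 40, 40))
  expect_error(two_sample_power(0.5, 1, 20))
})
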