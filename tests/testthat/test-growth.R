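test_that("noise-free data recover the generating cubic exactly", {
  sim <- noiseless_cohort(n = 80, seed = 11)
  fit <- fit_cubic_lmm(sim$newborns)
  expect_true(fit$degenerate)
  expect_equal(fit$beta, published_beta, tolerance = 1e-6)
  expect_equal(fit$sd_resid, 0)
  # predictions equal the generating curve, and NWC at the nadir equals truth
  nw <- nwc_table(fit, sim$newborns)
  expect_equal(nw$nwc, sim$truth$subjects$nwc_true, tolerance = 1e-6)
})

test_that("noisy mixed-model fit recovers coefficients and random effects", {
  sim <- generate_newborns(growth_sim_params(n_newborns = 1500, seed = 21))
  fit <- fit_cubic_lmm(sim$newborns)
  expect_false(fit$degenerate)
  expect_equal(fit$beta[1], 3241.442, tolerance = 0.02)   # relative ~2%
  expect_lt(abs(fit$beta[2] - (-9.378)), 2)
  expect_lt(abs(sqrt(fit$re_cov[1, 1]) - 400), 60)
  expect_lt(abs(fit$sd_resid - 50), 20)
  # BLUP-based NWC tracks the per-subject truth
  nw <- nwc_table(fit, sim$newborns)
  # empirical-Bayes shrinkage and 50 g residual noise on two observations
  # bound how well per-subject NWC can be recovered
  expect_gt(cor(nw$nwc, sim$truth$subjects$nwc_true), 0.5)
  expect_lt(abs(mean(nw$nwc) - mean(sim$truth$subjects$nwc_true)), 0.5)
})

test_that("population nadir solves the stationarity condition in closed form", {
  expect_equal(population_nadir(c(0, -2, 1, 0)), 1)          # parabola vertex
  expect_equal(population_nadir(published_beta), 54.23307, tolerance = 1e-4)
  expect_error(population_nadir(c(0, 2, 1, 0)), "no interior minimum")
  expect_error(population_nadir(c(0, 1, -1, 0)), "no interior minimum")
})

test_that("closed-form nadir agrees with grid minimization", {
  set.seed(6)
  grid <- seq(0.001, 96, by = 0.001)
  checked <- 0
  while (checked < 20) {
    beta <- c(3200, runif(1, -15, -2), runif(1, 0.02, 0.3),
              runif(1, -0.002, -0.0001))
    t_cf <- tryCatch(population_nadir(beta), error = function(e) NULL)
    if (is.null(t_cf)) next
    t_grid <- grid[which.min(eval_cubic(grid, beta))]
    expect_lt(abs(t_cf - t_grid), 0.01)
    checked <- checked + 1
  }
})

test_that("subject-level prediction adds the predicted random effects", {
  sim <- generate_newborns(growth_sim_params(n_newborns = 300, seed = 13))
  fit <- fit_cubic_lmm(sim$newborns)
  id1 <- fit$ranef$id[1]
  b <- fit$ranef[1, ]
  expect_equal(predict_weight(fit, id1, 0), fit$beta[1] + b$b0)
  expect_equal(predict_weight(fit, id1, 30),
               eval_cubic(30, fit$beta) + b$b0 + b$b1 * 30)
  expect_error(predict_weight(fit, "nope", 10), "unknown id")
})

test_that("NWC formula and hourly rate are exact arithmetic", {
  expect_equal(compute_nwc(100, 93.14), -6.86)
  expect_equal(compute_nwc(3000, 3000), 0)
  expect_error(compute_nwc(0, 10), "positive")
  # the published curve evaluated at 52.3 h reproduces the published mean NWC
  expect_equal(compute_nwc(eval_cubic(0), eval_cubic(52.3)), -6.86,
               tolerance = 0.01)
  expect_equal(hourly_change_rate(1000, 900, 20), -0.5)
  expect_equal(hourly_change_rate(1000, 1000, 48), 0)
  expect_equal(hourly_change_rate(3000, 2820, 12), -0.5)
  expect_error(hourly_change_rate(1000, 900, 0), "positive")
})

test_that("exclusion cascade applies stages in order and conserves counts", {
  d <- cascade_fixture()
  res <- apply_exclusion_cascade(d)
  rep <- res$report
  expect_equal(rep$n_excluded, c(471, 28, 19, 0))
  expect_equal(rep$n_remaining, c(1335, 1307, 1288, 1288))
  expect_equal(nrow(res$kept), 1288)
  expect_equal(sum(res$reasons == "outlier_low"), 15)
  expect_equal(sum(res$reasons == "outlier_high"), 4)
  # conservation at every stage
  expect_equal(nrow(d) - cumsum(rep$n_excluded), rep$n_remaining)
  # each record carries exactly one reason
  expect_true(all(res$reasons %in% c("none", "missing_time", "after_96h",
                                     "outlier_low", "outlier_high",
                                     "incomplete_covariates")))
  txt <- format_cascade(rep)
  expect_match(txt[1], "1806")
  expect_match(txt[length(txt)], "1288")
})

test_that("Tukey fences flag exactly the constructed outlier", {
  rates <- c(rep(-0.15, 9) + seq(-0.02, 0.02, length.out = 9), -0.9)
  d <- data.frame(id = letters[1:10], birthweight = 1000,
                  meas_time = 10, meas_weight = 1000 * (1 + rates * 10 / 100))
  res <- apply_exclusion_cascade(d, key_vars = character(0))
  q <- quantile(rates, c(0.25, 0.75), names = FALSE)
  fence_lo <- q[1] - 3 * (q[2] - q[1])
  expect_equal(res$fences[1], fence_lo)
  expect_identical(which(res$reasons == "outlier_low"), 10L)
  expect_equal(nrow(res$kept), 9)

  clean <- d[1:9, ]
  res2 <- apply_exclusion_cascade(clean, key_vars = character(0))
  expect_equal(res2$report$n_excluded, rep(0L, 4), ignore_attr = TRUE)
  expect_error(apply_exclusion_cascade(d[0, ]), "empty")
})

test_that("fixed fences override the empirical ones", {
  d <- cascade_fixture()
  res <- apply_exclusion_cascade(d, fences = c(-0.50, 0.19))
  expect_equal(res$fences, c(-0.50, 0.19))
  # constructed extreme groups sit outside the published fences too
  expect_equal(sum(res$reasons %in% c("outlier_low", "outlier_high")), 19)
})
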