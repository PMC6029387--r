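# closed-form MVN loglik used as an independent oracle for FIML on complete data
mvn_loglik_byhand <- function(X, mu, Sigma) {
  k <- ncol(X)
  Sinv <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  s <- 0
  for (i in seq_len(nrow(X))) {
    d <- as.numeric(X[i, ]) - mu
    s <- s + (-0.5) * (k * log(2 * pi) + ld + drop(t(d) %*% Sinv %*% d))
  }
  as.numeric(s)
}

test_that("model variants carry exactly the published regressor sets", {
  m14 <- build_model("glucose", "model1_age4")
  expect_length(m14$equations[["glucose4_z"]], 5)
  expect_true("gestational_age" %in% m14$equations[["glucose4_z"]])
  m17 <- build_model("glucose", "model1_age7")
  expect_length(m17$equations[["glucose7_z"]], 4)
  expect_false("gestational_age" %in% m17$equations[["glucose7_z"]])
  m2 <- build_model("waist", "model2_age7")
  expect_true("waist4_z" %in% m2$equations[["waist7_z"]])
  expect_error(build_model("bmi", "model2_age7"), "unknown trait")
  j <- build_model("waist", "joint")
  expect_identical(j$endo, c("waist4_z", "waist7_z"))
})

test_that("implied moments follow recursive-system algebra", {
  spec <- build_model("waist", "joint")
  # all structural coefficients zero: block-diagonal implied covariance
  th0 <- path_theta(spec)
  mom <- implied_moments(spec, th0)
  expect_equal(mom$Sigma[spec$exog, spec$endo],
               matrix(0, 5, 2, dimnames = list(spec$exog, spec$endo)))
  expect_equal(mom$Sigma[spec$endo, spec$endo], diag(2),
               ignore_attr = TRUE)
  # single edge y = 0.7 x: Var(y) = 0.49 + 1, Cov = 0.7
  th1 <- path_theta(spec, coef = list(waist7_z = c(waist4_z = 0.7)))
  mom1 <- implied_moments(spec, th1)
  expect_equal(mom1$Sigma["waist7_z", "waist7_z"], 0.7^2 + 1)
  expect_equal(mom1$Sigma["waist7_z", "waist4_z"], 0.7)
})

test_that("implied moments match Monte-Carlo simulation of the equations", {
  spec <- build_model("ldl", "joint")
  set.seed(10)
  Phi <- crossprod(matrix(rnorm(25, sd = 0.5), 5)) + diag(5) * 0.5
  th <- path_theta(spec, mu_x = setNames(rnorm(5), spec$exog), Phi = Phi,
                   coef = list(ldl4_z = c(nwc = 0.3, birthweight = -0.2),
                               ldl7_z = c(ldl4_z = 0.6, nwc = 0.1)),
                   sd_resid = c(ldl4_z = 0.9, ldl7_z = 0.8))
  mom <- implied_moments(spec, th)
  n <- 1e6
  d <- simulate_path_cohort(spec, th, n, seed = 99)
  X <- as.matrix(d[, spec$vars])
  se_mu <- sqrt(diag(mom$Sigma) / n)
  expect_true(all(abs(colMeans(X) - mom$mu) < 4 * se_mu))
  S <- cov(X) * (n - 1) / n
  # covariance entries within 4 approximate standard errors
  for (i in 1:7) for (j in 1:7) {
    se_ij <- sqrt((mom$Sigma[i, j]^2 +
                     mom$Sigma[i, i] * mom$Sigma[j, j]) / n)
    expect_lt(abs(S[i, j] - mom$Sigma[i, j]), 4 * se_ij)
  }
})

test_that("FIML loglik equals the complete-data MVN loglik and is additive", {
  d <- model2_data(n = 120, seed = 5)
  spec <- build_model("waist", "model2_age7")
  th <- path_start_values(spec, d)
  mom <- implied_moments(spec, th)
  X <- as.matrix(d[, spec$vars])
  expect_equal(fiml_loglik(spec, th, d),
               mvn_loglik_byhand(X, mom$mu, mom$Sigma), tolerance = 1e-8)
  # duplicated rows exactly double the loglik
  expect_equal(fiml_loglik(spec, th, rbind(d, d)),
               2 * fiml_loglik(spec, th, d))
  expect_error(missing_patterns(data.frame(a = NA_real_, b = NA_real_),
                                c("a", "b")), "no observed variable")
})

test_that("a fully missing downstream variable marginalizes out of the loglik", {
  jd <- joint_data(n = 150, seed = 6)
  spec <- jd$spec
  d <- jd$data
  d$waist7_z <- NA_real_
  sub <- build_model("waist", "model1_age4")
  # the joint parameter vector is laid out [exog block, age-4 eq, age-7 eq];
  # its prefix is exactly the age-4 model's parameter vector
  th <- jd$theta
  th_sub <- th[seq_along(path_par_skeleton(sub))]
  expect_equal(fiml_loglik(spec, th, d),
               fiml_loglik(sub, th_sub, d[, sub$vars]))
})

test_that("FIML on complete data matches per-equation least squares", {
  jd <- joint_data(n = 350, seed = 7)
  fit <- fit_path(jd$spec, jd$data, se = FALSE)
  for (v in jd$spec$endo) {
    rhs <- jd$spec$equations[[v]]
    ols <- coef(lm(reformulate(rhs, v), data = jd$data))
    for (x in rhs)
      expect_lt(abs(path_coef(fit, v, x) - unname(ols[x])), 1e-6)
  }
})

test_that("FIML handles 30% missingness and stays close to truth", {
  jd <- joint_data(trait = "ldl", a = 0.3, b = 0.655, direct = 0, n = 900,
                   seed = 8)
  d <- inject_missingness(jd$data, c(ldl7_z = 0.3, ldl4_z = 0.15), "mcar",
                          seed = 8)
  fit <- fit_path(jd$spec, d, se = FALSE)
  expect_equal(path_coef(fit, "ldl7_z", "ldl4_z"), 0.655, tolerance = 0.1)
  expect_equal(path_coef(fit, "ldl4_z", "nwc"), 0.3, tolerance = 0.1)
})

test_that("fit statistics behave at the saturated and restricted models", {
  d <- model2_data(n = 200, seed = 9)
  spec <- build_model("waist", "model2_age7")
  fit <- fit_path(spec, d, se = FALSE)
  expect_equal(fit$df, 0)
  expect_equal(fit$chisq, 0, tolerance = 1e-4)
  expect_equal(unname(fit$fit_indices["cfi"]), 1)
  expect_equal(unname(fit$fit_indices["rmsea"]), 0)
  expect_true(is.na(fit$fit_indices["tli"]))
  # the joint model omits one edge -> one df, finite indices
  jd <- joint_data(n = 300, seed = 9)
  jfit <- fit_path(jd$spec, jd$data, se = FALSE)
  expect_equal(jfit$df, 1)
  expect_gte(jfit$fit_indices["rmsea"], 0)
})

test_that("fit indices implement the published formulas", {
  fi <- fit_indices(30, 20, 200, 30, 301)
  expect_equal(unname(fi["rmsea"]), sqrt(10 / 6000), tolerance = 1e-10)
  expect_equal(unname(fi["cfi"]), 1 - 10 / 170)
  fi2 <- fit_indices(20, 20, 200, 30, 301)
  expect_equal(unname(fi2["cfi"]), 1)
  expect_equal(unname(fi2["rmsea"]), 0)
  fi3 <- fit_indices(200, 30, 200, 30, 301)
  expect_equal(unname(fi3["cfi"]), 0)
})

test_that("effect decomposition is a product-and-sum identity", {
  jd <- joint_data(a = 0.5, b = 0.4, direct = 0.1, n = 2500, seed = 12)
  fit <- fit_path(jd$spec, jd$data, se = FALSE)
  eff <- effect_decomposition(fit)
  expect_equal(unname(eff["total"]),
               unname(eff["direct"] + eff["indirect"]), tolerance = 1e-10)
  expect_equal(unname(eff["indirect"]), 0.5 * 0.4, tolerance = 0.1)
  expect_error(effect_decomposition(fit_path(build_model("waist", "model2_age7"),
                                             model2_data(n = 100, seed = 1),
                                             se = FALSE)),
               "joint")
})

test_that("total effect equals the no-mediator coefficient when confounder sets match", {
  jd <- joint_data(a = 0.3, b = 0.5, direct = 0.15, n = 300, seed = 13,
                   include_ga_age7 = TRUE)
  fit <- fit_path(jd$spec, jd$data, se = FALSE)
  eff <- effect_decomposition(fit)
  ols <- coef(lm(waist7_z ~ nwc + maternal_education + pre_pregnancy_bmi +
                   gestational_age + birthweight, data = jd$data))
  expect_equal(unname(eff["total"]), unname(ols["nwc"]), tolerance = 1e-6)
})

test_that("percentile bootstrap is reproducible and brackets the estimate", {
  d <- model2_data(n = 150, seed = 14)
  spec <- build_model("waist", "model2_age7")
  bs <- bootstrap_ci(spec, d, n_boot = 200, seed = 77)
  expect_equal(bs$n_failed, 0)
  ci <- bs$ci
  est <- bs$fit$coefficients
  for (i in seq_len(nrow(est))) {
    j <- match(est$parameter[i], ci$parameter)
    expect_true(ci$lo[j] <= est$estimate[i] && est$estimate[i] <= ci$hi[j])
  }
  tr <- ci[ci$parameter == "waist7_z~waist4_z", ]
  expect_true(tr$lo < 0.725 && tr$hi > 0.5)  # interval in a sane range
  expect_error(bootstrap_ci(spec, d, n_boot = 50), "at least 200")
})

test_that("pearson matrix is symmetric with unit diagonal and sane nulls", {
  set.seed(15)
  d <- data.frame(a = rnorm(1000), b = rnorm(1000), c = rnorm(1000))
  pm <- pearson_matrix(d)
  expect_equal(diag(pm$r), c(a = 1, b = 1, c = 1))
  expect_equal(pm$r, t(pm$r))
  expect_true(all(abs(pm$r[upper.tri(pm$r)]) < 0.08))
  # a generating correlation of 0.776 is recovered from the sample
  z4 <- rnorm(2000)
  z7 <- 0.776 * z4 + sqrt(1 - 0.776^2) * rnorm(2000)
  pm2 <- pearson_matrix(data.frame(wc4 = z4, wc7 = z7))
  expect_equal(pm2$r["wc4", "wc7"], 0.776, tolerance = 0.03)
  expect_equal(pm2$stars["wc4", "wc7"], "***")
  expect_warning(pearson_matrix(data.frame(x = rnorm(10), y = rep(1, 10))),
                 "constant")
})
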