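# coefficients of the published population weight curve (g, g/h, g/h^2, g/h^3)
published_beta <- c(3241.442, -9.378, 0.119, -0.0004)

eval_cubic <- function(t, beta = published_beta) {
  beta[1] + beta[2] * t + beta[3] * t^2 + beta[4] * t^3
}

# cohort encoding the published exclusion-cascade structure:
# 471 missing measurement time, 28 measured after 96 h, 15 extreme-loss and
# 4 extreme-gain hourly rates among 1307 in-window records, 1288 unremarkable
cascade_fixture <- function(seed = 42) {
  set.seed(seed)
  mk <- function(n, rate, t) {
    bw <- rnorm(n, 3250, 350)
    data.frame(id = character(n), sex = sample(c("F", "M"), n, TRUE),
               birthweight = bw, meas_time = t,
               meas_weight = bw * (1 + rate * t / 100),
               maternal_education = 12, pre_pregnancy_bmi = 24,
               gestational_age = 39.5, stringsAsFactors = FALSE)
  }
  normal <- mk(1288, runif(1288, -0.30, -0.05), runif(1288, 10, 90))
  low <- mk(15, runif(15, -1.2, -0.8), runif(15, 10, 20))
  high <- mk(4, runif(4, 0.45, 0.60), runif(4, 10, 90))
  late <- mk(28, runif(28, -0.30, -0.05), runif(28, 96.5, 120))
  miss <- mk(471, -0.15, NA_real_)
  out <- rbind(normal, low, high, late, miss)
  out$id <- sprintf("C%04d", seq_len(nrow(out)))
  out
}

# noise-free cohort: every newborn lies exactly on the population cubic
noiseless_cohort <- function(n = 80, seed = 1) {
  p <- growth_sim_params(sd_b0 = 0, sd_b1 = 0, sd_resid = 0,
                         n_newborns = n, seed = seed)
  generate_newborns(p)
}

# complete-data cohort for path models: standard-normal confounders and NWC,
# one trait generated with a chosen tracking coefficient
model2_data <- function(trait = "waist", track = 0.725, n = 312, seed = 1,
                        nwc_effect = 0) {
  spec <- build_model(trait, "model2_age7")
  t4 <- paste0(trait, "4_z"); t7 <- paste0(trait, "7_z")
  theta <- path_theta(
    spec, coef = stats::setNames(
      list(stats::setNames(c(track, nwc_effect), c(t4, "nwc"))), t7),
    sd_resid = stats::setNames(sqrt(1 - track^2), t7))
  d <- simulate_path_cohort(spec, theta, n, seed = seed)
  # the age-4 trait is exogenous in this variant; already unit normal
  d
}

joint_data <- function(trait = "waist", a = 0.2, b = 0.6, direct = 0.1,
                       n = 400, seed = 1, include_ga_age7 = FALSE) {
  spec <- build_model(trait, "joint", include_ga_age7 = include_ga_age7)
  t4 <- paste0(trait, "4_z"); t7 <- paste0(trait, "7_z")
  coef <- stats::setNames(
    list(c(nwc = a), stats::setNames(c(direct, b), c("nwc", t4))),
    c(t4, t7))
  theta <- path_theta(spec, coef = coef)
  list(spec = spec,
       data = simulate_path_cohort(spec, theta, n, seed = seed),
       theta = theta)
}
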