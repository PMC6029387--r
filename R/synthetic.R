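#' Parameters for the neonatal growth simulator
#'
#' Bundles the population cubic weight curve, the bivariate-normal random
#' effects, the residual noise and the measurement-time window used by
#' [generate_newborns()]. Defaults reproduce the published population curve
#' (intercept 3241.442 g, linear -9.378 g/h, quadratic 0.119 g/h^2, cubic
#' -0.0004 g/h^3) with variance components chosen to give a realistic
#' newborn weight-change spread.
#'
#' @param beta0,beta1,beta2,beta3 Fixed cubic coefficients (g, g/h, g/h^2,
#'   g/h^3).
#' @param sd_b0 SD of the subject random intercept (g).
#' @param sd_b1 SD of the subject random slope (g/h).
#' @param corr_b0b1 Correlation between random intercept and slope.
#' @param sd_resid Residual measurement SD (g).
#' @param t_min,t_max Bounds (hours) of the uniform measurement-time window.
#' @param n_newborns Number of newborns to simulate.
#' @param seed Integer seed; all downstream randomness streams from it.
#' @return A `growth_sim_params` list.
#' @export
#' @examples
#' p <- growth_sim_params(n_newborns = 100, seed = 1)
#' cohort <- generate_newborns(p)
#' head(cohort$newborns)
growth_sim_params <- function(beta0 = 3241.442, beta1 = -9.378,
                              beta2 = 0.119, beta3 = -0.0004,
                              sd_b0 = 400, sd_b1 = 1, corr_b0b1 = -0.2,
                              sd_resid = 50, t_min = 6.3, t_max = 96,
                              n_newborns = 1500, seed = 1L) {
  stopifnot(sd_b0 >= 0, sd_b1 >= 0, sd_resid >= 0,
            abs(corr_b0b1) <= 1,
            t_min > 0, t_min < t_max, t_max <= 96)
  if (!is.numeric(n_newborns) || n_newborns < 1)
    stop("n_newborns must be a positive count")
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 sd_b0 = sd_b0, sd_b1 = sd_b1, corr_b0b1 = corr_b0b1,
                 sd_resid = sd_resid, t_min = t_min, t_max = t_max,
                 n_newborns = as.integer(n_newborns), seed = as.integer(seed)),
            class = "growth_sim_params")
}

# population cubic at time t (hours)
cubic_at <- function(t, beta) {
  beta[1] + beta[2] * t + beta[3] * t^2 + beta[4] * t^3
}

# interior minimum of beta0 + (beta1+b1) t + beta2 t^2 + beta3 t^3 on (0, tmax];
# returns the admissible stationary point or tmax when the curve has no
# interior minimum in range
subject_nadir_time <- function(beta, b1 = 0, t_max = 96) {
  d1 <- beta[2] + b1            # derivative coefficients: d1 + 2 b2 t + 3 b3 t^2
  a <- 3 * beta[4]; b <- 2 * beta[3]; cc <- d1
  cand <- numeric(0)
  if (abs(a) > .Machine$double.eps) {
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) cand <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  } else if (abs(b) > .Machine$double.eps) {
    cand <- -cc / b
  }
  curv <- function(t) b + 2 * a * t
  ok <- cand[cand > 0 & cand <= t_max & curv(cand) > 0]
  if (length(ok) == 0) return(t_max)
  min(ok)
}

#' Simulate a cohort of newborns with one timed post-birth weight
#'
#' Each newborn follows a subject-specific cubic weight curve: the population
#' cubic plus a random intercept and random slope. Birthweight is the subject
#' curve observed at t = 0 plus residual noise; one further weight is observed
#' at a time drawn uniformly on `[t_min, t_max]` hours, again with residual
#' noise. A truth table records the realized random effects and the
#' noise-free weight and weight-change percentage at each subject's own nadir.
#'
#' @param params A [growth_sim_params()] object.
#' @return A list with `newborns` (one row per newborn: id, sex, birthweight,
#'   meas_time, meas_weight, maternal covariates, gestational age) and
#'   `truth` (params plus per-subject random effects, true nadir time,
#'   true minimum weight and true NWC percentage).
#' @export
generate_newborns <- function(params) {
  stopifnot(inherits(params, "growth_sim_params"))
  n <- params$n_newborns
  beta <- c(params$beta0, params$beta1, params$beta2, params$beta3)
  set.seed(params$seed)

  Sigma <- matrix(c(params$sd_b0^2,
                    params$corr_b0b1 * params$sd_b0 * params$sd_b1,
                    params$corr_b0b1 * params$sd_b0 * params$sd_b1,
                    params$sd_b1^2), 2, 2)
  re <- if (all(Sigma == 0)) matrix(0, n, 2) else MASS::mvrnorm(n, c(0, 0), Sigma)

  t_meas <- stats::runif(n, params$t_min, params$t_max)
  bw <- cubic_at(0, beta) + re[, 1] + stats::rnorm(n, 0, params$sd_resid)
  w2 <- cubic_at(t_meas, beta) + re[, 1] + re[, 2] * t_meas +
    stats::rnorm(n, 0, params$sd_resid)

  sex <- sample(c("F", "M"), n, replace = TRUE)
  medu <- round(pmin(pmax(stats::rnorm(n, 11, 4), 4), 22))
  mbmi <- pmin(pmax(stats::rnorm(n, 24, 4), 15), 45)
  ga <- pmin(pmax(stats::rnorm(n, 39.4, 1.2), 37), 42)

  nadir_t <- vapply(re[, 2], function(b1)
    subject_nadir_time(beta, b1, params$t_max), numeric(1))
  w_nadir <- cubic_at(nadir_t, beta) + re[, 1] + re[, 2] * nadir_t
  w0 <- cubic_at(0, beta) + re[, 1]
  nwc_true <- (w_nadir - w0) / w0 * 100

  id <- sprintf("NB%05d", seq_len(n))
  list(
    newborns = data.frame(
      id = id, sex = sex, birthweight = bw,
      meas_time = t_meas, meas_weight = w2,
      maternal_education = medu, pre_pregnancy_bmi = mbmi,
      gestational_age = ga, stringsAsFactors = FALSE),
    truth = list(
      params = unclass(params),
      subjects = data.frame(
        id = id, b0 = re[, 1], b1 = re[, 2],
        nadir_time_true = nadir_t, weight_nadir_true = w_nadir,
        nwc_true = nwc_true, stringsAsFactors = FALSE))
  )
}

#' Parameters for the childhood trait simulator
#'
#' Describes the structural model used by [generate_child_outcomes()]:
#' for each trait, a z-scored age-4 equation (confounders + NWC + noise) and a
#' z-scored age-7 equation (confounders + NWC + tracking on the same trait at
#' age 4 + noise), then a mapping back to natural units via per-age means/SDs.
#' Defaults use published cohort means/SDs and the published age-4 to age-7
#' tracking coefficients; NWC and confounder effects default to zero, the
#' null structure.
#'
#' @param traits Character vector of trait names (fixed set of six).
#' @param mean4,sd4,mean7,sd7 Named numeric vectors of natural-scale means/SDs
#'   per trait at each age.
#' @param tracking Named numeric vector of standardized age-4 to age-7 path
#'   coefficients per trait.
#' @param nwc_effect_4,nwc_effect_7 Standardized NWC coefficients (scalar or
#'   named per trait); default 0.
#' @param confounder_effects Named numeric vector of standardized effects for
#'   `maternal_education`, `pre_pregnancy_bmi`, `gestational_age`,
#'   `birthweight` applied to every trait equation; default all 0.
#' @param resid_cor4,resid_cor7 Residual cross-trait correlation matrices
#'   (traits x traits) at each age; must be positive semi-definite.
#' @param missing_rate Named per-variable missingness rates in [0, 1) applied
#'   by [inject_missingness()] when requested; default 0.
#' @param seed Integer seed.
#' @return A `tracking_sim_params` list.
#' @export
tracking_sim_params <- function(
    traits = c("glucose", "ldl", "tg", "waist", "sbp", "dbp"),
    mean4 = c(glucose = 77.9, ldl = 107.0, tg = 61.0, waist = 52.0,
              sbp = 97.3, dbp = 56.1),
    sd4 = c(glucose = 7.9, ldl = 23.5, tg = 25 / 1.349, waist = 4.2,
            sbp = 7.6, dbp = 7.8),
    mean7 = c(glucose = 83.0, ldl = 99.8, tg = 55.0, waist = 58.3,
              sbp = 105.0, dbp = 69.2),
    sd7 = c(glucose = 5.7, ldl = 22.2, tg = 28 / 1.349, waist = 6.2,
            sbp = 8.7, dbp = 7.4),
    tracking = c(glucose = 0.235, ldl = 0.655, tg = 0.281, waist = 0.725,
                 sbp = 0.369, dbp = 0.153),
    nwc_effect_4 = 0, nwc_effect_7 = 0,
    confounder_effects = c(maternal_education = 0, pre_pregnancy_bmi = 0,
                           gestational_age = 0, birthweight = 0),
    resid_cor4 = default_resid_cor(traits),
    resid_cor7 = default_resid_cor(traits),
    missing_rate = 0, seed = 1L) {
  k <- length(traits)
  expand <- function(x) {
    if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, k), traits)
    stopifnot(all(traits %in% names(x)))
    x[traits]
  }
  mean4 <- expand(mean4); sd4 <- expand(sd4)
  mean7 <- expand(mean7); sd7 <- expand(sd7)
  tracking <- expand(tracking)
  nwc_effect_4 <- expand(nwc_effect_4); nwc_effect_7 <- expand(nwc_effect_7)
  stopifnot(all(sd4 > 0), all(sd7 > 0), all(abs(tracking) < 1))
  check_psd(resid_cor4, "resid_cor4"); check_psd(resid_cor7, "resid_cor7")
  structure(list(traits = traits, mean4 = mean4, sd4 = sd4,
                 mean7 = mean7, sd7 = sd7, tracking = tracking,
                 nwc_effect_4 = nwc_effect_4, nwc_effect_7 = nwc_effect_7,
                 confounder_effects = confounder_effects,
                 resid_cor4 = resid_cor4, resid_cor7 = resid_cor7,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "tracking_sim_params")
}

#' @rdname tracking_sim_params
#' @export
default_resid_cor <- function(traits) {
  k <- length(traits)
  R <- diag(k); dimnames(R) <- list(traits, traits)
  set_r <- function(a, b, v) {
    if (all(c(a, b) %in% traits)) { R[a, b] <<- v; R[b, a] <<- v }
  }
  # magnitudes in line with observed cross-sectional trait correlations
  set_r("sbp", "dbp", 0.50)
  set_r("waist", "sbp", 0.20)
  set_r("waist", "dbp", 0.12)
  set_r("ldl", "tg", 0.12)
  set_r("glucose", "sbp", 0.12)
  R
}

check_psd <- function(R, name) {
  if (!isSymmetric(unname(R)) || min(eigen(R, symmetric = TRUE,
                                           only.values = TRUE)$values) < -1e-8)
    stop(name, " is not a positive semi-definite correlation matrix")
  invisible(TRUE)
}

#' Simulate childhood visit tables at ages 4 and 7
#'
#' Generates trait z-scores from the structural equations (confounders + NWC
#' at age 4; confounders + NWC + tracking at age 7), maps them to natural
#' units, and emits the raw component measurements that the clinical
#' derivation step consumes: total cholesterol / HDL-C / triglycerides in
#' place of LDL-C, and repeated blood-pressure readings in place of a single
#' BP value. Heights are generated so height-banded BP references have
#' structure to use.
#'
#' @param newborns Newborn table from [generate_newborns()].
#' @param params A [tracking_sim_params()] object.
#' @param nwc Numeric vector of NWC percentages aligned with `newborns`; if
#'   `NULL`, a crude observed change percentage is computed from the measured
#'   weights.
#' @return List with `age4` and `age7` visit tables and `truth` (generating
#'   z-scores and coefficients).
#' @export
generate_child_outcomes <- function(newborns, params, nwc = NULL) {
  stopifnot(inherits(params, "tracking_sim_params"))
  n <- nrow(newborns)
  if (n < 1) stop("newborn table is empty")
  traits <- params$traits
  k <- length(traits)
  set.seed(params$seed + 1L)

  if (is.null(nwc))
    nwc <- (newborns$meas_weight - newborns$birthweight) /
      newborns$birthweight * 100
  zx <- function(v) as.numeric(scale(v))
  nwc_z <- zx(nwc)
  conf <- cbind(maternal_education = zx(newborns$maternal_education),
                pre_pregnancy_bmi = zx(newborns$pre_pregnancy_bmi),
                gestational_age = zx(newborns$gestational_age),
                birthweight = zx(newborns$birthweight))
  ce <- params$confounder_effects[colnames(conf)]
  ce[is.na(ce)] <- 0
  lin_conf <- drop(conf %*% ce)

  e4 <- MASS::mvrnorm(n, rep(0, k), params$resid_cor4)
  z4 <- matrix(lin_conf, n, k) + outer(nwc_z, params$nwc_effect_4) + e4
  resid_sd7 <- sqrt(pmax(1 - params$tracking^2, 0.05))
  e7 <- MASS::mvrnorm(n, rep(0, k), params$resid_cor7) %*% diag(resid_sd7)
  z7 <- z4 %*% diag(params$tracking) + matrix(lin_conf, n, k) +
    outer(nwc_z, params$nwc_effect_7) + e7
  colnames(z4) <- colnames(z7) <- traits

  build_visit <- function(z, means, sds, age_mean, height_mean, height_sd) {
    nat <- sweep(sweep(z, 2, sds, "*"), 2, means, "+")
    nat[, "glucose"] <- pmax(nat[, "glucose"], 40)
    nat[, "tg"] <- pmax(nat[, "tg"], 20)
    nat[, "ldl"] <- pmax(nat[, "ldl"], 30)
    age <- stats::rnorm(n, age_mean, 0.25)
    # height correlates with waist girth, as in real child anthropometry
    height <- height_mean + height_sd * (0.4 * z[, "waist"] +
                                           sqrt(1 - 0.4^2) * stats::rnorm(n))
    hdl <- pmax(stats::rnorm(n, 52, 10), 20)
    tc <- nat[, "ldl"] + hdl + nat[, "tg"] / 5
    bp_readings <- function(true) {
      r1 <- true + stats::rnorm(n, 0, 1.5)
      r2 <- true + stats::rnorm(n, 0, 1.5)
      need3 <- abs(r1 - r2) >= 5
      r3 <- ifelse(need3, true + stats::rnorm(n, 0, 1.5), NA_real_)
      cbind(r1, r2, r3)
    }
    sbp_r <- bp_readings(nat[, "sbp"]); dbp_r <- bp_readings(nat[, "dbp"])
    data.frame(
      id = newborns$id, sex = newborns$sex, visit_age = age,
      height = round(height, 1), waist = round(nat[, "waist"], 1),
      sbp1 = round(sbp_r[, 1]), sbp2 = round(sbp_r[, 2]), sbp3 = round(sbp_r[, 3]),
      dbp1 = round(dbp_r[, 1]), dbp2 = round(dbp_r[, 2]), dbp3 = round(dbp_r[, 3]),
      glucose = round(nat[, "glucose"], 1), total_chol = round(tc, 1),
      hdl = round(hdl, 1), tg = round(nat[, "tg"], 1),
      stringsAsFactors = FALSE)
  }

  age4 <- build_visit(z4, params$mean4, params$sd4, 4.2, 105, 4.5)
  age7 <- build_visit(z7, params$mean7, params$sd7, 7.2, 125, 5.5)
  list(age4 = age4, age7 = age7,
       truth = list(z4 = z4, z7 = z7, nwc_z = nwc_z,
                    params = unclass(params)))
}

#' Delete values completely at random or conditionally at random
#'
#' Punches holes into a visit table either MCAR (each value independently
#' missing with its rate) or MAR, where the deletion probability for a target
#' column depends on the tertile of a fully observed conditioning column
#' (rates scaled by 0.5 / 1 / 1.5 across tertiles, preserving the marginal
#' rate).
#'
#' @param tbl A data frame.
#' @param rates Named numeric vector of per-column missingness rates in
#'   [0, 1), or a single rate applied to all named columns in `cols`.
#' @param mechanism `"mcar"` or `"mar"`.
#' @param condition_on Column name driving MAR deletion; must itself be
#'   fully observed.
#' @param cols Columns to target when `rates` is unnamed.
#' @param seed Integer seed.
#' @return The table with `NA`s injected; observed values are unchanged.
#' @export
inject_missingness <- function(tbl, rates, mechanism = c("mcar", "mar"),
                               condition_on = NULL, cols = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (is.null(names(rates))) {
    stopifnot(!is.null(cols))
    rates <- stats::setNames(rep(rates, length(cols)), cols)
  }
  stopifnot(all(rates >= 0), all(rates < 1))
  if (mechanism == "mar") {
    if (is.null(condition_on)) stop("MAR requires condition_on")
    if (anyNA(tbl[[condition_on]]))
      stop("MAR conditioning variable '", condition_on, "' has missing values")
  }
  set.seed(seed)
  n <- nrow(tbl)
  for (v in names(rates)) {
    r <- rates[[v]]
    if (r == 0) next
    if (mechanism == "mcar") {
      p <- rep(r, n)
    } else {
      cuts <- stats::quantile(tbl[[condition_on]], c(1 / 3, 2 / 3), na.rm = TRUE)
      tert <- findInterval(tbl[[condition_on]], cuts) + 1L
      p <- pmin(r * c(0.5, 1, 1.5)[tert], 0.99)
    }
    tbl[[v]][stats::runif(n) < p] <- NA
  }
  tbl
}
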