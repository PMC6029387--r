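#' Fit the cubic random-effects postnatal growth model
#'
#' Stacks each newborn's birthweight as a t = 0 observation together with the
#' timed post-birth weight, and fits
#' weight ~ t + t^2 + t^3 with a correlated random intercept and slope per
#' subject, by maximum likelihood (ML rather than REML so log-likelihoods are
#' comparable across mean structures). Per-subject effects are
#' empirical-Bayes (BLUP) predictions.
#'
#' When the stacked data are exactly polynomial (noise-free degenerate case)
#' the mixed model has no variance to estimate; the fit then reduces to the
#' exact least-squares cubic with zero variance components, flagged
#' `degenerate = TRUE`. A singular random-effect covariance estimate triggers
#' a warning and a refit with a random intercept only, in which case every
#' subject's slope effect is 0.
#'
#' @param records Newborn table with columns `id`, `birthweight`,
#'   `meas_time`, `meas_weight` (see [generate_newborns()]).
#' @return A `growth_fit` object: fixed coefficients `beta` (length 4),
#'   random-effect covariance `re_cov`, residual SD, per-subject effects
#'   (`ranef`, columns `b0`, `b1`), `nadir_time`, `loglik`, flags.
#' @export
fit_cubic_lmm <- function(records) {
  need <- c("id", "birthweight", "meas_time", "meas_weight")
  stopifnot(all(need %in% names(records)))
  records <- records[!is.na(records$meas_time) & !is.na(records$meas_weight) &
                       !is.na(records$birthweight), , drop = FALSE]
  if (length(unique(records$id)) < 50)
    warning("fewer than 50 subjects: variance components may be unstable")

  long <- data.frame(
    id = rep(records$id, 2),
    t = c(rep(0, nrow(records)), records$meas_time),
    weight = c(records$birthweight, records$meas_weight))

  ols <- stats::lm(weight ~ t + I(t^2) + I(t^3), data = long)
  scale0 <- stats::sd(long$weight)
  if (max(abs(stats::resid(ols))) < 1e-8 * scale0) {
    beta <- unname(stats::coef(ols))
    ids <- unique(records$id)
    fit <- structure(list(
      beta = beta, re_cov = matrix(0, 2, 2), sd_resid = 0,
      ranef = data.frame(id = ids, b0 = 0, b1 = 0, stringsAsFactors = FALSE),
      loglik = NA_real_, degenerate = TRUE, intercept_only = FALSE),
      class = "growth_fit")
    fit$nadir_time <- population_nadir(fit)
    return(fit)
  }

  # with one t = 0 and one timed weight per subject the per-subject design is
  # minimal, but the variance components are identified across subjects
  # because measurement times differ; relax lme4's obs-vs-RE count check
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.nobs.vs.nRE = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.scaleX = "ignore")
  # lme4 emits a "boundary (singular) fit" message when the RE covariance
  # collapses; we detect that case explicitly below and fall back
  m <- suppressMessages(
    lme4::lmer(weight ~ t + I(t^2) + I(t^3) + (t | id), data = long,
               REML = FALSE, control = ctrl))
  intercept_only <- FALSE
  if (lme4::isSingular(m, tol = 1e-5)) {
    warning("singular random-effect covariance; refitting with random intercept only")
    m <- suppressMessages(
      lme4::lmer(weight ~ t + I(t^2) + I(t^3) + (1 | id), data = long,
                 REML = FALSE, control = ctrl))
    intercept_only <- TRUE
  }

  beta <- unname(lme4::fixef(m))
  vc <- as.matrix(lme4::VarCorr(m)$id)
  re_cov <- matrix(0, 2, 2)
  re_cov[seq_len(nrow(vc)), seq_len(ncol(vc))] <- vc
  re <- lme4::ranef(m)$id
  ranef_df <- data.frame(id = rownames(re),
                         b0 = re[["(Intercept)"]],
                         b1 = if ("t" %in% names(re)) re[["t"]] else 0,
                         stringsAsFactors = FALSE)
  fit <- structure(list(
    beta = beta, re_cov = re_cov,
    sd_resid = stats::sigma(m),
    ranef = ranef_df, loglik = as.numeric(stats::logLik(m)),
    degenerate = FALSE, intercept_only = intercept_only),
    class = "growth_fit")
  fit$nadir_time <- population_nadir(fit)
  fit
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Cubic random-effects growth model (ML)\n")
  cat(sprintf("  weight(t) = %.3f + (%.4f) t + (%.5f) t^2 + (%.7f) t^3\n",
              x$beta[1], x$beta[2], x$beta[3], x$beta[4]))
  cat(sprintf("  random effects: SD(b0) = %.2f g, SD(b1) = %.3f g/h, corr = %.3f\n",
              sqrt(x$re_cov[1, 1]), sqrt(x$re_cov[2, 2]),
              if (x$re_cov[1, 1] > 0 && x$re_cov[2, 2] > 0)
                x$re_cov[1, 2] / sqrt(x$re_cov[1, 1] * x$re_cov[2, 2]) else 0))
  cat(sprintf("  residual SD = %.2f g; population nadir = %.2f h\n",
              x$sd_resid, x$nadir_time))
  invisible(x)
}

#' Interior minimum of the population growth curve
#'
#' Solves beta1 + 2 beta2 t + 3 beta3 t^2 = 0 in closed form and returns the
#' root in (0, 96] with positive second derivative — the population nadir
#' time in hours. If two admissible minima existed (impossible for a cubic,
#' asserted anyway) the smaller would be returned.
#'
#' @param fit A `growth_fit`, or a numeric vector of 4 cubic coefficients.
#' @param t_max Upper bound of the admissible window (hours).
#' @return Nadir time in hours.
#' @export
population_nadir <- function(fit, t_max = 96) {
  beta <- if (inherits(fit, "growth_fit")) fit$beta else fit
  stopifnot(length(beta) == 4)
  if (abs(beta[4]) < .Machine$double.eps && beta[3] <= 0)
    stop("no interior minimum: curve has no positive curvature")
  a <- 3 * beta[4]; b <- 2 * beta[3]; cc <- beta[2]
  if (abs(a) < .Machine$double.eps) {
    root <- -cc / b
    if (root <= 0 || root > t_max) stop("no interior minimum in (0, ", t_max, "]")
    return(root)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no interior minimum: derivative has no real root")
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  ok <- roots[roots > 0 & roots <= t_max & (b + 2 * a * roots) > 0]
  if (length(ok) == 0) stop("no interior minimum in (0, ", t_max, "]")
  stopifnot(length(ok) == 1)  # a cubic admits at most one interior minimum
  min(ok)
}

#' Predict a subject's weight at time t
#'
#' Fixed cubic at `t` plus the subject's predicted random intercept and
#' slope contribution.
#'
#' @param fit A `growth_fit`.
#' @param id Subject identifier(s) present in the fit.
#' @param t Time(s) in hours since birth; recycled against `id`.
#' @return Predicted weight(s) in grams.
#' @export
predict_weight <- function(fit, id, t) {
  stopifnot(inherits(fit, "growth_fit"))
  idx <- match(id, fit$ranef$id)
  if (anyNA(idx)) stop("unknown id: ", paste(id[is.na(idx)], collapse = ", "))
  cubic_at(t, fit$beta) + fit$ranef$b0[idx] + fit$ranef$b1[idx] * t
}

#' Newborn weight change as a percentage of birthweight
#'
#' NWC(\%) = ((estimated minimum weight - birthweight) / birthweight) x 100;
#' negative values are weight loss.
#'
#' @param birthweight Birthweight in grams (> 0).
#' @param est_min_weight Estimated minimum weight in grams.
#' @return Signed percentage.
#' @export
compute_nwc <- function(birthweight, est_min_weight) {
  if (any(birthweight <= 0, na.rm = TRUE)) stop("birthweight must be positive")
  (est_min_weight - birthweight) / birthweight * 100
}

#' Observed hourly weight-change rate
#'
#' Percentage change from birthweight per hour of life, the quantity screened
#' for outliers in the exclusion cascade.
#'
#' @param birthweight,meas_weight Grams.
#' @param meas_time Hours since birth (> 0).
#' @return Percent of birthweight per hour.
#' @export
hourly_change_rate <- function(birthweight, meas_weight, meas_time) {
  if (any(meas_time <= 0, na.rm = TRUE)) stop("meas_time must be positive")
  ((meas_weight - birthweight) / birthweight * 100) / meas_time
}

#' Apply the cohort exclusion cascade
#'
#' Stages, in order: (1) missing measurement time; (2) measured after
#' `t_max` hours; (3) hourly-rate outliers outside the Tukey fences
#' Q1 - 3 IQR / Q3 + 3 IQR, computed on the records remaining after stages
#' 1-2 (or fixed at supplied fences); (4) incomplete key covariates.
#' Each excluded record carries the first reason triggered.
#'
#' @param records Newborn table.
#' @param t_max Window bound in hours (default 96).
#' @param fences Optional fixed `c(low, high)` fences in percent per hour; by
#'   default the fences are the analysis sample's empirical Tukey fences.
#' @param key_vars Columns required complete at the final stage.
#' @return List with `kept` (records surviving all stages), `reasons`
#'   (per-input-record exclusion reason, `"none"` if kept), `fences`, and
#'   `report` (a `cascade_report` data frame of stage, n_excluded,
#'   n_remaining).
#' @export
apply_exclusion_cascade <- function(records, t_max = 96, fences = NULL,
                                    key_vars = c("sex", "birthweight",
                                                 "meas_weight",
                                                 "maternal_education",
                                                 "pre_pregnancy_bmi",
                                                 "gestational_age")) {
  if (nrow(records) == 0) stop("empty input")
  n0 <- nrow(records)
  reason <- rep("none", n0)

  reason[is.na(records$meas_time)] <- "missing_time"
  alive <- reason == "none"
  reason[alive & records$meas_time > t_max] <- "after_96h"
  alive <- reason == "none"

  rate <- rep(NA_real_, n0)
  rate[alive] <- hourly_change_rate(records$birthweight[alive],
                                    records$meas_weight[alive],
                                    records$meas_time[alive])
  if (is.null(fences)) {
    q <- stats::quantile(rate[alive], c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    fences <- c(q[1] - 3 * iqr, q[2] + 3 * iqr)
  }
  reason[alive & !is.na(rate) & rate < fences[1]] <- "outlier_low"
  reason[alive & !is.na(rate) & rate > fences[2]] <- "outlier_high"
  alive <- reason == "none"

  key_vars <- intersect(key_vars, names(records))
  incomplete <- rowSums(is.na(records[, key_vars, drop = FALSE])) > 0
  reason[alive & incomplete] <- "incomplete_covariates"

  stages <- c("missing_time", "after_96h", "outlier", "incomplete_covariates")
  n_exc <- c(sum(reason == "missing_time"),
             sum(reason == "after_96h"),
             sum(reason %in% c("outlier_low", "outlier_high")),
             sum(reason == "incomplete_covariates"))
  report <- data.frame(stage = stages, n_excluded = n_exc,
                       n_remaining = n0 - cumsum(n_exc),
                       stringsAsFactors = FALSE)
  class(report) <- c("cascade_report", "data.frame")
  list(kept = records[reason == "none", , drop = FALSE],
       reasons = reason, fences = fences, report = report)
}

#' Render an exclusion cascade as a text flow chart
#'
#' @param report A `cascade_report` from [apply_exclusion_cascade()].
#' @param n_in Initial count (defaults to first remaining + first excluded).
#' @return Character vector of lines (invisibly printed).
#' @export
format_cascade <- function(report, n_in = report$n_remaining[1] +
                             report$n_excluded[1]) {
  lines <- sprintf("eligible: n = %d", n_in)
  for (i in seq_len(nrow(report))) {
    lines <- c(lines,
               sprintf("  |- excluded (%s): %d", report$stage[i],
                       report$n_excluded[i]),
               sprintf("  v remaining: %d", report$n_remaining[i]))
  }
  lines
}

#' Per-newborn NWC at the population nadir
#'
#' Predicts each newborn's weight at the population nadir time and converts
#' it to the NWC percentage. The observed hourly change rate is carried along
#' for outlier accounting.
#'
#' @param fit A `growth_fit`.
#' @param records Newborn table (ids must be present in the fit).
#' @param nadir_time Evaluation time in hours; defaults to the fitted
#'   population nadir.
#' @return Data frame: id, est_min_weight, nwc, hourly_rate.
#' @export
nwc_table <- function(fit, records, nadir_time = fit$nadir_time) {
  est <- predict_weight(fit, records$id, nadir_time)
  data.frame(
    id = records$id,
    est_min_weight = est,
    nwc = compute_nwc(records$birthweight, est),
    hourly_rate = hourly_change_rate(records$birthweight,
                                     records$meas_weight,
                                     records$meas_time),
    stringsAsFactors = FALSE)
}
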