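#' Specify a recursive path model
#'
#' Builds the structural specification used throughout the path-analysis
#' machinery: a set of exogenous variables with freely estimated means and
#' covariance, and one or two endogenous equations with an intercept,
#' regression coefficients and a residual variance. No residual covariances
#' among endogenous variables are allowed, so every specification is a
#' recursive (and hence identified) system.
#'
#' Variants:
#' \describe{
#'   \item{model1_age4}{trait at 4 ~ NWC + maternal education + pre-pregnancy
#'     BMI + gestational age + birthweight.}
#'   \item{model1_age7}{trait at 7 ~ NWC + maternal education + pre-pregnancy
#'     BMI + birthweight (gestational age omitted, as published).}
#'   \item{model2_age7}{trait at 7 ~ the model1_age7 regressors + the same
#'     trait at age 4 (the tracking edge).}
#'   \item{joint}{the full mediation system: the model1_age4 equation for the
#'     age-4 trait and the model2_age7 equation for the age-7 trait, fitted
#'     jointly so direct, indirect and total effects of NWC are defined.}
#' }
#'
#' @param trait Trait stem, e.g. `"waist"`; equation variables are
#'   `<trait>4_z` / `<trait>7_z`.
#' @param variant One of `"model1_age4"`, `"model1_age7"`, `"model2_age7"`,
#'   `"joint"`.
#' @param include_ga_age7 Add gestational age to the age-7 equation(s),
#'   making the two joint equations share one confounder set (required for
#'   the exact total-effect identity).
#' @return A `path_spec` object.
#' @export
build_model <- function(trait,
                        variant = c("model1_age4", "model1_age7",
                                    "model2_age7", "joint"),
                        include_ga_age7 = FALSE) {
  variant <- match.arg(variant)
  known <- c("glucose", "ldl", "tg", "waist", "sbp", "dbp")
  if (!trait %in% known)
    stop("unknown trait '", trait, "'; expected one of: ",
         paste(known, collapse = ", "))
  t4 <- paste0(trait, "4_z"); t7 <- paste0(trait, "7_z")
  conf4 <- c("nwc", "maternal_education", "pre_pregnancy_bmi",
             "gestational_age", "birthweight")
  conf7 <- c("nwc", "maternal_education", "pre_pregnancy_bmi", "birthweight")
  if (include_ga_age7) conf7 <- c(conf7[1:3], "gestational_age", "birthweight")

  eqs <- switch(variant,
    model1_age4 = stats::setNames(list(conf4), t4),
    model1_age7 = stats::setNames(list(conf7), t7),
    model2_age7 = stats::setNames(list(c(conf7, t4)), t7),
    joint = stats::setNames(list(conf4, c(conf7, t4)), c(t4, t7)))

  endo <- names(eqs)
  exog <- setdiff(unique(unlist(eqs)), endo)
  spec <- structure(list(trait = trait, variant = variant,
                         exog = exog, endo = endo, equations = eqs,
                         vars = c(exog, endo)),
                    class = "path_spec")
  stopifnot(path_spec_acyclic(spec))
  spec
}

path_spec_acyclic <- function(spec) {
  # endogenous equations may only reference exogenous vars or earlier
  # endogenous vars in declaration order
  seen <- spec$exog
  for (v in spec$endo) {
    if (!all(spec$equations[[v]] %in% seen)) return(FALSE)
    seen <- c(seen, v)
  }
  TRUE
}

#' @export
print.path_spec <- function(x, ...) {
  cat("Recursive path model (", x$variant, ", trait = ", x$trait, ")\n", sep = "")
  for (v in x$endo)
    cat("  ", v, " ~ ", paste(x$equations[[v]], collapse = " + "), "\n", sep = "")
  cat("  exogenous (saturated means/covariance): ",
      paste(x$exog, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- parameter vector layout -------------------------------------------------
# theta = [ exog means (px) | exog cov log-Cholesky (px(px+1)/2) |
#           per endogenous equation: intercept, coefs, log residual SD ]

path_par_skeleton <- function(spec) {
  px <- length(spec$exog)
  labs <- c(paste0("mean.", spec$exog),
            paste0("chol.", seq_len(px * (px + 1) / 2)))
  for (v in spec$endo)
    labs <- c(labs, paste0(v, ".intercept"),
              paste0(v, "~", spec$equations[[v]]),
              paste0(v, ".log_sd"))
  labs
}

# lower-triangular Cholesky factor with log-diagonal parameterization
chol_from_par <- function(p, px) {
  L <- matrix(0, px, px)
  L[lower.tri(L, diag = TRUE)] <- p
  diag(L) <- exp(diag(L))
  L
}

par_to_chol <- function(Sigma) {
  L <- t(chol(Sigma))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

path_unpack <- function(spec, theta) {
  px <- length(spec$exog)
  i <- 0
  mu_x <- theta[i + seq_len(px)]; i <- i + px
  nL <- px * (px + 1) / 2
  L <- chol_from_par(theta[i + seq_len(nL)], px); i <- i + nL
  Phi <- L %*% t(L)
  eqs <- list()
  for (v in spec$endo) {
    np <- length(spec$equations[[v]])
    eqs[[v]] <- list(intercept = theta[i + 1],
                     coef = stats::setNames(theta[i + 1 + seq_len(np)],
                                            spec$equations[[v]]),
                     sd = exp(theta[i + np + 2]))
    i <- i + np + 2
  }
  list(mu_x = stats::setNames(mu_x, spec$exog), Phi = Phi, eqs = eqs)
}

#' Model-implied mean vector and covariance matrix
#'
#' Standard recursive-system algebra: with all variables stacked as
#' v = alpha + A v + zeta, the implied moments are
#' mu = (I - A)^-1 alpha and Sigma = (I - A)^-1 Omega (I - A)^-T, where
#' Omega holds the exogenous covariance block and the endogenous residual
#' variances.
#'
#' @param spec A `path_spec`.
#' @param theta Parameter vector in the internal layout (see
#'   [path_start_values()]), or the list returned by fitting.
#' @return List with `mu` (named) and `Sigma` (named dimnames), ordered as
#'   `spec$vars`.
#' @export
implied_moments <- function(spec, theta) {
  pp <- if (is.list(theta)) theta else path_unpack(spec, theta)
  vars <- spec$vars
  p <- length(vars)
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  alpha <- stats::setNames(rep(0, p), vars)
  Omega <- matrix(0, p, p, dimnames = list(vars, vars))
  alpha[spec$exog] <- pp$mu_x
  Omega[spec$exog, spec$exog] <- pp$Phi
  for (v in spec$endo) {
    e <- pp$eqs[[v]]
    alpha[v] <- e$intercept
    A[v, names(e$coef)] <- e$coef
    Omega[v, v] <- e$sd^2
  }
  IAinv <- solve(diag(p) - A)
  mu <- drop(IAinv %*% alpha)
  Sigma <- IAinv %*% Omega %*% t(IAinv)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("implied covariance not positive semi-definite; check residual ",
         "variances and exogenous covariance parameters")
  names(mu) <- vars; dimnames(Sigma) <- list(vars, vars)
  list(mu = mu, Sigma = Sigma)
}

# ---- missingness patterns & sufficient statistics ---------------------------

#' Group rows of a data matrix by missingness pattern
#'
#' Each pattern stores the observed-variable mask, its row count, the
#' observed-variable sample mean and (uncentred about the model mean) scatter,
#' so the FIML log-likelihood can be evaluated from sufficient statistics.
#'
#' @param data Data frame or matrix containing at least `vars`.
#' @param vars Variables to use, in model order.
#' @return List of pattern records; rows with no observed variable are
#'   rejected.
#' @export
missing_patterns <- function(data, vars) {
  X <- as.matrix(as.data.frame(data)[, vars, drop = FALSE])
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0))
    stop("rows with no observed variable are not allowed")
  key <- apply(obs, 1, function(m) paste(as.integer(m), collapse = ""))
  lapply(split(seq_len(nrow(X)), key), function(idx) {
    mask <- obs[idx[1], ]
    Xi <- X[idx, mask, drop = FALSE]
    n <- nrow(Xi)
    xbar <- colMeans(Xi)
    S <- crossprod(sweep(Xi, 2, xbar)) / n
    list(mask = mask, n = n, mean = xbar, scatter = S, rows = idx)
  })
}

mvn_pattern_loglik <- function(patterns, mu, Sigma) {
  ll <- 0
  for (pt in patterns) {
    m <- pt$mask
    S_m <- Sigma[m, m, drop = FALSE]
    ch <- tryCatch(chol(S_m), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    k <- sum(m)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    d <- pt$mean - mu[m]
    quad <- sum(Sinv * pt$scatter) + drop(t(d) %*% Sinv %*% d)
    ll <- ll + pt$n * (-0.5) * (k * log(2 * pi) + logdet + quad)
  }
  ll
}

#' Full-information maximum-likelihood log-likelihood
#'
#' Sum over missingness patterns of the multivariate-normal log-likelihood of
#' each pattern's observed marginal of the model-implied moments. On complete
#' data this is exactly the complete-data multivariate-normal log-likelihood.
#'
#' @param spec A `path_spec`.
#' @param theta Parameter vector (internal layout).
#' @param data Data frame with the model variables (missing values allowed).
#' @param patterns Optional precomputed [missing_patterns()] result.
#' @return Scalar log-likelihood.
#' @export
fiml_loglik <- function(spec, theta, data, patterns = NULL) {
  if (is.null(patterns)) patterns <- missing_patterns(data, spec$vars)
  mom <- implied_moments(spec, theta)
  mvn_pattern_loglik(patterns, mom$mu, mom$Sigma)
}

#' Starting values from complete-case moments and per-equation least squares
#'
#' @param spec A `path_spec`.
#' @param data Data frame.
#' @return Named numeric parameter vector.
#' @export
path_start_values <- function(spec, data) {
  X <- as.data.frame(data)[, spec$vars, drop = FALSE]
  mu_x <- vapply(spec$exog, function(v) mean(X[[v]], na.rm = TRUE), numeric(1))
  Phi <- stats::cov(X[, spec$exog, drop = FALSE], use = "pairwise.complete.obs")
  Phi[is.na(Phi)] <- 0
  # guard against a pairwise covariance that is not PD
  ev <- eigen((Phi + t(Phi)) / 2, symmetric = TRUE)
  Phi <- ev$vectors %*% diag(pmax(ev$values, 1e-6), length(ev$values)) %*%
    t(ev$vectors)
  theta <- c(mu_x, par_to_chol(Phi))
  for (v in spec$endo) {
    rhs <- spec$equations[[v]]
    cc <- stats::complete.cases(X[, c(v, rhs)])
    if (sum(cc) > length(rhs) + 2) {
      f <- stats::lm(stats::reformulate(rhs, v), data = X[cc, , drop = FALSE])
      b <- stats::coef(f)
      s <- stats::sigma(f)
    } else {
      b <- c(mean(X[[v]], na.rm = TRUE), rep(0, length(rhs)))
      s <- stats::sd(X[[v]], na.rm = TRUE)
    }
    b[is.na(b)] <- 0
    if (!is.finite(s) || s <= 0) s <- 1
    theta <- c(theta, b, log(s))
  }
  stats::setNames(theta, path_par_skeleton(spec))
}

# EM algorithm for the saturated multivariate normal with missing data;
# returns the maximized log-likelihood (used for the model chi-square)
mvn_saturated_loglik <- function(patterns, p, tol = 1e-8, max_iter = 500) {
  # initialize from available-case moments
  nt <- sum(vapply(patterns, `[[`, numeric(1), "n"))
  mu <- rep(0, p); M2 <- diag(p)
  sw <- rep(0, p)
  for (pt in patterns) {
    mu[pt$mask] <- mu[pt$mask] + pt$n * pt$mean
    sw[pt$mask] <- sw[pt$mask] + pt$n
  }
  mu <- mu / pmax(sw, 1)
  Sigma <- diag(p)
  for (pt in patterns) {
    m <- which(pt$mask)
    Sigma[m, m] <- pt$scatter + tcrossprod(pt$mean - mu[m])
    break
  }
  Sigma <- (Sigma + t(Sigma)) / 2 + diag(1e-6, p)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    sum1 <- rep(0, p); sum2 <- matrix(0, p, p)
    for (pt in patterns) {
      o <- which(pt$mask); miss <- which(!pt$mask)
      Soo_inv <- solve(Sigma[o, o, drop = FALSE])
      d <- pt$mean - mu[o]
      if (length(miss) == 0) {
        Ex <- pt$mean
        Exx <- pt$scatter + tcrossprod(Ex)
        E2 <- matrix(0, p, p); E2[o, o] <- Exx
        E1 <- rep(0, p); E1[o] <- Ex
      } else {
        B <- Sigma[miss, o, drop = FALSE] %*% Soo_inv
        Em <- mu[miss] + drop(B %*% d)
        Cmm <- Sigma[miss, miss, drop = FALSE] -
          B %*% Sigma[o, miss, drop = FALSE]
        E1 <- rep(0, p); E1[o] <- pt$mean; E1[miss] <- Em
        # E[x x'] per pattern using the pattern's observed scatter
        Soo <- pt$scatter + tcrossprod(pt$mean)
        Som <- (pt$scatter + tcrossprod(pt$mean, pt$mean)) %*% t(B) +
          tcrossprod(pt$mean, Em - drop(B %*% pt$mean))
        Smm <- Cmm + B %*% pt$scatter %*% t(B) + tcrossprod(Em)
        E2 <- matrix(0, p, p)
        E2[o, o] <- Soo
        E2[o, miss] <- Som
        E2[miss, o] <- t(Som)
        E2[miss, miss] <- Smm
      }
      sum1 <- sum1 + pt$n * E1
      sum2 <- sum2 + pt$n * E2
    }
    mu <- sum1 / nt
    Sigma <- sum2 / nt - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- mvn_pattern_loglik(patterns, mu, Sigma)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  ll
}

# independence baseline: per-variable univariate normal ML on observed values
mvn_baseline_loglik <- function(data, vars) {
  ll <- 0
  for (v in vars) {
    x <- data[[v]]; x <- x[!is.na(x)]
    n <- length(x)
    s2 <- sum((x - mean(x))^2) / n
    ll <- ll + (-0.5) * n * (log(2 * pi) + log(s2) + 1)
  }
  ll
}

#' Fit a recursive path model by FIML
#'
#' Maximizes the pattern-wise multivariate-normal log-likelihood over the
#' structural coefficients, intercepts, log residual SDs, and the saturated
#' exogenous means/covariance (log-Cholesky parameterized), by quasi-Newton
#' (BFGS). On complete data the coefficient estimates coincide with
#' per-equation ordinary least squares, the classical equivalence for
#' recursive systems. The model chi-square is 2 (saturated - model)
#' log-likelihood, with the saturated model fitted by EM under missingness;
#' the baseline for CFI/TLI is the independence model.
#'
#' @param spec A `path_spec`.
#' @param data Data frame with the model variables.
#' @param se Compute analytic standard errors from the numerical Hessian.
#' @param start Optional starting parameter vector.
#' @param control Passed to [stats::optim()] (BFGS); `maxit` defaults to 500
#'   and `reltol` to 1e-12.
#' @return A `path_fit` object: `coefficients` (data frame with estimate and
#'   SE for the structural parameters), `theta`, `loglik`, `chisq`, `df`,
#'   `fit_indices`, `n`, convergence info.
#' @export
fit_path <- function(spec, data, se = TRUE, start = NULL, control = list()) {
  patterns <- missing_patterns(data, spec$vars)
  n <- sum(vapply(patterns, `[[`, numeric(1), "n"))
  if (is.null(start)) start <- path_start_values(spec, data)
  negll <- function(th) {
    ll <- tryCatch(fiml_loglik(spec, th, data, patterns = patterns),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  opt <- stats::optim(start, negll, method = "BFGS", control = ctrl)
  if (opt$convergence != 0)
    stop("FIML optimization did not converge (code ", opt$convergence,
         "): ", opt$message)
  theta <- opt$par
  ll <- -opt$value

  p <- length(spec$vars)
  ll_sat <- if (length(patterns) == 1 && all(patterns[[1]]$mask)) {
    pt <- patterns[[1]]
    mvn_pattern_loglik(patterns, pt$mean, pt$scatter)
  } else mvn_saturated_loglik(patterns, p)
  n_par_sat <- p + p * (p + 1) / 2
  chisq <- max(2 * (ll_sat - ll), 0)
  df <- n_par_sat - length(theta)

  ll_base <- mvn_baseline_loglik(as.data.frame(data)[, spec$vars], spec$vars)
  chisq_b <- max(2 * (ll_sat - ll_base), 0)
  df_b <- n_par_sat - 2 * p
  fi <- fit_indices(chisq, df, chisq_b, df_b, n)

  ses <- rep(NA_real_, length(theta))
  if (se) {
    H <- stats::optimHess(theta, negll)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      ok <- is.finite(dv) & dv > 0
      ses[ok] <- sqrt(dv[ok])
    }
  }
  labs <- path_par_skeleton(spec)
  keep <- grepl("~|\\.intercept$", labs)
  coefs <- data.frame(parameter = labs[keep], estimate = unname(theta[keep]),
                      se = ses[keep], stringsAsFactors = FALSE)
  coefs$ci_lo <- coefs$estimate - 1.959964 * coefs$se
  coefs$ci_hi <- coefs$estimate + 1.959964 * coefs$se
  structure(list(spec = spec, coefficients = coefs, theta = theta,
                 loglik = ll, loglik_saturated = ll_sat,
                 chisq = chisq, df = df,
                 chisq_baseline = chisq_b, df_baseline = df_b,
                 fit_indices = fi, n = n, convergence = opt$convergence,
                 counts = opt$counts),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("FIML path model fit (", x$spec$variant, ", trait = ", x$spec$trait,
      ", n = ", x$n, ")\n", sep = "")
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), ci_lo = round(ci_lo, 4),
                  ci_hi = round(ci_hi, 4)), row.names = FALSE)
  cat(sprintf("loglik %.3f; chi-square %.3f on %d df; CFI %.3f TLI %s RMSEA %.4f\n",
              x$loglik, x$chisq, x$df, x$fit_indices["cfi"],
              ifelse(is.na(x$fit_indices["tli"]), "NA",
                     sprintf("%.3f", x$fit_indices["tli"])),
              x$fit_indices["rmsea"]))
  invisible(x)
}

#' Extract a structural coefficient from a path fit
#'
#' @param fit A `path_fit`.
#' @param outcome,predictor Variable names of the edge `outcome ~ predictor`.
#' @return The point estimate.
#' @export
path_coef <- function(fit, outcome, predictor) {
  lab <- paste0(outcome, "~", predictor)
  i <- match(lab, fit$coefficients$parameter)
  if (is.na(i)) stop("no edge ", lab, " in this model")
  fit$coefficients$estimate[i]
}

#' Incremental and absolute fit indices
#'
#' CFI = 1 - max(chisq_m - df_m, 0) / max(chisq_b - df_b, chisq_m - df_m, 0);
#' TLI = ((chisq_b/df_b) - (chisq_m/df_m)) / ((chisq_b/df_b) - 1);
#' RMSEA = sqrt(max(chisq_m - df_m, 0) / (df_m (n - 1))).
#' With zero model degrees of freedom RMSEA is defined as 0 and TLI is
#' undefined (returned `NA`). CFI and TLI are clamped to [0, 1].
#'
#' @param chisq_m,df_m Model chi-square and degrees of freedom.
#' @param chisq_b,df_b Baseline (independence) chi-square and df.
#' @param n Sample size.
#' @return Named vector `c(cfi, tli, rmsea)`.
#' @export
fit_indices <- function(chisq_m, df_m, chisq_b, df_b, n) {
  num <- max(chisq_m - df_m, 0)
  den <- max(chisq_b - df_b, chisq_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  if (df_m == 0) {
    tli <- NA_real_
    rmsea <- 0
  } else {
    rb <- chisq_b / df_b
    tli <- (rb - chisq_m / df_m) / (rb - 1)
    rmsea <- sqrt(max(chisq_m - df_m, 0) / (df_m * (n - 1)))
  }
  c(cfi = min(max(cfi, 0), 1),
    tli = if (is.na(tli)) NA_real_ else min(max(tli, 0), 1),
    rmsea = rmsea)
}

#' Direct, indirect and total effect of NWC on the age-7 trait
#'
#' Requires a joint mediation fit. The indirect effect is the product of the
#' NWC -> trait-at-4 and trait-at-4 -> trait-at-7 coefficients; the total is
#' direct + indirect, an identity at the point estimates.
#'
#' @param fit A `path_fit` of a `"joint"` specification.
#' @return Named vector `c(direct, indirect, total)`.
#' @export
effect_decomposition <- function(fit) {
  if (fit$spec$variant != "joint")
    stop("effect decomposition requires the joint mediation model")
  t4 <- paste0(fit$spec$trait, "4_z"); t7 <- paste0(fit$spec$trait, "7_z")
  a <- path_coef(fit, t4, "nwc")
  b <- path_coef(fit, t7, t4)
  direct <- path_coef(fit, t7, "nwc")
  c(direct = direct, indirect = a * b, total = direct + a * b)
}

#' Percentile bootstrap confidence intervals for a path model
#'
#' Resamples children (rows) with replacement, refits by FIML starting from
#' the full-data solution, and takes the 2.5/97.5 percentiles of each
#' structural coefficient (and, for joint models, of the effect
#' decomposition). Failed replicates are dropped and counted; more than 10%
#' failures is an error.
#'
#' @param spec A `path_spec`.
#' @param data Data frame.
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param seed Integer seed; results are fully reproducible.
#' @param level Confidence level (default 0.95).
#' @return List with `ci` (data frame: parameter, lo, hi), `n_failed`,
#'   `fit` (the full-data fit) and the replicate draws.
#' @export
bootstrap_ci <- function(spec, data, n_boot = 1000, seed = 1L, level = 0.95) {
  if (n_boot < 200) stop("n_boot must be at least 200")
  data <- as.data.frame(data)
  fit0 <- fit_path(spec, data, se = FALSE)
  keep <- grepl("~|\\.intercept$", path_par_skeleton(spec))
  is_joint <- spec$variant == "joint"
  set.seed(seed)
  n <- nrow(data)
  draws <- matrix(NA_real_, n_boot,
                  sum(keep) + if (is_joint) 3 else 0)
  cn <- path_par_skeleton(spec)[keep]
  if (is_joint) cn <- c(cn, "effect.direct", "effect.indirect", "effect.total")
  colnames(draws) <- cn
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      fit_path(spec, data[idx, , drop = FALSE], se = FALSE,
               start = fit0$theta),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fb)) { n_failed <- n_failed + 1L; next }
    row <- fb$theta[keep]
    if (is_joint) row <- c(row, effect_decomposition(fb))
    draws[b, ] <- row
  }
  if (n_failed > 0.1 * n_boot)
    stop(n_failed, " of ", n_boot, " bootstrap replicates failed to converge")
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, type = 7))
  list(ci = data.frame(parameter = rownames(ci), lo = ci[, 1], hi = ci[, 2],
                       row.names = NULL, stringsAsFactors = FALSE),
       n_failed = n_failed, fit = fit0, draws = draws)
}

#' Simulate data from a recursive path model
#'
#' Draws the exogenous block from its multivariate normal and propagates the
#' structural equations in declaration order, adding normal residuals. Used
#' for parameter-recovery experiments and as the Monte-Carlo oracle for the
#' implied-moment algebra.
#'
#' @param spec A `path_spec`.
#' @param theta Parameter vector in the internal layout, e.g. from
#'   [path_theta()] or a previous fit.
#' @param n Number of rows.
#' @param seed Optional integer seed.
#' @return Data frame with the model variables.
#' @export
simulate_path_cohort <- function(spec, theta, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pp <- if (is.list(theta)) theta else path_unpack(spec, theta)
  X <- MASS::mvrnorm(n, pp$mu_x, pp$Phi)
  if (length(spec$exog) == 1) X <- matrix(X, ncol = 1)
  colnames(X) <- spec$exog
  out <- as.data.frame(X)
  for (v in spec$endo) {
    e <- pp$eqs[[v]]
    out[[v]] <- e$intercept +
      drop(as.matrix(out[, names(e$coef), drop = FALSE]) %*% e$coef) +
      stats::rnorm(n, 0, e$sd)
  }
  out
}

#' Assemble a parameter vector for a path specification
#'
#' Convenience constructor for simulation and for evaluating
#' [fiml_loglik()] / [implied_moments()] at chosen values: exogenous means
#' and covariance plus per-equation intercepts, named coefficients and
#' residual SDs. Unnamed coefficients default to 0, residual SDs to 1.
#'
#' @param spec A `path_spec`.
#' @param mu_x Named exogenous means (default all 0).
#' @param Phi Exogenous covariance (default identity).
#' @param coef Named list per endogenous variable of named coefficient
#'   vectors (partial: missing entries are 0).
#' @param intercept Named intercepts (default 0).
#' @param sd_resid Named residual SDs (default 1).
#' @return Named parameter vector in the internal layout.
#' @export
path_theta <- function(spec, mu_x = NULL, Phi = NULL, coef = list(),
                       intercept = NULL, sd_resid = NULL) {
  px <- length(spec$exog)
  if (is.null(mu_x)) mu_x <- stats::setNames(rep(0, px), spec$exog)
  if (is.null(Phi)) Phi <- diag(px)
  theta <- c(mu_x[spec$exog], par_to_chol(Phi))
  for (v in spec$endo) {
    rhs <- spec$equations[[v]]
    b <- stats::setNames(rep(0, length(rhs)), rhs)
    if (!is.null(coef[[v]])) b[names(coef[[v]])] <- coef[[v]]
    a <- if (!is.null(intercept) && v %in% names(intercept)) intercept[[v]] else 0
    s <- if (!is.null(sd_resid) && v %in% names(sd_resid)) sd_resid[[v]] else 1
    theta <- c(theta, a, b, log(s))
  }
  stats::setNames(theta, path_par_skeleton(spec))
}

#' Pairwise-complete Pearson correlation matrix with significance stars
#'
#' @param data Data frame of numeric columns (e.g. NWC plus trait z-scores
#'   at both ages).
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return List with matrices `r`, `p`, `n`, and `stars` (`*` p < 0.05,
#'   `**` p < 0.01, `***` p < 0.001). Constant variables yield `NA` cells
#'   with a warning.
#' @export
pearson_matrix <- function(data, min_pairs = 3) {
  data <- as.data.frame(data)
  vars <- names(data)
  k <- length(vars)
  r <- p <- nn <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  const <- vapply(data, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                    all(is.na(x)), logical(1))
  if (any(const))
    warning("constant variable(s): ", paste(vars[const], collapse = ", "))
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; nn[i, j] <- sum(!is.na(data[[i]])); next }
    cc <- stats::complete.cases(data[[i]], data[[j]])
    nn[i, j] <- nn[j, i] <- sum(cc)
    if (sum(cc) < min_pairs || const[i] || const[j]) next
    ct <- stats::cor.test(data[[i]][cc], data[[j]][cc], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  list(r = r, p = p, n = nn, stars = stars)
}
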