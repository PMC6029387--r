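#' LDL cholesterol by the Friedewald equation
#'
#' LDL-C = total cholesterol - HDL-C - triglycerides / 5, all in mg/dL.
#' Returns `NA` where triglycerides exceed 400 mg/dL, outside the equation's
#' validity range.
#'
#' @param total_chol,hdl,tg Concentrations in mg/dL (vectorized, >= 0).
#' @return LDL-C in mg/dL.
#' @export
#' @examples
#' friedewald_ldl(170, 50, 61)  # 107.8
friedewald_ldl <- function(total_chol, hdl, tg) {
  if (any(c(total_chol, hdl, tg) < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  ldl <- total_chol - hdl - tg / 5
  ldl[!is.na(tg) & tg > 400] <- NA_real_
  ldl
}

#' Summarize repeated blood-pressure readings
#'
#' Protocol: with two readings differing by less than 5 mmHg, their mean;
#' otherwise a third reading is required and the mean of the two closest
#' readings is used. Readings differing by exactly 5 mmHg are treated as
#' requiring the third measurement. When the third reading is equidistant
#' from both others (a closest-pair tie) the pair with the lower mean is
#' taken — a deterministic, conservative convention.
#'
#' @param readings Numeric vector of 2 or 3 readings (mmHg); `NA` third
#'   reading is treated as absent.
#' @param tie Tie-break for an equidistant third reading: `"lower"` (default)
#'   or `"higher"` mean pair.
#' @return Summary BP in mmHg, or `NA` (with a warning) when two discrepant
#'   readings lack the required third.
#' @export
bp_summary <- function(readings, tie = c("lower", "higher")) {
  tie <- match.arg(tie)
  readings <- readings[!is.na(readings)]
  if (length(readings) < 2 || length(readings) > 3)
    stop("2 or 3 readings required")
  if (length(readings) == 2) {
    if (abs(readings[1] - readings[2]) < 5) return(mean(readings))
    warning("readings differ by >= 5 mmHg and no third reading is available")
    return(NA_real_)
  }
  pairs <- utils::combn(3, 2)
  d <- apply(pairs, 2, function(j) abs(diff(readings[j])))
  m <- apply(pairs, 2, function(j) mean(readings[j]))
  best <- which(d == min(d))
  if (length(best) > 1)
    best <- best[if (tie == "lower") which.min(m[best]) else which.max(m[best])]
  m[best]
}

#' Apply the BP protocol to reading columns of a visit table
#'
#' @param tbl Visit table.
#' @param prefix `"sbp"` or `"dbp"`; columns `<prefix>1..3` are consumed.
#' @param tie Passed to [bp_summary()].
#' @return Numeric vector of summarized pressures.
#' @export
bp_summarize_columns <- function(tbl, prefix, tie = "lower") {
  cols <- paste0(prefix, 1:3)
  stopifnot(all(cols[1:2] %in% names(tbl)))
  r <- as.matrix(tbl[, intersect(cols, names(tbl)), drop = FALSE])
  apply(r, 1, function(x) {
    if (sum(!is.na(x)) < 2) return(NA_real_)
    suppressWarnings(bp_summary(x, tie = tie))
  })
}

#' Build an age- and sex-specific cohort reference table
#'
#' Splits the cohort into 6-month (by default) age bins per sex and computes
#' the per-cell mean and SD (n - 1 denominator) of each trait; traits listed
#' in `height_banded` are additionally split into height-quantile bands
#' within each (sex, age-bin) cell, so that standardization against the
#' table is independent of height.
#'
#' @param panel Data frame with `sex`, `visit_age`, optionally `height`, and
#'   the trait columns.
#' @param traits Character vector of trait columns to summarize.
#' @param bin_width Age-bin width in years (default 0.5).
#' @param height_banded Traits to band by height (requires `height`).
#' @param n_height_bands Number of equal-probability height bands.
#' @param min_n Cells with fewer observations are flagged `sparse`.
#' @return A `cohort_reference` data frame: sex, age_lo, age_hi, height_band,
#'   height_lo, height_hi, trait, mean, sd, n, sparse.
#' @export
build_reference <- function(panel, traits, bin_width = 0.5,
                            height_banded = character(0),
                            n_height_bands = 3, min_n = 2) {
  stopifnot(all(c("sex", "visit_age") %in% names(panel)),
            all(traits %in% names(panel)))
  a0 <- floor(min(panel$visit_age, na.rm = TRUE) / bin_width) * bin_width
  a1 <- max(panel$visit_age, na.rm = TRUE)
  breaks <- seq(a0, a1 + bin_width, by = bin_width)
  bin <- findInterval(panel$visit_age, breaks, rightmost.closed = TRUE)

  rows <- list()
  for (s in unique(panel$sex)) for (b in sort(unique(bin))) {
    cell <- panel$sex == s & bin == b & !is.na(panel$visit_age)
    if (!any(cell)) next
    for (tr in traits) {
      if (tr %in% height_banded) {
        h <- panel$height[cell]
        hq <- stats::quantile(h, probs = seq(0, 1, length.out = n_height_bands + 1),
                              na.rm = TRUE, names = FALSE)
        hq[1] <- -Inf; hq[length(hq)] <- Inf
        hb <- findInterval(panel$height, hq, rightmost.closed = TRUE)
        for (k in seq_len(n_height_bands)) {
          sel <- cell & hb == k
          v <- panel[[tr]][sel]; v <- v[!is.na(v)]
          if (length(v) == 0) next
          rows[[length(rows) + 1]] <- data.frame(
            sex = s, age_lo = breaks[b], age_hi = breaks[b + 1],
            height_band = k, height_lo = hq[k], height_hi = hq[k + 1],
            trait = tr, mean = mean(v), sd = stats::sd(v), n = length(v),
            sparse = length(v) < min_n, stringsAsFactors = FALSE)
        }
      } else {
        v <- panel[[tr]][cell]; v <- v[!is.na(v)]
        if (length(v) == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          sex = s, age_lo = breaks[b], age_hi = breaks[b + 1],
          height_band = NA_integer_, height_lo = NA_real_, height_hi = NA_real_,
          trait = tr, mean = mean(v), sd = stats::sd(v), n = length(v),
          sparse = length(v) < min_n, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) stop("no non-empty (sex, bin, trait) cells")
  ref <- do.call(rbind, rows)
  if (any(is.na(ref$sd) | ref$sd <= 0))
    ref$sparse[is.na(ref$sd) | ref$sd <= 0] <- TRUE
  class(ref) <- c("cohort_reference", "data.frame")
  ref
}

#' Standardize a value against a cohort reference
#'
#' Looks up the (sex, age-bin[, height-band]) cell and returns
#' (value - mean) / sd. No extrapolation: a missing cell yields `NA` with a
#' warning.
#'
#' @param value Numeric value(s) on the trait's natural scale.
#' @param sex,age Matching keys (vectorized along `value`).
#' @param trait Trait name present in the reference.
#' @param reference A [build_reference()] table.
#' @param height Height in cm, required for height-banded traits.
#' @return z-score(s).
#' @export
zscore <- function(value, sex, age, trait, reference, height = NA) {
  stopifnot(inherits(reference, "cohort_reference"))
  ref <- reference[reference$trait == trait, , drop = FALSE]
  if (nrow(ref) == 0) stop("trait '", trait, "' not in reference")
  banded <- !all(is.na(ref$height_band))
  n <- length(value)
  sex <- rep_len(sex, n); age <- rep_len(age, n); height <- rep_len(height, n)
  out <- rep(NA_real_, n)
  unmatched <- 0L
  for (i in seq_len(n)) {
    if (is.na(value[i]) || is.na(age[i])) next
    hit <- ref$sex == sex[i] & ref$age_lo <= age[i] & age[i] < ref$age_hi
    if (banded) {
      if (is.na(height[i])) next
      hit <- hit & ref$height_lo <= height[i] & height[i] < ref$height_hi
    }
    j <- which(hit)
    if (length(j) != 1 || is.na(ref$sd[j]) || ref$sd[j] <= 0) {
      unmatched <- unmatched + 1L
      next
    }
    out[i] <- (value[i] - ref$mean[j]) / ref$sd[j]
  }
  if (unmatched > 0)
    warning(unmatched, " value(s) had no matching reference cell; returned NA")
  out
}

#' Flag values above the cohort's 90th percentile
#'
#' The threshold is the empirical 90th percentile by the linear-interpolation
#' quantile definition (R type 7); flags are strictly above it, so constant
#' data flags nothing.
#'
#' @param values Numeric vector (>= 10 non-missing values required).
#' @param prob Percentile (default 0.9).
#' @return Logical vector aligned with `values` (`NA` where value missing).
#' @export
high_flag <- function(values, prob = 0.9) {
  ok <- !is.na(values)
  if (sum(ok) < 10) stop("need at least 10 non-missing values")
  thr <- stats::quantile(values[ok], prob, type = 7, names = FALSE)
  out <- values > thr
  out[!ok] <- NA
  out
}

#' Derive the outcome panel from raw visit measurements
#'
#' Computes LDL-C by Friedewald, protocol-averaged SBP/DBP, then z-scores
#' every trait against the supplied (or internally built) cohort reference
#' and flags values above the cohort 90th percentile. BP traits are
#' standardized against height-banded cells when `bp_height_bands > 0`.
#'
#' @param visits Raw visit table (see [generate_child_outcomes()]).
#' @param reference Optional [build_reference()] table; by default the
#'   cohort's own reference is built from `visits` (internal standardization).
#' @param bp_height_bands Number of height bands for the BP reference cells
#'   (0 disables height banding).
#' @param bin_width Age-bin width in years.
#' @return An `outcome_panel` data frame: id, sex, visit_age, height, per
#'   trait the natural value, `<trait>_z` and `<trait>_high`.
#' @export
derive_outcomes <- function(visits, reference = NULL, bp_height_bands = 3,
                            bin_width = 0.5) {
  panel <- data.frame(id = visits$id, sex = visits$sex,
                      visit_age = visits$visit_age, height = visits$height,
                      stringsAsFactors = FALSE)
  panel$waist <- visits$waist
  panel$glucose <- visits$glucose
  panel$tg <- visits$tg
  panel$ldl <- friedewald_ldl(visits$total_chol, visits$hdl, visits$tg)
  panel$sbp <- bp_summarize_columns(visits, "sbp")
  panel$dbp <- bp_summarize_columns(visits, "dbp")

  traits <- c("glucose", "ldl", "tg", "waist", "sbp", "dbp")
  if (is.null(reference)) {
    banded <- if (bp_height_bands > 0) c("sbp", "dbp") else character(0)
    reference <- build_reference(panel, traits, bin_width = bin_width,
                                 height_banded = banded,
                                 n_height_bands = max(bp_height_bands, 1))
  }
  for (tr in traits) {
    panel[[paste0(tr, "_z")]] <- zscore(panel[[tr]], panel$sex,
                                        panel$visit_age, tr, reference,
                                        height = panel$height)
    panel[[paste0(tr, "_high")]] <- high_flag(panel[[tr]])
  }
  attr(panel, "reference") <- reference
  class(panel) <- c("outcome_panel", "data.frame")
  panel
}
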