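#' Configuration for a full pipeline run
#'
#' @param growth A [growth_sim_params()] object (or a list of overrides for
#'   its defaults).
#' @param tracking A [tracking_sim_params()] object (or overrides).
#' @param seed Master seed; the growth and tracking streams are derived from
#'   it unless their own seeds are given explicitly.
#' @param n_boot Bootstrap replicates for the path models (0 disables
#'   bootstrap CIs and reports analytic Wald CIs only).
#' @param traits Traits to run path models for.
#' @param fence_mode `"empirical"` (Tukey fences from the analysis sample) or
#'   `"fixed"` with `fences = c(low, high)` percent per hour.
#' @param fences Fixed fences when `fence_mode = "fixed"`.
#' @param missing_rate Per-variable missingness rate applied to the trait
#'   columns of both visit tables (MCAR) before analysis; 0 keeps the data
#'   complete.
#' @param out_dir Output directory for intermediate CSVs; `NULL` keeps
#'   everything in memory.
#' @return A `run_config` list.
#' @export
run_config <- function(growth = growth_sim_params(),
                       tracking = tracking_sim_params(),
                       seed = 1L, n_boot = 0,
                       traits = c("glucose", "ldl", "tg", "waist", "sbp", "dbp"),
                       fence_mode = c("empirical", "fixed"),
                       fences = c(-0.50, 0.19),
                       missing_rate = 0,
                       out_dir = NULL) {
  fence_mode <- match.arg(fence_mode)
  if (is.list(growth) && !inherits(growth, "growth_sim_params"))
    growth <- do.call(growth_sim_params, growth)
  if (is.list(tracking) && !inherits(tracking, "tracking_sim_params"))
    tracking <- do.call(tracking_sim_params, tracking)
  growth$seed <- as.integer(seed)
  tracking$seed <- as.integer(seed) + 1000L
  structure(list(growth = growth, tracking = tracking, seed = as.integer(seed),
                 n_boot = n_boot, traits = traits, fence_mode = fence_mode,
                 fences = fences, missing_rate = missing_rate,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may hold `growth:` and `tracking:` mappings mirroring the two
#' parameter constructors plus the top-level `run_config()` fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$growth)) args$growth <- do.call(growth_sim_params, y$growth)
  if (!is.null(y$tracking)) {
    tr <- y$tracking
    for (f in c("mean4", "sd4", "mean7", "sd7", "tracking",
                "nwc_effect_4", "nwc_effect_7", "confounder_effects"))
      if (!is.null(tr[[f]])) tr[[f]] <- unlist(tr[[f]])
    args$tracking <- do.call(tracking_sim_params, tr)
  }
  for (f in c("seed", "n_boot", "traits", "fence_mode", "fences",
              "missing_rate", "out_dir"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(run_config, args)
}

#' Table-1-style descriptive summary of an outcome panel
#'
#' Mean (SD) for all traits except triglycerides, which get median (IQR);
#' plus n (%) above the cohort 90th percentile.
#'
#' @param panel An `outcome_panel` from [derive_outcomes()].
#' @param traits Trait columns to summarize.
#' @return Data frame: trait, n, mean, sd, median, iqr, n_high, pct_high.
#' @export
describe_panel <- function(panel,
                           traits = c("glucose", "ldl", "tg", "waist",
                                      "sbp", "dbp")) {
  if (nrow(panel) == 0) stop("empty panel")
  rows <- lapply(traits, function(tr) {
    v <- panel[[tr]]; v <- v[!is.na(v)]
    hf <- panel[[paste0(tr, "_high")]]
    data.frame(trait = tr, n = length(v),
               mean = mean(v), sd = stats::sd(v),
               median = stats::median(v),
               iqr = unname(diff(stats::quantile(v, c(0.25, 0.75)))),
               n_high = sum(hf, na.rm = TRUE),
               pct_high = 100 * mean(hf, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages: simulate newborns -> fit the growth model and compute NWC ->
#' apply the exclusion cascade -> simulate and derive childhood outcome
#' panels -> merge one row per child -> correlation matrix and per-trait
#' path models. Deterministic under a fixed config.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `cascade` report, `fences`, `growth_fit`,
#'   `table1` (per age), `table2` (correlation matrices), `table3`
#'   (coefficient table across traits/variants), `merged` data, and a
#'   provenance block (seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- generate_newborns(config$growth)
  casc <- apply_exclusion_cascade(
    sim$newborns,
    fences = if (config$fence_mode == "fixed") config$fences else NULL)
  kept <- casc$kept

  gfit <- fit_cubic_lmm(kept)
  nwc <- nwc_table(gfit, kept)

  kids <- generate_child_outcomes(kept, config$tracking,
                                  nwc = nwc$nwc[match(kept$id, nwc$id)])
  age4 <- kids$age4; age7 <- kids$age7
  if (config$missing_rate > 0) {
    tcols <- c("glucose", "total_chol", "hdl", "tg", "waist",
               "sbp1", "sbp2", "dbp1", "dbp2")
    age4 <- inject_missingness(age4, config$missing_rate, "mcar",
                               cols = tcols, seed = config$seed + 11L)
    age7 <- inject_missingness(age7, config$missing_rate, "mcar",
                               cols = tcols, seed = config$seed + 12L)
  }
  pan4 <- derive_outcomes(age4)
  pan7 <- derive_outcomes(age7)

  merged <- data.frame(id = kept$id,
                       nwc = nwc$nwc[match(kept$id, nwc$id)],
                       maternal_education = kept$maternal_education,
                       pre_pregnancy_bmi = kept$pre_pregnancy_bmi,
                       gestational_age = kept$gestational_age,
                       birthweight = kept$birthweight,
                       stringsAsFactors = FALSE)
  for (tr in config$traits) {
    merged[[paste0(tr, "4_z")]] <- pan4[[paste0(tr, "_z")]][match(kept$id, pan4$id)]
    merged[[paste0(tr, "7_z")]] <- pan7[[paste0(tr, "_z")]][match(kept$id, pan7$id)]
  }

  zcols <- c("nwc", paste0(rep(config$traits, each = 2), c("4_z", "7_z")))
  tab2 <- pearson_matrix(merged[, zcols])

  rows <- list()
  for (tr in config$traits) {
    for (variant in c("model1_age4", "model1_age7", "model2_age7")) {
      spec <- build_model(tr, variant)
      fit <- fit_path(spec, merged)
      cc <- fit$coefficients
      cc <- cc[grepl("~", cc$parameter), , drop = FALSE]
      if (config$n_boot >= 200) {
        bs <- bootstrap_ci(spec, merged, n_boot = config$n_boot,
                           seed = config$seed + 7L)
        m <- match(cc$parameter, bs$ci$parameter)
        cc$ci_lo <- bs$ci$lo[m]; cc$ci_hi <- bs$ci$hi[m]
      }
      cc$trait <- tr; cc$variant <- variant
      cc$cfi <- fit$fit_indices["cfi"]
      cc$rmsea <- fit$fit_indices["rmsea"]
      rows[[length(rows) + 1]] <- cc
    }
  }
  tab3 <- do.call(rbind, rows)

  report <- structure(list(
    cascade = casc$report, fences = casc$fences, growth_fit = gfit,
    nadir_time = gfit$nadir_time,
    table1 = list(nwc = c(mean = mean(nwc$nwc), sd = stats::sd(nwc$nwc)),
                  age4 = describe_panel(pan4), age7 = describe_panel(pan7)),
    table2 = tab2, table3 = tab3, merged = merged,
    provenance = list(seed = config$seed,
                      n_boot = config$n_boot,
                      fence_mode = config$fence_mode,
                      package_version =
                        as.character(utils::packageVersion("nadirpath")))),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.csv(x, file.path(config$out_dir, f),
                                         row.names = FALSE)
    w(sim$newborns, "newborns.csv")
    w(sim$truth$subjects, "truth_subjects.csv")
    w(casc$report, "cascade.csv")
    w(nwc, "nwc.csv")
    w(as.data.frame(pan4), "panel_age4.csv")
    w(as.data.frame(pan7), "panel_age7.csv")
    w(merged, "merged.csv")
    w(tab3, "table3.csv")
    yaml::write_yaml(list(growth = unclass(config$growth),
                          seed = config$seed),
                     file.path(config$out_dir, "params.yaml"))
    writeLines(format_cascade(casc$report),
               file.path(config$out_dir, "flowchart.txt"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$provenance$seed, ")\n", sep = "")
  writeLines(format_cascade(x$cascade))
  cat(sprintf("population nadir: %.2f h;  NWC mean %.2f (SD %.2f) %%\n",
              x$nadir_time, x$table1$nwc["mean"], x$table1$nwc["sd"]))
  cat("NWC coefficients (model 1 / model 2):\n")
  nw <- x$table3[grepl("~nwc$", x$table3$parameter), ]
  print(data.frame(trait = nw$trait, variant = nw$variant,
                   beta = round(nw$estimate, 3),
                   ci = sprintf("(%.3f; %.3f)", nw$ci_lo, nw$ci_hi)),
        row.names = FALSE)
  invisible(x)
}
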