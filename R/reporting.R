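#' Default comorbidity code map
#'
#' Diagnosis-code prefixes defining the comorbidity groups tabulated in
#' the demographics table. The prefixes are documented STAND-INS (the
#' validated code lists behind published claims analyses are not
#' redistributable); edit or replace for substantive use.
#'
#' @return data.table with columns `group`, `dx_prefix`.
#' @export
default_comorbidity_map <- function() {
  data.table(
    group = c("scoliosis", "dyspnea_respiratory", "muscle_weakness",
              "chronic_respiratory_failure", "feeding_difficulties",
              "neurodevelopmental", "elimination", "anxiety",
              "depressive"),
    dx_prefix = c("M41", "R06", "M62.81", "J96.1", "R63.3", "F88",
                  "F98.0", "F41", "F32"))
}

#' Classify a patient's risdiplam treatment regimen
#'
#' Based on dated nusinersen / onasemnogene-abeparvovec claims relative
#' to the index date: `risdiplam_monotherapy` (no other DMT claim ever),
#' `prior_nusinersen` (nusinersen before index only),
#' `prior_nusinersen_switchback` (nusinersen both before and after
#' index), `post_nusinersen_and_onasemnogene` (both other DMTs before
#' index). Any remaining combination (e.g. a first nusinersen claim
#' after index with no prior exposure) is labelled
#' `other_dmt_exposure`.
#'
#' @param bundle a [claims_bundle()].
#' @param patient_id the patient.
#' @param index_date the patient's index date.
#' @return character scalar regimen class.
#' @export
classify_regimen <- function(bundle, patient_id, index_date) {
  pid <- patient_id   # avoid capture by the data.table column
  med <- bundle$medical[bundle$medical$patient_id == pid, ]
  flags <- .split_tokens(med$flags)
  nus <- med$service_date[vapply(flags, function(v)
    "dmt_nusinersen" %in% v, logical(1))]
  oa <- med$service_date[vapply(flags, function(v)
    "dmt_onasemnogene" %in% v, logical(1))]
  if (!length(nus) && !length(oa)) return("risdiplam_monotherapy")
  if (length(nus) && length(oa) && any(nus < index_date) &&
      any(oa < index_date)) {
    return("post_nusinersen_and_onasemnogene")
  }
  if (length(nus) && any(nus < index_date)) {
    if (any(nus > index_date)) return("prior_nusinersen_switchback")
    return("prior_nusinersen")
  }
  "other_dmt_exposure"
}

#' Assemble the report bundle
#'
#' Writes the analysis tables to `out_dir`: `table1.csv` (demographics
#' and study-period comorbidity prevalence by SMA type), `table2.csv`
#' (PDC summaries and adherent counts overall, by type and by age
#' group), `table3.csv` (PPPY cost summaries by adherence status x SMA
#' type), `km_curve.csv` (product-limit curves overall and by type),
#' `pdc_band_costs.csv` (PPPY cost summaries by PDC band),
#' `regimens.csv`, `patients.csv` (the per-patient course table) and a
#' machine-readable `manifest.json`. Comorbidity prevalence is computed
#' over the study window only.
#'
#' @param bundle a [claims_bundle()].
#' @param cohort output of [select_cohort()].
#' @param adherence output of [compute_adherence()].
#' @param persistence output of [compute_persistence()].
#' @param costs output of [compute_patient_costs()].
#' @param out_dir output directory.
#' @param comorbidity_map see [default_comorbidity_map()].
#' @param outlier_threshold passed to [apply_outlier_exclusion()].
#' @param manifest named list merged into the run manifest.
#' @return Invisibly, the named vector of files written.
#' @export
build_report <- function(bundle, cohort, adherence, persistence, costs,
                         out_dir,
                         comorbidity_map = default_comorbidity_map(),
                         outlier_threshold = 4e6, manifest = list()) {
  windows <- cohort$windows
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, name)

  ## per-patient course table joining every stage
  course <- copy(windows)
  course <- merge(course, adherence, by = "patient_id", all.x = TRUE,
                  sort = TRUE)
  course <- merge(course, persistence, by = "patient_id", all.x = TRUE,
                  sort = TRUE)
  course[, regimen := vapply(seq_len(.N), function(k)
    classify_regimen(bundle, patient_id[k], index_date[k]),
    character(1))]
  fwrite(course, f("patients.csv"), dateTimeAs = "ISO")

  ## table 1: demographics + comorbidity prevalence, by type
  demo <- merge(windows, bundle$demographics, by = "patient_id")
  demo[, age := floor(as.numeric(index_date - birth_date) / 365.25)]
  t1 <- demo[, {
    res <- list(n = .N, age_mean = mean(age),
                age_sd = if (.N > 1) sd(age) else NA_real_,
                age_median = median(age), pct_female = 100 *
                  mean(sex == "F"))
    for (reg in c("South", "Midwest", "West", "Northeast")) {
      res[[paste0("pct_", tolower(reg))]] <- 100 * mean(region == reg)
    }
    res
  }, by = sma_type]
  como <- rbindlist(lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k]
    med <- bundle$medical[patient_id == w$patient_id &
                            service_date >= w$index_date &
                            service_date <= w$end_date]
    dx <- unique(unlist(.split_tokens(med$dx_codes)))
    row <- data.table(patient_id = w$patient_id, sma_type = w$sma_type)
    for (k2 in seq_len(nrow(comorbidity_map))) {
      set(row, j = comorbidity_map$group[k2],
          value = any(startsWith(dx, comorbidity_map$dx_prefix[k2])))
    }
    row
  }))
  if (nrow(como)) {
    prev <- como[, lapply(.SD, function(v) 100 * mean(v)),
                 by = sma_type, .SDcols = comorbidity_map$group]
    t1 <- merge(t1, prev, by = "sma_type", all.x = TRUE)
  }
  setorder(t1, sma_type)
  fwrite(t1, f("table1.csv"))

  ## table 2: adherence overall / by type / by age group
  adh <- merge(adherence, windows[, .(patient_id, sma_type)],
               by = "patient_id")
  t2_block <- function(d, label) {
    if (!nrow(d)) return(NULL)
    d[, .(stratum = label, n = .N, pdc_mean = mean(pdc),
          pdc_sd = if (.N > 1) sd(pdc) else NA_real_,
          pdc_median = median(pdc),
          pdc_q25 = unname(quantile(pdc, 0.25)),
          pdc_q75 = unname(quantile(pdc, 0.75)),
          n_adherent = sum(adherent),
          pct_adherent = 100 * mean(adherent),
          pct_nonadherent = 100 * mean(!adherent))]
  }
  t2 <- rbindlist(c(
    list(t2_block(adh, "overall")),
    lapply(sort(unique(adh$sma_type)), function(ty)
      t2_block(adh[sma_type == ty], paste0("type_", ty))),
    lapply(sort(unique(adh$age_group)), function(g)
      t2_block(adh[age_group == g], paste0("age_", g)))),
    use.names = TRUE)
  if (!ncol(t2)) {
    t2 <- data.table(stratum = character(), n = integer(),
                     pdc_mean = numeric(), pdc_sd = numeric(),
                     pdc_median = numeric(), pdc_q25 = numeric(),
                     pdc_q75 = numeric(), n_adherent = integer(),
                     pct_adherent = numeric(),
                     pct_nonadherent = numeric())
  }
  fwrite(t2, f("table2.csv"))

  ## table 3: costs by adherence x type (outlier-excluded)
  cost_tab <- merge(costs, adh[, .(patient_id, adherent, band)],
                    by = "patient_id")
  cost_tab <- merge(cost_tab, windows[, .(patient_id, sma_type)],
                    by = "patient_id")
  split3 <- apply_outlier_exclusion(cost_tab, outlier_threshold)
  kept <- split3$kept
  t3_by <- if (nrow(kept)) {
    paste0("type_", kept$sma_type, "_",
           ifelse(kept$adherent, "adherent", "nonadherent"))
  } else character(0)
  t3 <- summarize_costs(kept, by = t3_by)
  fwrite(t3, f("table3.csv"))

  ## KM curves overall and by type
  pers <- merge(persistence, windows[, .(patient_id, sma_type)],
                by = "patient_id")
  km_rows <- list()
  if (nrow(pers)) {
    km_all <- km_estimate(pers)
    km_rows[[1]] <- data.table(stratum = "overall", time = km_all$time,
                               n_risk = km_all$n_risk,
                               n_event = km_all$n_event,
                               n_censor = km_all$n_censor,
                               survival = km_all$survival)
    for (ty in sort(unique(pers$sma_type))) {
      cv <- km_estimate(pers[sma_type == ty])
      km_rows[[length(km_rows) + 1L]] <-
        data.table(stratum = paste0("type_", ty), time = cv$time,
                   n_risk = cv$n_risk, n_event = cv$n_event,
                   n_censor = cv$n_censor, survival = cv$survival)
    }
  }
  km_out <- if (length(km_rows)) rbindlist(km_rows) else
    data.table(stratum = character(), time = numeric(),
               n_risk = numeric(), n_event = numeric(),
               n_censor = numeric(), survival = numeric())
  fwrite(km_out, f("km_curve.csv"))

  ## costs by PDC band (outlier-excluded)
  band_tab <- summarize_costs(kept, by = kept$band)
  fwrite(band_tab, f("pdc_band_costs.csv"))

  ## regimen distribution
  reg <- course[, .(n = .N), by = .(regimen)]
  reg[, pct := 100 * n / sum(n)]
  fwrite(reg, f("regimens.csv"))

  manifest <- c(list(package = "smaclaims",
                     version = as.character(packageVersion("smaclaims")),
                     n_cohort = nrow(windows),
                     n_outlier_excluded = nrow(split3$excluded),
                     selection_log = as.list(setNames(
                       cohort$log$n_remaining, cohort$log$criterion))),
                manifest)
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  fwrite(cohort$log, f("selection_log.csv"))

  invisible(setNames(
    f(c("patients.csv", "table1.csv", "table2.csv", "table3.csv",
        "km_curve.csv", "pdc_band_costs.csv", "regimens.csv",
        "selection_log.csv", "manifest.json")),
    c("patients", "table1", "table2", "table3", "km_curve",
      "pdc_band_costs", "regimens", "selection_log", "manifest")))
}

#' Run the end-to-end pipeline
#'
#' Executes: (optionally) simulate -> read -> cohort selection -> typing
#' -> adherence -> persistence -> costs -> report. Deterministic for
#' fixed inputs and seed.
#'
#' @param bundle_dir directory with the four schema files; ignored when
#'   `simulate` is given.
#' @param simulate optional [sim_config()]; when supplied the bundle is
#'   generated (and written to `file.path(out_dir, "bundle")`).
#' @param out_dir report output directory.
#' @param cohort_cfg a [cohort_config()].
#' @param index_table an [inflation_index()].
#' @param gap_days allowable refill gap for persistence.
#' @param carry_forward PDC stacking convention.
#' @param bins age-group preset.
#' @param outlier_threshold cost outlier threshold.
#' @return Invisibly, a list with all stage outputs and written files.
#' @export
run_pipeline <- function(bundle_dir = NULL, simulate = NULL,
                         out_dir = tempfile("smaclaims_report_"),
                         cohort_cfg = cohort_config(),
                         index_table = default_pce_index(),
                         gap_days = 30L, carry_forward = TRUE,
                         bins = "results", outlier_threshold = 4e6) {
  truth <- NULL
  if (!is.null(simulate)) {
    sim <- generate_claims(simulate)
    bundle <- sim$bundle
    truth <- sim$truth
    bdir <- file.path(out_dir, "bundle")
    write_bundle(bundle, bdir)
    fwrite(truth$patients, file.path(bdir, "ground_truth.csv"),
           dateTimeAs = "ISO")
  } else if (!is.null(bundle_dir)) {
    bundle <- read_bundle(bundle_dir)
  } else {
    stop("either 'bundle_dir' or 'simulate' must be supplied",
         call. = FALSE)
  }
  cohort <- select_cohort(bundle, cohort_cfg)
  adherence <- compute_adherence(bundle, cohort$windows,
                                 carry_forward = carry_forward,
                                 bins = bins)
  persistence <- compute_persistence(bundle, cohort$windows,
                                     gap_days = gap_days)
  costs <- compute_patient_costs(bundle, cohort$windows, index_table)
  files <- build_report(
    bundle, cohort, adherence, persistence, costs, out_dir,
    outlier_threshold = outlier_threshold,
    manifest = list(
      seed = if (!is.null(simulate)) simulate$seed else NA,
      simulated = !is.null(simulate), gap_days = gap_days,
      carry_forward = carry_forward, age_bins = bins))
  invisible(list(bundle = bundle, truth = truth, cohort = cohort,
                 adherence = adherence, persistence = persistence,
                 costs = costs, files = files, out_dir = out_dir))
}
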