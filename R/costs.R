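#' Default health-price inflation index snapshot
#'
#' Year-to-index mapping in the role of the Personal Consumption
#' Expenditures (PCE) Health Index, used to express costs in
#' reference-year (2023) dollars. The packaged values are an approximate
#' SYNTHETIC snapshot (roughly 2-3% annual health-price growth), shipped
#' only so the pipeline runs reproducibly offline; substitute the
#' official BEA series via `inflation_index()` for substantive use.
#'
#' @return an `inflation_index` object.
#' @export
default_pce_index <- function() {
  inflation_index(c(`2019` = 108.1, `2020` = 109.7, `2021` = 112.0,
                    `2022` = 116.1, `2023` = 120.1),
                  reference_year = 2023L)
}

#' Construct an inflation index
#'
#' @param values named numeric vector, names are calendar years.
#' @param reference_year year costs are expressed in; must be present.
#' @return list of class `inflation_index`.
#' @export
inflation_index <- function(values, reference_year = 2023L) {
  stopifnot(!is.null(names(values)), all(values > 0))
  years <- as.integer(names(values))
  if (!reference_year %in% years) {
    stop(sprintf("reference year %d missing from inflation index",
                 reference_year), call. = FALSE)
  }
  structure(list(values = setNames(as.numeric(values), years),
                 reference_year = as.integer(reference_year)),
            class = "inflation_index")
}

#' Inflate amounts to reference-year currency
#'
#' `amount * index[reference_year] / index[service_year]`.
#'
#' @param amount numeric vector of amounts.
#' @param service_year integer vector of service years (recycled).
#' @param index an [inflation_index()].
#' @return numeric vector of inflated amounts.
#' @export
inflate <- function(amount, service_year, index = default_pce_index()) {
  stopifnot(inherits(index, "inflation_index"))
  yr <- as.character(service_year)
  miss <- setdiff(unique(yr), names(index$values))
  if (length(miss)) {
    stop(sprintf("inflation index missing year(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  amount * index$values[[as.character(index$reference_year)]] /
    unname(index$values[yr])
}

#' Categorize one patient's claim costs within the study window
#'
#' Medical claims inside `[index, end]` are bucketed by setting
#' (inpatient / outpatient / emergency / other); claims flagged
#' `mechanical_ventilation` or `nutritional_support` are additionally
#' accumulated into those overlay subcategories (reported as part of
#' medical services costs, hence excluded from the setting-sum identity).
#' Disease-modifying-therapy costs never enter any category: medical
#' claims flagged `dmt_nusinersen`/`dmt_onasemnogene` and risdiplam
#' pharmacy fills contribute zero. Non-risdiplam pharmacy fills sum into
#' `pharmacy`. When `index_table` is supplied each claim is inflated by
#' its service calendar year before summing.
#'
#' @param bundle a [claims_bundle()].
#' @param window list with `index_date`, `end_date`.
#' @param patient_id the patient.
#' @param index_table optional [inflation_index()].
#' @return named list of raw category totals: `inpatient`, `outpatient`,
#'   `emergency`, `other_medical`, `ventilation`, `nutrition`,
#'   `medical_total`, `pharmacy`, `total`.
#' @export
categorize_costs <- function(bundle, window, patient_id,
                             index_table = NULL) {
  pid <- patient_id
  index <- as.Date(window$index_date)
  end <- as.Date(window$end_date)

  med <- bundle$medical[bundle$medical$patient_id == pid &
                          bundle$medical$service_date >= index &
                          bundle$medical$service_date <= end]
  flags <- .split_tokens(med$flags)
  is_dmt <- vapply(flags, function(v) any(v %in% .DMT_FLAGS), logical(1))
  med <- med[!is_dmt]
  flags <- flags[!is_dmt]
  cost <- med$allowed_cost
  if (!is.null(index_table)) {
    cost <- inflate(cost, as.integer(format(med$service_date, "%Y")),
                    index_table)
  }
  by_setting <- function(s) sum(cost[med$setting == s])
  has_flag <- function(f) vapply(flags, function(v) f %in% v, logical(1))

  rx <- bundle$pharmacy[bundle$pharmacy$patient_id == pid &
                          bundle$pharmacy$drug == "other" &
                          bundle$pharmacy$fill_date >= index &
                          bundle$pharmacy$fill_date <= end]
  rx_cost <- rx$allowed_cost
  if (!is.null(index_table) && nrow(rx)) {
    rx_cost <- inflate(rx_cost, as.integer(format(rx$fill_date, "%Y")),
                       index_table)
  }
  medical_total <- sum(cost)
  pharmacy <- sum(rx_cost)
  list(inpatient = by_setting("inpatient"),
       outpatient = by_setting("outpatient"),
       emergency = by_setting("emergency"),
       other_medical = by_setting("other"),
       ventilation = sum(cost[has_flag("mechanical_ventilation")]),
       nutrition = sum(cost[has_flag("nutritional_support")]),
       medical_total = medical_total,
       pharmacy = pharmacy,
       total = medical_total + pharmacy)
}

#' Annualize a study-period cost to per-patient per-year
#'
#' `raw_total / (window_length_days / 365.25)`.
#'
#' @param raw_total study-period cost total.
#' @param window_days window length in days (end - index + 1).
#' @return PPPY amount.
#' @export
annualize_pppy <- function(raw_total, window_days) {
  stopifnot(all(window_days >= 1))
  raw_total / (window_days / 365.25)
}

#' Per-patient cost table for a cohort
#'
#' Runs [categorize_costs()] (with inflation) and [annualize_pppy()] per
#' patient.
#'
#' @param bundle a [claims_bundle()].
#' @param windows the `windows` table from [select_cohort()].
#' @param index_table an [inflation_index()] (or `NULL` to skip
#'   inflation).
#' @return data.table, one row per patient: `follow_up_years`, per
#'   category `<cat>_raw` and `<cat>_pppy` columns.
#' @export
compute_patient_costs <- function(bundle, windows,
                                  index_table = default_pce_index()) {
  cats <- c("inpatient", "outpatient", "emergency", "other_medical",
            "ventilation", "nutrition", "medical_total", "pharmacy",
            "total")
  if (!nrow(windows)) {
    cols <- c("patient_id", "follow_up_years",
              paste0(cats, "_raw"), paste0(cats, "_pppy"))
    empty <- as.data.table(setNames(
      c(list(character(), numeric()),
        replicate(2 * length(cats), numeric(), simplify = FALSE)), cols))
    return(empty)
  }
  rbindlist(lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k]
    raw <- categorize_costs(bundle, w, w$patient_id, index_table)
    fy <- w$window_days / 365.25
    row <- data.table(patient_id = w$patient_id, follow_up_years = fy)
    for (cat in cats) {
      set(row, j = paste0(cat, "_raw"), value = raw[[cat]])
      set(row, j = paste0(cat, "_pppy"),
          value = annualize_pppy(raw[[cat]], w$window_days))
    }
    row
  }))
}

#' Apply the high-cost outlier exclusion
#'
#' Patients whose raw study-period total exceeds `threshold` (default
#' $4,000,000) are moved to the excluded list.
#'
#' @param patients output of [compute_patient_costs()].
#' @param threshold exclusion threshold on `total_raw`.
#' @return list with `kept` and `excluded` data.tables.
#' @export
apply_outlier_exclusion <- function(patients, threshold = 4e6) {
  patients <- as.data.table(patients)
  out <- patients$total_raw > threshold
  list(kept = patients[!out], excluded = patients[out])
}

#' Summarize PPPY costs by stratum
#'
#' Per-stratum descriptive statistics (n; mean; sample SD, n-1
#' denominator, `NA` for a single patient; median; 25th/75th percentiles
#' by linear interpolation) of each PPPY category. Empty strata are
#' emitted with `n = 0` and `NA` statistics.
#'
#' @param patients output of [compute_patient_costs()].
#' @param by character vector of stratum labels aligned with rows of
#'   `patients`.
#' @param strata optional character vector of stratum levels to emit
#'   (defaults to the observed labels).
#' @return data.table with `stratum`, `category`, `n`, `mean`, `sd`,
#'   `median`, `q25`, `q75`.
#' @export
summarize_costs <- function(patients, by,
                            strata = sort(unique(by))) {
  patients <- as.data.table(patients)
  stopifnot(length(by) == nrow(patients))
  cats <- sub("_pppy$", "", grep("_pppy$", names(patients), value = TRUE))
  out <- list()
  for (s in strata) {
    sub <- patients[by == s]
    for (cat in cats) {
      v <- sub[[paste0(cat, "_pppy")]]
      out[[length(out) + 1L]] <- data.table(
        stratum = s, category = cat, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else NA_real_,
        median = if (length(v)) median(v) else NA_real_,
        q25 = if (length(v)) unname(quantile(v, 0.25, type = 7))
              else NA_real_,
        q75 = if (length(v)) unname(quantile(v, 0.75, type = 7))
              else NA_real_)
    }
  }
  if (!length(out)) {
    return(data.table(stratum = character(), category = character(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      median = numeric(), q25 = numeric(),
                      q75 = numeric()))
  }
  rbindlist(out)
}
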