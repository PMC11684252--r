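#' Cohort selection configuration
#'
#' Inclusion criteria and window bounds for [select_cohort()]. Months are
#' interpreted as fixed day counts (3 months = 92 days, 6 months = 183
#' days) so the checks are deterministic; both are configurable. The
#' one-year follow-up cap is 365 days after the index date, with the
#' window inclusive of the index day (window length = end - index + 1).
#'
#' @param approval_date earliest qualifying index fill date.
#' @param data_start,data_end bounds of data availability.
#' @param sma_codes qualifying ICD-10-CM diagnosis codes.
#' @param post_days required continuous enrollment after index (days).
#' @param pre_days required continuous enrollment before index (days),
#'   applied only to `pre_required_types`.
#' @param pre_required_types SMA types subject to the pre-index
#'   enrollment requirement (infantile-onset type 1 is exempt).
#' @param allowable_gap_days enrollment gap still counted as continuous.
#' @param max_follow_days follow-up cap after index.
#' @param typing_rules rule table used for the type-dependent criterion;
#'   see [default_typing_rules()].
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(approval_date = as.Date("2020-08-07"),
                          data_start = as.Date("2020-01-01"),
                          data_end = as.Date("2022-06-30"),
                          sma_codes = c("G12.0", "G12.1", "G12.9"),
                          post_days = 183L, pre_days = 92L,
                          pre_required_types = c(2L, 3L, 4L),
                          allowable_gap_days = 0L,
                          max_follow_days = 365L,
                          typing_rules = default_typing_rules()) {
  structure(as.list(environment()), class = "cohort_config")
}

#' Assign the index date from a patient's pharmacy claims
#'
#' The index date is the earliest risdiplam fill on or after the approval
#' date; `NA` when no such fill exists.
#'
#' @param pharmacy pharmacy claims for one patient (`fill_date`, `drug`).
#' @param approval_date inclusive lower bound for a qualifying fill.
#' @return A `Date`, or `NA` if no qualifying fill.
#' @export
assign_index_date <- function(pharmacy,
                              approval_date = as.Date("2020-08-07")) {
  pharmacy <- as.data.table(pharmacy)
  fills <- pharmacy[drug == "risdiplam" & fill_date >= approval_date,
                    fill_date]
  if (!length(fills)) return(as.Date(NA))
  min(fills)
}

#' Check continuous enrollment around the index date
#'
#' `TRUE` iff, after normalization with the given allowable gap, a single
#' enrollment span covers `[index - pre_days, index + post_days]`.
#'
#' @param spans enrollment spans for one patient.
#' @param index_date the index date.
#' @param pre_days,post_days required coverage before/after index (days).
#' @param allowable_gap_days coverage gap still counted as continuous.
#' @return logical.
#' @export
check_enrollment <- function(spans, index_date, pre_days = 0L,
                             post_days = 183L, allowable_gap_days = 0L) {
  spans <- normalize_enrollment(as.data.table(spans), allowable_gap_days)
  if (!nrow(spans)) return(FALSE)
  lo <- index_date - pre_days
  hi <- index_date + post_days
  any(spans$start_date <= lo & spans$end_date >= hi)
}

#' Compute a patient's study window
#'
#' The window runs from the index date to the earliest of: end of the
#' continuous enrollment span containing the index, end of data
#' availability, and the follow-up cap. Ties are attributed in the order
#' `one_year_cap` > `data_end` > `enrollment_end`.
#'
#' @param index_date the index date.
#' @param spans the patient's enrollment spans.
#' @param data_end end of data availability.
#' @param max_follow_days follow-up cap (days after index).
#' @param allowable_gap_days enrollment gap still counted as continuous.
#' @return list with `index_date`, `end_date`, `end_reason`.
#' @export
compute_study_window <- function(index_date, spans,
                                 data_end = as.Date("2022-06-30"),
                                 max_follow_days = 365L,
                                 allowable_gap_days = 0L) {
  spans <- normalize_enrollment(as.data.table(spans), allowable_gap_days)
  cover <- spans[start_date <= index_date & end_date >= index_date]
  if (!nrow(cover)) {
    stop("index date not covered by any enrollment span", call. = FALSE)
  }
  enroll_end <- max(cover$end_date)
  cap <- index_date + max_follow_days
  end <- min(enroll_end, data_end, cap)
  reason <- if (end == cap) "one_year_cap"
            else if (end == data_end) "data_end"
            else "enrollment_end"
  list(index_date = index_date, end_date = end, end_reason = reason)
}

#' Apply the inclusion criteria and build the study cohort
#'
#' Applies, in order: (1) at least one qualifying SMA diagnosis code on a
#' medical claim inside the data window; (2) an assignable index date
#' (first risdiplam fill on/after approval); (3) continuous enrollment for
#' `post_days` after index; (4) for patients classified as SMA types 2-4,
#' continuous enrollment for `pre_days` before index (classification uses
#' the configured typing rule table; patients matching no rule are exempt,
#' mirroring the type-1 exemption). A selection log records the count
#' remaining after each criterion.
#'
#' @param bundle a [claims_bundle()].
#' @param config a [cohort_config()].
#' @return list with `windows` (data.table: `patient_id`, `index_date`,
#'   `end_date`, `end_reason`, `window_days`, `sma_type`) and `log`
#'   (data.table: `criterion`, `n_remaining`).
#' @export
select_cohort <- function(bundle, config = cohort_config()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  cfg <- config
  ids <- bundle$demographics$patient_id
  log_lab <- c("all_patients", "sma_diagnosis", "index_date_assignable",
               "post_index_enrollment", "pre_index_enrollment")
  log_n <- integer(5)
  log_n[1] <- length(ids)

  ## 1. qualifying SMA diagnosis inside the data window
  med <- bundle$medical[service_date >= cfg$data_start &
                          service_date <= cfg$data_end]
  has_dx <- unique(med[vapply(.split_tokens(dx_codes), function(v)
    any(v %in% cfg$sma_codes), logical(1)), patient_id])
  ids <- ids[ids %in% has_dx]
  log_n[2] <- length(ids)

  ## 2. index date assignable
  qualifying <- bundle$pharmacy[drug == "risdiplam" &
                                  fill_date >= cfg$approval_date]
  idx <- if (nrow(qualifying)) {
    qualifying[, .(index_date = min(fill_date)), by = patient_id]
  } else {
    data.table(patient_id = character(),
               index_date = as.Date(character()))
  }
  ids <- ids[ids %in% idx$patient_id]
  index_of <- setNames(idx$index_date, idx$patient_id)
  log_n[3] <- length(ids)

  ## 3. post-index continuous enrollment
  keep <- vapply(ids, function(pid) {
    check_enrollment(bundle$enrollment[patient_id == pid],
                     index_of[[pid]], pre_days = 0L,
                     post_days = cfg$post_days,
                     allowable_gap_days = cfg$allowable_gap_days)
  }, logical(1))
  ids <- ids[keep]
  log_n[4] <- length(ids)

  ## 4. classify survivors; pre-index enrollment for types 2-4
  types <- vapply(ids, function(pid) {
    feats <- extract_typing_features(bundle, pid, cfg$data_end,
                                     sma_codes = cfg$sma_codes)
    classify_sma_type(feats, cfg$typing_rules)$sma_type
  }, integer(1))
  keep <- vapply(seq_along(ids), function(k) {
    if (!types[k] %in% cfg$pre_required_types) return(TRUE)
    check_enrollment(bundle$enrollment[patient_id == ids[k]],
                     index_of[[ids[k]]], pre_days = cfg$pre_days,
                     post_days = 0L,
                     allowable_gap_days = cfg$allowable_gap_days)
  }, logical(1))
  ids <- ids[keep]
  types <- types[keep]
  log_n[5] <- length(ids)

  windows <- rbindlist(lapply(seq_along(ids), function(k) {
    w <- compute_study_window(index_of[[ids[k]]],
                              bundle$enrollment[patient_id == ids[k]],
                              data_end = cfg$data_end,
                              max_follow_days = cfg$max_follow_days,
                              allowable_gap_days = cfg$allowable_gap_days)
    data.table(patient_id = ids[k], index_date = w$index_date,
               end_date = w$end_date, end_reason = w$end_reason,
               window_days = as.integer(w$end_date - w$index_date) + 1L,
               sma_type = types[k])
  }))
  if (!length(ids)) {
    windows <- data.table(patient_id = character(),
                          index_date = as.Date(character()),
                          end_date = as.Date(character()),
                          end_reason = character(),
                          window_days = integer(), sma_type = integer())
  }
  list(windows = windows,
       log = data.table(criterion = log_lab, n_remaining = log_n))
}
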