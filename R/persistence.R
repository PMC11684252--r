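#' Detect treatment discontinuation for one patient
#'
#' Discontinuation is the earlier of (a) a refill gap: no risdiplam fill
#' within `gap_days` days after the previous days of supply (stacked with
#' carry-forward, as in the adherence engine) was exhausted — the event
#' is dated at the exhaustion day, and a gap of exactly `gap_days` days
#' is still allowable; and (b) a switch: the earliest nusinersen or
#' onasemnogene-abeparvovec claim after the index date, even if
#' risdiplam supply remains on hand. A trailing gap counts only when the
#' window extends more than `gap_days` days past the last exhaustion;
#' otherwise the patient is censored at the window end. Patients with
#' neither event are censored with `time_days` equal to the window
#' length. Time is measured in days from the index date.
#'
#' @param fills risdiplam fills for one patient (`fill_date`,
#'   `days_supply`).
#' @param switch_events data.frame with `date` and `reason`
#'   (`"switch_nusinersen"` / `"switch_onasemnogene"`), or `NULL`.
#' @param window list with `index_date`, `end_date`.
#' @param gap_days allowable refill gap (default 30).
#' @return list with `time_days`, `event`, `reason`.
#' @export
detect_discontinuation <- function(fills, switch_events = NULL, window,
                                   gap_days = 30L) {
  index <- as.Date(window$index_date)
  end <- as.Date(window$end_date)
  wl <- as.integer(end - index) + 1L

  fills <- as.data.table(fills)
  if (nrow(fills)) fills <- fills[fill_date >= index & fill_date <= end]
  setorder(fills, fill_date)

  ## stacked effective supply intervals, not truncated: exhaustion past
  ## the window end means still on treatment at the end (censored)
  gap_time <- NA_integer_
  if (nrow(fills)) {
    fd <- as.integer(fills$fill_date)
    prev_end <- as.integer(index) - 1L
    for (k in seq_len(nrow(fills))) {
      if (k > 1L && fd[k] - prev_end > gap_days) {
        gap_time <- prev_end - as.integer(index)
        break
      }
      s <- max(fd[k], prev_end + 1L)
      prev_end <- s + fills$days_supply[k] - 1L
    }
    if (is.na(gap_time) && prev_end < as.integer(end) &&
        as.integer(end) - prev_end > gap_days) {
      gap_time <- prev_end - as.integer(index)
    }
  } else {
    ## no fills at all inside the window: discontinued at the index day
    if (wl > gap_days) gap_time <- 0L
  }

  switch_time <- NA_integer_
  switch_reason <- NA_character_
  if (!is.null(switch_events) && nrow(as.data.table(switch_events))) {
    se <- as.data.table(switch_events)
    se <- se[se$date > index & se$date <= end]
    if (nrow(se)) {
      setorder(se, date)
      switch_time <- as.integer(se$date[1] - index)
      switch_reason <- se$reason[1]
    }
  }

  cand_t <- c(gap = gap_time, switch = switch_time)
  if (all(is.na(cand_t))) {
    return(list(time_days = wl, event = FALSE, reason = "censored"))
  }
  ## earlier candidate wins; exact ties attributed to the gap
  if (!is.na(gap_time) && (is.na(switch_time) || gap_time <= switch_time)) {
    list(time_days = gap_time, event = TRUE, reason = "gap")
  } else {
    list(time_days = switch_time, event = TRUE, reason = switch_reason)
  }
}

#' Persistence records for a cohort
#'
#' Runs [detect_discontinuation()] per patient, taking switch events from
#' medical claims flagged `dmt_nusinersen` / `dmt_onasemnogene`.
#'
#' @param bundle a [claims_bundle()].
#' @param windows the `windows` table from [select_cohort()].
#' @param gap_days allowable refill gap.
#' @return data.table with `patient_id`, `time_days`, `event`, `reason`.
#' @export
compute_persistence <- function(bundle, windows, gap_days = 30L) {
  if (!nrow(windows)) {
    return(data.table(patient_id = character(), time_days = integer(),
                      event = logical(), reason = character()))
  }
  med <- bundle$medical
  flag_lists <- .split_tokens(med$flags)
  has_nus <- vapply(flag_lists, function(v) "dmt_nusinersen" %in% v,
                    logical(1))
  has_oa <- vapply(flag_lists, function(v) "dmt_onasemnogene" %in% v,
                   logical(1))
  switches <- rbind(
    data.table(patient_id = med$patient_id[has_nus],
               date = med$service_date[has_nus],
               reason = "switch_nusinersen"),
    data.table(patient_id = med$patient_id[has_oa],
               date = med$service_date[has_oa],
               reason = "switch_onasemnogene"))
  rbindlist(lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k]
    rec <- detect_discontinuation(
      bundle$pharmacy[patient_id == w$patient_id & drug == "risdiplam"],
      switches[patient_id == w$patient_id], w, gap_days)
    data.table(patient_id = w$patient_id, time_days = rec$time_days,
               event = rec$event, reason = rec$reason)
  }))
}

#' Kaplan-Meier product-limit estimator
#'
#' From-scratch product-limit estimate: at each distinct observed time
#' `t_i`, with `n_i` subjects at risk (time >= t_i), `d_i` events and
#' `c_i` censorings, `S(t_i) = prod_{j<=i} (1 - d_j / n_j)`. Censorings
#' tied with events at the same time remain in that risk set (standard
#' convention: censored after events).
#'
#' @param records data.frame with `time_days` and logical `event`.
#' @return data.table of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(records) {
  records <- as.data.table(records)
  if (!nrow(records)) stop("no persistence records", call. = FALSE)
  t <- as.numeric(records$time_days)
  ev <- as.logical(records$event)
  times <- sort(unique(t))
  n <- length(t)
  d <- vapply(times, function(x) sum(t == x & ev), numeric(1))
  c_ <- vapply(times, function(x) sum(t == x & !ev), numeric(1))
  n_risk <- n - cumsum(c(0, (d + c_)[-length(times)]))
  surv <- cumprod(1 - d / n_risk)
  out <- data.table(time = times, n_risk = n_risk, n_event = d,
                    n_censor = c_, survival = surv)
  setattr(out, "class", c("km_curve", class(out)))
  out
}

#' Median survival time from a Kaplan-Meier curve
#'
#' Smallest observed time with `S(t) <= 0.5`; `NA` ("not reached") when
#' the curve never drops to 0.5.
#'
#' @param curve a [km_estimate()] result.
#' @return numeric, or `NA` if not reached.
#' @export
km_median <- function(curve) {
  hit <- which(curve$survival <= 0.5 + 1e-12)
  if (!length(hit)) return(NA_real_)
  curve$time[hit[1]]
}

#' Summarize persistence by stratum
#'
#' Per-stratum patient count, event count, discontinuation percentage and
#' Kaplan-Meier median time (reported `NA` = "not reached" when the curve
#' stays above 0.5).
#'
#' @param records persistence records ([compute_persistence()]).
#' @param by optional character vector of stratum labels aligned with
#'   `records` rows; `NULL` for a single overall stratum.
#' @return data.table with `stratum`, `n`, `n_event`, `pct_discontinued`,
#'   `median_time_days`.
#' @export
summarize_persistence <- function(records, by = NULL) {
  records <- as.data.table(records)
  if (is.null(by)) by <- rep("overall", nrow(records))
  stopifnot(length(by) == nrow(records))
  records <- copy(records)[, stratum := by]
  records[, {
    curve <- km_estimate(.SD)
    list(n = .N, n_event = sum(event),
         pct_discontinued = 100 * sum(event) / .N,
         median_time_days = km_median(curve))
  }, by = stratum][]
}
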