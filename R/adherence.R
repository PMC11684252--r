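#' Build a risdiplam coverage calendar for one patient
#'
#' Turns dated fills with days of supply into effective coverage
#' intervals inside the study window. With `carry_forward = TRUE` (the
#' default, the standard PDC convention) an early refill is banked: each
#' fill's effective start is `max(fill_date, previous effective end + 1)`
#' and its effective end is `effective start + days_supply - 1`. With
#' `carry_forward = FALSE` each fill covers `[fill_date, fill_date +
#' days_supply - 1]` and overlapping days count once (no banking). In
#' both variants supply extending beyond the window end is truncated
#' after stacking, and fills dated outside the window are ignored with a
#' warning.
#'
#' @param fills data.frame of risdiplam fills (`fill_date`,
#'   `days_supply`) for one patient.
#' @param window list or one-row data.frame with `index_date` and
#'   `end_date`.
#' @param carry_forward bank oversupply from early refills (default).
#' @return An object of class `coverage_calendar`: list with `window`,
#'   `intervals` (data.table `start`,`end`), `covered_days`,
#'   `window_days`.
#' @export
build_coverage <- function(fills, window, carry_forward = TRUE) {
  fills <- as.data.table(fills)
  index <- as.Date(window$index_date)
  end <- as.Date(window$end_date)
  stopifnot(index <= end)
  wl <- as.integer(end - index) + 1L

  if (nrow(fills)) {
    out <- fills$fill_date < index | fills$fill_date > end
    if (any(out)) {
      warning(sprintf("%d fill(s) outside the study window ignored",
                      sum(out)), call. = FALSE)
      fills <- fills[!out]
    }
  }
  setorder(fills, fill_date)

  if (!nrow(fills)) {
    cal <- list(window = list(index_date = index, end_date = end),
                intervals = data.table(start = as.Date(character()),
                                       end = as.Date(character())),
                covered_days = 0L, window_days = wl)
    class(cal) <- "coverage_calendar"
    return(cal)
  }

  if (carry_forward) {
    s <- e <- as.integer(rep(NA_integer_, nrow(fills)))
    prev_end <- as.integer(index) - 1L
    fd <- as.integer(fills$fill_date)
    for (k in seq_len(nrow(fills))) {
      s[k] <- max(fd[k], prev_end + 1L)
      e[k] <- s[k] + fills$days_supply[k] - 1L
      prev_end <- max(prev_end, e[k])
    }
    iv <- data.table(start = s, end = pmin(e, as.integer(end)))
    iv <- iv[start <= end]
    covered <- sum(iv$end - iv$start + 1L)
  } else {
    fd <- as.integer(fills$fill_date)
    iv <- data.table(start = fd,
                     end = pmin(fd + fills$days_supply - 1L,
                                as.integer(end)))
    setorder(iv, start)
    ## merge overlapping nominal intervals (each day counts once)
    ms <- iv$start[1]; me <- iv$end[1]; os <- integer(0); oe <- integer(0)
    if (nrow(iv) > 1L) for (k in 2L:nrow(iv)) {
      if (iv$start[k] <= me + 1L) me <- max(me, iv$end[k]) else {
        os <- c(os, ms); oe <- c(oe, me); ms <- iv$start[k]; me <- iv$end[k]
      }
    }
    iv <- data.table(start = c(os, ms), end = c(oe, me))
    covered <- sum(iv$end - iv$start + 1L)
  }
  cal <- list(window = list(index_date = index, end_date = end),
              intervals = data.table(
                start = as.Date(iv$start, origin = "1970-01-01"),
                end = as.Date(iv$end, origin = "1970-01-01")),
              covered_days = as.integer(covered), window_days = wl)
  class(cal) <- "coverage_calendar"
  cal
}

#' Proportion of days covered
#'
#' `covered_days / window_days`, the window length counted inclusively
#' (`end - index + 1`).
#'
#' @param calendar a [build_coverage()] result.
#' @return numeric in `[0, 1]`.
#' @export
compute_pdc <- function(calendar) {
  stopifnot(inherits(calendar, "coverage_calendar"))
  calendar$covered_days / calendar$window_days
}

#' Classify adherence status and PDC band
#'
#' Dichotomizes PDC at `threshold` (adherent iff PDC >= 0.80 by default)
#' and bins it into bands `lt_080` (< 0.80), `band_080_090`
#' (>= 0.80 and < 0.90) and `band_090_100` (>= 0.90, closed at 1).
#'
#' @param pdc numeric vector of PDC values in `[0, 1]`.
#' @param threshold adherence cutoff (default 0.80).
#' @param band_edges interior band edges (default `c(0.80, 0.90)`).
#' @return data.table with columns `pdc`, `adherent`, `band`.
#' @export
classify_adherence <- function(pdc, threshold = 0.80,
                               band_edges = c(0.80, 0.90)) {
  if (any(pdc < 0 | pdc > 1, na.rm = TRUE)) {
    stop("pdc must lie in [0, 1]", call. = FALSE)
  }
  band <- cut(pdc, breaks = c(-Inf, band_edges, 1),
              labels = c("lt_080", "band_080_090", "band_090_100"),
              right = FALSE)
  ## right = FALSE makes [0.9, 1) the top bin but excludes 1 itself;
  ## the +1 upper break plus this patch keeps pdc = 1 in band_090_100
  band[pdc == 1] <- "band_090_100"
  data.table(pdc = pdc, adherent = pdc >= threshold,
             band = as.character(band))
}

#' Assign an age group at the index date
#'
#' Age is completed years at index (exact day difference / 365.25,
#' floored). Two shipped presets mirror the two groupings used in SMA
#' adherence reporting: `"methods"` = 0-2, 3-5, 6-17, >= 18;
#' `"results"` = 0-2, 3-5, 6-12, 13-17, >= 18.
#'
#' @param birth_date,index_date dates; `birth_date <= index_date`.
#' @param bins `"methods"`, `"results"`, or a numeric vector of
#'   left-closed break points starting at 0 (e.g. `c(0, 3, 6, 18)`).
#' @return character vector of age-group labels.
#' @export
assign_age_group <- function(birth_date, index_date, bins = "results") {
  stopifnot(all(birth_date <= index_date))
  age <- floor(as.numeric(index_date - birth_date) / 365.25)
  edges <- if (identical(bins, "methods")) c(0, 3, 6, 18)
           else if (identical(bins, "results")) c(0, 3, 6, 13, 18)
           else as.numeric(bins)
  labels <- c(paste0(edges[-length(edges)], "-",
                     edges[-1] - 1), paste0(edges[length(edges)], "+"))
  idx <- findInterval(age, edges)
  labels[pmax(idx, 1L)]
}

#' Compute adherence results for a cohort
#'
#' Convenience wrapper running [build_coverage()], [compute_pdc()],
#' [classify_adherence()] and [assign_age_group()] per patient.
#'
#' @param bundle a [claims_bundle()].
#' @param windows the `windows` table from [select_cohort()].
#' @param carry_forward see [build_coverage()].
#' @param threshold,band_edges see [classify_adherence()].
#' @param bins see [assign_age_group()].
#' @return data.table with `patient_id`, `pdc`, `adherent`, `band`,
#'   `age_group`.
#' @export
compute_adherence <- function(bundle, windows, carry_forward = TRUE,
                              threshold = 0.80,
                              band_edges = c(0.80, 0.90),
                              bins = "results") {
  if (!nrow(windows)) {
    return(data.table(patient_id = character(), pdc = numeric(),
                      adherent = logical(), band = character(),
                      age_group = character()))
  }
  birth <- setNames(bundle$demographics$birth_date,
                    bundle$demographics$patient_id)
  out <- lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k]
    fills <- bundle$pharmacy[patient_id == w$patient_id &
                               drug == "risdiplam"]
    cal <- suppressWarnings(build_coverage(fills, w, carry_forward))
    p <- compute_pdc(cal)
    cls <- classify_adherence(p, threshold, band_edges)
    data.table(patient_id = w$patient_id, pdc = p,
               adherent = cls$adherent, band = cls$band,
               age_group = assign_age_group(birth[[w$patient_id]],
                                            w$index_date, bins))
  })
  rbindlist(out)
}
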