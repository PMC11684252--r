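#' Construct and validate a claims bundle
#'
#' A claims bundle is the pipeline's sole input: four tables shaped like a
#' minimal administrative-claims extract.
#'
#' * `enrollment`: `patient_id`, `start_date`, `end_date` — insurance
#'   coverage spans, inclusive on both ends.
#' * `medical`: `patient_id`, `service_date`, `dx_codes` (semicolon-joined
#'   ICD-10-CM), `proc_code`, `setting`
#'   (`inpatient`/`outpatient`/`emergency`/`other`), `allowed_cost`,
#'   `flags` (semicolon-joined subset of `mechanical_ventilation`,
#'   `nutritional_support`, `dme`, `dmt_nusinersen`, `dmt_onasemnogene`).
#' * `pharmacy`: `patient_id`, `fill_date`, `drug`
#'   (`risdiplam`/`other`), `days_supply`, `allowed_cost`.
#' * `demographics`: `patient_id`, `birth_date`, `sex`, `region`.
#'
#' Validation enforces the schema invariants: nonnegative costs,
#' `days_supply >= 1`, at most one DMT flag per claim, every patient seen
#' in a claim present in `demographics`, `birth_date` preceding all claim
#' dates. Enrollment spans are normalized on construction: exact duplicates
#' optionally dropped, day-adjacent spans (gap of 0 days) merged.
#'
#' @param enrollment,medical,pharmacy,demographics data.frames with the
#'   columns above (dates as `Date` or ISO-8601 strings).
#' @param dedupe drop exact duplicate rows in each claims table (claims
#'   extracts commonly carry multi-source duplicates). Default `TRUE`.
#' @return An object of class `claims_bundle`: a list of four data.tables.
#' @export
claims_bundle <- function(enrollment, medical, pharmacy, demographics,
                          dedupe = TRUE) {
  enrollment <- .coerce_table(enrollment,
    c("patient_id", "start_date", "end_date"), "enrollment")
  medical <- .coerce_table(medical,
    c("patient_id", "service_date", "dx_codes", "proc_code", "setting",
      "allowed_cost", "flags"), "medical_claims")
  pharmacy <- .coerce_table(pharmacy,
    c("patient_id", "fill_date", "drug", "days_supply", "allowed_cost"),
    "pharmacy_claims")
  demographics <- .coerce_table(demographics,
    c("patient_id", "birth_date", "sex", "region"), "demographics")

  for (col in c("start_date", "end_date")) {
    enrollment[[col]] <- .as_date_col(enrollment[[col]], col, "enrollment")
  }
  medical$service_date <- .as_date_col(medical$service_date,
                                       "service_date", "medical_claims")
  medical$allowed_cost <- as.numeric(medical$allowed_cost)
  pharmacy$fill_date <- .as_date_col(pharmacy$fill_date,
                                     "fill_date", "pharmacy_claims")
  pharmacy$days_supply <- as.integer(pharmacy$days_supply)
  pharmacy$allowed_cost <- as.numeric(pharmacy$allowed_cost)
  demographics$birth_date <- .as_date_col(demographics$birth_date,
                                          "birth_date", "demographics")

  if (dedupe) {
    enrollment <- unique(enrollment)
    medical <- unique(medical)
    pharmacy <- unique(pharmacy)
    demographics <- unique(demographics)
  }

  .validate_bundle_tables(enrollment, medical, pharmacy, demographics)
  enrollment <- normalize_enrollment(enrollment, allowable_gap_days = 0L)

  structure(list(enrollment = enrollment, medical = medical,
                 pharmacy = pharmacy, demographics = demographics),
            class = "claims_bundle")
}

.coerce_table <- function(x, cols, what) {
  if (!is.data.frame(x)) stop(sprintf("'%s' must be a data.frame", what),
                              call. = FALSE)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    stop(sprintf("schema error in %s: missing column(s) %s", what,
                 paste(sQuote(missing_cols), collapse = ", ")),
         call. = FALSE)
  }
  dt <- as.data.table(x)[, cols, with = FALSE]
  dt$patient_id <- as.character(dt$patient_id)
  for (col in intersect(c("dx_codes", "proc_code", "flags", "drug",
                          "setting", "sex", "region"), cols)) {
    dt[[col]] <- ifelse(is.na(dt[[col]]), "", as.character(dt[[col]]))
  }
  dt
}

.as_date_col <- function(x, column, what) {
  if (inherits(x, "Date")) return(x)
  .parse_dates(as.character(x), column, what)
}

.validate_bundle_tables <- function(enrollment, medical, pharmacy,
                                    demographics) {
  if (anyDuplicated(demographics$patient_id)) {
    stop("validation error: duplicate patient_id in demographics",
         call. = FALSE)
  }
  if (nrow(enrollment) && any(enrollment$start_date > enrollment$end_date)) {
    stop("validation error: enrollment start_date after end_date",
         call. = FALSE)
  }
  if (nrow(medical)) {
    if (any(medical$allowed_cost < 0)) {
      stop("validation error: negative allowed_cost in medical claims",
           call. = FALSE)
    }
    if (!all(medical$setting %in% .SETTINGS)) {
      stop(sprintf("validation error: setting must be one of %s",
                   paste(.SETTINGS, collapse = ", ")), call. = FALSE)
    }
    toks <- .split_tokens(medical$flags)
    bad <- !vapply(toks, function(v) all(v %in% .FLAGS), logical(1))
    if (any(bad)) {
      stop("validation error: unknown claim flag in medical claims",
           call. = FALSE)
    }
    ndmt <- vapply(toks, function(v) sum(v %in% .DMT_FLAGS), integer(1))
    if (any(ndmt > 1L)) {
      stop("validation error: more than one dmt_* flag on a claim",
           call. = FALSE)
    }
  }
  if (nrow(pharmacy)) {
    if (any(is.na(pharmacy$days_supply)) || any(pharmacy$days_supply < 1L)) {
      stop("validation error: days_supply must be >= 1", call. = FALSE)
    }
    if (any(pharmacy$allowed_cost < 0)) {
      stop("validation error: negative allowed_cost in pharmacy claims",
           call. = FALSE)
    }
    if (!all(pharmacy$drug %in% .DRUGS)) {
      stop("validation error: drug must be 'risdiplam' or 'other'",
           call. = FALSE)
    }
  }
  claim_pids <- unique(c(enrollment$patient_id, medical$patient_id,
                         pharmacy$patient_id))
  orphan <- setdiff(claim_pids, demographics$patient_id)
  if (length(orphan)) {
    stop(sprintf("validation error: patient(s) %s missing from demographics",
                 paste(utils::head(orphan, 5L), collapse = ", ")),
         call. = FALSE)
  }
  ## birth precedes every claim date
  if (nrow(demographics)) {
    birth <- setNames(demographics$birth_date, demographics$patient_id)
    chk <- function(pid, d) any(d < birth[pid], na.rm = TRUE)
    if ((nrow(medical) && chk(medical$patient_id, medical$service_date)) ||
        (nrow(pharmacy) && chk(pharmacy$patient_id, pharmacy$fill_date))) {
      stop("validation error: claim dated before patient birth_date",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Normalize enrollment spans
#'
#' Sorts spans per patient and merges spans whose inter-span gap does not
#' exceed `allowable_gap_days`; with the default 0, day-adjacent spans
#' (next start = previous end + 1) merge. Overlapping spans always merge.
#' Normalization is idempotent and independent of input row order.
#'
#' @param spans data.frame with `patient_id`, `start_date`, `end_date`.
#' @param allowable_gap_days largest permissible coverage gap, in days,
#'   that still counts as continuous.
#' @return data.table of merged spans sorted by patient and start date.
#' @export
normalize_enrollment <- function(spans, allowable_gap_days = 0L) {
  spans <- as.data.table(spans)
  if (!nrow(spans)) return(spans[])
  setorder(spans, patient_id, start_date, end_date)
  spans[, {
    s <- as.integer(start_date); e <- as.integer(end_date)
    ms <- s[1]; me <- e[1]; out_s <- integer(0); out_e <- integer(0)
    if (length(s) > 1L) for (k in 2L:length(s)) {
      if (s[k] <= me + 1L + allowable_gap_days) {
        me <- max(me, e[k])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[k]; me <- e[k]
      }
    }
    out_s <- c(out_s, ms); out_e <- c(out_e, me)
    list(start_date = as.Date(out_s, origin = "1970-01-01"),
         end_date = as.Date(out_e, origin = "1970-01-01"))
  }, by = patient_id][]
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  patients:        %d\n", nrow(x$demographics)))
  cat(sprintf("  enrollment spans:%5d\n", nrow(x$enrollment)))
  cat(sprintf("  medical claims:  %5d\n", nrow(x$medical)))
  cat(sprintf("  pharmacy claims: %5d\n", nrow(x$pharmacy)))
  invisible(x)
}
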