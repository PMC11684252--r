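#' Default SMA typing rule table
#'
#' Claims-based SMA type classification runs on an ordered rule table:
#' each rule names a target type, a half-open age-at-first-diagnosis
#' interval `[age_dx_lo, age_dx_hi)` in years, an optional minimum age at
#' the end of observed clinical activity (`age_end_min`), a set of
#' required markers (any-of; semicolon-joined) and a set of excluded
#' markers. The first rule, in priority order, whose conditions all hold
#' determines the type.
#'
#' The table shipped here is a NON-AUTHORITATIVE default: published
#' claims-based algorithms for SMA typing rest on proprietary code lists
#' that are not redistributable, so this table encodes only the broad
#' clinical structure — infantile diagnosis with mechanical ventilation
#' maps to type 1; early-childhood diagnosis (or infantile diagnosis
#' without ventilator dependence) to type 2; childhood diagnosis to type
#' 3; adult diagnosis to type 4. Replace it with a locally validated
#' table via [read_typing_rules()] for substantive use.
#'
#' @return data.table with columns `rule_id`, `priority`, `type`,
#'   `age_dx_lo`, `age_dx_hi`, `age_end_min`, `require_markers`,
#'   `exclude_markers`.
#' @export
default_typing_rules <- function() {
  data.table(
    rule_id = c("T1_infant_ventilated", "T2_early_supported",
                "T2_toddler_onset", "T2_infant_no_vent",
                "T3_childhood_onset", "T4_adult_onset"),
    priority = 1:6,
    type = c(1L, 2L, 2L, 2L, 3L, 4L),
    age_dx_lo = c(0, 0, 1, 0, 3, 18),
    age_dx_hi = c(1, 3, 3, 1, 18, 200),
    age_end_min = NA_real_,
    require_markers = c("mechanical_ventilation",
                        "nutritional_support;dme;scoliosis",
                        "", "", "", ""),
    exclude_markers = c("", "", "", "mechanical_ventilation", "", ""))
}

#' Read a typing rule table from a delimited file
#'
#' One rule per row with the columns documented in
#' [default_typing_rules()]; rows are sorted by `priority`.
#'
#' @param path CSV file path.
#' @return data.table rule table.
#' @export
read_typing_rules <- function(path) {
  rules <- fread(path, na.strings = c("NA", ""),
                 colClasses = list(character = c("rule_id",
                                                 "require_markers",
                                                 "exclude_markers")))
  need <- c("rule_id", "priority", "type", "age_dx_lo", "age_dx_hi",
            "age_end_min", "require_markers", "exclude_markers")
  missing_cols <- setdiff(need, names(rules))
  if (length(missing_cols)) {
    stop(sprintf("rule table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("require_markers", "exclude_markers")) {
    rules[[col]] <- ifelse(is.na(rules[[col]]), "", rules[[col]])
  }
  for (col in c("age_dx_lo", "age_dx_hi", "age_end_min")) {
    rules[[col]] <- as.numeric(rules[[col]])
  }
  setorder(rules, priority)[]
}

#' Default map from diagnosis-code prefixes to typing markers
#'
#' Diagnosis-derived severity markers supplement the claim flags; the
#' default maps idiopathic-scoliosis codes (M41*) to the `scoliosis`
#' marker. Stand-in values — replace with validated code lists.
#'
#' @return data.table with columns `dx_prefix`, `marker`.
#' @export
default_marker_dx_map <- function() {
  data.table(dx_prefix = "M41", marker = "scoliosis")
}

#' Extract typing features for one patient
#'
#' Computes age at first qualifying SMA diagnosis, age at the end of
#' observed clinical activity (the later of the last claim date and the
#' enrollment end, capped at data availability), and the set of severity
#' markers observed on any claim (claim flags other than DMT flags, plus
#' diagnosis-derived markers via `marker_dx_map`). Ages are exact day
#' differences divided by 365.25.
#'
#' @param bundle a [claims_bundle()].
#' @param patient_id the patient.
#' @param data_end end of data availability (caps the age-at-end date).
#' @param sma_codes qualifying diagnosis codes.
#' @param marker_dx_map see [default_marker_dx_map()].
#' @return list with `patient_id`, `age_first_dx`, `age_end`, `markers`.
#' @export
extract_typing_features <- function(bundle, patient_id,
                                    data_end = as.Date("2022-06-30"),
                                    sma_codes = c("G12.0", "G12.1",
                                                  "G12.9"),
                                    marker_dx_map =
                                      default_marker_dx_map()) {
  pid <- patient_id
  demo <- bundle$demographics[bundle$demographics$patient_id == pid]
  if (!nrow(demo) || is.na(demo$birth_date)) {
    stop(sprintf("missing birth_date for patient %s", pid), call. = FALSE)
  }
  birth <- demo$birth_date
  med <- bundle$medical[bundle$medical$patient_id == pid]
  dx_lists <- .split_tokens(med$dx_codes)
  is_sma <- vapply(dx_lists, function(v) any(v %in% sma_codes), logical(1))
  if (!any(is_sma)) {
    stop(sprintf("patient %s has no qualifying SMA diagnosis claim", pid),
         call. = FALSE)
  }
  first_dx <- min(med$service_date[is_sma])

  last_claim <- suppressWarnings(max(
    c(med$service_date,
      bundle$pharmacy[bundle$pharmacy$patient_id == pid, fill_date])))
  enr <- bundle$enrollment[bundle$enrollment$patient_id == pid]
  enroll_end <- if (nrow(enr)) max(enr$end_date) else as.Date(NA)
  end_date <- min(max(last_claim, enroll_end, na.rm = TRUE), data_end)

  markers <- setdiff(unique(unlist(.split_tokens(med$flags))), .DMT_FLAGS)
  if (nrow(marker_dx_map)) {
    all_dx <- unique(unlist(dx_lists))
    for (k in seq_len(nrow(marker_dx_map))) {
      if (any(startsWith(all_dx, marker_dx_map$dx_prefix[k]))) {
        markers <- union(markers, marker_dx_map$marker[k])
      }
    }
  }
  list(patient_id = pid,
       age_first_dx = as.numeric(first_dx - birth) / 365.25,
       age_end = as.numeric(end_date - birth) / 365.25,
       markers = markers)
}

#' Classify one patient's SMA type from extracted features
#'
#' Walks the rule table in priority order; the first rule whose age
#' interval contains `age_first_dx`, whose `age_end_min` floor (if any)
#' is met, whose required-marker set (any-of) intersects the observed
#' markers, and none of whose excluded markers are present, fires. A pure
#' function of (features, rules): claims order never matters.
#'
#' @param features output of [extract_typing_features()].
#' @param rules a rule table (see [default_typing_rules()]).
#' @return list with `patient_id`, `sma_type` (integer 1-4, or
#'   `NA_integer_` when no rule fires), `rule_id`, `evidence` (markers).
#' @export
classify_sma_type <- function(features, rules = default_typing_rules()) {
  rules <- as.data.table(rules)
  if (!nrow(rules)) stop("empty typing rule table", call. = FALSE)
  setorder(rules, priority)
  for (k in seq_len(nrow(rules))) {
    r <- rules[k]
    if (features$age_first_dx < r$age_dx_lo ||
        features$age_first_dx >= r$age_dx_hi) next
    if (!is.na(r$age_end_min) && features$age_end < r$age_end_min) next
    req <- .split_tokens(r$require_markers)[[1]]
    if (length(req) && !any(req %in% features$markers)) next
    exc <- .split_tokens(r$exclude_markers)[[1]]
    if (length(exc) && any(exc %in% features$markers)) next
    return(list(patient_id = features$patient_id,
                sma_type = as.integer(r$type), rule_id = r$rule_id,
                evidence = features$markers))
  }
  list(patient_id = features$patient_id, sma_type = NA_integer_,
       rule_id = NA_character_, evidence = features$markers)
}
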