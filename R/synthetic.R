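#' Simulation configuration for the synthetic claims generator
#'
#' Builds the validated parameter list consumed by [generate_claims()].
#' Defaults describe a plausible commercially-insured SMA cohort initiating
#' oral disease-modifying therapy: the type mix, prior-nusinersen share,
#' switch-back share and single gene-therapy exposure follow the published
#' cohort composition for this population (1/18/47/20 across types 1-4 of
#' 86 patients; 42/86 with prior nusinersen, 9 of those switching back);
#' refill behavior is a 30-day supply cycle with a per-type probability of
#' a late refill and exponentially distributed extra gap days; a small
#' per-refill stopping probability (0.02, giving roughly one patient in
#' five stopping within a year of 30-day cycles) drives discontinuation.
#' Cost amounts are log-normal per service category, with ventilation and
#' nutritional-support claims attached only to severe types (1-2, rarely 3),
#' so type-4 strata show zero medians in those categories.
#'
#' @param n_patients number of intended-includable patients.
#' @param seed integer root seed; per-patient substreams are derived by an
#'   integer hash of (seed, patient index).
#' @param type_mix probability vector over SMA types 1-4 (sums to 1).
#' @param refill_days days of supply per dispensing.
#' @param adherence_profile per-type list with `gap_prob` (probability a
#'   refill is late) and `mean_gap_days` (mean extra gap when late).
#' @param stop_prob per-refill probability of permanently stopping therapy.
#' @param prior_nusinersen_prob,switchback_prob,oa_prob regimen-history
#'   probabilities (switchback conditional on prior nusinersen).
#' @param decoy_fracs named fractions (of `n_patients`) of decoy patients
#'   violating, respectively, the diagnosis, index-date and post-index
#'   enrollment inclusion criteria.
#' @param cost_model per-category log-normal parameters and event rates
#'   (annual rates; `prob` elements are per-type probabilities).
#' @param comorbidity_probs per-group, per-type prevalence of comorbidity
#'   diagnosis claims during follow-up.
#' @param enrollment_model pre-/post-index enrollment span lengths (days).
#' @param calendar_start,data_end data window bounds.
#' @param approval_date first date a qualifying index fill can occur.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_patients = 86L,
    seed = 20200807L,
    type_mix = c(`1` = 1, `2` = 18, `3` = 47, `4` = 20) / 86,
    refill_days = 30L,
    adherence_profile = list(
      `1` = list(gap_prob = 0.05, mean_gap_days = 8),
      `2` = list(gap_prob = 0.12, mean_gap_days = 10),
      `3` = list(gap_prob = 0.15, mean_gap_days = 12),
      `4` = list(gap_prob = 0.20, mean_gap_days = 14)),
    stop_prob = 0.015,
    prior_nusinersen_prob = 42 / 86,
    switchback_prob = 9 / 42,
    oa_prob = 1 / 86,
    decoy_fracs = c(no_sma_dx = 0.10, pre_approval_fills = 0.10,
                    short_enrollment = 0.10),
    cost_model = list(
      outpatient = list(rate = 6, meanlog = 6.2, sdlog = 1.0),
      inpatient = list(prob = c(`1` = 0.8, `2` = 0.5, `3` = 0.25,
                                `4` = 0.15), meanlog = 9.2, sdlog = 0.8),
      emergency = list(rate = 0.5, meanlog = 7.0, sdlog = 0.7),
      other = list(rate = 2, meanlog = 5.5, sdlog = 1.0),
      ventilation = list(prob = c(`1` = 1.0, `2` = 0.45, `3` = 0.10,
                                  `4` = 0), rate = 3, meanlog = 7.5,
                         sdlog = 1.0),
      nutrition = list(prob = c(`1` = 0.9, `2` = 0.45, `3` = 0.15,
                                `4` = 0.02), rate = 3, meanlog = 6.5,
                       sdlog = 1.0),
      pharmacy = list(rate = 4, meanlog = 4.5, sdlog = 1.0),
      risdiplam = list(meanlog = log(28000), sdlog = 0.05),
      dmt = list(meanlog = log(125000), sdlog = 0.1)),
    comorbidity_probs = list(
      scoliosis = c(1, 0.72, 0.70, 0),
      dyspnea_respiratory = c(1, 0.44, 0.45, 0.05),
      muscle_weakness = c(0, 0.67, 0.26, 0.25),
      chronic_respiratory_failure = c(1, 0.44, 0.32, 0.05),
      feeding_difficulties = c(0, 0.44, 0.19, 0.05),
      neurodevelopmental = c(1, 0.39, 0.15, 0.05),
      elimination = c(0, 0.11, 0.15, 0.05),
      anxiety = c(0, 0, 0.09, 0.25),
      depressive = c(0, 0, 0.06, 0.25)),
    enrollment_model = list(pre_extra_max = 300L, post_extra_mean = 200),
    calendar_start = as.Date("2020-01-01"),
    data_end = as.Date("2022-06-30"),
    approval_date = as.Date("2020-08-07")) {
  cfg <- as.list(environment())
  if (cfg$n_patients < 0) stop("config error: n_patients must be >= 0",
                               call. = FALSE)
  if (abs(sum(cfg$type_mix) - 1) > 1e-9 || any(cfg$type_mix < 0)) {
    stop("config error: type_mix must be a probability vector summing to 1",
         call. = FALSE)
  }
  probs <- c(cfg$stop_prob, cfg$prior_nusinersen_prob, cfg$switchback_prob,
             cfg$oa_prob, cfg$decoy_fracs,
             vapply(cfg$adherence_profile, `[[`, numeric(1), "gap_prob"))
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(vapply(cfg$adherence_profile, `[[`, numeric(1),
                 "mean_gap_days") <= 0)) {
    stop("config error: mean_gap_days must be positive", call. = FALSE)
  }
  if (cfg$refill_days < 1) stop("config error: refill_days must be >= 1",
                                call. = FALSE)
  structure(cfg, class = "sim_config")
}

## comorbidity group -> representative ICD-10-CM code used when emitting
## synthetic diagnosis claims; prefixes match default_comorbidity_map()
.COMORBIDITY_CODES <- c(
  scoliosis = "M41.9", dyspnea_respiratory = "R06.0",
  muscle_weakness = "M62.81", chronic_respiratory_failure = "J96.10",
  feeding_difficulties = "R63.3", neurodevelopmental = "F88",
  elimination = "F98.0", anxiety = "F41.9", depressive = "F32.9")

#' Generate a synthetic claims bundle with ground truth
#'
#' Emits a [claims_bundle()] plus a ground-truth object recording, per
#' patient, the true SMA type, index date, study window, refill schedule,
#' switch events and per-category cost totals inside the window. Intended
#' cohort patients satisfy every inclusion criterion by construction; decoy
#' patients (fractions set by `decoy_fracs`) each violate exactly one
#' criterion (no qualifying SMA diagnosis code; pre-approval fills only;
#' under six months of post-index enrollment) so the selection funnel can
#' be audited exactly.
#'
#' Generation is deterministic for a fixed seed: each patient's draws come
#' from a substream seeded by a hash of (seed, patient index).
#'
#' @param config a [sim_config()].
#' @return list with elements `bundle` (a `claims_bundle`) and `truth`
#'   (list: `patients` one row per patient, `fills` the true risdiplam
#'   refill schedule, identical to the emitted risdiplam pharmacy claims).
#' @export
generate_claims <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$n_patients)
  n_decoy <- vapply(config$decoy_fracs,
                    function(f) as.integer(round(f * n)), integer(1))
  roles <- c(rep("cohort", n),
             rep(names(n_decoy), n_decoy))
  total <- length(roles)
  if (total == 0L) {
    empty <- .empty_bundle()
    return(list(bundle = empty, truth = .empty_truth()))
  }
  parts <- vector("list", total)
  for (i in seq_len(total)) {
    parts[[i]] <- .gen_patient(i, roles[i], config)
  }
  bundle <- claims_bundle(
    rbindlist(lapply(parts, `[[`, "enroll")),
    rbindlist(lapply(parts, `[[`, "medical")),
    rbindlist(lapply(parts, `[[`, "pharmacy")),
    rbindlist(lapply(parts, `[[`, "demo")))
  truth_patients <- rbindlist(lapply(parts, `[[`, "truth"))
  fills <- bundle$pharmacy[drug == "risdiplam",
                           .(patient_id, fill_date, days_supply)]
  list(bundle = bundle,
       truth = list(patients = truth_patients, fills = fills))
}

.empty_bundle <- function() {
  claims_bundle(
    data.frame(patient_id = character(), start_date = character(),
               end_date = character()),
    data.frame(patient_id = character(), service_date = character(),
               dx_codes = character(), proc_code = character(),
               setting = character(), allowed_cost = numeric(),
               flags = character()),
    data.frame(patient_id = character(), fill_date = character(),
               drug = character(), days_supply = integer(),
               allowed_cost = numeric()),
    data.frame(patient_id = character(), birth_date = character(),
               sex = character(), region = character()))
}

.empty_truth <- function() {
  list(patients = data.table(patient_id = character(), role = character(),
                             true_type = integer()),
       fills = data.table(patient_id = character(),
                          fill_date = as.Date(character()),
                          days_supply = integer()))
}

## single-patient generation inside its own seeded substream
.gen_patient <- function(i, role, cfg) {
  set.seed(.substream(cfg$seed, i))
  pid <- sprintf("P%04d", i)
  approval <- cfg$approval_date
  data_end <- cfg$data_end

  type <- sample.int(4L, 1L, prob = cfg$type_mix)
  dx_age <- switch(type, runif(1, 0.1, 0.9), runif(1, 1.05, 2.9),
                   runif(1, 3.1, 17.5), runif(1, 18.5, 55))
  sma_code <- c("G12.0", "G12.1", "G12.9", "G12.9")[type]

  ## index uniformly over dates that still allow >= 183 days of follow-up
  max_index_off <- as.integer(data_end - 183L - approval)
  index <- approval + sample.int(max_index_off + 1L, 1L) - 1L
  first_dx <- max(index - sample(30:365, 1L), cfg$calendar_start)
  birth <- first_dx - as.integer(round(dx_age * 365.25))
  sex <- sample(c("F", "M"), 1L,
                prob = if (type == 1) c(0.4, 0.6) else c(0.57, 0.43))
  region <- sample(c("South", "Midwest", "West", "Northeast"), 1L,
                   prob = c(0.40, 0.30, 0.16, 0.14))

  enroll_start <- min(first_dx, index - 92L) -
    sample.int(cfg$enrollment_model$pre_extra_max, 1L)
  post_extra <- rgeom(1L, 1 / (1 + cfg$enrollment_model$post_extra_mean))
  enroll_end <- min(data_end, index + 183L + post_extra)
  if (role == "short_enrollment") {
    enroll_end <- index + sample(30:120, 1L)
  }
  window_end <- min(enroll_end, data_end, index + 365L)
  wl <- as.integer(window_end - index) + 1L

  ## regimen history
  prior_nus <- runif(1) < cfg$prior_nusinersen_prob
  oa <- prior_nus && runif(1) < cfg$oa_prob
  switchback <- prior_nus && runif(1) < cfg$switchback_prob && wl >= 150L
  switch_date <- if (switchback) {
    index + sample(60:min(330L, wl - 2L), 1L)
  } else as.Date(NA)

  ## risdiplam refill schedule: 30-day cycles, late-refill gaps,
  ## per-refill stopping hazard, truncated at any switch
  prof <- cfg$adherence_profile[[as.character(type)]]
  ds <- as.integer(cfg$refill_days)
  fill_off <- integer(0)
  t <- 0L
  fill_cap <- as.integer(min(enroll_end, data_end) - index)
  repeat {
    if (t > fill_cap) break
    if (switchback && index + t >= switch_date) break
    fill_off <- c(fill_off, t)
    if (runif(1) < cfg$stop_prob) break
    gap <- if (runif(1) < prof$gap_prob) {
      as.integer(round(rexp(1, 1 / prof$mean_gap_days)))
    } else 0L
    t <- t + ds + gap
  }
  ## stop_prob break leaves t equal to the last appended fill offset
  stopped <- length(fill_off) > 0 && t == fill_off[length(fill_off)]
  if (role == "pre_approval_fills") {
    ## fills exist but all predate approval; no index date assignable
    anchor <- approval - sample(150:220, 1L)
    fill_off <- NULL
    fill_dates <- anchor + c(0L, 30L, 60L)
    fill_dates <- fill_dates[fill_dates >= enroll_start]
  } else {
    fill_dates <- index + fill_off
  }
  pharmacy <- data.table(
    patient_id = pid, fill_date = fill_dates, drug = "risdiplam",
    days_supply = ds,
    allowed_cost = round(rlnorm(length(fill_dates),
                                cfg$cost_model$risdiplam$meanlog,
                                cfg$cost_model$risdiplam$sdlog), 2))

  ## other-drug pharmacy fills
  n_rx <- rpois(1L, cfg$cost_model$pharmacy$rate * wl / 365.25)
  if (n_rx > 0) {
    pharmacy <- rbind(pharmacy, data.table(
      patient_id = pid,
      fill_date = index + sample.int(wl, n_rx, replace = TRUE) - 1L,
      drug = "other", days_supply = 30L,
      allowed_cost = round(rlnorm(n_rx, cfg$cost_model$pharmacy$meanlog,
                                  cfg$cost_model$pharmacy$sdlog), 2)))
  }

  med <- list()
  mk <- function(date, dx = "", proc = "", setting = "outpatient",
                 cost = 0, flags = "") {
    data.table(patient_id = pid, service_date = date, dx_codes = dx,
               proc_code = proc, setting = setting,
               allowed_cost = round(cost, 2), flags = flags)
  }
  ## SMA diagnosis claims (decoy 'no_sma_dx' carries a non-qualifying code)
  dxc <- if (role == "no_sma_dx") "G12.8" else sma_code
  n_dx <- sample(2:4, 1L)
  dx_dates <- c(first_dx,
                first_dx + sample.int(max(1L, as.integer(window_end -
                  first_dx)), n_dx - 1L, replace = TRUE))
  med[[length(med) + 1L]] <- mk(dx_dates, dx = dxc,
                                cost = rlnorm(n_dx, 5, 0.5))

  ## severity-marker claims with costs (ventilation / nutrition / DME)
  cm <- cfg$cost_model
  if (runif(1) < cm$ventilation$prob[type]) {
    nv <- 1L + rpois(1L, cm$ventilation$rate * wl / 365.25)
    med[[length(med) + 1L]] <- mk(
      index + sample.int(wl, nv, replace = TRUE) - 1L,
      proc = "VENT", setting = "other",
      cost = rlnorm(nv, cm$ventilation$meanlog, cm$ventilation$sdlog),
      flags = "mechanical_ventilation")
  }
  if (runif(1) < cm$nutrition$prob[type]) {
    nn <- 1L + rpois(1L, cm$nutrition$rate * wl / 365.25)
    med[[length(med) + 1L]] <- mk(
      index + sample.int(wl, nn, replace = TRUE) - 1L,
      proc = "NUTR", setting = "other",
      cost = rlnorm(nn, cm$nutrition$meanlog, cm$nutrition$sdlog),
      flags = "nutritional_support")
  }
  if (type %in% 2:3 && runif(1) < 0.5) {
    med[[length(med) + 1L]] <- mk(
      index + sample.int(wl, 1L) - 1L, proc = "DME", setting = "other",
      cost = rlnorm(1, cm$other$meanlog, cm$other$sdlog), flags = "dme")
  }

  ## comorbidity diagnosis claims during follow-up
  for (grp in names(cfg$comorbidity_probs)) {
    if (runif(1) < cfg$comorbidity_probs[[grp]][type]) {
      med[[length(med) + 1L]] <- mk(
        index + sample.int(wl, 1L) - 1L, dx = .COMORBIDITY_CODES[[grp]],
        cost = rlnorm(1, 5.5, 0.5))
    }
  }

  ## setting-level utilization
  n_op <- rpois(1L, cm$outpatient$rate * wl / 365.25)
  if (n_op > 0) med[[length(med) + 1L]] <- mk(
    index + sample.int(wl, n_op, replace = TRUE) - 1L,
    setting = "outpatient",
    cost = rlnorm(n_op, cm$outpatient$meanlog, cm$outpatient$sdlog))
  if (runif(1) < cm$inpatient$prob[type]) med[[length(med) + 1L]] <- mk(
    index + sample.int(wl, 1L) - 1L, setting = "inpatient",
    cost = rlnorm(1, cm$inpatient$meanlog, cm$inpatient$sdlog))
  n_ed <- rpois(1L, cm$emergency$rate * wl / 365.25)
  if (n_ed > 0) med[[length(med) + 1L]] <- mk(
    index + sample.int(wl, n_ed, replace = TRUE) - 1L,
    setting = "emergency",
    cost = rlnorm(n_ed, cm$emergency$meanlog, cm$emergency$sdlog))
  n_ot <- rpois(1L, cm$other$rate * wl / 365.25)
  if (n_ot > 0) med[[length(med) + 1L]] <- mk(
    index + sample.int(wl, n_ot, replace = TRUE) - 1L,
    setting = "other",
    cost = rlnorm(n_ot, cm$other$meanlog, cm$other$sdlog))
  ## a couple of pre-index outpatient claims exercise window filtering
  if (first_dx < index - 1L && runif(1) < 0.7) {
    pre_n <- sample(1:2, 1L)
    med[[length(med) + 1L]] <- mk(
      first_dx + sample.int(as.integer(index - first_dx), pre_n,
                            replace = TRUE) - 1L,
      setting = "outpatient",
      cost = rlnorm(pre_n, cm$outpatient$meanlog, cm$outpatient$sdlog))
  }

  ## DMT administration claims (always cost-excluded downstream)
  oa_date <- as.Date(NA)
  if (prior_nus) {
    span <- max(1L, as.integer(index - first_dx))
    nus_dates <- first_dx + sort(sample.int(span, min(2L, span))) - 1L
    med[[length(med) + 1L]] <- mk(
      nus_dates, proc = "J2326", setting = "outpatient",
      cost = rlnorm(length(nus_dates), cm$dmt$meanlog, cm$dmt$sdlog),
      flags = "dmt_nusinersen")
    if (oa) {
      oa_date <- first_dx + sample.int(span, 1L) - 1L
      med[[length(med) + 1L]] <- mk(
        oa_date, proc = "J3399", setting = "inpatient",
        cost = rlnorm(1, log(2.1e6), 0.02), flags = "dmt_onasemnogene")
    }
  }
  if (switchback) {
    med[[length(med) + 1L]] <- mk(
      switch_date, proc = "J2326", setting = "outpatient",
      cost = rlnorm(1, cm$dmt$meanlog, cm$dmt$sdlog),
      flags = "dmt_nusinersen")
  }

  medical <- rbindlist(med)

  ## ground-truth cost totals inside the study window, DMT excluded
  truth_costs <- .true_costs(medical, pharmacy, index, window_end)
  covered <- if (role == "pre_approval_fills") NA_integer_ else {
    .stock_covered_days(as.integer(fill_dates - index),
                        rep(ds, length(fill_dates)), wl)
  }
  truth <- data.table(
    patient_id = pid, role = role, true_type = type,
    birth_date = birth,
    index_date = if (role == "pre_approval_fills") as.Date(NA) else index,
    enroll_start = enroll_start, enroll_end = enroll_end,
    window_end = if (role %in% c("cohort")) window_end else as.Date(NA),
    window_days = if (role == "cohort") wl else NA_integer_,
    n_fills = length(fill_dates),
    true_covered_days = if (role == "cohort") covered else NA_integer_,
    true_pdc = if (role == "cohort") covered / wl else NA_real_,
    true_adherent = if (role == "cohort") covered / wl >= 0.80 else NA,
    stopped = stopped, prior_nusinersen = prior_nus,
    switch_date = switch_date, oa_date = oa_date, perturbed = FALSE)
  truth <- cbind(truth, truth_costs)

  list(
    enroll = data.table(patient_id = pid, start_date = enroll_start,
                        end_date = enroll_end),
    medical = medical, pharmacy = pharmacy,
    demo = data.table(patient_id = pid, birth_date = birth, sex = sex,
                      region = region),
    truth = truth)
}

## generator-side daily pill-stock simulation (oversupply banked,
## truncated at the window end); defines "true" coverage in the truth
.stock_covered_days <- function(offsets, ds, wl) {
  if (wl < 1L) return(0L)
  supply_on <- numeric(wl)
  keep <- offsets >= 0L & offsets < wl
  offsets <- offsets[keep]; ds <- ds[keep]
  for (j in seq_along(offsets)) {
    supply_on[offsets[j] + 1L] <- supply_on[offsets[j] + 1L] + ds[j]
  }
  stock <- 0; covered <- 0L
  for (d in seq_len(wl)) {
    stock <- stock + supply_on[d]
    if (stock > 0) { covered <- covered + 1L; stock <- stock - 1 }
  }
  covered
}

.true_costs <- function(medical, pharmacy, index, window_end) {
  inwin <- medical[service_date >= index & service_date <= window_end]
  flags <- .split_tokens(inwin$flags)
  is_dmt <- vapply(flags, function(v) any(v %in% .DMT_FLAGS), logical(1))
  inwin <- inwin[!is_dmt]
  flags <- flags[!is_dmt]
  bysetting <- function(s) sum(inwin$allowed_cost[inwin$setting == s])
  vent <- sum(inwin$allowed_cost[vapply(flags, function(v)
    "mechanical_ventilation" %in% v, logical(1))])
  nutr <- sum(inwin$allowed_cost[vapply(flags, function(v)
    "nutritional_support" %in% v, logical(1))])
  rx <- pharmacy[drug == "other" & fill_date >= index &
                   fill_date <= window_end, sum(allowed_cost)]
  med_total <- sum(inwin$allowed_cost)
  data.table(
    cost_inpatient = bysetting("inpatient"),
    cost_outpatient = bysetting("outpatient"),
    cost_emergency = bysetting("emergency"),
    cost_other_medical = bysetting("other"),
    cost_ventilation = vent, cost_nutrition = nutr,
    cost_medical_total = med_total, cost_pharmacy = rx,
    cost_total = med_total + rx)
}

#' Perturb a synthetic bundle toward nonadherence
#'
#' Selects each intended cohort patient independently with probability
#' `fraction` (seeded) and trims their risdiplam refill schedule so total
#' dispensed supply is at most 75% of the study window, forcing true PDC
#' below the 0.80 adherence threshold. Ground truth is updated to match.
#'
#' @param bundle,truth output of [generate_claims()].
#' @param fraction probability each cohort patient is perturbed.
#' @param seed integer seed for the selection and trimming.
#' @return list with updated `bundle` and `truth`.
#' @export
perturb_to_nonadherent <- function(bundle, truth, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0 || !nrow(truth$patients)) {
    return(list(bundle = bundle, truth = truth))
  }
  set.seed(.substream(seed, 0L))
  pts <- copy(truth$patients)
  cohort_ids <- pts[role == "cohort", patient_id]
  hit <- cohort_ids[runif(length(cohort_ids)) < fraction]
  if (!length(hit)) return(list(bundle = bundle, truth = truth))

  pharmacy <- copy(bundle$pharmacy)
  for (pid in hit) {
    row <- pts[patient_id == pid]
    wl <- row$window_days
    cap <- max(1L, as.integer(floor(0.75 * wl)))
    idx <- which(pharmacy$patient_id == pid & pharmacy$drug == "risdiplam")
    idx <- idx[order(pharmacy$fill_date[idx])]
    ds <- pharmacy$days_supply[idx]
    keep <- cumsum(as.numeric(ds)) <= cap
    keep[1L] <- TRUE
    drop_idx <- idx[!keep]
    idx <- idx[keep]
    if (pharmacy$days_supply[idx[1L]] > cap) {
      pharmacy$days_supply[idx[1L]] <- cap
    }
    if (length(drop_idx)) pharmacy <- pharmacy[-drop_idx]
    offs <- as.integer(pharmacy$fill_date[pharmacy$patient_id == pid &
                                            pharmacy$drug == "risdiplam"] -
                         row$index_date)
    dss <- pharmacy$days_supply[pharmacy$patient_id == pid &
                                  pharmacy$drug == "risdiplam"]
    covered <- .stock_covered_days(offs, dss, wl)
    pts[patient_id == pid, `:=`(
      n_fills = length(offs), true_covered_days = covered,
      true_pdc = covered / wl, true_adherent = covered / wl >= 0.80,
      perturbed = TRUE)]
  }
  new_bundle <- claims_bundle(bundle$enrollment, bundle$medical,
                              pharmacy, bundle$demographics)
  fills <- new_bundle$pharmacy[drug == "risdiplam",
                               .(patient_id, fill_date, days_supply)]
  list(bundle = new_bundle, truth = list(patients = pts, fills = fills))
}
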