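## fixture builders: all test data is constructed in code

mk_demo <- function(pid, birth = "2000-01-01", sex = "F",
                    region = "South") {
  data.frame(patient_id = pid, birth_date = birth, sex = sex,
             region = region)
}

mk_enroll <- function(pid, start, end) {
  data.frame(patient_id = pid, start_date = start, end_date = end)
}

mk_med <- function(pid, date, dx = "", proc = "", setting = "outpatient",
                   cost = 0, flags = "") {
  data.frame(patient_id = pid, service_date = as.Date(date),
             dx_codes = dx, proc_code = proc, setting = setting,
             allowed_cost = cost, flags = flags)
}

mk_rx <- function(pid, date, drug = "risdiplam", ds = 30L, cost = 100) {
  data.frame(patient_id = pid, fill_date = as.Date(date), drug = drug,
             days_supply = ds, allowed_cost = cost)
}

## a minimal single-patient bundle centred on an index fill
one_patient_bundle <- function(pid = "P1", birth = "2010-01-01",
                               enroll_start = "2020-01-01",
                               enroll_end = "2022-06-30",
                               dx_date = "2020-06-01", dx = "G12.1",
                               fill_dates = "2020-09-01", ds = 30L,
                               extra_medical = NULL,
                               extra_pharmacy = NULL) {
  med <- mk_med(pid, dx_date, dx = dx)
  if (!is.null(extra_medical)) med <- rbind(med, extra_medical)
  rx <- do.call(rbind, lapply(fill_dates, function(d)
    mk_rx(pid, d, ds = ds)))
  if (!is.null(extra_pharmacy)) rx <- rbind(rx, extra_pharmacy)
  claims_bundle(mk_enroll(pid, enroll_start, enroll_end), med, rx,
                mk_demo(pid, birth = birth))
}

## small deterministic sim config for pipeline-level tests
quiet_sim <- function(n = 40, seed = 42, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

## no-gap, no-stop, no-switch, no-decoy config: every patient's PDC is 1
perfect_sim <- function(n, seed, stop_prob = 0, ...) {
  prof <- list(gap_prob = 0, mean_gap_days = 1)
  sim_config(
    n_patients = n, seed = seed,
    adherence_profile = list(`1` = prof, `2` = prof, `3` = prof,
                             `4` = prof),
    stop_prob = stop_prob, switchback_prob = 0, oa_prob = 0,
    decoy_fracs = c(no_sma_dx = 0, pre_approval_fills = 0,
                    short_enrollment = 0), ...)
}
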