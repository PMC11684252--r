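cwin <- function(index = "2021-01-01", end = "2021-12-31") {
  list(index_date = as.Date(index), end_date = as.Date(end))
}

test_that("inflation is the index ratio, with named-year errors", {
  ix <- inflation_index(c(`2021` = 100, `2023` = 105),
                        reference_year = 2023)
  expect_equal(inflate(1000, 2021, ix), 1050)
  expect_equal(inflate(0, 2021, ix), 0)
  flat <- inflation_index(c(`2021` = 1, `2023` = 1))
  expect_equal(inflate(123.45, 2021, flat), 123.45)
  expect_error(inflate(1, 2019, ix), "2019")
  expect_error(inflation_index(c(`2020` = 100), reference_year = 2023),
               "reference year")
})

test_that("risdiplam and DMT-flagged claims contribute zero everywhere", {
  b <- one_patient_bundle(
    birth = "2000-01-01", fill_dates = "2021-02-01",
    extra_medical = mk_med("P1", "2021-03-01", setting = "inpatient",
                           cost = 5e5, flags = "dmt_nusinersen"))
  ## bump risdiplam fill cost
  b$pharmacy[b$pharmacy$drug == "risdiplam", "allowed_cost"] <- 30000
  cc <- categorize_costs(b, cwin(), "P1")
  expect_equal(cc$total, 0)
  expect_equal(cc$pharmacy, 0)
  expect_equal(cc$inpatient, 0)
})

test_that("setting buckets and ventilation/nutrition overlays", {
  extra <- rbind(
    mk_med("P1", "2021-03-01", setting = "inpatient", cost = 1000,
           flags = "mechanical_ventilation"),
    mk_med("P1", "2021-04-01", setting = "outpatient", cost = 200),
    mk_med("P1", "2021-05-01", setting = "emergency", cost = 300),
    mk_med("P1", "2021-06-01", setting = "other", cost = 400,
           flags = "nutritional_support"),
    mk_med("P1", "2020-06-15", setting = "inpatient", cost = 9999))
  b <- one_patient_bundle(
    birth = "2000-01-01", dx_date = "2020-06-01",
    extra_medical = extra,
    extra_pharmacy = mk_rx("P1", "2021-07-01", drug = "other",
                           cost = 55))
  cc <- categorize_costs(b, cwin(), "P1")
  expect_equal(cc$inpatient, 1000)       # window excludes the 2020 claim
  expect_equal(cc$outpatient, 200)
  expect_equal(cc$emergency, 300)
  expect_equal(cc$other_medical, 400)
  expect_equal(cc$ventilation, 1000)     # overlay, double-counted
  expect_equal(cc$nutrition, 400)
  expect_equal(cc$medical_total, 1900)
  expect_equal(cc$pharmacy, 55)
  expect_equal(cc$total, 1955)
})

test_that("no claims in window means all-zero categories", {
  b <- one_patient_bundle(birth = "2000-01-01")
  cc <- categorize_costs(b, cwin("2022-01-01", "2022-06-30"), "P1")
  expect_true(all(unlist(cc) == 0))
})

test_that("PPPY annualization divides by years of follow-up", {
  expect_equal(annualize_pppy(10000, 365.25), 10000)
  expect_equal(annualize_pppy(10000, 365.25 / 2), 20000)
  expect_equal(annualize_pppy(0, 200), 0)
})

test_that("outlier exclusion is a strict threshold on raw total", {
  pts <- data.table::data.table(patient_id = c("a", "b", "c"),
                                total_raw = c(4e6, 4e6 + 1, 10))
  split <- apply_outlier_exclusion(pts)
  expect_identical(split$excluded$patient_id, "b")
  expect_identical(nrow(apply_outlier_exclusion(pts,
                                                Inf)$excluded), 0L)
})

test_that("cost summaries use sample SD and interpolated quartiles", {
  pts <- data.table::data.table(patient_id = c("a", "b", "c"),
                                total_pppy = c(1, 2, 3))
  s <- summarize_costs(pts, by = rep("g", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$median, 2)
  expect_equal(s$q25, 1.5)
  expect_equal(s$q75, 2.5)

  one <- summarize_costs(pts[1], by = "g")
  expect_equal(one$mean, one$median)
  expect_true(is.na(one$sd))

  empty <- summarize_costs(pts, by = rep("g", 3), strata = c("g", "h"))
  expect_identical(empty[empty$stratum == "h", ]$n, 0L)
})

test_that("categories conserve and pipeline equals ground truth", {
  sim <- generate_claims(quiet_sim(n = 30, seed = 41))
  cohort <- select_cohort(sim$bundle)
  flat <- inflation_index(c(`2020` = 1, `2021` = 1, `2022` = 1,
                            `2023` = 1))
  costs <- compute_patient_costs(sim$bundle, cohort$windows, flat)
  expect_equal(costs$inpatient_raw + costs$outpatient_raw +
                 costs$emergency_raw + costs$other_medical_raw,
               costs$medical_total_raw, tolerance = 1e-6)
  expect_equal(costs$medical_total_raw + costs$pharmacy_raw,
               costs$total_raw, tolerance = 1e-6)

  tr <- merge(costs, sim$truth$patients, by = "patient_id")
  expect_equal(tr$total_raw, tr$cost_total, tolerance = 1e-9)
  expect_equal(tr$ventilation_raw, tr$cost_ventilation,
               tolerance = 1e-9)
  expect_equal(tr$total_pppy,
               tr$cost_total / (tr$window_days / 365.25),
               tolerance = 1e-9)
})

test_that("adding DMT-flagged claims changes no reported number", {
  sim <- generate_claims(quiet_sim(n = 10, seed = 43))
  cohort <- select_cohort(sim$bundle)
  costs0 <- compute_patient_costs(sim$bundle, cohort$windows)

  w <- cohort$windows[1, ]
  spiked <- claims_bundle(
    sim$bundle$enrollment,
    rbind(sim$bundle$medical,
          mk_med(w$patient_id, as.character(w$index_date + 10),
                 setting = "inpatient", cost = 9.9e9,
                 flags = "dmt_onasemnogene")),
    sim$bundle$pharmacy, sim$bundle$demographics)
  costs1 <- compute_patient_costs(spiked, cohort$windows)
  expect_equal(costs0, costs1)
})
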