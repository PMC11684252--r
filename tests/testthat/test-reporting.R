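test_that("regimen classes follow DMT claim dates around index", {
  idx <- as.Date("2020-10-01")
  mono <- one_patient_bundle(fill_dates = "2020-10-01")
  expect_identical(classify_regimen(mono, "P1", idx),
                   "risdiplam_monotherapy")

  prior <- one_patient_bundle(
    fill_dates = "2020-10-01",
    extra_medical = mk_med("P1", "2020-05-01", cost = 1e5,
                           flags = "dmt_nusinersen"))
  expect_identical(classify_regimen(prior, "P1", idx),
                   "prior_nusinersen")

  back <- one_patient_bundle(
    fill_dates = "2020-10-01",
    extra_medical = rbind(
      mk_med("P1", "2020-05-01", cost = 1e5, flags = "dmt_nusinersen"),
      mk_med("P1", "2021-02-01", cost = 1e5, flags = "dmt_nusinersen")))
  expect_identical(classify_regimen(back, "P1", idx),
                   "prior_nusinersen_switchback")

  both <- one_patient_bundle(
    fill_dates = "2020-10-01",
    extra_medical = rbind(
      mk_med("P1", "2020-04-01", cost = 1e5, flags = "dmt_nusinersen"),
      mk_med("P1", "2020-06-01", cost = 2e6,
             flags = "dmt_onasemnogene")))
  expect_identical(classify_regimen(both, "P1", idx),
                   "post_nusinersen_and_onasemnogene")
})

test_that("regimen classification only sees the patient's own claims", {
  ## regression: another patient's DMT claims must not leak in
  b <- claims_bundle(
    rbind(mk_enroll("P1", "2020-01-01", "2022-06-30"),
          mk_enroll("P2", "2020-01-01", "2022-06-30")),
    rbind(mk_med("P1", "2020-06-01", dx = "G12.9"),
          mk_med("P2", "2020-06-01", dx = "G12.9"),
          mk_med("P2", "2020-05-01", cost = 1e5,
                 flags = "dmt_nusinersen")),
    rbind(mk_rx("P1", "2020-10-01"), mk_rx("P2", "2020-10-01")),
    rbind(mk_demo("P1"), mk_demo("P2")))
  idx <- as.Date("2020-10-01")
  expect_identical(classify_regimen(b, "P1", idx),
                   "risdiplam_monotherapy")
  expect_identical(classify_regimen(b, "P2", idx), "prior_nusinersen")
})

test_that("regimen classes agree with generator truth", {
  sim <- generate_claims(quiet_sim(n = 40, seed = 57))
  cohort <- select_cohort(sim$bundle)
  tr <- sim$truth$patients
  for (k in seq_len(nrow(cohort$windows))) {
    w <- cohort$windows[k, ]
    got <- classify_regimen(sim$bundle, w$patient_id, w$index_date)
    row <- tr[tr$patient_id == w$patient_id, ]
    want <- if (!row$prior_nusinersen) "risdiplam_monotherapy"
            else if (!is.na(row$oa_date)) "post_nusinersen_and_onasemnogene"
            else if (!is.na(row$switch_date)) "prior_nusinersen_switchback"
            else "prior_nusinersen"
    expect_identical(got, want, info = w$patient_id)
  }
})

test_that("pipeline smoke: all report files written with headers", {
  d <- withr::local_tempdir()
  res <- run_pipeline(simulate = quiet_sim(n = 20, seed = 51),
                      out_dir = d)
  for (fn in c("table1.csv", "table2.csv", "table3.csv", "km_curve.csv",
               "pdc_band_costs.csv", "regimens.csv", "patients.csv",
               "selection_log.csv", "manifest.json")) {
    expect_true(file.exists(file.path(d, fn)), info = fn)
  }
  t2 <- read.csv(file.path(d, "table2.csv"))
  ## adherent% + nonadherent% = 100 in every stratum
  expect_equal(t2$pct_adherent + t2$pct_nonadherent,
               rep(100, nrow(t2)))
  ## stratum n's partition the cohort
  n_cohort <- t2$n[t2$stratum == "overall"]
  expect_equal(sum(t2$n[grepl("^type_", t2$stratum)]), n_cohort)
  expect_equal(sum(t2$n[grepl("^age_", t2$stratum)]), n_cohort)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_identical(man$package, "smaclaims")
})

test_that("a zero-patient cohort still writes header-only tables", {
  d <- withr::local_tempdir()
  b <- one_patient_bundle(dx = "G12.8")  # excluded at step 1
  dir.create(file.path(d, "in"))
  write_bundle(b, file.path(d, "in"))
  res <- run_pipeline(bundle_dir = file.path(d, "in"),
                      out_dir = file.path(d, "out"))
  expect_identical(nrow(res$cohort$windows), 0L)
  km <- read.csv(file.path(d, "out", "km_curve.csv"))
  expect_identical(nrow(km), 0L)
})

test_that("comorbidity prevalence counts the study window only", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  base <- quiet_sim(n = 15, seed = 53)
  res1 <- run_pipeline(simulate = base, out_dir = d1)

  ## spike a pre-index scoliosis claim (outside the study window) on a
  ## type 3/4 patient, whose typing is marker-insensitive, and re-report
  w <- res1$cohort$windows[res1$cohort$windows$sma_type >= 3, ][1, ]
  spiked <- claims_bundle(
    res1$bundle$enrollment,
    rbind(res1$bundle$medical,
          mk_med(w$patient_id, as.character(w$index_date - 1),
                 dx = "M41.9", cost = 1)),
    res1$bundle$pharmacy, res1$bundle$demographics)
  bdir <- file.path(d2, "in")
  write_bundle(spiked, bdir)
  res2 <- run_pipeline(bundle_dir = bdir, out_dir = file.path(d2, "out"))
  t1a <- read.csv(file.path(d1, "table1.csv"))
  t1b <- read.csv(file.path(d2, "out", "table1.csv"))
  expect_equal(t1a$scoliosis, t1b$scoliosis)
})

test_that("the CLI dispatches simulate and run", {
  d <- withr::local_tempdir()
  expect_message(
    claims_cli(c("simulate", "--out", file.path(d, "b"), "--seed", "3",
                 "--n", "10")),
    "synthetic bundle")
  expect_true(file.exists(file.path(d, "b", "pharmacy_claims.csv")))
  expect_message(
    claims_cli(c("run", "--bundle", file.path(d, "b"), "--out",
                 file.path(d, "r"))),
    "report written")
  expect_true(file.exists(file.path(d, "r", "table2.csv")))
  expect_error(claims_cli(c("nope")), "unknown subcommand")
})
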