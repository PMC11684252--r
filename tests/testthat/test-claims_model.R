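test_that("header-only files read to an empty bundle", {
  d <- withr::local_tempdir()
  writeLines("patient_id,start_date,end_date",
             file.path(d, "enrollment.csv"))
  writeLines("patient_id,service_date,dx_codes,proc_code,setting,allowed_cost,flags",
             file.path(d, "medical_claims.csv"))
  writeLines("patient_id,fill_date,drug,days_supply,allowed_cost",
             file.path(d, "pharmacy_claims.csv"))
  writeLines("patient_id,birth_date,sex,region",
             file.path(d, "demographics.csv"))
  b <- read_bundle(d)
  expect_s3_class(b, "claims_bundle")
  expect_identical(nrow(b$demographics), 0L)
  expect_identical(nrow(b$pharmacy), 0L)
})

test_that("pharmacy rows are preserved on read", {
  d <- withr::local_tempdir()
  b0 <- claims_bundle(
    mk_enroll("A", "2020-01-01", "2021-12-31"),
    mk_med("A", "2020-06-01", dx = "G12.9"),
    do.call(rbind, lapply(c("2020-09-01", "2020-10-01", "2020-11-01"),
                          function(x) mk_rx("A", x))),
    mk_demo("A"))
  write_bundle(b0, d)
  b <- read_bundle(d)
  expect_identical(nrow(b$pharmacy), 3L)
})

test_that("day-adjacent enrollment spans merge; distant spans do not", {
  spans <- rbind(mk_enroll("A", "2020-01-01", "2020-06-30"),
                 mk_enroll("A", "2020-07-01", "2020-12-31"))
  spans$start_date <- as.Date(spans$start_date)
  spans$end_date <- as.Date(spans$end_date)
  m <- normalize_enrollment(spans)
  expect_identical(nrow(m), 1L)
  expect_equal(m$start_date, as.Date("2020-01-01"))
  expect_equal(m$end_date, as.Date("2020-12-31"))

  spans$start_date[2] <- as.Date("2020-07-02")  # 1-day gap
  expect_identical(nrow(normalize_enrollment(spans)), 2L)
  expect_identical(nrow(normalize_enrollment(spans,
                                             allowable_gap_days = 1L)), 1L)
})

test_that("normalization is idempotent and order-independent", {
  set.seed(3)
  spans <- data.frame(
    patient_id = "A",
    start_date = as.Date("2020-01-01") + sample(0:400, 12),
    end_date = as.Date(NA))
  spans$end_date <- spans$start_date + sample(5:60, 12, replace = TRUE)
  n1 <- normalize_enrollment(spans)
  expect_identical(n1, normalize_enrollment(n1))
  shuffled <- spans[sample(nrow(spans)), ]
  expect_identical(n1, normalize_enrollment(shuffled))
})

test_that("round trip read(write(b)) is record-equal, incl. non-ASCII ids", {
  b0 <- claims_bundle(
    mk_enroll(c("Ä-1", "p2"), c("2020-01-01", "2020-02-01"),
              c("2021-12-31", "2021-06-30")),
    rbind(mk_med("Ä-1", "2020-06-01", dx = "G12.0;M41.9", cost = 12.5,
                 flags = "mechanical_ventilation"),
          mk_med("p2", "2020-07-01", dx = "G12.9", setting = "inpatient",
                 cost = 999.99)),
    rbind(mk_rx("Ä-1", "2020-09-01"), mk_rx("p2", "2020-10-01",
                                            drug = "other")),
    rbind(mk_demo("Ä-1"), mk_demo("p2", sex = "M", region = "West")))
  d <- withr::local_tempdir()
  write_bundle(b0, d)
  b1 <- read_bundle(d)
  for (tb in c("enrollment", "medical", "pharmacy", "demographics")) {
    expect_equal(as.data.frame(b1[[tb]]), as.data.frame(b0[[tb]]),
                 info = tb)
  }
  expect_true("Ä-1" %in% b1$demographics$patient_id)
})

test_that("schema and validation errors are specific", {
  d <- withr::local_tempdir()
  b0 <- one_patient_bundle()
  write_bundle(b0, d)

  ## missing column
  enr <- read.csv(file.path(d, "enrollment.csv"))
  write.csv(enr[, c("patient_id", "start_date")],
            file.path(d, "enrollment.csv"), row.names = FALSE)
  expect_error(read_bundle(d), "end_date")
  write_bundle(b0, d)

  ## unparseable date with row context
  rx <- read.csv(file.path(d, "pharmacy_claims.csv"))
  rx$fill_date[1] <- "09/01/2020"
  write.csv(rx, file.path(d, "pharmacy_claims.csv"), row.names = FALSE)
  expect_error(read_bundle(d), "fill_date.*row", perl = TRUE)
  write_bundle(b0, d)

  ## invariant violations
  expect_error(claims_bundle(b0$enrollment, b0$medical,
                             mk_rx("P1", "2020-09-01", ds = 0L),
                             b0$demographics), "days_supply")
  expect_error(claims_bundle(b0$enrollment,
                             mk_med("P1", "2020-06-01", cost = -1),
                             b0$pharmacy, b0$demographics),
               "negative allowed_cost")
  expect_error(claims_bundle(b0$enrollment, b0$medical, b0$pharmacy,
                             mk_demo("OTHER")), "missing from demographics")
  expect_error(
    claims_bundle(b0$enrollment,
                  mk_med("P1", "2020-06-01",
                         flags = "dmt_nusinersen;dmt_onasemnogene"),
                  b0$pharmacy, b0$demographics),
    "dmt")
})

test_that("exact-duplicate claims are dropped only when dedupe is on", {
  med <- rbind(mk_med("P1", "2020-06-01", dx = "G12.1", cost = 5),
               mk_med("P1", "2020-06-01", dx = "G12.1", cost = 5))
  b_on <- claims_bundle(mk_enroll("P1", "2020-01-01", "2021-12-31"), med,
                        mk_rx("P1", "2020-09-01"), mk_demo("P1"))
  b_off <- claims_bundle(mk_enroll("P1", "2020-01-01", "2021-12-31"), med,
                         mk_rx("P1", "2020-09-01"), mk_demo("P1"),
                         dedupe = FALSE)
  expect_identical(nrow(b_on$medical), 1L)
  expect_identical(nrow(b_off$medical), 2L)
})

test_that("a flag map derives DMT flags from procedure codes at read", {
  d <- withr::local_tempdir()
  b0 <- one_patient_bundle(
    extra_medical = mk_med("P1", "2020-05-01", proc = "J2326",
                           cost = 120000))
  write_bundle(b0, d)
  fm <- data.frame(code = "J2326", flag = "dmt_nusinersen")
  b <- read_bundle(d, flag_map = fm)
  expect_true(any(grepl("dmt_nusinersen", b$medical$flags)))
})
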