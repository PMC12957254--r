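test_that("dedup keeps the latest report per caseid and is idempotent", {
  demo <- tiny_dataset()$demo
  out <- dedup_cases(demo)
  expect_equal(sort(out$primaryid), c("102", "103"))   # 20240301 beats 20240101
  expect_equal(nrow(dedup_cases(out)), nrow(out))      # idempotent
  expect_equal(as.data.frame(dedup_cases(out)[order(caseid)]),
               as.data.frame(out[order(caseid)]), ignore_attr = TRUE)

  # order independence: same survivors under any row order
  set.seed(1)
  shuffled <- demo[sample(nrow(demo))]
  expect_setequal(dedup_cases(shuffled)$primaryid, out$primaryid)

  # tie on fda_dt -> largest primaryid survives
  tie <- data.table::data.table(primaryid = c("5", "9"), caseid = "C9",
                                fda_dt = "20240101")
  expect_equal(dedup_cases(tie)$primaryid, "9")

  # missing caseid rows are excluded and counted
  withmiss <- data.table::data.table(primaryid = c("1", "2"),
                                     caseid = c("C1", NA),
                                     fda_dt = c("20240101", "20240101"))
  res <- dedup_cases(withmiss)
  expect_equal(nrow(res), 1L)
  expect_equal(attr(res, "n_dropped_missing_caseid"), 1L)

  # three distinct caseids all survive
  three <- data.table::data.table(primaryid = c("1", "2", "3"),
                                  caseid = c("A", "B", "C"),
                                  fda_dt = "20240101")
  expect_equal(nrow(dedup_cases(three)), 3L)
})

test_that("standardize_drug maps keywords case/punctuation-insensitively", {
  expect_equal(standardize_drug("SKYRIZI 150MG/ML"), "risankizumab")
  expect_equal(standardize_drug("tremfya"), "guselkumab")
  expect_equal(standardize_drug("ABBV-066"), "risankizumab")
  expect_equal(standardize_drug("abbv066 injection"), "risankizumab")
  expect_true(is.na(standardize_drug("adalimumab")))
  # prod_ai match suffices
  expect_equal(standardize_drug("unknown brand", "RISANKIZUMAB"),
               "risankizumab")
})

test_that("normalize_age converts units and rejects implausible values", {
  expect_equal(normalize_age(6, "DEC"), 60)
  expect_equal(normalize_age(12, "MON"), normalize_age(1, "YR"))
  expect_equal(normalize_age(365.25, "DY"), 1)
  expect_equal(normalize_age(52.14, "WK"), 1)
  expect_equal(normalize_age(8766, "HR"), 1)
  expect_true(is.na(normalize_age(150, "YR")))
  expect_true(is.na(normalize_age(-3, "YR")))
  expect_true(is.na(normalize_age(5, "XX")))
  # missing unit code with plausible value reads as years
  expect_equal(normalize_age(40, NA), 40)
})

test_that("classify_outcomes flags the severe subset only", {
  expect_true(classify_outcomes("HO")$serious)
  expect_true(classify_outcomes(c("OT", "DE"))$serious)
  expect_false(classify_outcomes("OT")$serious)
  expect_false(classify_outcomes(character())$serious)
  expect_setequal(classify_outcomes(c("DE", "LT"))$outcomes,
                  c("death", "life-threatening"))
  # unknown code retained verbatim
  expect_true("ZZ" %in% classify_outcomes(c("ZZ", "HO"))$outcomes)
})

test_that("build_records applies the primary-suspect rule and uniqueness", {
  ds <- dedup_dataset(tiny_dataset())
  rec <- build_records(ds)
  # report 102: SKYRIZI PS with PTs {pruritus, fall} -> 2 records
  expect_equal(sort(rec$pt[rec$primaryid == "102" &
                             rec$drug == "risankizumab"]),
               c("fall", "pruritus"))
  # concomitant-only target drug contributes no records when ps_only
  ds2 <- tiny_dataset()
  ds2$drug$role_cod <- c("C", "C", "C", "PS")
  rec2 <- build_records(dedup_dataset(ds2))
  expect_false(any(rec2$drug == "risankizumab"))
  # duplicated PT within one report collapses to one record
  ds3 <- tiny_dataset()
  ds3$reac <- rbind(ds3$reac, data.table::data.table(primaryid = "102",
                                                     pt = "pruritus",
                                                     quarter = "24Q1"))
  rec3 <- build_records(dedup_dataset(ds3))
  expect_equal(sum(rec3$primaryid == "102" & rec3$pt == "pruritus" &
                     rec3$drug == "risankizumab"), 1L)
  # report with target drug but no REAC rows contributes zero, logged
  ds4 <- tiny_dataset()
  ds4$reac <- ds4$reac[ds4$reac$primaryid != "103"]
  rec4 <- build_records(dedup_dataset(ds4))
  expect_false(any(rec4$drug == "guselkumab"))
  expect_equal(attr(rec4, "n_reports_no_reac"), 1L)
})

test_that("record margins are conserved", {
  env <- shared_synth()
  rec <- env$records
  per_drug <- table(rec$drug[rec$is_target])
  for (d in names(per_drug)) {
    pair_counts <- table(rec$pt[rec$drug == d])
    expect_equal(sum(pair_counts), unname(per_drug[[d]]))
  }
  expect_equal(sum(table(rec$drug)), nrow(rec))
})

test_that("demographic_summary reproduces constructed proportions", {
  n <- 100L
  demo <- data.table::data.table(
    primaryid = as.character(seq_len(n)),
    caseid = paste0("C", seq_len(n)),
    fda_dt = "20240101", event_dt = "",
    age = NA_real_, age_cod = "",
    sex = rep(c("F", "M"), c(60L, 40L)),
    occp_cod = "CN", reporter_country = "US")
  # ages with a known median/IQR by construction: 1..99 plus one NA
  demo$age[seq_len(99L)] <- seq_len(99L)
  demo$age_cod[seq_len(99L)] <- "YR"
  drug <- data.table::data.table(primaryid = demo$primaryid, drug_seq = "1",
                                 role_cod = "PS", drugname = "SKYRIZI",
                                 prod_ai = "RISANKIZUMAB")
  reac <- data.table::data.table(primaryid = demo$primaryid, pt = "pruritus")
  ds <- dedup_dataset(faers_data(list(demo = demo, drug = drug,
                                      reac = reac)))
  reports <- build_case_reports(ds)
  records <- build_records(ds)
  summ <- demographic_summary(reports, records)
  sex <- summ[summ$section == "sex"]
  expect_equal(sex$pct[sex$level == "female"], 60)
  expect_equal(sex$pct[sex$level == "male"], 40)
  med <- summ[summ$section == "age" & summ$level == "median_iqr"]
  expect_equal(med$n, 50)        # median of 1..99
  expect_equal(med$q1, 25.5)
  expect_equal(med$q3, 74.5)
  # all-missing ages -> 100% unknown band
  demo2 <- data.table::copy(demo)
  demo2$age <- NA_real_
  ds2 <- dedup_dataset(faers_data(list(demo = demo2, drug = drug,
                                       reac = reac)))
  summ2 <- demographic_summary(build_case_reports(ds2), build_records(ds2))
  band <- summ2[summ2$section == "age_band"]
  expect_equal(band$pct[band$level == "unknown"], 100)
})

test_that("indication and concomitant tables rank by case count", {
  ds <- dedup_dataset(tiny_dataset())
  rec <- build_records(ds)
  res <- indication_concomitant_summary(ds, rec)
  ind_r <- res$indications[res$indications$drug == "risankizumab"]
  expect_equal(ind_r$indication, "psoriasis")
  expect_equal(ind_r$pct, 100)   # 1/1 surviving risankizumab report
  con_r <- res$concomitant[res$concomitant$drug == "risankizumab"]
  expect_equal(con_r$concomitant, "aspirin")
  # no concomitant rows -> empty concomitant table for that drug
  expect_false("guselkumab" %in% res$concomitant$drug)
})
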