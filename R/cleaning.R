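# Cleaning: case deduplication, drug-name standardization, demographic
# normalization, outcome/reporter classification, descriptive summaries.

#' Default drug synonym table
#'
#' Maps generic names, brand names, and development codes to the two
#' canonical study drug labels. Matching is case- and punctuation-
#' insensitive substring search (see [standardize_drug()]), so dose and
#' formulation suffixes in free-text drugnames do not matter.
#'
#' @return A `data.table` with columns `keyword`, `label`.
#' @export
default_synonyms <- function() {
  data.table::data.table(
    keyword = c("guselkumab", "tremfya",
                "risankizumab", "skyrizi", "abbv-066"),
    label = c("guselkumab", "guselkumab",
              "risankizumab", "risankizumab", "risankizumab")
  )
}

.fold <- function(x) gsub("[^a-z0-9]", "", tolower(as.character(x)))

#' Standardize free-text drug names to canonical labels
#'
#' @param drugname Character vector of verbatim drug names.
#' @param prod_ai Character vector of active-ingredient strings (same
#'   length; may be `NA`).
#' @param synonyms Synonym table as from [default_synonyms()].
#' @return Character vector of canonical labels; `NA` where no keyword
#'   matches (a valid outcome: a background drug).
#' @export
standardize_drug <- function(drugname, prod_ai = NA_character_,
                             synonyms = default_synonyms()) {
  stopifnot(all(c("keyword", "label") %in% names(synonyms)))
  dn <- .fold(drugname)
  ai <- .fold(prod_ai)
  ai[is.na(ai)] <- ""
  dn[is.na(dn)] <- ""
  out <- rep(NA_character_, length(dn))
  for (i in seq_len(nrow(synonyms))) {
    key <- .fold(synonyms$keyword[i])
    hit <- is.na(out) &
      (grepl(key, dn, fixed = TRUE) | grepl(key, ai, fixed = TRUE))
    out[hit] <- synonyms$label[i]
  }
  out
}

#' Deduplicate case reports
#'
#' FAERS re-publishes updated versions of a case across quarters under the
#' same `caseid`. For each `caseid`, only the latest report by `fda_dt` is
#' retained; ties on `fda_dt` keep the largest `primaryid` (the latest
#' submission sequence). Rows with a missing `caseid` are dropped and
#' counted.
#'
#' @param demo The DEMO table.
#' @return A `data.table` with one row per `caseid`, with attribute
#'   `n_dropped_missing_caseid`.
#' @export
dedup_cases <- function(demo) {
  demo <- data.table::as.data.table(demo)
  stopifnot(all(c("caseid", "fda_dt") %in% names(demo)))
  caseid <- fda_dt <- primaryid <- NULL # R CMD check NSE
  miss <- is.na(demo$caseid) | trimws(as.character(demo$caseid)) == ""
  n_dropped <- sum(miss)
  out <- demo[!miss]
  # latest fda_dt wins; missing/partial dates sort first (lose to any date)
  fda_num <- suppressWarnings(as.numeric(out$fda_dt))
  fda_num[is.na(fda_num)] <- -Inf
  pid_num <- suppressWarnings(as.numeric(out$primaryid))
  pid_num[is.na(pid_num)] <- -Inf
  ord <- order(out$caseid, fda_num, pid_num)
  out <- out[ord]
  out <- out[!duplicated(out$caseid, fromLast = TRUE)]
  data.table::setattr(out, "n_dropped_missing_caseid", n_dropped)
  out[]
}

#' Restrict all tables of a dataset to surviving primaryids
#'
#' Applies [dedup_cases()] to DEMO and filters every other table to the
#' surviving `primaryid` values.
#'
#' @param dataset A `faers_data` object.
#' @return A deduplicated `faers_data` object.
#' @export
dedup_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "faers_data"))
  demo <- dedup_cases(dataset$demo)
  keep <- unique(demo$primaryid)
  out <- lapply(names(faers_schemas), function(nm) {
    if (nm == "demo") return(demo)
    tab <- dataset[[nm]]
    tab[tab$primaryid %in% keep]
  })
  names(out) <- names(faers_schemas)
  class(out) <- "faers_data"
  out
}

# age unit codes -> factor converting the recorded value to years
.age_unit_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.14,
                      DY = 1 / 365.25, HR = 1 / 8766)

#' Normalize age to years
#'
#' Converts (age, unit-code) pairs to years: decades x10, months /12,
#' weeks /52.14, days /365.25, hours /8766. Results outside [0, 120] years
#' and unknown unit codes become missing (implausible ages are treated as
#' recording errors, not truncated).
#'
#' @param age Numeric vector of recorded ages.
#' @param age_cod Character vector of unit codes (`DEC`, `YR`, `MON`, `WK`,
#'   `DY`, `HR`); missing code with a plausible value is read as years.
#' @return Numeric vector of ages in years, `NA` where unusable.
#' @export
normalize_age <- function(age, age_cod) {
  age <- as.numeric(age)
  code <- toupper(trimws(as.character(age_cod)))
  code[is.na(code) | code == ""] <- "YR"
  fac <- .age_unit_factor[code]
  yrs <- age * as.numeric(fac)
  yrs[is.na(fac)] <- NA_real_
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

# OUTC codes -> outcome labels; the "serious" flag covers the severe subset
.outcome_labels <- c(DE = "death", LT = "life-threatening",
                     HO = "hospitalization", DS = "disability",
                     CA = "congenital-anomaly", RI = "required-intervention",
                     OT = "other-serious")
.severe_outcomes <- c("death", "disability", "life-threatening",
                      "hospitalization")

#' Classify outcome codes
#'
#' Maps OUTC vocabulary codes to outcome labels and flags a report as
#' serious when any of death, disability, life-threatening, or
#' hospitalization is present ("other serious" is tabulated but does not
#' set the flag). Unknown codes are retained verbatim.
#'
#' @param outc_codes Character vector of outcome codes for one report.
#' @return List with `outcomes` (character vector of labels) and `serious`
#'   (logical scalar).
#' @export
classify_outcomes <- function(outc_codes) {
  codes <- toupper(trimws(as.character(outc_codes)))
  codes <- codes[!is.na(codes) & codes != ""]
  labels <- unname(.outcome_labels[codes])
  labels[is.na(labels)] <- codes[is.na(labels)]
  labels <- unique(labels)
  list(outcomes = labels, serious = any(labels %in% .severe_outcomes))
}

# occp_cod -> reporter category
.reporter_labels <- c(CN = "consumer", PH = "pharmacist", MD = "physician",
                      HP = "other-health-professional",
                      OT = "other-health-professional", LW = "lawyer")

#' Build cleaned case-level reports
#'
#' One row per deduplicated report with normalized demographics, reporter
#' class, outcome labels, and the serious flag.
#'
#' @param dataset A deduplicated `faers_data` object (see [dedup_dataset()]).
#' @return A `data.table` with columns `primaryid`, `caseid`, `fda_dt`,
#'   `event_dt`, `age_years`, `sex`, `reporter`, `country`, `outcomes`
#'   (list column), `serious`, `quarter`.
#' @export
build_case_reports <- function(dataset) {
  stopifnot(inherits(dataset, "faers_data"))
  demo <- dataset$demo
  sexes <- toupper(trimws(as.character(demo$sex)))
  sex <- data.table::fcase(sexes == "F", "female",
                           sexes == "M", "male",
                           default = "unknown")
  occ <- toupper(trimws(as.character(demo$occp_cod)))
  reporter <- unname(.reporter_labels[occ])
  reporter[is.na(reporter)] <- "unknown"
  out <- data.table::data.table(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = demo$fda_dt,
    event_dt = demo$event_dt,
    age_years = normalize_age(demo$age, demo$age_cod),
    sex = sex,
    reporter = reporter,
    country = demo$reporter_country,
    quarter = demo$quarter
  )
  outc <- dataset$outc
  by_report <- outc[, list(codes = list(.SD$outc_cod)), by = "primaryid"]
  idx <- match(out$primaryid, by_report$primaryid)
  cls <- lapply(idx, function(i) {
    if (is.na(i)) classify_outcomes(character()) else
      classify_outcomes(by_report$codes[[i]])
  })
  out[, "outcomes" := lapply(cls, `[[`, "outcomes")]
  out[, "serious" := vapply(cls, `[[`, logical(1L), "serious")]
  out[]
}

#' Build drug-event records, the counting unit of disproportionality
#'
#' One record per (report, drug, preferred term) after cleaning: the drug
#' label comes from [standardize_drug()] for the target drugs and the
#' case-folded verbatim drugname for background drugs; duplicate PTs within
#' a report collapse to one record. With `ps_only = TRUE` (the default,
#' applied to target drugs) only reports naming the target drug as primary
#' suspect (role code PS) contribute.
#'
#' @param dataset A deduplicated `faers_data` object.
#' @param synonyms Synonym table for the target drugs.
#' @param ps_only Require role PS for target-drug records.
#' @return A `data.table` with columns `primaryid`, `drug`, `pt`, `role`,
#'   `is_target`; attribute `n_reports_no_reac` counts target-drug reports
#'   contributing zero records for lack of REAC rows.
#' @export
build_records <- function(dataset, synonyms = default_synonyms(),
                          ps_only = TRUE) {
  stopifnot(inherits(dataset, "faers_data"))
  drug <- data.table::as.data.table(dataset$drug)
  label <- standardize_drug(drug$drugname, drug$prod_ai, synonyms)
  is_target <- !is.na(label)
  label[!is_target] <- .fold(drug$drugname[!is_target])
  role <- toupper(trimws(as.character(drug$role_cod)))
  keep <- !is.na(label) & label != ""
  if (ps_only) keep <- keep & role == "PS"
  dlab <- data.table::data.table(primaryid = drug$primaryid[keep],
                                 drug = label[keep], role = role[keep],
                                 is_target = is_target[keep])
  dlab <- unique(dlab, by = c("primaryid", "drug"))
  reac <- data.table::as.data.table(dataset$reac)
  reac <- reac[!is.na(reac$pt) & trimws(reac$pt) != ""]
  reac <- unique(reac[, c("primaryid", "pt")])
  no_reac <- setdiff(dlab$primaryid[dlab$is_target], reac$primaryid)
  out <- merge(dlab, reac, by = "primaryid", allow.cartesian = TRUE)
  data.table::setorderv(out, c("primaryid", "drug", "pt"))
  out <- out[, c("primaryid", "drug", "pt", "role", "is_target")]
  data.table::setattr(out, "n_reports_no_reac", length(no_reac))
  out[]
}

.age_band <- function(age_years) {
  data.table::fcase(is.na(age_years), "unknown",
                    age_years < 18, "<18",
                    age_years < 65, "18-65",
                    default = ">=65")
}

#' Demographic summary of target-drug reports
#'
#' Per-drug counts and percentages for sex, age bands, reporter type,
#' serious outcome categories, and reporting countries, plus report / AE
#' record totals and median (IQR) age. Percentages are of the per-drug
#' report total (outcome categories are not mutually exclusive).
#'
#' @param reports Cleaned case reports from [build_case_reports()].
#' @param records Drug-event records from [build_records()].
#' @param drugs Canonical labels to summarize (default: targets present).
#' @param n_countries Number of top countries listed individually.
#' @return A long `data.table`: `drug`, `section`, `level`, `n`, `pct`
#'   (median/IQR rows carry values in `n` and `pct` columns `q1`,`q3`).
#' @export
demographic_summary <- function(reports, records, drugs = NULL,
                                n_countries = 4L) {
  records <- data.table::as.data.table(records)
  targets <- records[records$is_target]
  if (is.null(drugs)) drugs <- sort(unique(targets$drug))
  out <- list()
  for (d in drugs) {
    pids <- unique(targets$primaryid[targets$drug == d])
    rep_d <- reports[reports$primaryid %in% pids]
    n_rep <- nrow(rep_d)
    add <- function(section, level, n) {
      data.table::data.table(drug = d, section = section, level = level,
                             n = n, pct = if (n_rep) 100 * n / n_rep else NA_real_)
    }
    rows <- list(
      add("totals", "reports", n_rep),
      add("totals", "ae_records", sum(targets$drug == d))
    )
    for (lv in c("female", "male", "unknown")) {
      rows <- c(rows, list(add("sex", lv, sum(rep_d$sex == lv))))
    }
    band <- .age_band(rep_d$age_years)
    for (lv in c("<18", "18-65", ">=65", "unknown")) {
      rows <- c(rows, list(add("age_band", lv, sum(band == lv))))
    }
    qs <- stats::quantile(rep_d$age_years, c(0.25, 0.5, 0.75), na.rm = TRUE,
                          names = FALSE, type = 7)
    med <- data.table::data.table(drug = d, section = "age", level = "median_iqr",
                                  n = qs[2L], pct = NA_real_)
    med[, c("q1", "q3") := list(qs[1L], qs[3L])]
    rows <- c(rows, list(med))
    for (lv in sort(unique(rep_d$reporter))) {
      rows <- c(rows, list(add("reporter", lv, sum(rep_d$reporter == lv))))
    }
    all_out <- unlist(rep_d$outcomes)
    for (lv in unname(.outcome_labels)) {
      rows <- c(rows, list(add("outcome", lv, sum(all_out == lv))))
    }
    ctry <- sort(table(rep_d$country), decreasing = TRUE)
    top <- utils::head(names(ctry), n_countries)
    for (lv in top) rows <- c(rows, list(add("country", lv, unname(ctry[lv]))))
    rows <- c(rows, list(add("country", "other",
                             n_rep - sum(ctry[top]))))
    out <- c(out, rows)
  }
  data.table::rbindlist(out, fill = TRUE)
}

#' Top indications and concomitant drugs per target drug
#'
#' Ranks the target drug's indication preferred terms (INDI rows linked to
#' the target drug's sequence) and the verbatim drugnames reported with role
#' C (concomitant) in the same cases, by case count, with percentages of the
#' per-drug report total. Ties in count break alphabetically and both
#' entries are listed.
#'
#' @param dataset A deduplicated `faers_data` object.
#' @param records Records from [build_records()].
#' @param synonyms Synonym table for the target drugs.
#' @param n_indications,n_concomitant Number of rows kept per drug.
#' @return List of two `data.table`s: `indications`, `concomitant`.
#' @export
indication_concomitant_summary <- function(dataset, records,
                                           synonyms = default_synonyms(),
                                           n_indications = 3L,
                                           n_concomitant = 5L) {
  stopifnot(inherits(dataset, "faers_data"))
  records <- data.table::as.data.table(records)
  targets <- records[records$is_target]
  drug <- data.table::as.data.table(dataset$drug)
  drug[, "label" := standardize_drug(drug$drugname, drug$prod_ai, synonyms)]
  drug[, "role" := toupper(trimws(as.character(drug$role_cod)))]
  indi <- data.table::as.data.table(dataset$indi)
  ind_rows <- list(); con_rows <- list()
  for (d in sort(unique(targets$drug))) {
    pids <- unique(targets$primaryid[targets$drug == d])
    n_rep <- length(pids)
    # indications attached to this drug's DRUG rows via drug_seq
    dseq <- drug[drug$label %in% d & drug$primaryid %in% pids,
                 c("primaryid", "drug_seq")]
    ind <- merge(indi, dseq,
                 by.x = c("primaryid", "indi_drug_seq"),
                 by.y = c("primaryid", "drug_seq"))
    ind <- ind[!is.na(ind$indi_pt) & trimws(ind$indi_pt) != ""]
    ind <- unique(ind[, c("primaryid", "indi_pt")])
    cnt <- ind[, list(n = .N), by = "indi_pt"]
    data.table::setorderv(cnt, c("n", "indi_pt"), c(-1L, 1L))
    cnt <- utils::head(cnt, n_indications)
    if (nrow(cnt)) {
      ind_rows[[d]] <- data.table::data.table(
        drug = d, indication = cnt$indi_pt, n = cnt$n,
        pct = 100 * cnt$n / n_rep, rank = seq_len(nrow(cnt)))
    }
    con <- drug[drug$primaryid %in% pids & drug$role == "C" &
                  (is.na(drug$label) | !drug$label %in% d)]
    if (nrow(con)) {
      con[, "name" := tolower(trimws(con$drugname))]
      con <- unique(con[!is.na(con$name) & con$name != "",
                        c("primaryid", "name")])
      ccnt <- con[, list(n = .N), by = "name"]
      data.table::setorderv(ccnt, c("n", "name"), c(-1L, 1L))
      ccnt <- utils::head(ccnt, n_concomitant)
      con_rows[[d]] <- data.table::data.table(
        drug = d, concomitant = ccnt$name, n = ccnt$n,
        pct = 100 * ccnt$n / n_rep, rank = seq_len(nrow(ccnt)))
    }
  }
  list(indications = data.table::rbindlist(ind_rows),
       concomitant = data.table::rbindlist(con_rows))
}
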