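# Synthetic FAERS-dialect data with known ground truth.
#
# The generator emulates the structural features the pipeline must survive:
# multi-table cases keyed by primaryid/caseid, duplicate caseids with later
# fda_dt, role-coded drug rows with free-text names (brand/generic/dose
# suffixes), multiple PTs per report, demographic missingness, outcome
# codes, therapy start dates and event dates yielding Weibull-distributed
# onset times, and drug-event pairs injected at a configurable relative
# risk. It does not simulate reporting-bias dynamics or real MedDRA term
# frequencies.

#' Default preferred-term vocabulary with background probabilities
#'
#' A long-tailed vocabulary: per-report occurrence probabilities are
#' proportional to `1/(rank + 4)` and scaled so their sum (the expected
#' number of PTs per report) is `mean_pts`.
#'
#' @param n_pts Vocabulary size.
#' @param mean_pts Expected PTs per report (AE records per report).
#' @return A `data.table` with columns `pt`, `prob`.
#' @export
default_pt_vocab <- function(n_pts = 60L, mean_pts = 2.1) {
  base <- 1 / (seq_len(n_pts) + 4)
  data.table::data.table(pt = sprintf("pt_%02d", seq_len(n_pts)),
                         prob = base / sum(base) * mean_pts)
}

#' Synthetic-dataset configuration
#'
#' Defaults state a desk-scale world consistent with the structure of a
#' two-drug FAERS cohort: report counts in the observed ~2:1 target-arm
#' ratio against a larger all-other-drugs background, demographic mixes and
#' missingness near the descriptive-table proportions, per-drug Weibull
#' onset parameters at the published fits, and roughly a quarter of reports
#' with usable onset dates.
#'
#' @param n_risankizumab,n_guselkumab,n_background Reports per arm.
#' @param n_background_drugs Size of the background drug-name pool.
#' @param pt_vocab PT vocabulary table (`pt`, `prob`).
#' @param injected_signals `data.table(drug, pt, rr)` of drug-event pairs
#'   whose per-report probability is multiplied by `rr` (`NULL` = none).
#' @param duplicate_rate Fraction of caseids re-reported with a later
#'   `fda_dt` and a new `primaryid`.
#' @param age_missing_rate,sex_probs,reporter_probs,country_probs,outcome_probs
#'   Demographic and outcome distributions.
#' @param onset Named list of `c(scale, shape)` Weibull onset parameters per
#'   arm (`risankizumab`, `guselkumab`, `background`).
#' @param start_missing_rate,event_missing_rate Probability that the therapy
#'   start / event date is absent; a further `partial_date_rate` of the
#'   present dates are truncated to `YYYYMM` precision.
#' @param partial_date_rate See above.
#' @param seed Integer RNG seed; fixed seed gives identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_risankizumab = 2000L, n_guselkumab = 1000L,
                         n_background = 10000L, n_background_drugs = 50L,
                         pt_vocab = default_pt_vocab(),
                         injected_signals = NULL,
                         duplicate_rate = 0.05,
                         age_missing_rate = 0.5,
                         sex_probs = c(F = 0.51, M = 0.39, U = 0.10),
                         reporter_probs = c(CN = 0.68, PH = 0.19, MD = 0.10,
                                            U = 0.03),
                         country_probs = c(US = 0.81, CA = 0.06, GB = 0.02,
                                           DE = 0.015, FR = 0.015, JP = 0.08),
                         outcome_probs = c(HO = 0.17, OT = 0.33, DE = 0.034,
                                           LT = 0.004, DS = 0.003),
                         onset = list(
                           risankizumab = c(scale = 241.61, shape = 0.69),
                           guselkumab = c(scale = 109.71, shape = 0.44),
                           background = c(scale = 180, shape = 0.8)),
                         start_missing_rate = 0.5,
                         event_missing_rate = 0.45,
                         partial_date_rate = 0.03,
                         seed = 20170701L) {
  pt_vocab <- data.table::as.data.table(pt_vocab)
  stopifnot(all(c("pt", "prob") %in% names(pt_vocab)),
            all(pt_vocab$prob >= 0), all(pt_vocab$prob <= 1),
            duplicate_rate >= 0, duplicate_rate < 1)
  if (!is.null(injected_signals)) {
    injected_signals <- data.table::as.data.table(injected_signals)
    stopifnot(all(c("drug", "pt", "rr") %in% names(injected_signals)),
              all(injected_signals$rr >= 0))
    base <- pt_vocab$prob[match(injected_signals$pt, pt_vocab$pt)]
    if (anyNA(base)) stop("injected PT not in vocabulary")
    if (any(injected_signals$rr * base > 1)) {
      stop("injected rr x background probability exceeds 1; ",
           "renormalize the vocabulary or lower rr")
    }
  }
  structure(list(
    n_risankizumab = as.integer(n_risankizumab),
    n_guselkumab = as.integer(n_guselkumab),
    n_background = as.integer(n_background),
    n_background_drugs = as.integer(n_background_drugs),
    pt_vocab = pt_vocab, injected_signals = injected_signals,
    duplicate_rate = duplicate_rate, age_missing_rate = age_missing_rate,
    sex_probs = sex_probs, reporter_probs = reporter_probs,
    country_probs = country_probs, outcome_probs = outcome_probs,
    onset = onset, start_missing_rate = start_missing_rate,
    event_missing_rate = event_missing_rate,
    partial_date_rate = partial_date_rate, seed = as.integer(seed)),
    class = "synth_config")
}

.fmt_dt <- function(d) format(d, "%Y%m%d")

#' Generate a synthetic FAERS-dialect dataset
#'
#' @param config A [synth_config()] object.
#' @return List with `dataset` (a `faers_data`) and `manifest` (ground
#'   truth: injected pairs, onset parameters, duplicate case map, the PT
#'   vocabulary, and per-arm report counts).
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  arms <- c(rep("risankizumab", config$n_risankizumab),
            rep("guselkumab", config$n_guselkumab),
            rep("background", config$n_background))
  n <- length(arms)
  primaryid <- as.character(1000000L + seq_len(n))
  caseid <- as.character(5000000L + seq_len(n))

  # demographics -------------------------------------------------------
  sex <- sample(c("F", "M", NA_character_), n, replace = TRUE,
                prob = config$sex_probs)
  age_years <- pmin(pmax(stats::rnorm(n, 55, 14), 5), 95)
  age_missing <- stats::runif(n) < config$age_missing_rate
  unit <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                 prob = c(0.9, 0.05, 0.05))
  age_val <- data.table::fcase(unit == "YR", round(age_years),
                               unit == "DEC", round(age_years / 10, 1),
                               unit == "MON", round(age_years * 12))
  age_val[age_missing] <- NA_real_
  unit[age_missing] <- NA_character_
  occp <- sample(c("CN", "PH", "MD", NA_character_), n, replace = TRUE,
                 prob = config$reporter_probs)
  country <- sample(names(config$country_probs), n, replace = TRUE,
                    prob = config$country_probs)

  # onset times and dates ----------------------------------------------
  tto <- numeric(n)
  for (arm in names(config$onset)) {
    idx <- arms == arm
    par <- config$onset[[arm]]
    tto[idx] <- stats::rweibull(sum(idx), shape = par[["shape"]],
                                scale = par[["scale"]])
  }
  start_date <- as.Date("2018-01-01") + sample.int(2300L, n, replace = TRUE)
  event_date <- start_date + round(tto)
  fda_date <- event_date + sample.int(180L, n, replace = TRUE)
  start_dt <- .fmt_dt(start_date)
  event_dt <- .fmt_dt(event_date)
  start_dt[stats::runif(n) < config$start_missing_rate] <- NA_character_
  event_dt[stats::runif(n) < config$event_missing_rate] <- NA_character_
  part <- stats::runif(n) < config$partial_date_rate & !is.na(start_dt)
  start_dt[part] <- substr(start_dt[part], 1L, 6L)
  part_e <- stats::runif(n) < config$partial_date_rate & !is.na(event_dt)
  event_dt[part_e] <- substr(event_dt[part_e], 1L, 6L)

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = .fmt_dt(fda_date),
    event_dt = event_dt, age = age_val, age_cod = unit, sex = sex,
    occp_cod = occp, reporter_country = country)

  # drugs ---------------------------------------------------------------
  bg_pool <- sprintf("backgrounddrug%02d", seq_len(config$n_background_drugs))
  spellings <- list(
    risankizumab = c("SKYRIZI", "RISANKIZUMAB", "SKYRIZI 150MG/ML",
                     "Skyrizi (risankizumab)", "ABBV-066"),
    guselkumab = c("TREMFYA", "GUSELKUMAB", "TREMFYA 100MG",
                   "Tremfya (guselkumab)"))
  drugname <- character(n)
  prod_ai <- character(n)
  for (arm in c("risankizumab", "guselkumab")) {
    idx <- arms == arm
    drugname[idx] <- sample(spellings[[arm]], sum(idx), replace = TRUE)
    prod_ai[idx] <- toupper(arm)
  }
  idx_bg <- arms == "background"
  drugname[idx_bg] <- sample(bg_pool, sum(idx_bg), replace = TRUE)
  prod_ai[idx_bg] <- toupper(drugname[idx_bg])
  drug <- data.table::data.table(primaryid = primaryid, drug_seq = "1",
                                 role_cod = "PS", drugname = drugname,
                                 prod_ai = prod_ai)
  # concomitants (role C) on target reports
  idx_t <- which(!idx_bg)
  n_con <- stats::rbinom(length(idx_t), 3L, 0.2)
  if (sum(n_con)) {
    con_pid <- rep(primaryid[idx_t], n_con)
    con <- data.table::data.table(
      primaryid = con_pid,
      drug_seq = as.character(unlist(lapply(n_con[n_con > 0L],
                                            function(k) seq_len(k) + 1L))),
      role_cod = "C",
      drugname = sample(bg_pool, length(con_pid), replace = TRUE))
    con[, "prod_ai" := toupper(con$drugname)]
    drug <- rbind(drug, con)
  }

  # reactions: independent Bernoulli per vocabulary PT, rr-scaled for
  # injected pairs; empty draws are topped up with one weighted PT
  vocab <- config$pt_vocab
  m <- nrow(vocab)
  probs <- matrix(rep(vocab$prob, each = n), nrow = n)
  if (!is.null(config$injected_signals)) {
    for (i in seq_len(nrow(config$injected_signals))) {
      sig <- config$injected_signals[i]
      j <- match(sig$pt, vocab$pt)
      probs[arms == sig$drug, j] <- pmin(vocab$prob[j] * sig$rr, 1)
    }
  }
  hit <- matrix(stats::runif(n * m), nrow = n) < probs
  none <- rowSums(hit) == 0L
  if (any(none)) {
    forced <- sample.int(m, sum(none), replace = TRUE, prob = vocab$prob)
    hit[cbind(which(none), forced)] <- TRUE
  }
  idx_hit <- which(hit, arr.ind = TRUE)
  reac <- data.table::data.table(primaryid = primaryid[idx_hit[, 1L]],
                                 pt = vocab$pt[idx_hit[, 2L]])
  data.table::setorderv(reac, c("primaryid", "pt"))

  # outcomes -------------------------------------------------------------
  outc_rows <- lapply(names(config$outcome_probs), function(code) {
    sel <- stats::runif(n) < config$outcome_probs[[code]]
    data.table::data.table(primaryid = primaryid[sel], outc_cod = code)
  })
  outc <- data.table::rbindlist(outc_rows)
  data.table::setorderv(outc, "primaryid")

  rpsr <- data.table::data.table(
    primaryid = primaryid,
    rpsr_cod = sample(c("EXP", "CSM", "HP"), n, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1)))

  ther <- data.table::data.table(primaryid = primaryid, dsg_drug_seq = "1",
                                 start_dt = start_dt)

  # indications on target reports ---------------------------------------
  ind_terms <- c("psoriasis", "crohn's disease", "psoriatic arthritis",
                 "ulcerative colitis", "")
  ind_probs <- c(0.50, 0.15, 0.10, 0.05, 0.20)
  ind <- sample(ind_terms, length(idx_t), replace = TRUE, prob = ind_probs)
  keep_ind <- ind != ""
  indi <- data.table::data.table(primaryid = primaryid[idx_t][keep_ind],
                                 indi_drug_seq = "1",
                                 indi_pt = ind[keep_ind])

  # duplicate caseids: later re-reports that must win deduplication ------
  n_dup <- floor(config$duplicate_rate * n)
  dup_map <- data.table::data.table(caseid = character(),
                                    orig_primaryid = character(),
                                    dup_primaryid = character())
  if (n_dup > 0L) {
    dup_idx <- sort(sample.int(n, n_dup))
    dup_pid <- as.character(9000000L + seq_len(n_dup))
    dup_demo <- demo[dup_idx]
    dup_demo[, "primaryid" := dup_pid]
    dup_demo[, "fda_dt" := .fmt_dt(fda_date[dup_idx] +
                                     sample(30:400, n_dup, replace = TRUE))]
    demo <- rbind(demo, dup_demo)
    orig_pid <- primaryid[dup_idx]
    relabel <- function(tab) {
      sel <- which(tab$primaryid %in% orig_pid)
      if (!length(sel)) return(tab)
      sub <- tab[sel]
      new_pid <- dup_pid[match(sub$primaryid, orig_pid)]
      data.table::set(sub, j = "primaryid", value = new_pid)
      rbind(tab, sub)
    }
    drug <- relabel(drug); reac <- relabel(reac); outc <- relabel(outc)
    rpsr <- relabel(rpsr); ther <- relabel(ther); indi <- relabel(indi)
    dup_map <- data.table::data.table(caseid = caseid[dup_idx],
                                      orig_primaryid = primaryid[dup_idx],
                                      dup_primaryid = dup_pid)
  }

  dataset <- faers_data(list(demo = demo, drug = drug, reac = reac,
                             outc = outc, rpsr = rpsr, ther = ther,
                             indi = indi), quarter = "SYN")
  manifest <- list(
    injected = config$injected_signals,
    onset = config$onset,
    duplicates = dup_map,
    pt_vocab = vocab,
    n_reports = c(risankizumab = config$n_risankizumab,
                  guselkumab = config$n_guselkumab,
                  background = config$n_background),
    true_tto = data.table::data.table(primaryid = primaryid, arm = arms,
                                      tto_days = tto))
  list(dataset = dataset, manifest = manifest)
}

#' Generate and write a synthetic quarter to disk
#'
#' Writes the seven FAERS-dialect files plus `manifest_*.csv` ground-truth
#' tables into `dir`.
#'
#' @param config A [synth_config()] object.
#' @param dir Output directory.
#' @param quarter Quarter label used in file names.
#' @return Invisibly, the generated list from [synth_generate()].
#' @export
synth_write <- function(config, dir, quarter = "24Q1") {
  gen <- synth_generate(config)
  write_faers_quarter(gen$dataset, dir, quarter = quarter)
  if (!is.null(gen$manifest$injected)) {
    data.table::fwrite(gen$manifest$injected,
                       file.path(dir, "manifest_injected.csv"))
  }
  data.table::fwrite(gen$manifest$duplicates,
                     file.path(dir, "manifest_duplicates.csv"))
  data.table::fwrite(gen$manifest$pt_vocab,
                     file.path(dir, "manifest_pt_vocab.csv"))
  invisible(gen)
}
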