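# Shared fixtures and independent oracles. Everything is built in code;
# nothing is read from disk except files the tests themselves write.

# A hand-enumerable three-report dataset: two risankizumab reports (one a
# later duplicate of case C1) and one guselkumab report.
tiny_dataset <- function() {
  demo <- data.table::data.table(
    primaryid = c("101", "102", "103"),
    caseid = c("C1", "C1", "C2"),
    fda_dt = c("20240101", "20240301", "20240215"),
    event_dt = c("20231201", "20231201", "2023"),
    age = c(45, 45, 6),
    age_cod = c("YR", "YR", "DEC"),
    sex = c("F", "F", "M"),
    occp_cod = c("CN", "CN", "MD"),
    reporter_country = c("US", "US", "DE"))
  drug <- data.table::data.table(
    primaryid = c("101", "102", "102", "103"),
    drug_seq = c("1", "1", "2", "1"),
    role_cod = c("PS", "PS", "C", "PS"),
    drugname = c("SKYRIZI 150MG/ML", "SKYRIZI 150MG/ML", "aspirin",
                 "TREMFYA"),
    prod_ai = c("RISANKIZUMAB", "RISANKIZUMAB", "ASPIRIN", "GUSELKUMAB"))
  reac <- data.table::data.table(
    primaryid = c("101", "102", "102", "103", "103"),
    pt = c("pruritus", "pruritus", "fall", "pruritus", "headache"))
  outc <- data.table::data.table(
    primaryid = c("102", "103"),
    outc_cod = c("HO", "OT"))
  ther <- data.table::data.table(
    primaryid = c("101", "102", "103"),
    dsg_drug_seq = c("1", "1", "1"),
    start_dt = c("20231101", "20231101", "20231215"))
  indi <- data.table::data.table(
    primaryid = c("102", "103"),
    indi_drug_seq = c("1", "1"),
    indi_pt = c("psoriasis", "psoriasis"))
  faers_data(list(demo = demo, drug = drug, reac = reac, outc = outc,
                  ther = ther, indi = indi), quarter = "24Q1")
}

# Exhaustive-enumeration oracle for 2x2 cells: plain loops over the record
# list, independent of build_contingency's aggregation path.
brute_contingency <- function(records, drug, pt) {
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(records))) {
    is_d <- records$drug[i] == drug
    is_p <- records$pt[i] == pt
    if (is_d && is_p) a <- a + 1L
    else if (is_d) b <- b + 1L
    else if (is_p) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Closed-form expected record-level ROR under the generative model:
# per-report PT probability is q (rr-scaled for injected pairs) plus the
# zero-draw top-up P0 * w; expected records per report is sum(q) + P0.
expected_record_ror <- function(cfg, drug, pt) {
  vocab <- cfg$pt_vocab
  j <- match(pt, vocab$pt)
  w <- vocab$prob / sum(vocab$prob)
  q_for <- function(arm) {
    q <- vocab$prob
    inj <- cfg$injected_signals
    if (!is.null(inj)) {
      for (i in seq_len(nrow(inj))) {
        if (inj$drug[i] == arm) {
          k <- match(inj$pt[i], vocab$pt)
          q[k] <- min(q[k] * inj$rr[i], 1)
        }
      }
    }
    q
  }
  arms <- c(risankizumab = cfg$n_risankizumab,
            guselkumab = cfg$n_guselkumab,
            background = cfg$n_background)
  a <- b <- cc <- d <- 0
  for (arm in names(arms)) {
    n <- arms[[arm]]
    if (n == 0L) next
    q <- q_for(arm)
    P0 <- prod(1 - q)
    p <- q[j] + P0 * w[j]
    R <- sum(q) + P0
    if (arm == drug) {
      a <- a + n * p; b <- b + n * (R - p)
    } else {
      cc <- cc + n * p; d <- d + n * (R - p)
    }
  }
  (a / b) / (cc / d)
}

# One moderate synthetic dataset shared (read-only) across test files.
.shared_env <- new.env(parent = emptyenv())
shared_synth <- function() {
  if (is.null(.shared_env$gen)) {
    cfg <- synth_config(
      n_risankizumab = 1500L, n_guselkumab = 800L, n_background = 6000L,
      injected_signals = data.table::data.table(
        drug = c("risankizumab", "guselkumab"),
        pt = c("pt_30", "pt_40"),
        rr = c(10, 8)),
      seed = 424242L)
    .shared_env$gen <- synth_generate(cfg)
    ds <- dedup_dataset(.shared_env$gen$dataset)
    .shared_env$clean <- ds
    .shared_env$records <- build_records(ds)
    .shared_env$reports <- build_case_reports(ds)
  }
  .shared_env
}
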