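# Disproportionality statistics on 2x2 contingency tables.
#
# Cell layout for a (drug D, event P) pair against the database background:
#         event P   other events
#   D        a           b          a+b = D's record total
#   others   c           d          c+d = background record total
#
# The counting unit is the drug-event record (one report contributing one
# row per distinct PT), so a+b reproduces the per-drug AE totals used as
# margins in the descriptive tables.

#' Construct the 2x2 contingency table for one drug-event pair
#'
#' @param records Drug-event records from [build_records()].
#' @param drug Canonical drug label.
#' @param pt Preferred term.
#' @return A `contingency_table`: list with integer cells `a`, `b`, `c`,
#'   `d` and logical `drug_present`.
#' @export
build_contingency <- function(records, drug, pt) {
  records <- data.table::as.data.table(records)
  is_d <- records$drug == drug
  is_p <- records$pt == pt
  tab <- list(a = sum(is_d & is_p), b = sum(is_d & !is_p),
              c = sum(!is_d & is_p), d = sum(!is_d & !is_p),
              drug_present = any(is_d))
  structure(tab, class = "contingency_table")
}

#' Disproportionality statistics for 2x2 tables (vectorized)
#'
#' Computes, for each table:
#' * ROR = ad/(bc) with Woolf 95% CI
#'   `exp(log ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`;
#' * PRR = (a/(a+b)) / (c/(c+d)) with 95% CI using
#'   `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`;
#' * Pearson chi-square without continuity correction,
#'   `N (ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`;
#' * BCPNN information component `IC = log2(a N / ((a+b)(a+c)))` with the
#'   shrinkage-style lower bound `IC025 = IC - 3.3 a^(-1/2) - 2 a^(-3/2)`.
#'
#' No zero-cell continuity correction is applied by default: statistics
#' whose defining cells are zero are returned as `NA` (flagged undefined),
#' never as infinities. With `haldane = TRUE` a 0.5 is added to every cell
#' of tables containing a zero before computing.
#'
#' @param a,b,c,d Integer vectors of cells (recycled to common length), or
#'   `a` may be a single `contingency_table`.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to zero-cell
#'   tables.
#' @return A `data.table` with columns `a`, `b`, `c`, `d`, `n` (= a), `ror`,
#'   `ror_lo`, `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `chisq`, `ic`, `ic025`.
#' @export
disproportionality_stats <- function(a, b = NULL, c = NULL, d = NULL,
                                     haldane = FALSE) {
  if (inherits(a, "contingency_table")) {
    tab <- a; a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  len <- max(length(a), length(b), length(c), length(d))
  a <- as.numeric(rep_len(a, len)); b <- as.numeric(rep_len(b, len))
  c <- as.numeric(rep_len(c, len)); d <- as.numeric(rep_len(d, len))
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  a0 <- a; n <- a
  if (haldane) {
    z <- a == 0 | b == 0 | c == 0 | d == 0
    a[z] <- a[z] + 0.5; b[z] <- b[z] + 0.5
    c[z] <- c[z] + 0.5; d[z] <- d[z] + 0.5
  }
  N <- a + b + c + d
  # ROR: needs all four cells positive
  ok_ror <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ror_lo <- ror_hi <- rep(NA_real_, len)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror[ok_ror] <- (a * d / (b * c))[ok_ror]
  ror_lo[ok_ror] <- exp(log(ror) - 1.96 * se)[ok_ror]
  ror_hi[ok_ror] <- exp(log(ror) + 1.96 * se)[ok_ror]
  # PRR: needs a>0, c>0 and both margins positive
  ok_prr <- a > 0 & c > 0 & (a + b) > 0 & (c + d) > 0
  prr <- prr_lo <- prr_hi <- rep(NA_real_, len)
  prr[ok_prr] <- ((a / (a + b)) / (c / (c + d)))[ok_prr]
  se_prr <- sqrt(pmax(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d), 0))
  prr_lo[ok_prr] <- exp(log(prr) - 1.96 * se_prr)[ok_prr]
  prr_hi[ok_prr] <- exp(log(prr) + 1.96 * se_prr)[ok_prr]
  # Pearson chi-square, uncorrected; defined when all margins positive
  ok_chi <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  chisq <- rep(NA_real_, len)
  chisq[ok_chi] <- (N * (a * d - b * c)^2 /
                      ((a + b) * (c + d) * (a + c) * (b + d)))[ok_chi]
  # IC: observed vs expected; needs a>0 and positive margins
  ok_ic <- a > 0 & (a + b) > 0 & (a + c) > 0
  ic <- ic025 <- rep(NA_real_, len)
  ic[ok_ic] <- log2(a * N / ((a + b) * (a + c)))[ok_ic]
  ic025[ok_ic] <- (ic - 3.3 * a^(-0.5) - 2 * a^(-1.5))[ok_ic]
  data.table::data.table(a = a0, b = b, c = c, d = d, n = n,
                         ror = ror, ror_lo = ror_lo, ror_hi = ror_hi,
                         prr = prr, prr_lo = prr_lo, prr_hi = prr_hi,
                         chisq = chisq, ic = ic, ic025 = ic025)
}

#' Signal criteria
#'
#' The default thresholds implement the standard three-algorithm rule set:
#' ROR 95% CI lower bound > 1 with N >= 3; PRR >= 2 with chi-square >= 4 and
#' N >= 3; IC025 > 0. The minimum record count `min_n` is enforced globally
#' across all rules. `combine = "any"` flags a pair when at least one rule
#' fires; `"all"` requires all three.
#'
#' @param min_n Minimum number of drug-event records.
#' @param ror_ci_low,prr_min,chisq_min,ic025_min Rule thresholds.
#' @param combine `"any"` or `"all"`.
#' @return A `signal_criteria` list.
#' @export
signal_criteria <- function(min_n = 3L, ror_ci_low = 1, prr_min = 2,
                            chisq_min = 4, ic025_min = 0,
                            combine = c("any", "all")) {
  combine <- match.arg(combine)
  stopifnot(min_n >= 0, prr_min > 0, chisq_min >= 0)
  structure(list(min_n = as.integer(min_n), ror_ci_low = ror_ci_low,
                 prr_min = prr_min, chisq_min = chisq_min,
                 ic025_min = ic025_min, combine = combine),
            class = "signal_criteria")
}

#' Evaluate signal criteria on computed statistics
#'
#' Thresholds are inclusive for PRR and chi-square (`>=`) and strict for
#' the CI lower bound and IC025 (`>`), matching the conventional rule
#' wording. `NA` statistics never fire a rule.
#'
#' @param stats A `data.table` from [disproportionality_stats()].
#' @param criteria A [signal_criteria()] object.
#' @return `stats` with added logical columns `sig_ror`, `sig_prr`,
#'   `sig_ic`, `signal`.
#' @export
evaluate_signal <- function(stats, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  stats <- data.table::as.data.table(stats)
  n_ok <- stats$n >= criteria$min_n
  f <- function(x) !is.na(x) & x
  sig_ror <- f(stats$ror_lo > criteria$ror_ci_low) & n_ok
  sig_prr <- f(stats$prr >= criteria$prr_min) &
    f(stats$chisq >= criteria$chisq_min) & n_ok
  sig_ic <- f(stats$ic025 > criteria$ic025_min) & n_ok
  overall <- if (criteria$combine == "any") {
    sig_ror | sig_prr | sig_ic
  } else {
    sig_ror & sig_prr & sig_ic
  }
  out <- data.table::copy(stats)
  out[, c("sig_ror", "sig_prr", "sig_ic", "signal") :=
        list(sig_ror, sig_prr, sig_ic, overall)]
  out[]
}

#' Screen every preferred term for one drug
#'
#' Builds all (drug, PT) contingency tables in one aggregation pass,
#' computes the disproportionality statistics, applies the criteria, and
#' ranks. Indication-related PTs can be excluded up front. Ranking is by
#' descending ROR, ties broken by larger N then PT alphabetically.
#'
#' @param records Drug-event records from [build_records()].
#' @param drug Canonical drug label to screen.
#' @param criteria A [signal_criteria()] object.
#' @param exclusions Character vector of PTs to drop (case-insensitive).
#' @param min_n_report Drop PTs with fewer target records than this before
#'   reporting (defaults to the criteria's `min_n`).
#' @param signals_only Keep only rows with `signal == TRUE`.
#' @param sort_by `"ror"` (signal strength) or `"n"` (report frequency).
#' @return A ranked `data.table`: `pt`, `n`, statistics columns, rule flags.
#' @export
screen_all_pts <- function(records, drug, criteria = signal_criteria(),
                           exclusions = character(),
                           min_n_report = criteria$min_n,
                           signals_only = FALSE,
                           sort_by = c("ror", "n")) {
  sort_by <- match.arg(sort_by)
  records <- data.table::as.data.table(records)
  pt <- NULL
  if (length(exclusions)) {
    records <- records[!tolower(records$pt) %in% tolower(exclusions)]
  }
  n_drug <- sum(records$drug == drug)
  n_tot <- nrow(records)
  a_vec <- tapply(records$drug == drug, records$pt, sum)
  m_vec <- tapply(rep(1L, nrow(records)), records$pt, sum)
  pts <- names(a_vec)
  a <- as.numeric(a_vec)
  b <- n_drug - a
  c <- as.numeric(m_vec) - a
  d <- n_tot - n_drug - c
  keep <- a >= min_n_report
  stats <- disproportionality_stats(a[keep], b[keep], c[keep], d[keep])
  stats <- evaluate_signal(stats, criteria)
  stats[, "pt" := pts[keep]]
  data.table::setcolorder(stats, "pt")
  if (signals_only) stats <- stats[stats$signal]
  if (sort_by == "ror") {
    ord <- order(-data.table::fifelse(is.na(stats$ror), -Inf, stats$ror),
                 -stats$n, stats$pt)
  } else {
    ord <- order(-stats$n, stats$pt)
  }
  stats[ord]
}

#' System-organ-class profile of drug-event records
#'
#' Maps each record's PT to its SOC and tabulates per-drug record counts
#' and proportions (summing to 1 per drug). PTs absent from the mapping go
#' to an `"unmapped"` bucket with a warning.
#'
#' @param records Drug-event records (typically target drugs only).
#' @param pt_to_soc Two-column table (`pt`, `soc`); case-insensitive on PT.
#' @param drugs Drug labels to profile (default: target drugs present).
#' @return A `data.table`: `drug`, `soc`, `n`, `prop`.
#' @export
soc_profile <- function(records, pt_to_soc, drugs = NULL) {
  records <- data.table::as.data.table(records)
  pt_to_soc <- data.table::as.data.table(pt_to_soc)
  stopifnot(all(c("pt", "soc") %in% names(pt_to_soc)))
  if (is.null(drugs)) {
    drugs <- if ("is_target" %in% names(records)) {
      sort(unique(records$drug[records$is_target]))
    } else sort(unique(records$drug))
  }
  recs <- records[records$drug %in% drugs]
  soc <- pt_to_soc$soc[match(tolower(recs$pt), tolower(pt_to_soc$pt))]
  if (anyNA(soc)) {
    warning(sum(is.na(soc)), " record(s) with PTs missing from the ",
            "PT->SOC mapping assigned to 'unmapped'")
    soc[is.na(soc)] <- "unmapped"
  }
  out <- data.table::data.table(drug = recs$drug, soc = soc)
  out <- out[, list(n = .N), by = c("drug", "soc")]
  out[, "prop" := list(.SD$n / sum(.SD$n)), by = "drug"]
  data.table::setorderv(out, c("drug", "n"), c(1L, -1L))
  out[]
}

#' Bubble-plot table for SOC-level signal comparison
#'
#' Emits, per SOC, the plot-ready coordinates used in SOC signal panels:
#' x = log2(ROR), y = sqrt(chi-square), bubble size = N.
#'
#' @param screened Output of [screen_all_pts()].
#' @param pt_to_soc Two-column `pt`/`soc` mapping.
#' @return A `data.table`: `soc`, `pt`, `n`, `log2_ror`, `sqrt_chisq`.
#' @export
soc_bubble_table <- function(screened, pt_to_soc) {
  screened <- data.table::as.data.table(screened)
  pt_to_soc <- data.table::as.data.table(pt_to_soc)
  soc <- pt_to_soc$soc[match(tolower(screened$pt), tolower(pt_to_soc$pt))]
  soc[is.na(soc)] <- "unmapped"
  data.table::data.table(soc = soc, pt = screened$pt, n = screened$n,
                         log2_ror = log2(screened$ror),
                         sqrt_chisq = sqrt(screened$chisq))
}

#' Reconstruct a 2x2 table from printed summary statistics
#'
#' Completes a contingency table from the published case count `a`, the
#' drug's AE-record margin, and the printed PRR point estimate; when the
#' printed Pearson chi-square is also supplied, the unknown background
#' total `M = c + d` is solved numerically so the uncorrected chi-square of
#' the completed table equals it. Used for internal-consistency checks of
#' published signal tables.
#'
#' @param a Case count for the pair.
#' @param drug_total The drug's total AE-record margin (a + b).
#' @param prr Printed PRR point estimate.
#' @param chisq Printed Pearson chi-square (optional).
#' @return List with `a`, `b`, `c`, `d` (c, d are `NA` without `chisq`),
#'   the background event proportion `p`, and `ror` computed from the
#'   printed quantities.
#' @export
reconstruct_contingency <- function(a, drug_total, prr, chisq = NULL) {
  stopifnot(a > 0, drug_total > a, prr > 0)
  b <- drug_total - a
  p <- (a / drug_total) / prr   # background event proportion c/(c+d)
  stopifnot(p < 1)
  ror <- (a / b) / (p / (1 - p))
  cc <- dd <- NA_real_
  if (!is.null(chisq)) {
    chi_at <- function(M) {
      disproportionality_stats(a, b, p * M, (1 - p) * M)$chisq
    }
    sol <- stats::uniroot(function(M) chi_at(M) - chisq,
                          lower = drug_total, upper = 1e12, tol = 1e-8)
    M <- sol$root
    cc <- p * M
    dd <- (1 - p) * M
  }
  list(a = a, b = b, c = cc, d = dd, p = p, ror = ror)
}
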