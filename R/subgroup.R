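# Age-stratified signal screening with multiplicity adjustment.
# Strata use the cleaned age in years; records from reports with missing
# age are excluded from every stratum (they are tabulated separately in the
# descriptive summary, not silently assigned).

.age_strata <- c("<18", "18-65", ">=65")

#' Partition drug-event records by age band
#'
#' @param records Drug-event records from [build_records()].
#' @param reports Cleaned case reports from [build_case_reports()] (source
#'   of `age_years`).
#' @return Named list of record `data.table`s, one per stratum
#'   (`<18`, `18-65`, `>=65`); missing-age records appear in none.
#' @export
stratify_by_age <- function(records, reports) {
  records <- data.table::as.data.table(records)
  reports <- data.table::as.data.table(reports)
  age <- reports$age_years[match(records$primaryid, reports$primaryid)]
  band <- .age_band(age)
  out <- lapply(.age_strata, function(s) records[band == s])
  names(out) <- .age_strata
  out
}

#' Stratified signal screen with adjusted p-values
#'
#' Recomputes all disproportionality statistics within each age stratum —
#' the comparator background is the other drugs *in the same stratum*, so
#' stratified RORs are internally valid. Raw p-values come from the
#' uncorrected Pearson chi-square (1 df); adjustment is applied within each
#' stratum-by-drug family (Benjamini-Hochberg by default, Bonferroni
#' available). Volcano coordinates `log2(ROR)` and `-log10(p_adj)` are
#' emitted per PT.
#'
#' @param records Drug-event records (all drugs, all ages).
#' @param reports Cleaned case reports (for age).
#' @param drug Canonical drug label to screen.
#' @param criteria A [signal_criteria()] object.
#' @param exclusions PTs to drop before screening.
#' @param method Multiplicity adjustment: `"BH"` or `"bonferroni"`.
#' @return A `data.table`: `stratum`, `pt`, `n`, `ror`, `ic`, `chisq`,
#'   `p_raw`, `p_adj`, `log2_ror`, `neg_log10_p_adj`, `signal`.
#' @export
stratified_screen <- function(records, reports, drug,
                              criteria = signal_criteria(),
                              exclusions = character(),
                              method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  strata <- stratify_by_age(records, reports)
  out <- lapply(names(strata), function(s) {
    recs <- strata[[s]]
    if (!nrow(recs) || !any(recs$drug == drug)) {
      warning("stratum '", s, "' has no records for drug '", drug, "'")
      return(NULL)
    }
    sc <- screen_all_pts(recs, drug, criteria = criteria,
                         exclusions = exclusions)
    if (!nrow(sc)) return(NULL)
    p_raw <- stats::pchisq(sc$chisq, df = 1L, lower.tail = FALSE)
    p_adj <- stats::p.adjust(p_raw, method = method)
    data.table::data.table(stratum = s, pt = sc$pt, n = sc$n, ror = sc$ror,
                           ic = sc$ic, chisq = sc$chisq,
                           p_raw = p_raw, p_adj = p_adj,
                           log2_ror = log2(sc$ror),
                           neg_log10_p_adj = -log10(p_adj),
                           signal = sc$signal)
  })
  data.table::rbindlist(out)
}
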