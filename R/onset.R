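# Time-to-onset: extraction from THER/DEMO dates, two-parameter Weibull MLE
# with failure-pattern classification, Kaplan-Meier cumulative incidence,
# log-rank test, and a two-group Cox hazard ratio. Spontaneous reports carry
# only events, so all survival machinery runs uncensored.

#' Extract time-to-onset records for a target drug
#'
#' Onset is `event_dt - earliest start_dt` over the target drug's therapy
#' rows (linked via `dsg_drug_seq`), in days. Reports are excluded, with
#' reasons tallied, when either date is missing, partial, or malformed,
#' when the event precedes therapy start, or when the event post-dates the
#' report's `fda_dt` (an incorrect onset date). Same-day onsets (0 days)
#' are recoded to 0.5 days so the Weibull likelihood stays defined.
#'
#' @param dataset A deduplicated `faers_data` object.
#' @param drug Canonical drug label.
#' @param synonyms Synonym table for target-drug identification.
#' @param ps_only Restrict to reports naming the drug as primary suspect.
#' @return A `data.table` (`primaryid`, `drug`, `tto_days`) with attribute
#'   `exclusions`, a named integer vector of per-reason counts.
#' @export
extract_tto <- function(dataset, drug, synonyms = default_synonyms(),
                        ps_only = TRUE) {
  stopifnot(inherits(dataset, "faers_data"))
  dtab <- data.table::as.data.table(dataset$drug)
  label <- standardize_drug(dtab$drugname, dtab$prod_ai, synonyms)
  role <- toupper(trimws(as.character(dtab$role_cod)))
  keep <- !is.na(label) & label == drug
  if (ps_only) keep <- keep & role == "PS"
  dseq <- dtab[keep, c("primaryid", "drug_seq")]
  ther <- data.table::as.data.table(dataset$ther)
  ther <- merge(ther, dseq, by.x = c("primaryid", "dsg_drug_seq"),
                by.y = c("primaryid", "drug_seq"))
  excl <- c(no_therapy_row = 0L, start_unusable = 0L, event_unusable = 0L,
            negative_tto = 0L, future_dated = 0L)
  pids <- unique(dseq$primaryid)
  excl["no_therapy_row"] <- length(setdiff(pids, ther$primaryid))
  start <- parse_faers_date(ther$start_dt)
  ther[, "start_date" := start$date]
  ok_start <- ther[!is.na(ther$start_date)]
  data.table::setorderv(ok_start, c("primaryid", "start_date"))
  starts <- ok_start[!duplicated(ok_start$primaryid)] # earliest start per report
  excl["start_unusable"] <- length(setdiff(intersect(pids, ther$primaryid),
                                           starts$primaryid))
  demo <- data.table::as.data.table(dataset$demo)
  demo <- demo[demo$primaryid %in% starts$primaryid]
  ev <- parse_faers_date(demo$event_dt)
  fda <- parse_faers_date(demo$fda_dt)
  usable_ev <- ev$precision == "day"
  excl["event_unusable"] <- sum(!usable_ev)
  demo <- demo[usable_ev]
  ev_date <- ev$date[usable_ev]
  fda_date <- fda$date[usable_ev]
  idx <- match(demo$primaryid, starts$primaryid)
  tto <- as.numeric(ev_date - starts$start_date[idx])
  neg <- tto < 0
  fut <- !neg & !is.na(fda_date) & ev_date > fda_date
  excl["negative_tto"] <- sum(neg)
  excl["future_dated"] <- sum(fut)
  ok <- !neg & !fut
  tto <- tto[ok]
  tto[tto == 0] <- 0.5
  out <- data.table::data.table(primaryid = demo$primaryid[ok],
                                drug = drug, tto_days = tto)
  data.table::setattr(out, "exclusions", excl)
  out[]
}

# negative log-likelihood of a two-parameter Weibull on log(scale), log(shape);
# guarded so optimizer excursions return a large finite value, not NaN
.weibull_nll <- function(par, x) {
  if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e10)
  alpha <- exp(par[1L]); beta <- exp(par[2L])
  ll <- suppressWarnings(
    sum(stats::dweibull(x, shape = beta, scale = alpha, log = TRUE)))
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Two-parameter Weibull fit with failure-pattern classification
#'
#' Maximum-likelihood fit of an uncensored Weibull sample. The likelihood
#' is maximised over (log alpha, log beta) by BFGS; 95% confidence
#' intervals come from the observed information matrix on the log scale,
#' back-transformed. The failure pattern follows the shape parameter's CI
#' against 1: entirely below 1 is `early-failure` (decreasing hazard),
#' containing 1 is `random-failure`, entirely above is `wear-out`.
#'
#' @param times Positive onset times in days; `n >= 10` required.
#' @return A `weibull_fit`: list with `alpha`, `alpha_ci`, `beta`,
#'   `beta_ci`, `n`, `pattern`, `loglik`.
#' @export
fit_weibull <- function(times) {
  times <- as.numeric(times)
  stopifnot(all(is.finite(times)), all(times > 0))
  n <- length(times)
  if (n < 10L) stop("need at least 10 onset times, got ", n)
  if (stats::sd(times) == 0) {
    stop("all onset times identical; Weibull shape diverges")
  }
  # moment-style start: shape from log-time spread, scale from the mean
  lx <- log(times)
  beta0 <- max(0.05, min(20, 1.2 / stats::sd(lx)))
  alpha0 <- mean(times) / gamma(1 + 1 / beta0)
  opt <- stats::optim(c(log(alpha0), log(beta0)), .weibull_nll, x = times,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500L, reltol = 1e-12))
  if (opt$convergence != 0L) {
    stop("Weibull likelihood optimisation failed to converge (code ",
         opt$convergence, ")")
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    stop("observed information matrix is singular")
  })
  se <- sqrt(pmax(diag(vc), 0))
  est <- exp(opt$par)
  ci <- rbind(exp(opt$par[1L] + c(-1, 1) * 1.96 * se[1L]),
              exp(opt$par[2L] + c(-1, 1) * 1.96 * se[2L]))
  pattern <- if (ci[2L, 2L] < 1) "early-failure"
  else if (ci[2L, 1L] > 1) "wear-out"
  else "random-failure"
  structure(list(alpha = est[1L], alpha_ci = ci[1L, ],
                 beta = est[2L], beta_ci = ci[2L, ],
                 n = n, pattern = pattern, loglik = -opt$value),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "Weibull fit (n=%d): alpha=%.2f (%.2f, %.2f)  beta=%.3f (%.3f, %.3f)  %s\n",
    x$n, x$alpha, x$alpha_ci[1L], x$alpha_ci[2L],
    x$beta, x$beta_ci[1L], x$beta_ci[2L], x$pattern))
  invisible(x)
}

#' Kaplan-Meier cumulative incidence and onset-interval histogram
#'
#' With no censoring the cumulative incidence `1 - S(t)` equals the
#' empirical CDF; it is still computed through [survival::survfit()] so the
#' machinery extends unchanged if censoring were introduced. Also tabulates
#' report counts and percentages per onset interval.
#'
#' @param times_by_group Named list of positive onset-time vectors.
#' @param interval_width Width in days of the histogram bins (default 30).
#' @return List with `curves` (`data.table`: `group`, `time`, `cuminc`) and
#'   `intervals` (`data.table`: `group`, `interval`, `n`, `pct`).
#' @export
km_cumulative_incidence <- function(times_by_group, interval_width = 30) {
  stopifnot(length(times_by_group) >= 1L,
            all(vapply(times_by_group, length, integer(1L)) > 0L))
  if (is.null(names(times_by_group))) {
    names(times_by_group) <- paste0("group", seq_along(times_by_group))
  }
  curves <- data.table::rbindlist(lapply(names(times_by_group), function(g) {
    tt <- as.numeric(times_by_group[[g]])
    fit <- survival::survfit(survival::Surv(tt, rep(1L, length(tt))) ~ 1)
    data.table::data.table(group = g, time = fit$time,
                           cuminc = 1 - fit$surv)
  }))
  max_t <- max(unlist(times_by_group))
  breaks <- seq(0, ceiling(max_t / interval_width) * interval_width,
                by = interval_width)
  intervals <- data.table::rbindlist(lapply(names(times_by_group), function(g) {
    tt <- as.numeric(times_by_group[[g]])
    cut_idx <- cut(tt, breaks = breaks, include.lowest = TRUE, right = TRUE)
    cnt <- table(cut_idx)
    data.table::data.table(group = g, interval = names(cnt),
                           n = as.integer(cnt),
                           pct = 100 * as.integer(cnt) / length(tt))
  }))
  list(curves = curves, intervals = intervals)
}

#' Log-rank test between two uncensored onset-time samples
#'
#' @param times_a,times_b Non-empty numeric vectors of onset times.
#' @return List with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(times_a, times_b) {
  stopifnot(length(times_a) > 0L, length(times_b) > 0L)
  time <- c(as.numeric(times_a), as.numeric(times_b))
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(
    survival::Surv(time, rep(1L, length(time))) ~ grp)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(unname(sd$chisq), df = 1L, lower.tail = FALSE))
}

#' Two-group Cox proportional-hazards hazard ratio
#'
#' Univariate Cox partial likelihood with Efron tie handling (day-granular
#' onset times are heavily tied). The hazard ratio compares `group` against
#' the reference level, so with reference `risankizumab` an HR above 1
#' means earlier onset for the other drug.
#'
#' @param times Positive onset times (all events, no censoring).
#' @param group Two-level factor/character of group membership.
#' @param reference Reference level (default `"risankizumab"` if present,
#'   else the first sorted level).
#' @return A `cox_result`: list with `hr`, `hr_ci`, `coef`, `se`,
#'   `logrank_stat`, `logrank_p`, `n`.
#' @export
cox_hazard_ratio <- function(times, group, reference = NULL) {
  times <- as.numeric(times)
  group <- as.character(group)
  stopifnot(length(times) == length(group))
  lev <- sort(unique(group))
  if (length(lev) != 2L) stop("exactly two groups required, got ", length(lev))
  if (min(table(group)) < 2L) stop("need at least 2 events per group")
  if (is.null(reference)) {
    reference <- if ("risankizumab" %in% lev) "risankizumab" else lev[1L]
  }
  stopifnot(reference %in% lev)
  g <- factor(group, levels = c(reference, setdiff(lev, reference)))
  fit <- survival::coxph(
    survival::Surv(times, rep(1L, length(times))) ~ g,
    ties = "efron", control = survival::coxph.control(iter.max = 50L))
  if (!is.null(fit$info) || any(is.na(stats::coef(fit)))) {
    stop("Cox model failed to produce a finite coefficient")
  }
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 20) {
    stop("Cox model did not converge (possible complete separation)")
  }
  lr <- logrank_test(times[group == reference], times[group != reference])
  structure(list(hr = exp(beta), hr_ci = exp(beta + c(-1, 1) * 1.96 * se),
                 coef = beta, se = se,
                 logrank_stat = lr$statistic, logrank_p = lr$p,
                 n = length(times)),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox HR = %.3f (95%% CI %.3f-%.3f); log-rank chisq = %.2f, p = %.3g\n",
              x$hr, x$hr_ci[1L], x$hr_ci[2L], x$logrank_stat, x$logrank_p))
  invisible(x)
}

#' Onset summary table for two drugs
#'
#' Combines per-drug sample size, median (IQR), Weibull scale/shape with
#' CIs, and failure pattern into one table shaped like a published
#' time-to-onset summary.
#'
#' @param onset_by_drug Named list of onset-time vectors, one per drug.
#' @return A `data.table` with one row per drug.
#' @export
onset_summary_table <- function(onset_by_drug) {
  data.table::rbindlist(lapply(names(onset_by_drug), function(d) {
    tt <- as.numeric(onset_by_drug[[d]])
    fit <- fit_weibull(tt)
    qs <- stats::quantile(tt, c(0.25, 0.5, 0.75), names = FALSE)
    data.table::data.table(
      drug = d, n = length(tt), median = qs[2L], q1 = qs[1L], q3 = qs[3L],
      alpha = fit$alpha, alpha_lo = fit$alpha_ci[1L],
      alpha_hi = fit$alpha_ci[2L],
      beta = fit$beta, beta_lo = fit$beta_ci[1L], beta_hi = fit$beta_ci[2L],
      pattern = fit$pattern)
  }))
}
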