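# End-to-end orchestration: simulate/ingest -> clean -> screen -> SOC ->
# onset -> subgroup -> report. Every stage is a pure function of
# (inputs, config, seed); outputs are CSV files plus a run log.

#' Pipeline configuration
#'
#' Either `input_dir` (directories of FAERS-dialect quarters, one per
#' subdirectory or a single flat directory) or `synth` (a [synth_config()])
#' must be given.
#'
#' @param input_dir Directory of FAERS-dialect files, or `NULL`.
#' @param synth A [synth_config()] used when `input_dir` is `NULL`.
#' @param drugs Canonical target labels.
#' @param synonyms Synonym table (see [default_synonyms()]).
#' @param criteria A [signal_criteria()].
#' @param exclusions Character vector of indication-related PTs to exclude
#'   from screening (or a path to a one-column text file).
#' @param pt_to_soc `data.table(pt, soc)` mapping, a path to a two-column
#'   CSV, or `NULL` to skip the SOC profile.
#' @param output_dir Where result CSVs and the run log are written.
#' @param seed Seed applied before any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, synth = synth_config(),
                            drugs = c("risankizumab", "guselkumab"),
                            synonyms = default_synonyms(),
                            criteria = signal_criteria(),
                            exclusions = character(),
                            pt_to_soc = NULL,
                            output_dir = tempfile("faerscreen_run_"),
                            seed = 1L) {
  if (is.character(exclusions) && length(exclusions) == 1L &&
      file.exists(exclusions)) {
    exclusions <- readLines(exclusions, warn = FALSE)
    exclusions <- trimws(exclusions[trimws(exclusions) != ""])
  }
  if (is.character(pt_to_soc) && length(pt_to_soc) == 1L) {
    pt_to_soc <- data.table::fread(pt_to_soc, colClasses = "character")
  }
  structure(list(input_dir = input_dir, synth = synth, drugs = drugs,
                 synonyms = synonyms, criteria = criteria,
                 exclusions = exclusions, pt_to_soc = pt_to_soc,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_line <- function(log, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  c(log, msg)
}

#' Run the full screening pipeline
#'
#' Stages: (1) simulate or ingest quarters; (2) deduplicate and clean;
#' (3) build drug-event records; (4) descriptive summaries; (5) PT-level
#' screen per target drug; (6) SOC profile (if a mapping is supplied);
#' (7) time-to-onset (Weibull, KM, log-rank, Cox, needs both drugs with
#' >= 10 usable onsets); (8) age-stratified screen. Each stage's outputs
#' are written as CSVs under `config$output_dir`; a failure in any stage
#' halts with a stage-named error and removes partial outputs. The same
#' config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of all stage results plus `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  made <- character()
  log <- character()
  emit <- function(name, tab) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    data.table::fwrite(data.table::as.data.table(tab), path)
    made <<- c(made, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(made)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(config$seed)

  dataset <- stage("ingest", {
    if (is.null(config$input_dir)) {
      log <- .log_line(log, "ingest: synthetic dataset, seed ",
                       config$synth$seed)
      synth_generate(config$synth)$dataset
    } else {
      subdirs <- list.dirs(config$input_dir, recursive = FALSE)
      if (!length(subdirs)) subdirs <- config$input_dir
      log <- .log_line(log, "ingest: ", length(subdirs), " quarter(s) from ",
                       config$input_dir)
      link_quarters(lapply(subdirs, read_faers_quarter))
    }
  })

  clean <- stage("clean", {
    n_before <- nrow(dataset$demo)
    ds <- dedup_dataset(dataset)
    log <- .log_line(log, "clean: dedup removed ",
                     n_before - nrow(ds$demo), " of ", n_before,
                     " demo rows")
    ds
  })
  reports <- stage("clean", build_case_reports(clean))
  records <- stage("records", {
    r <- build_records(clean, config$synonyms, ps_only = TRUE)
    log <- .log_line(log, "records: ", nrow(r), " drug-event records; ",
                     attr(r, "n_reports_no_reac"),
                     " target report(s) without reactions")
    r
  })

  results <- list(dataset = clean, reports = reports, records = records)

  stage("describe", {
    results$demographics <- demographic_summary(reports, records,
                                                drugs = config$drugs)
    emit("table1_demographics", results$demographics)
    ic <- indication_concomitant_summary(clean, records, config$synonyms)
    results$indications <- ic$indications
    results$concomitant <- ic$concomitant
    emit("table2_indications", ic$indications)
    emit("table2_concomitant", ic$concomitant)
  })

  results$screen <- stage("screen", {
    scr <- lapply(config$drugs, function(d) {
      s <- screen_all_pts(records, d, criteria = config$criteria,
                          exclusions = config$exclusions)
      emit(paste0("signals_", d), s)
      s
    })
    names(scr) <- config$drugs
    log <- .log_line(log, "screen: ",
                     paste(config$drugs, vapply(scr, function(s)
                       sum(s$signal), numeric(1L)), collapse = "; "),
                     " positive signals")
    scr
  })

  if (!is.null(config$pt_to_soc)) {
    results$soc <- stage("soc", {
      p <- soc_profile(records, config$pt_to_soc, drugs = config$drugs)
      emit("soc_profile", p)
      p
    })
  }

  results$onset <- stage("onset", {
    tto <- lapply(config$drugs, function(d)
      extract_tto(clean, d, config$synonyms))
    names(tto) <- config$drugs
    onset_tab <- data.table::rbindlist(lapply(config$drugs, function(d)
      tto[[d]]))
    emit("onset_records", onset_tab)
    times <- lapply(tto, function(x) x$tto_days)
    enough <- vapply(times, length, integer(1L)) >= 10L
    res <- list(records = tto)
    if (all(enough) && length(times) == 2L) {
      res$summary <- onset_summary_table(times)
      emit("table5_onset_summary", res$summary)
      km <- km_cumulative_incidence(times)
      emit("fig4_km_curves", km$curves)
      emit("fig4_intervals", km$intervals)
      res$km <- km
      grp <- rep(names(times), vapply(times, length, integer(1L)))
      cox <- cox_hazard_ratio(unlist(times), grp)
      res$cox <- cox
      emit("cox_result", data.table::data.table(
        hr = cox$hr, hr_lo = cox$hr_ci[1L], hr_hi = cox$hr_ci[2L],
        logrank_stat = cox$logrank_stat, logrank_p = cox$logrank_p))
      log <- .log_line(log, sprintf(
        "onset: HR %.3f (%.3f-%.3f), log-rank p %.3g",
        cox$hr, cox$hr_ci[1L], cox$hr_ci[2L], cox$logrank_p))
    } else {
      log <- .log_line(log, "onset: skipped model fits (insufficient ",
                       "usable onset records)")
    }
    res
  })

  results$subgroup <- stage("subgroup", {
    sg <- lapply(config$drugs, function(d) {
      tab <- suppressWarnings(
        stratified_screen(records, reports, d, criteria = config$criteria,
                          exclusions = config$exclusions))
      emit(paste0("fig5_volcano_", d), tab)
      tab
    })
    names(sg) <- config$drugs
    sg
  })

  log <- .log_line(log, "done: ", length(made), " artifact(s) in ", out_dir)
  writeLines(log, file.path(out_dir, "run_log.txt"))
  results$log <- log
  results$artifacts <- made
  invisible(results)
}
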