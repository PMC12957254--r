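# FAERS quarterly ASCII dialect: "$"-delimited, header row first, no quoting,
# UTF-8 (invalid bytes replaced on read). Column names are lower-cased on read.

#' Table schemas of a FAERS quarterly extract
#'
#' The seven tables of a quarterly extract and the columns this package
#' requires from each. FAERS distributions carry additional columns; extras
#' are read and preserved, but the mandatory ones must be present.
#'
#' @format A named list; one character vector of mandatory column names per
#'   table (`demo`, `drug`, `reac`, `outc`, `rpsr`, `ther`, `indi`).
#' @export
faers_schemas <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "reporter_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  rpsr = c("primaryid", "rpsr_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

# columns coerced to numeric on read; everything else (including the date
# fields, which may be partial) stays character
.faers_numeric_cols <- c("age")

#' Read one FAERS-dialect table
#'
#' Reads a "$"-delimited FAERS ASCII table. Date fields are kept as raw
#' strings so that partial dates (YYYYMM, YYYY) and malformed values survive
#' ingestion; use [parse_faers_date()] to interpret them. Row count equals
#' the file's line count minus the header. An empty file yields an empty
#' table with the schema's columns.
#'
#' @param path Path to the table file.
#' @param schema_name One of `names(faers_schemas)`.
#' @return A `data.table` with lower-cased column names, all mandatory
#'   schema columns present, and `age` coerced to numeric.
#' @export
read_faers_table <- function(path, schema_name) {
  schema_name <- match.arg(schema_name, names(faers_schemas))
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- faers_schemas[[schema_name]]
  if (file.size(path) == 0L) {
    out <- data.table::as.data.table(
      stats::setNames(rep(list(character()), length(cols)), cols))
  } else {
    out <- data.table::fread(path, sep = "$", quote = "", header = TRUE,
                             colClasses = "character", na.strings = "",
                             encoding = "UTF-8", showProgress = FALSE)
    data.table::setnames(out, tolower(names(out)))
    missing_cols <- setdiff(cols, names(out))
    if (length(missing_cols)) {
      stop("table '", schema_name, "' is missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
    }
  }
  for (col in intersect(.faers_numeric_cols, names(out))) {
    data.table::set(out, j = col, value = suppressWarnings(as.numeric(out[[col]])))
  }
  out[]
}

#' Parse FAERS date strings
#'
#' FAERS dates are nominally 8-digit `YYYYMMDD` integers, but partial
#' (`YYYYMM`, `YYYY`), empty, and malformed values occur. Nothing is imputed:
#' each value is classified and only full-precision dates receive a `Date`.
#'
#' @param x Character (or numeric) vector of raw date fields.
#' @return A `data.table` with columns `raw`, `date` (`Date`, `NA` unless
#'   precision is `"day"`), and `precision` in
#'   `c("day", "month", "year", "missing", "invalid")`.
#' @export
parse_faers_date <- function(x) {
  raw <- as.character(x)
  trimmed <- trimws(raw)
  precision <- rep("invalid", length(raw))
  precision[is.na(trimmed) | trimmed == ""] <- "missing"
  precision[grepl("^\\d{4}$", trimmed)] <- "year"
  precision[grepl("^\\d{6}$", trimmed)] <- "month"
  is8 <- grepl("^\\d{8}$", trimmed)
  date <- rep(as.Date(NA), length(raw))
  if (any(is8)) {
    d <- as.Date(trimmed[is8], format = "%Y%m%d") # NA for e.g. month 13
    date[is8] <- d
    precision[is8] <- ifelse(is.na(d), "invalid", "day")
  }
  data.table::data.table(raw = raw, date = date, precision = precision)
}

#' Assemble a linked FAERS dataset from per-table data
#'
#' @param tables Named list with elements `demo`, `drug`, `reac`, `outc`,
#'   `rpsr`, `ther`, `indi` (missing ones become empty tables).
#' @param quarter Quarter label (e.g. `"24Q1"`) attached to every row as a
#'   `quarter` provenance column.
#' @return A `faers_data` object: a list of the seven data.tables.
#' @export
faers_data <- function(tables, quarter = NA_character_) {
  out <- lapply(names(faers_schemas), function(nm) {
    tab <- tables[[nm]]
    if (is.null(tab)) {
      tab <- data.table::as.data.table(
        stats::setNames(rep(list(character()), length(faers_schemas[[nm]])),
                        faers_schemas[[nm]]))
    }
    tab <- data.table::as.data.table(tab)
    for (col in setdiff(faers_schemas[[nm]], names(tab))) {
      data.table::set(tab, j = col, value = NA_character_)
    }
    if (!"quarter" %in% names(tab)) {
      data.table::set(tab, j = "quarter", value = quarter)
    }
    tab
  })
  names(out) <- names(faers_schemas)
  structure(out, class = "faers_data")
}

#' @export
print.faers_data <- function(x, ...) {
  cat("<faers_data>\n")
  for (nm in names(faers_schemas)) {
    cat(sprintf("  %-5s %8d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Read one quarter's seven tables from a directory
#'
#' Expects files named `DEMO<label>.txt`, `DRUG<label>.txt`, ... (case
#' insensitive). Absent optional tables become empty.
#'
#' @param dir Directory holding the seven files.
#' @param quarter Quarter label; defaults to the directory's basename.
#' @return A `faers_data` object.
#' @export
read_faers_quarter <- function(dir, quarter = basename(dir)) {
  files <- list.files(dir, full.names = TRUE)
  tables <- lapply(names(faers_schemas), function(nm) {
    hit <- files[grepl(paste0("^", nm), tolower(basename(files)))]
    if (!length(hit)) return(NULL)
    read_faers_table(hit[[1L]], nm)
  })
  names(tables) <- names(faers_schemas)
  faers_data(tables, quarter = quarter)
}

#' Write a dataset as one quarter of FAERS-dialect files
#'
#' Emits the seven "$"-delimited files (`DEMO<label>.txt`, ...) with header
#' rows; missing values become empty fields. `read_faers_quarter()` on the
#' result restores the dataset field-for-field.
#'
#' @param dataset A `faers_data` object.
#' @param dir Output directory (created if needed).
#' @param quarter Label used in the file names.
#' @return Invisibly, the paths written.
#' @export
write_faers_quarter <- function(dataset, dir, quarter = "24Q1") {
  stopifnot(inherits(dataset, "faers_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(faers_schemas), function(nm) {
    path <- file.path(dir, paste0(toupper(nm), quarter, ".txt"))
    tab <- data.table::copy(dataset[[nm]])
    tab[, "quarter" := NULL]
    data.table::fwrite(tab, path, sep = "$", quote = FALSE, na = "",
                       col.names = TRUE)
    path
  }, character(1L))
  invisible(paths)
}

#' Concatenate quarterly datasets into one linked dataset
#'
#' Duplicate `primaryid`/`caseid` values across quarters are retained here;
#' deduplication is a later cleaning stage. Row provenance is carried in the
#' per-row `quarter` column.
#'
#' @param quarters List of `faers_data` objects.
#' @return A single `faers_data` object.
#' @export
link_quarters <- function(quarters) {
  if (!length(quarters)) stop("at least one quarter is required")
  if (!all(vapply(quarters, inherits, logical(1L), "faers_data"))) {
    stop("all elements must be faers_data objects")
  }
  tables <- lapply(names(faers_schemas), function(nm) {
    parts <- lapply(quarters, `[[`, nm)
    cols <- lapply(parts, names)
    if (length(unique(lapply(cols, sort))) > 1L) {
      stop("conflicting schemas for table '", nm, "' across quarters")
    }
    data.table::rbindlist(parts, use.names = TRUE)
  })
  names(tables) <- names(faers_schemas)
  out <- tables
  class(out) <- "faers_data"
  out
}
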