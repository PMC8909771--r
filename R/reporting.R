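# Session records, per-target report tables, descriptive summaries
# (mean +/- sample SD, min, max) and deterministic CSV/JSON rendering.

.required_record_cols <- c("patient", "target", "size_cm", "distance_mm",
                           "time_min", "modality")

#' Load per-target session records from CSV
#'
#' The schema mirrors the per-target clinical report table: patient,
#' target, size_cm, distance_mm, time_min, modality, and optionally
#' margin_residual_pct plus the success flags. Decimal-comma cells
#' (e.g. "2,2") are normalized to decimal points with a warning.
#'
#' @param path CSV file path.
#' @return data.frame of typed records.
#' @export
loadSessionRecords <- function(path) {
    if (!file.exists(path)) .abort(sprintf("no such file: %s", path),
                                   "arguide_schema_error")
    df <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character"),
                   error = function(e) .abort(
                       sprintf("%s: %s", path, conditionMessage(e)),
                       "arguide_schema_error"))
    missing_cols <- setdiff(.required_record_cols, names(df))
    if (length(missing_cols))
        .abort(sprintf("missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "arguide_schema_error")
    if (nrow(df) == 0L)
        .abort(sprintf("%s: no records", path), "arguide_schema_error")
    df <- df[df$patient != "Overall", , drop = FALSE]

    numify <- function(col) {
        x <- df[[col]]
        comma <- grepl("^-?[0-9]+,[0-9]+$", x)
        if (any(comma)) {
            warning(sprintf(
                "column '%s': normalized decimal-comma cell(s) %s",
                col, paste(shQuote(x[comma]), collapse = ", ")))
            x[comma] <- sub(",", ".", x[comma], fixed = TRUE)
        }
        suppressWarnings(as.numeric(x))
    }
    num_cols <- intersect(c("size_cm", "distance_mm", "time_min",
                            "margin_residual_pct"), names(df))
    for (col in num_cols) df[[col]] <- numify(col)
    for (col in intersect(c("complete_ablation", "margin_success",
                            "technical_success"), names(df)))
        df[[col]] <- as.logical(df[[col]])

    if (any(!is.na(df$size_cm) & df$size_cm <= 0))
        .abort("size_cm must be > 0", "arguide_schema_error")
    if (any(!is.na(df$distance_mm) & df$distance_mm < 0))
        .abort("distance_mm must be >= 0", "arguide_schema_error")
    bad_mod <- !is.na(df$modality) & df$modality != "" &
        !(df$modality %in% c("US", "CT"))
    if (any(bad_mod))
        .abort(sprintf("modality must be US or CT (got %s)",
                       paste(unique(df$modality[bad_mod]), collapse = ", ")),
               "arguide_schema_error")
    df
}

#' Load per-target residual-margin records from CSV
#'
#' Schema: patient, target, margin_residual_pct (one row per lesion).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
loadMarginRecords <- function(path) {
    if (!file.exists(path)) .abort(sprintf("no such file: %s", path),
                                   "arguide_schema_error")
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("patient", "target", "margin_residual_pct") %in% names(df)))
        .abort("margin table needs patient, target, margin_residual_pct",
               "arguide_schema_error")
    if (nrow(df) == 0L) .abort(sprintf("%s: no records", path),
                               "arguide_schema_error")
    df <- df[df$patient != "Overall", , drop = FALSE]
    x <- df$margin_residual_pct
    comma <- grepl("^-?[0-9]+,[0-9]+$", x)
    if (any(comma)) {
        warning("normalized decimal-comma margin cell(s)")
        x[comma] <- sub(",", ".", x[comma], fixed = TRUE)
    }
    df$margin_residual_pct <- as.numeric(x)
    df
}

#' Packaged per-target fixture tables
#'
#' Paths to the per-target session table (15 targets: size, tip-to-target
#' distance, time to target, verification modality) and the residual
#' 5-mm margin table shipped with the package.
#'
#' @return file path.
#' @export
sessionTablePath <- function() {
    system.file("extdata", "session_targets.csv", package = "arguide",
                mustWork = TRUE)
}

#' @rdname sessionTablePath
#' @export
marginTablePath <- function() {
    system.file("extdata", "margin_residuals.csv", package = "arguide",
                mustWork = TRUE)
}

#' Summarize one numeric field of a record table
#'
#' Exact arithmetic on the stored values; rounding happens only at
#' presentation (one decimal, see \code{\link{formatSummary}}). The
#' dispersion is the sample standard deviation (n - 1 denominator); a
#' single record reports SD 0 with the singleton flag set.
#'
#' @param records data.frame of records.
#' @param field name of a numeric column.
#' @return A \linkS4class{SummaryStats}.
#' @export
summarizeRecords <- function(records, field) {
    if (!field %in% names(records))
        .abort(sprintf("no such field: %s", field), "arguide_summary_error")
    x <- records[[field]]
    x <- x[!is.na(x)]
    if (length(x) == 0L)
        .abort(sprintf("no values to summarize in '%s'", field),
               "arguide_summary_error")
    n <- length(x)
    new("SummaryStats", field = field, n = n, mean = mean(x),
        sd = if (n > 1L) stats::sd(x) else 0, min = min(x), max = max(x),
        singleton = n == 1L)
}

#' Present a summary as "mean +/- sd"
#'
#' @param s a \linkS4class{SummaryStats}.
#' @param digits presentation decimals (default 1).
#' @return character scalar like \code{"3.2 ± 0.7"}.
#' @export
formatSummary <- function(s, digits = 1L) {
    sprintf("%s ± %s", formatC(round(s@mean, digits), format = "f",
                                    digits = digits),
            formatC(round(s@sd, digits), format = "f", digits = digits))
}

setMethod("show", "SummaryStats", function(object) {
    cat(sprintf("SummaryStats[%s] | n=%d | %s (range %.1f-%.1f)%s\n",
                object@field, object@n, formatSummary(object),
                object@min, object@max,
                if (object@singleton) " | singleton" else ""))
})

#' Render session records to deterministic CSV and JSON reports
#'
#' Writes a per-target CSV mirroring the session table layout with an
#' "Overall" row (mean +/- SD at one decimal), a residual-margin CSV when
#' margins are present, and a JSON report carrying the records, the
#' summaries at full precision, and every configurable setting supplied
#' via \code{settings} (so each run is self-describing). Output bytes are
#' deterministic for fixed input.
#'
#' @param records data.frame of session records.
#' @param dir output directory (created if needed).
#' @param settings named list of thresholds/flags to log in the JSON.
#' @return invisible character vector of the files written.
#' @export
renderReport <- function(records, dir, settings = list()) {
    if (!dir.exists(dir)) {
        ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        if (!ok && !dir.exists(dir))
            .abort(sprintf("cannot create output directory %s", dir),
                   "arguide_io_error")
    }
    files <- character(0)

    fmt_num <- function(x) ifelse(is.na(x), "",
                                  format(x, digits = 15, trim = TRUE,
                                         scientific = FALSE))
    sess_cols <- intersect(c(.required_record_cols, "margin_residual_pct",
                             "complete_ablation", "margin_success",
                             "technical_success"), names(records))
    out <- records[, sess_cols, drop = FALSE]
    for (cl in sess_cols)
        if (is.numeric(out[[cl]])) out[[cl]] <- fmt_num(out[[cl]])

    summaries <- list()
    if (nrow(records) > 0L) {
        for (f in intersect(c("size_cm", "distance_mm", "time_min",
                              "margin_residual_pct"), names(records))) {
            if (all(is.na(records[[f]]))) next
            summaries[[f]] <- summarizeRecords(records, f)
        }
        overall <- out[1L, , drop = FALSE]
        overall[1L, ] <- ""
        overall$patient <- "Overall"
        for (f in names(summaries))
            if (f %in% names(overall))
                overall[[f]] <- formatSummary(summaries[[f]])
        out <- rbind(out, overall)
    }
    sess_path <- file.path(dir, "session_report.csv")
    write.csv(out, sess_path, row.names = FALSE, quote = TRUE)
    files <- c(files, sess_path)

    if ("margin_residual_pct" %in% names(records) && nrow(records) > 0L) {
        mg <- records[, c("patient", "target", "margin_residual_pct")]
        mg$margin_residual_pct <- fmt_num(mg$margin_residual_pct)
        mo <- data.frame(patient = "Overall", target = "",
                         margin_residual_pct =
                             formatSummary(summaries$margin_residual_pct),
                         stringsAsFactors = FALSE)
        mg_path <- file.path(dir, "margin_report.csv")
        write.csv(rbind(mg, mo), mg_path, row.names = FALSE, quote = TRUE)
        files <- c(files, mg_path)
    }

    json <- list(
        schema = "arguide-report/1",
        records = records,
        summaries = lapply(summaries, function(s)
            list(n = s@n, mean = s@mean, sd = s@sd, min = s@min,
                 max = s@max)),
        settings = settings)
    json_path <- file.path(dir, "report.json")
    jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, json_path)
    invisible(files)
}
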