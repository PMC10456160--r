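#' Read a delimited response matrix
#'
#' Reads integer item responses from a CSV/TSV file, one row per
#' respondent and one column per item. The delimiter is auto-detected
#' between tab and comma (whitespace as a fallback) unless given; a
#' header row of item labels is auto-detected unless `header` is set.
#'
#' @param path file path.
#' @param delimiter field separator, or `NULL` to auto-detect.
#' @param header logical, or `NA` to auto-detect from the first row.
#' @param categories declared category ranges, see [response_matrix()].
#' @return a [response_matrix()].
#' @export
read_responses <- function(path, delimiter = NULL, header = NA,
                           categories = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file")
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", first)) "\t"
    else if (grepl(",", first)) ","
    else ""
  }
  if (is.na(header)) {
    fields <- strsplit(first, if (delimiter == "") "[[:space:]]+" else delimiter,
                       fixed = delimiter != "")[[1L]]
    header <- anyNA(suppressWarnings(as.numeric(fields)))
  }
  df <- utils::read.table(path, sep = delimiter, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fill = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric value at row %d, column %d",
                   bad[1L, 1L], bad[1L, 2L]))
    storage.mode(m) <- "numeric"
  }
  response_matrix(m, categories = categories,
                  item_labels = if (header) colnames(df) else NULL)
}

#' Write a screening report
#'
#' JSON keeps the full report (coordinates, intervals, flags, kept set);
#' TSV writes the tabular part with a fixed column order: label, P,
#' P_lo, P_hi, h, h_lo, h_hi, MSA, PIE, R-PIE, decision.
#'
#' @param report a `gpool_screen` result or a `gpool_flags` table.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv"),
                         force = FALSE) {
  format <- match.arg(format)
  if (file.exists(path) && !force)
    stop(sprintf("refusing to overwrite %s (use force = TRUE)", path))
  flags <- if (inherits(report, "gpool_screen")) report$report else report
  stopifnot(inherits(flags, "gpool_flags"))
  if (format == "tsv") {
    cols <- c("label", "P", "P_lo", "P_hi", "h", "h_lo", "h_hi", "msa",
              "pie", "r_pie", "decision")
    utils::write.table(flags[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    payload <- if (inherits(report, "gpool_screen")) {
      list(model = report$model, region = unclass(report$region),
           bootstrap = list(B = report$bootstrap$B,
                            level = report$bootstrap$level,
                            n_dropped = report$bootstrap$n_dropped),
           seed = report$seed, items = flags, kept = report$kept)
    } else {
      list(items = flags)
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Read back a JSON screening report
#'
#' @param path file written by [write_report()] in JSON format.
#' @return list with the report contents; the `items` element is a data
#'   frame.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write the simulation summary as TSV
#'
#' @param study a `gpool_study` from [run_study()].
#' @param path output file.
#' @param outcomes also write the per-replicate outcomes (classification
#'   and focal coordinates) alongside as `<path>.outcomes.tsv`.
#' @param force overwrite existing files.
#' @return `path`, invisibly.
#' @export
write_study_summary <- function(study, path, outcomes = FALSE,
                                force = FALSE) {
  stopifnot(inherits(study, "gpool_study"))
  if (file.exists(path) && !force)
    stop(sprintf("refusing to overwrite %s (use force = TRUE)", path))
  utils::write.table(study_table(study), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (outcomes) {
    utils::write.table(study$outcomes, paste0(path, ".outcomes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
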