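#' Read a cohort table from CSV, TSV or SAS-XPORT
#'
#' Reads the file, optionally renames columns via a mapping (survey variable
#' names rarely match analysis names), lower-cases gender labels, and
#' coerces biomarker columns to numeric. Unparseable numeric cells become
#' missing values; their count is recorded in the attached read log rather
#' than failing the whole row.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"xpt"`
#'   (SAS transport, the NHANES distribution format).
#' @param column_map Named character vector mapping file column names to
#'   canonical names, e.g. `c(LBXSCR = "creatinine", RIDAGEYR = "ca")`.
#' @param numeric_cols Columns to coerce to numeric; defaults to every
#'   column except `subject_id`, `gender` and `group`.
#' @return Data frame with attribute `"read_log"` (list with
#'   `n_unparseable`). Requires `ca` and `gender` columns after mapping.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "tsv", "xpt"),
                        column_map = NULL, numeric_cols = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("read_cohort: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", xpt = "xpt",
                     stop_config("read_cohort: unknown format '", ext, "'"))
  }
  raw <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE),
    xpt = foreign::read.xport(path))
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- unname(column_map[names(raw)[hit]])
  }
  if (!all(c("ca", "gender") %in% names(raw))) {
    stop_schema("read_cohort: mandatory columns `ca` and `gender` not found",
                " (after column mapping)")
  }
  raw$gender <- tolower(as.character(raw$gender))
  if (is.null(numeric_cols)) {
    numeric_cols <- setdiff(names(raw), c("subject_id", "gender", "group"))
  }
  n_unparseable <- 0L
  for (m in numeric_cols) {
    if (is.numeric(raw[[m]])) next
    parsed <- suppressWarnings(as.numeric(raw[[m]]))
    n_unparseable <- n_unparseable +
      sum(is.na(parsed) & !is.na(raw[[m]]) & nzchar(trimws(raw[[m]])))
    raw[[m]] <- parsed
  }
  if (!"subject_id" %in% names(raw)) {
    raw$subject_id <- sprintf("row%05d", seq_len(nrow(raw)))
  }
  attr(raw, "read_log") <- list(n_unparseable = n_unparseable,
                                format = format, n_rows = nrow(raw))
  raw
}

#' Write a cohort or result table as CSV
#'
#' @param data Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
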