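# On-disk dialect: plain TSV, one leading comment line carrying the schema
# name, version and any scalar attributes, e.g.
#   # ftcdlat recording v1 child=P001_1 sampling_rate=25
# Recordings have columns time_s, left_cm_s, right_cm_s; trial markers live
# in a sidecar table (child_id, trial, onset_s, valid, word_count). This
# format is an invention of this package for synthetic and adapted data;
# it is not the format of any public fTCD deposit.

header_line <- function(schema, attrs = character()) {
  a <- if (length(attrs))
    paste(" ", paste(names(attrs), unname(attrs), sep = "=", collapse = " "))
  else ""
  sprintf("# ftcdlat %s v1%s", schema, a)
}

parse_header <- function(path, schema) {
  h <- readLines(path, n = 1)
  if (!startsWith(h, sprintf("# ftcdlat %s v1", schema)))
    stop("malformed file (expected ", schema, " header): ", path)
  toks <- strsplit(sub(sprintf("^# ftcdlat %s v1 ?", schema), "", h), " ")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(list())
  kv <- strsplit(toks, "=")
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
}

write_tsv_with_header <- function(df, path, schema, attrs = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_line(schema, attrs), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_with_header <- function(path, schema) {
  parse_header(path, schema)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a recording in the package's TSV dialect
#'
#' A recording file holds the time grid and both velocity channels; trial
#' markers are written to a shared sidecar table (see
#' [write_markers()]). The header comment line carries the schema version,
#' child id and sampling rate.
#'
#' @param rec an [ftcd_recording()].
#' @param path file path.
#' @return `write_recording()` returns the path invisibly;
#'   `read_recording()` returns an [ftcd_recording()] (markers must be
#'   supplied from the sidecar).
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = rec$time, left_cm_s = rec$left,
                   right_cm_s = rec$right)
  write_tsv_with_header(df, path, "recording",
                        c(child = rec$child_id,
                          sampling_rate = format(rec$sampling_rate)))
}

#' @rdname write_recording
#' @param markers marker rows for this child (columns `trial`, `onset_s`,
#'   `valid`, `word_count`).
#' @export
read_recording <- function(path, markers) {
  at <- parse_header(path, "recording")
  df <- utils::read.delim(path, comment.char = "#")
  ftcd_recording(as.character(at$child), as.numeric(at$sampling_rate),
                 df$time_s, df$left_cm_s, df$right_cm_s,
                 markers[c("trial", "onset_s", "valid", "word_count")])
}

#' Write / read the trial-marker sidecar table
#'
#' One row per administered trial across all children: `child_id`, `trial`,
#' `onset_s` (talk onset), `valid` (behavioural flag), `word_count`.
#'
#' @param markers data frame.
#' @param path file path.
#' @export
write_markers <- function(markers, path)
  write_tsv_with_header(markers, path, "markers")

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  df <- read_tsv_with_header(path, "markers")
  df$valid <- as.logical(df$valid)
  df
}

#' Write / read a generic cohort-level table
#'
#' Used for the cohort metadata, ground truth, per-trial metadata and
#' laterality-results tables; the schema name in the header line documents
#' which.
#'
#' @param df data frame.
#' @param path file path.
#' @param schema schema name (e.g. `"cohort"`, `"truth"`, `"trials"`,
#'   `"results"`).
#' @export
write_cohort_table <- function(df, path, schema = "cohort")
  write_tsv_with_header(df, path, schema)

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path, schema = "cohort")
  read_tsv_with_header(path, schema)
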