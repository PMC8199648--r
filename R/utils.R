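`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a numeric value for byte-stable text output
#'
#' All writers funnel numbers through this so that two runs with identical
#' inputs produce byte-identical files.
#' @param x numeric vector
#' @return character vector
#' @keywords internal
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.10g", v)
  }, character(1))
  out
}

#' Write a data frame as a deterministic TSV
#'
#' Fixed column order (as given), fixed float formatting, LF line endings,
#' no quoting. Companion reader: [read_tsv()].
#' @param df data frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(is.na(out[[j]]), "NA", ifelse(out[[j]], "TRUE", "FALSE"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (or any plain tab-delimited table)
#' @param path input path
#' @return data frame
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Append a line to a run log (no timestamps, so runs stay byte-identical)
#' @keywords internal
log_line <- function(dir, ...) {
  if (is.null(dir)) return(invisible(NULL))
  cat(paste0(..., "\n"), file = file.path(dir, "run_log.txt"), append = TRUE)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Canonical unordered pair key
#' @keywords internal
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}
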