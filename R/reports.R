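#' Write an analysis product as a tab-delimited report
#'
#' Serialises a data frame (or an object with a [tidy()] method) as a
#' tab-delimited table with column headers, preceded by `#`-prefixed
#' provenance lines (arbitrary key-value metadata such as seeds and
#' thresholds). Reports in reference numbering keep the heavy-chain
#' position column first. [read_report()] parses the same format back.
#'
#' @param x a data frame, or an object with a `tidy()` method.
#' @param path output file.
#' @param meta named list of provenance values written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, meta = list()) {
  if (!is.data.frame(x)) x <- tidy(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15), collapse = " ")), con)
  }
  write.table(as.data.frame(x), con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()`: a tibble; provenance lines are returned in
#'   the `"meta"` attribute.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- sub("^#\\s*", "", lines[is_meta])
  body <- lines[!is_meta]
  if (length(body) < 1) abort(sprintf("report '%s' has no table", path))
  df <- read.table(
    text = paste(body, collapse = "\n"), header = TRUE,
    sep = "\t", stringsAsFactors = FALSE
  )
  out <- as_tibble(df)
  attr(out, "meta") <- meta
  out
}
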