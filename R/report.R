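#' Write a TSV report with a parameter comment block
#'
#' All tabular outputs use tab-separated values with a leading `#` comment
#' block recording the parameters that produced them.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list recorded as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params) > 0L)
    writeLines(sprintf("# %s: %s", names(params),
                       vapply(params, function(p)
                         paste(format(p), collapse = " "), character(1))),
               con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report
#'
#' @param path file written by [write_tsv_report()].
#' @return data.frame; the comment block is attached as the `"params"`
#'   attribute (named character vector).
#' @export
read_tsv_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  kv <- kv[lengths(kv) == 3L]
  attr(df, "params") <- stats::setNames(vapply(kv, `[`, character(1), 3L),
                                        vapply(kv, `[`, character(1), 2L))
  df
}
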