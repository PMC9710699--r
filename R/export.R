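# CSV export (RFC 4180-style quoting).

#' Export a result table to CSV
#'
#' Writes a header line of column names followed by one line per row.
#' Fields containing the delimiter, a double quote or a newline are
#' double-quoted with embedded quotes doubled; missing values are written
#' as empty fields; output is UTF-8. On write failure the partial file is
#' removed.
#'
#' @param rows A `data.table`/data.frame, e.g. from [execute_plan()].
#' @param path Destination file path.
#' @param delimiter Field delimiter (default `","`).
#' @return The number of data rows written, invisibly.
#' @export
export_csv <- function(rows, path, delimiter = ",") {
  ok <- FALSE
  on.exit(if (!ok && file.exists(path)) unlink(path))
  data.table::fwrite(rows, path, sep = delimiter, quote = "auto", na = "",
                     bom = FALSE, eol = "\n")
  ok <- TRUE
  invisible(nrow(rows))
}
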