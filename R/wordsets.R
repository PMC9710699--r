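# Wordsets: named sets of strings (typically gene symbols) used in
# membership filters (field IN WORDSET 'name').

#' Create a wordset from plain-text lines
#'
#' One term per line; surrounding whitespace and blank lines are stripped,
#' duplicates collapsed, case preserved. An empty result is an error.
#'
#' @param store A `variant_store`.
#' @param name Wordset name (not a reserved word).
#' @param lines Character vector of lines, or a file path.
#' @param overwrite Replace an existing wordset of the same name.
#' @return The word vector, invisibly.
#' @export
create_wordset <- function(store, name, lines, overwrite = FALSE) {
  check_selection_name(name)
  if (!overwrite && !is.null(store$wordsets[[name]]))
    vql_validation_error(paste0("wordset ", sQuote(name),
                                " already exists (use overwrite)"))
  if (length(lines) == 1L && !grepl("\n", lines) && file.exists(lines))
    lines <- readLines(lines, warn = FALSE)
  words <- unique(trimws(lines))
  words <- words[nzchar(words)]
  if (!length(words))
    vql_validation_error(paste0("wordset ", sQuote(name), " would be empty"))
  store$wordsets[[name]] <- words
  invisible(words)
}

#' Drop a wordset
#'
#' @param store A `variant_store`.
#' @param name Wordset name.
#' @return `TRUE` invisibly.
#' @export
drop_wordset <- function(store, name) {
  if (is.null(store$wordsets[[name]]))
    vql_validation_error(paste0("unknown wordset: ", sQuote(name)))
  store$wordsets[[name]] <- NULL
  invisible(TRUE)
}
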