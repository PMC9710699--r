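# Internal helpers: error conditions, name normalization, RNG scoping.

vql_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "vql_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

vql_syntax_error <- function(msg, line = NA_integer_, col = NA_integer_,
                             token = NA_character_) {
  loc <- if (!is.na(line)) sprintf(" at line %d, column %d", line, col) else ""
  tok <- if (!is.na(token)) sprintf(" near %s", sQuote(token)) else ""
  vql_error(paste0("VQL syntax error", loc, tok, ": ", msg),
            "vql_syntax_error", line = line, col = col, token = token)
}

vql_validation_error <- function(msg) {
  vql_error(paste0("VQL validation error: ", msg), "vql_validation_error")
}

#' @noRd
normalize_name <- function(x) {
  x <- tolower(x)
  gsub("[^a-z0-9_]+", "_", x)
}

# Run code with a private, restorable RNG state so generators are
# deterministic without clobbering the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Missing-aware scalar accessor
`%||%` <- function(a, b) if (is.null(a)) b else a

is_missing_value <- function(v) {
  is.null(v) || length(v) == 0L || (length(v) == 1L && is.na(v)) ||
    (is.character(v) && length(v) == 1L && !is.na(v) && v == "")
}

# variant identity tuple rendered as a stable string key
make_variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
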