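# VQL tokenizer.
#
# Keywords are case-insensitive; identifiers are lowercased; string
# literals are single-quoted, with typographic (curly) quotes accepted as
# equivalent to straight ones so queries pasted from formatted documents
# still parse.

VQL_KEYWORDS <- c("select", "from", "where", "order", "by", "limit",
                  "offset", "create", "drop", "import", "wordset",
                  "selection", "intersect", "in", "not", "and", "or",
                  "is", "null", "asc", "desc", "samples", "as")

QUOTE_CHARS <- c("'", "‘", "’", "“", "”", '"')

vql_token <- function(type, value, line, col) {
  list(type = type, value = value, line = line, col = col)
}

vql_tokenize <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  tokens <- list()
  i <- 1L; line <- 1L; col <- 1L
  advance <- function(k) {
    for (j in seq_len(k)) {
      if (chars[i + j - 1L] == "\n") { line <<- line + 1L; col <<- 1L }
      else col <<- col + 1L
    }
    i <<- i + k
  }
  two_char_ops <- c("!=", "<=", ">=")
  one_char_ops <- c("=", "<", ">", "~", "&", "|", "-", "+", ".", ",",
                    "(", ")", "[", "]", ";")
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[ \t\r\n]$", ch)) { advance(1L); next }
    tl <- line; tc <- col
    # string literal
    if (ch %in% QUOTE_CHARS) {
      j <- i + 1L
      while (j <= n && !(chars[j] %in% QUOTE_CHARS)) j <- j + 1L
      if (j > n)
        vql_syntax_error("unterminated string literal", tl, tc)
      value <- paste(chars[seq.int(i + 1L, length.out = j - i - 1L)],
                     collapse = "")
      tokens[[length(tokens) + 1L]] <- vql_token("STRING", value, tl, tc)
      advance(j - i + 1L)
      next
    }
    # number
    if (grepl("^[0-9]$", ch)) {
      rest <- paste(chars[i:n], collapse = "")
      m <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", rest))
      tokens[[length(tokens) + 1L]] <- vql_token("NUMBER", m, tl, tc)
      advance(nchar(m))
      next
    }
    # identifier / keyword
    if (grepl("^[A-Za-z_]$", ch)) {
      rest <- paste(chars[i:n], collapse = "")
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      low <- tolower(m)
      type <- if (low %in% VQL_KEYWORDS) "KEYWORD" else "IDENT"
      tokens[[length(tokens) + 1L]] <- vql_token(type, low, tl, tc)
      advance(nchar(m))
      next
    }
    # operators / punctuation
    pair <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (pair %in% two_char_ops) {
      tokens[[length(tokens) + 1L]] <- vql_token("OP", pair, tl, tc)
      advance(2L)
      next
    }
    if (ch %in% one_char_ops) {
      tokens[[length(tokens) + 1L]] <- vql_token("OP", ch, tl, tc)
      advance(1L)
      next
    }
    vql_syntax_error("unexpected character", tl, tc, token = ch)
  }
  tokens[[length(tokens) + 1L]] <- vql_token("EOF", "", line, col)
  tokens
}
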