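# VQL recursive-descent parser.
#
# Grammar (EBNF sketch):
#   statement := select | create | drop | import_wordset
#   select    := SELECT fieldlist FROM ident [WHERE expr]
#                [ORDER BY orderlist] [LIMIT int [OFFSET int]]
#   create    := CREATE ident ( '=' ident setop ident
#                             | FROM ident [WHERE expr] [INTERSECT string] )
#   drop      := DROP (SELECTION | WORDSET) ident
#   import_wordset := IMPORT WORDSET string AS ident
#   setop     := '&' | '|' | '-'
#   field     := ident | ann '.' ident | samples '[' string ']' '.' ident
#   expr      := or;  or := and (OR and)*;  and := unary (AND unary)*
#   unary     := NOT unary | '(' expr ')' | comparison
#   comparison:= field ( cmpop literal | [NOT] IN '(' literals ')'
#              | '~' string | IN WORDSET name | IS [NOT] NULL )
# Operator precedence: NOT > AND > OR; parentheses override.

field_ref <- function(namespace, name, sample = NULL) {
  structure(list(namespace = namespace, name = name, sample = sample),
            class = "vql_field")
}

filter_leaf <- function(field, op, value = NULL) {
  list(type = "cmp", field = field, op = op, value = value)
}

filter_branch <- function(type, children) {
  list(type = type, children = children)
}

new_parser <- function(text) {
  env <- new.env(parent = emptyenv())
  env$tokens <- vql_tokenize(text)
  env$pos <- 1L
  env
}

peek <- function(p, offset = 0L) p$tokens[[p$pos + offset]]
advance_token <- function(p) { t <- p$tokens[[p$pos]]; p$pos <- p$pos + 1L; t }

expect_token <- function(p, type, value = NULL, what = NULL) {
  t <- peek(p)
  ok <- t$type == type && (is.null(value) || t$value == value)
  if (!ok)
    vql_syntax_error(paste0("expected ", what %||% value %||% type),
                     t$line, t$col, token = if (t$type == "EOF") "end of input" else t$value)
  advance_token(p)
}

at_keyword <- function(p, kw) {
  t <- peek(p)
  t$type == "KEYWORD" && t$value == kw
}

accept_keyword <- function(p, kw) {
  if (at_keyword(p, kw)) { advance_token(p); TRUE } else FALSE
}

# identifiers may be bare IDENTs; a few keywords (samples, wordset, ...)
# never appear where a selection/field name is expected, so require IDENT.
expect_ident <- function(p, what) {
  t <- peek(p)
  if (t$type != "IDENT")
    vql_syntax_error(paste0("expected ", what),
                     t$line, t$col, token = if (t$type == "EOF") "end of input" else t$value)
  advance_token(p)$value
}

#' Parse a VQL statement
#'
#' Parses one VQL statement into its abstract syntax tree. Keywords are
#' case-insensitive, identifiers are lowercased, string literals are
#' single-quoted (typographic curly quotes are accepted as equivalent).
#' Operator precedence in filters is `NOT` > `AND` > `OR`, with
#' parentheses overriding.
#'
#' Statement kinds: `SELECT ... FROM ... [WHERE ...] [ORDER BY ...]
#' [LIMIT n [OFFSET m]]`; `CREATE name FROM source [WHERE ...]
#' [INTERSECT 'file.bed']`; `CREATE name = a & b` (also `|`, `-`);
#' `DROP SELECTION|WORDSET name`; `IMPORT WORDSET 'file' AS name`.
#'
#' @param text VQL statement text.
#' @return The AST: a list whose `kind` is one of `select`,
#'   `create_selection`, `create_from_setop`, `create_from_bed`, `drop`,
#'   `import_wordset`.
#' @examples
#' ast <- parse_vql("SELECT chr, pos FROM variants WHERE ann.impact = 'HIGH'")
#' ast$kind
#' @export
parse_vql <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    vql_syntax_error("empty query")
  p <- new_parser(text)
  t <- peek(p)
  ast <-
    if (at_keyword(p, "select")) parse_select(p)
    else if (at_keyword(p, "create")) parse_create(p)
    else if (at_keyword(p, "drop")) parse_drop(p)
    else if (at_keyword(p, "import")) parse_import_wordset(p)
    else vql_syntax_error("expected SELECT, CREATE, DROP or IMPORT",
                          t$line, t$col, token = t$value)
  if (peek(p)$type == "OP" && peek(p)$value == ";") advance_token(p)
  t <- peek(p)
  if (t$type != "EOF")
    vql_syntax_error("trailing input after statement", t$line, t$col,
                     token = t$value)
  ast
}

parse_select <- function(p) {
  expect_token(p, "KEYWORD", "select")
  if (at_keyword(p, "from"))
    vql_syntax_error("empty select list", peek(p)$line, peek(p)$col,
                     token = "from")
  select_list <- list(parse_field(p))
  while (peek(p)$type == "OP" && peek(p)$value == ",") {
    advance_token(p)
    select_list[[length(select_list) + 1L]] <- parse_field(p)
  }
  expect_token(p, "KEYWORD", "from")
  source <- expect_ident(p, "selection name after FROM")
  filter <- NULL
  if (accept_keyword(p, "where")) filter <- parse_expr(p)
  order_by <- list()
  if (accept_keyword(p, "order")) {
    expect_token(p, "KEYWORD", "by")
    repeat {
      f <- parse_field(p)
      dir <- if (accept_keyword(p, "desc")) "desc"
        else { accept_keyword(p, "asc"); "asc" }
      order_by[[length(order_by) + 1L]] <- list(field = f, dir = dir)
      if (peek(p)$type == "OP" && peek(p)$value == ",") advance_token(p)
      else break
    }
  }
  limit <- NULL; offset <- NULL
  if (accept_keyword(p, "limit")) {
    limit <- parse_int(p, "LIMIT")
    if (accept_keyword(p, "offset")) offset <- parse_int(p, "OFFSET")
  }
  list(kind = "select", select_list = select_list, source = source,
       filter = filter, order_by = order_by, limit = limit, offset = offset)
}

parse_int <- function(p, what) {
  t <- expect_token(p, "NUMBER", what = paste0("integer after ", what))
  v <- as.numeric(t$value)
  if (v != floor(v))
    vql_syntax_error(paste0(what, " must be an integer"), t$line, t$col,
                     token = t$value)
  as.integer(v)
}

parse_create <- function(p) {
  expect_token(p, "KEYWORD", "create")
  if (accept_keyword(p, "wordset")) {
    # CREATE WORDSET name FROM 'file' (alias of IMPORT WORDSET 'file' AS name)
    name <- expect_ident(p, "wordset name")
    expect_token(p, "KEYWORD", "from")
    path <- expect_token(p, "STRING", what = "quoted file path")$value
    return(list(kind = "import_wordset", name = name, path = path))
  }
  name <- expect_ident(p, "selection name after CREATE")
  t <- peek(p)
  if (t$type == "OP" && t$value == "=") {
    advance_token(p)
    left <- expect_ident(p, "selection name")
    opt <- peek(p)
    if (!(opt$type == "OP" && opt$value %in% c("&", "|", "-")))
      vql_syntax_error("expected set operator '&', '|' or '-'",
                       opt$line, opt$col, token = opt$value)
    advance_token(p)
    right <- expect_ident(p, "selection name")
    return(list(kind = "create_from_setop", name = name, left = left,
                op = opt$value, right = right))
  }
  expect_token(p, "KEYWORD", "from", what = "FROM or '='")
  source <- expect_ident(p, "selection name after FROM")
  filter <- NULL
  if (accept_keyword(p, "where")) filter <- parse_expr(p)
  if (accept_keyword(p, "intersect")) {
    bed <- expect_token(p, "STRING", what = "quoted BED path")$value
    return(list(kind = "create_from_bed", name = name, source = source,
                filter = filter, bed_path = bed))
  }
  list(kind = "create_selection", name = name, source = source,
       filter = filter)
}

parse_drop <- function(p) {
  expect_token(p, "KEYWORD", "drop")
  what <- if (accept_keyword(p, "wordset")) "wordset"
    else { accept_keyword(p, "selection"); "selection" }
  name <- expect_ident(p, paste0(what, " name"))
  list(kind = "drop", what = what, name = name)
}

parse_import_wordset <- function(p) {
  expect_token(p, "KEYWORD", "import")
  expect_token(p, "KEYWORD", "wordset")
  path <- expect_token(p, "STRING", what = "quoted file path")$value
  expect_token(p, "KEYWORD", "as")
  name <- expect_ident(p, "wordset name")
  list(kind = "import_wordset", name = name, path = path)
}

parse_field <- function(p) {
  t <- peek(p)
  if (at_keyword(p, "samples")) {
    advance_token(p)
    expect_token(p, "OP", "[")
    sample <- expect_token(p, "STRING", what = "quoted sample name")$value
    expect_token(p, "OP", "]")
    expect_token(p, "OP", ".")
    name <- expect_ident(p, "sample field name")
    return(field_ref("sample", name, sample = sample))
  }
  if (t$type != "IDENT")
    vql_syntax_error("expected field name", t$line, t$col,
                     token = if (t$type == "EOF") "end of input" else t$value)
  first <- advance_token(p)$value
  if (peek(p)$type == "OP" && peek(p)$value == ".") {
    if (first != "ann")
      vql_syntax_error("only 'ann.' and samples[...] field namespaces exist",
                       t$line, t$col, token = first)
    advance_token(p)
    name <- expect_ident(p, "annotation field name")
    return(field_ref("ann", name))
  }
  field_ref("bare", first)
}

parse_expr <- function(p) parse_or(p)

parse_or <- function(p) {
  left <- parse_and(p)
  children <- list(left)
  while (accept_keyword(p, "or"))
    children[[length(children) + 1L]] <- parse_and(p)
  if (length(children) == 1L) left else filter_branch("or", children)
}

parse_and <- function(p) {
  left <- parse_unary(p)
  children <- list(left)
  while (accept_keyword(p, "and"))
    children[[length(children) + 1L]] <- parse_unary(p)
  if (length(children) == 1L) left else filter_branch("and", children)
}

parse_unary <- function(p) {
  if (accept_keyword(p, "not"))
    return(list(type = "not", child = parse_unary(p)))
  t <- peek(p)
  if (t$type == "OP" && t$value == "(") {
    advance_token(p)
    e <- parse_expr(p)
    expect_token(p, "OP", ")")
    return(e)
  }
  parse_comparison(p)
}

parse_literal <- function(p) {
  t <- peek(p)
  if (t$type == "STRING") return(advance_token(p)$value)
  if (t$type == "NUMBER") return(as.numeric(advance_token(p)$value))
  if (t$type == "OP" && t$value %in% c("-", "+")) {
    sign <- advance_token(p)$value
    num <- expect_token(p, "NUMBER", what = "number after sign")
    return(as.numeric(num$value) * (if (sign == "-") -1 else 1))
  }
  if (t$type == "KEYWORD" && t$value == "null") { advance_token(p); return(NULL) }
  vql_syntax_error("expected a literal value", t$line, t$col,
                   token = if (t$type == "EOF") "end of input" else t$value)
}

parse_comparison <- function(p) {
  field <- parse_field(p)
  t <- peek(p)
  if (t$type == "OP" && t$value %in% c("=", "!=", "<", "<=", ">", ">=")) {
    advance_token(p)
    value <- parse_literal(p)
    if (is.null(value))
      vql_syntax_error("use IS NULL to test for missing values",
                       t$line, t$col, token = "NULL")
    return(filter_leaf(field, t$value, value))
  }
  if (t$type == "OP" && t$value == "~") {
    advance_token(p)
    pat <- expect_token(p, "STRING", what = "quoted regular expression")$value
    return(filter_leaf(field, "~", pat))
  }
  negated <- FALSE
  if (at_keyword(p, "not")) { advance_token(p); negated <- TRUE }
  if (accept_keyword(p, "in")) {
    if (!negated && accept_keyword(p, "wordset")) {
      t2 <- peek(p)
      name <- if (t2$type == "STRING") advance_token(p)$value
        else expect_ident(p, "wordset name")
      return(filter_leaf(field, "in_wordset", name))
    }
    expect_token(p, "OP", "(")
    values <- list(parse_literal(p))
    while (peek(p)$type == "OP" && peek(p)$value == ",") {
      advance_token(p)
      values[[length(values) + 1L]] <- parse_literal(p)
    }
    expect_token(p, "OP", ")")
    types <- vapply(values, function(v) class(v)[1], character(1))
    if (length(unique(types)) > 1L)
      vql_syntax_error("IN list values must all be strings or all numbers",
                       t$line, t$col)
    return(filter_leaf(field, if (negated) "not_in" else "in", values))
  }
  if (negated)
    vql_syntax_error("expected IN after NOT", t$line, t$col, token = t$value)
  if (accept_keyword(p, "is")) {
    neg <- accept_keyword(p, "not")
    expect_token(p, "KEYWORD", "null")
    return(filter_leaf(field, if (neg) "is_not_null" else "is_null"))
  }
  vql_syntax_error("expected a comparison operator", t$line, t$col,
                   token = if (t$type == "EOF") "end of input" else t$value)
}
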