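# Canonical VQL serialization: uppercase keywords, straight single quotes.
# parse(serialize(parse(x))) is structurally identical to parse(x).

serialize_field <- function(f) {
  switch(f$namespace,
    ann = paste0("ann.", f$name),
    sample = sprintf("samples['%s'].%s", f$sample, f$name),
    f$name)
}

serialize_literal <- function(v) {
  if (is.character(v)) paste0("'", v, "'")
  else format(v, digits = 15, trim = TRUE, scientific = FALSE)
}

filter_precedence <- function(node) {
  switch(node$type, or = 1L, and = 2L, not = 3L, 4L)
}

serialize_filter <- function(node) {
  if (node$type %in% c("and", "or")) {
    kw <- toupper(node$type)
    parts <- vapply(node$children, function(ch) {
      s <- serialize_filter(ch)
      if (filter_precedence(ch) <= filter_precedence(node))
        paste0("(", s, ")") else s
    }, character(1))
    return(paste(parts, collapse = paste0(" ", kw, " ")))
  }
  if (node$type == "not") {
    s <- serialize_filter(node$child)
    if (filter_precedence(node$child) <= filter_precedence(node))
      s <- paste0("(", s, ")")
    return(paste0("NOT ", s))
  }
  f <- serialize_field(node$field)
  switch(node$op,
    "~" = paste0(f, " ~ ", serialize_literal(node$value)),
    "in" = paste0(f, " IN (", paste(vapply(node$value, serialize_literal,
                                           character(1)), collapse = ", "), ")"),
    "not_in" = paste0(f, " NOT IN (", paste(vapply(node$value, serialize_literal,
                                                   character(1)), collapse = ", "), ")"),
    "in_wordset" = paste0(f, " IN WORDSET '", node$value, "'"),
    "is_null" = paste0(f, " IS NULL"),
    "is_not_null" = paste0(f, " IS NOT NULL"),
    paste0(f, " ", node$op, " ", serialize_literal(node$value)))
}

#' Serialize a VQL AST back to canonical query text
#'
#' The canonical form uses uppercase keywords and straight single quotes;
#' re-parsing the output yields a structurally identical AST
#' (`parse_vql(serialize_ast(ast))` equals `ast` for any parsed `ast`).
#'
#' @param ast An AST from [parse_vql()].
#' @return A single VQL statement string.
#' @examples
#' serialize_ast(parse_vql("select chr from variants where pos > 10"))
#' @export
serialize_ast <- function(ast) {
  switch(ast$kind,
    select = {
      out <- paste0("SELECT ",
                    paste(vapply(ast$select_list, serialize_field, character(1)),
                          collapse = ", "),
                    " FROM ", ast$source)
      if (!is.null(ast$filter))
        out <- paste0(out, " WHERE ", serialize_filter(ast$filter))
      if (length(ast$order_by)) {
        ob <- vapply(ast$order_by, function(o)
          paste0(serialize_field(o$field),
                 if (o$dir == "desc") " DESC" else " ASC"), character(1))
        out <- paste0(out, " ORDER BY ", paste(ob, collapse = ", "))
      }
      if (!is.null(ast$limit)) out <- paste0(out, " LIMIT ", ast$limit)
      if (!is.null(ast$offset)) out <- paste0(out, " OFFSET ", ast$offset)
      out
    },
    create_selection = {
      out <- paste0("CREATE ", ast$name, " FROM ", ast$source)
      if (!is.null(ast$filter))
        out <- paste0(out, " WHERE ", serialize_filter(ast$filter))
      out
    },
    create_from_setop = paste0("CREATE ", ast$name, " = ", ast$left, " ",
                               ast$op, " ", ast$right),
    create_from_bed = {
      out <- paste0("CREATE ", ast$name, " FROM ", ast$source)
      if (!is.null(ast$filter))
        out <- paste0(out, " WHERE ", serialize_filter(ast$filter))
      paste0(out, " INTERSECT '", ast$bed_path, "'")
    },
    drop = paste0("DROP ", toupper(ast$what), " ", ast$name),
    import_wordset = paste0("IMPORT WORDSET '", ast$path, "' AS ", ast$name),
    vql_error(paste0("cannot serialize statement kind: ", ast$kind),
              "vql_internal_error"))
}
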