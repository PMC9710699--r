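# AST validation against a store's schema: namespace resolution, existence
# checks for fields / samples / selections / wordsets, literal type checks.

CORE_FIELD_ALIASES <- c(chr = "chrom", chromosome = "chrom", position = "pos")

# Resolve a field reference against the catalogue. Bare names resolve
# core/info first, then the annotation namespace, so both `impact` and
# `ann.impact` denote the same column when no core field shadows it.
resolve_field <- function(f, store) {
  fields <- store$fields
  if (f$namespace == "sample") {
    if (!(f$sample %in% store$samples$name))
      vql_validation_error(paste0("unknown sample: ", sQuote(f$sample)))
    if (f$name == "gt") {
      f$value_type <- "int"
    } else {
      fd <- fields[category == "sample" & name == f$name]
      if (!nrow(fd))
        vql_validation_error(paste0("unknown sample field: ", sQuote(f$name)))
      f$value_type <- fd$value_type[1]
    }
    return(f)
  }
  if (f$namespace == "ann") {
    fd <- fields[category == "annotation" & name == f$name]
    if (!nrow(fd))
      vql_validation_error(paste0("unknown annotation field: ann.",
                                  f$name))
    f$value_type <- fd$value_type[1]
    return(f)
  }
  # bare name: alias, then core/info, then annotation
  nm <- unname(CORE_FIELD_ALIASES[f$name])
  if (is.na(nm) || is.null(nm)) nm <- f$name
  fd <- fields[category %in% c("core", "info") & name == nm]
  if (nrow(fd)) {
    f$namespace <- "core"
    f$name <- nm
    f$value_type <- fd$value_type[1]
    return(f)
  }
  fd <- fields[category == "annotation" & name == nm]
  if (nrow(fd)) {
    f$namespace <- "ann"
    f$name <- nm
    f$value_type <- fd$value_type[1]
    return(f)
  }
  vql_validation_error(paste0("unknown field: ", sQuote(f$name)))
}

check_literal_type <- function(op, value, field) {
  vt <- field$value_type
  numeric_field <- vt %in% c("int", "float")
  check_one <- function(v) {
    if (numeric_field && !is.numeric(v))
      vql_validation_error(sprintf(
        "field %s is %s but compared with string %s",
        serialize_field(field), vt, sQuote(v)))
    if (vt == "string" && is.numeric(v) && op %in% c("=", "!=", "in", "not_in"))
      vql_validation_error(sprintf(
        "field %s is a string but compared with number %s",
        serialize_field(field), format(v)))
    if (vt == "bool" && !is.numeric(v))
      vql_validation_error(sprintf(
        "field %s is a flag; compare with 0 or 1", serialize_field(field)))
  }
  switch(op,
    "~" = {
      if (vt != "string")
        vql_validation_error(sprintf(
          "regex '~' applies only to string fields, not %s (%s)",
          serialize_field(field), vt))
    },
    in_wordset = {
      if (vt != "string")
        vql_validation_error(sprintf(
          "IN WORDSET applies only to string fields, not %s (%s)",
          serialize_field(field), vt))
    },
    is_null = NULL, is_not_null = NULL,
    "in" = , not_in = for (v in value) check_one(v),
    "<" = , "<=" = , ">" = , ">=" = {
      if (!numeric_field && vt != "string")
        vql_validation_error(sprintf(
          "ordering comparison not supported for %s field %s",
          vt, serialize_field(field)))
      check_one(value)
    },
    check_one(value))
  invisible(TRUE)
}

validate_filter <- function(node, store) {
  if (is.null(node)) return(NULL)
  if (node$type %in% c("and", "or")) {
    node$children <- lapply(node$children, validate_filter, store = store)
    return(node)
  }
  if (node$type == "not") {
    node$child <- validate_filter(node$child, store)
    return(node)
  }
  node$field <- resolve_field(node$field, store)
  if (node$op == "in_wordset" && is.null(store$wordsets[[node$value]]))
    vql_validation_error(paste0("unknown wordset: ", sQuote(node$value)))
  check_literal_type(node$op, node$value, node$field)
  node
}

#' Validate a VQL AST against a store
#'
#' Resolves every field reference (bare names resolve to the core/INFO
#' namespace first, then to the annotation namespace), verifies that
#' samples, selections and wordsets named in the statement exist, and
#' type-checks literals against the declared field types (e.g. a regex on
#' an integer field is rejected).
#'
#' @param ast AST from [parse_vql()].
#' @param store A populated `variant_store`.
#' @return The checked AST: as the input, with field namespaces resolved
#'   to `core`/`ann`/`sample`, a `value_type` recorded on each field, and
#'   `checked = TRUE`.
#' @export
validate_ast <- function(ast, store) {
  switch(ast$kind,
    select = {
      ast$select_list <- lapply(ast$select_list, resolve_field, store = store)
      get_selection_ids(store, ast$source)  # existence check
      ast$filter <- validate_filter(ast$filter, store)
      ast$order_by <- lapply(ast$order_by, function(o) {
        o$field <- resolve_field(o$field, store)
        o
      })
    },
    create_selection = , create_from_bed = {
      check_selection_name(ast$name)
      get_selection_ids(store, ast$source)
      ast$filter <- validate_filter(ast$filter, store)
    },
    create_from_setop = {
      check_selection_name(ast$name)
      get_selection_ids(store, ast$left)
      get_selection_ids(store, ast$right)
    },
    drop = {
      if (ast$what == "selection" && is.null(store$selections[[ast$name]]))
        vql_validation_error(paste0("unknown selection: ", sQuote(ast$name)))
      if (ast$what == "wordset" && is.null(store$wordsets[[ast$name]]))
        vql_validation_error(paste0("unknown wordset: ", sQuote(ast$name)))
    },
    import_wordset = check_selection_name(ast$name))
  ast$checked <- TRUE
  ast
}
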