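# Query compilation and vectorized execution over the store tables.
#
# Row semantics: if the select list (or ORDER BY) references ann.* fields,
# the result has one row per (variant, matching annotation); otherwise
# annotation predicates are existential ("some annotation matches") and
# the result has one row per variant. Variants without annotations join a
# single all-missing annotation context, so IS NULL can test for them.

filter_refs <- function(node) {
  if (is.null(node)) return(list())
  if (node$type %in% c("and", "or"))
    return(do.call(c, lapply(node$children, filter_refs)))
  if (node$type == "not") return(filter_refs(node$child))
  list(node$field)
}

ast_field_refs <- function(ast) {
  c(ast$select_list, lapply(ast$order_by, `[[`, "field"), filter_refs(ast$filter))
}

#' Compile a validated SELECT statement into a query plan
#'
#' @param ast A checked AST from [validate_ast()] (an unchecked AST is
#'   validated first).
#' @param store A `variant_store`.
#' @return A `vql_plan`: the declarative execution plan consumed by
#'   [execute_plan()].
#' @export
compile_select <- function(ast, store) {
  if (!isTRUE(ast$checked)) ast <- validate_ast(ast, store)
  if (!identical(ast$kind, "select"))
    vql_error("compile_select expects a SELECT statement", "vql_internal_error")
  refs <- ast_field_refs(ast)
  ns <- vapply(refs, `[[`, character(1), "namespace")
  visible_ns <- vapply(c(ast$select_list, lapply(ast$order_by, `[[`, "field")),
                       `[[`, character(1), "namespace")
  sample_refs <- unique(lapply(refs[ns == "sample"],
                               function(f) f[c("sample", "name")]))
  structure(list(
    source = ast$source,
    select_list = ast$select_list,
    filter = ast$filter,
    order_by = ast$order_by,
    limit = ast$limit,
    offset = ast$offset,
    uses_ann = any(ns == "ann"),
    dedupe = !any(visible_ns == "ann"),
    sample_refs = sample_refs
  ), class = "vql_plan")
}

plan_column_name <- function(f) serialize_field(f)

# fetch the vector a resolved field reference denotes in the working table
plan_column <- function(tab, f) {
  nm <- switch(f$namespace,
    core = f$name,
    ann = paste0("ann.", f$name),
    sample = plan_column_name(f))
  col <- tab[[nm]]
  if (is.null(col)) rep(NA, nrow(tab)) else col
}

col_missing <- function(col) {
  if (is.character(col)) is.na(col) | !nzchar(col) else is.na(col)
}

# vectorized filter evaluation; missing values fail every comparison
eval_filter_vec <- function(node, tab, wordsets) {
  if (node$type == "and")
    return(Reduce(`&`, lapply(node$children, eval_filter_vec, tab = tab,
                              wordsets = wordsets)))
  if (node$type == "or")
    return(Reduce(`|`, lapply(node$children, eval_filter_vec, tab = tab,
                              wordsets = wordsets)))
  if (node$type == "not")
    return(!eval_filter_vec(node$child, tab, wordsets))
  col <- plan_column(tab, node$field)
  miss <- col_missing(col)
  if (is.logical(col) && node$field$value_type == "bool") {
    col <- as.numeric(col)
    col[is.na(col)] <- 0  # absent flag is FALSE, not missing
    miss <- rep(FALSE, length(col))
  }
  v <- node$value
  res <- switch(node$op,
    "=" = col == v,
    "!=" = col != v,
    "<" = col < v,
    "<=" = col <= v,
    ">" = col > v,
    ">=" = col >= v,
    "in" = col %in% unlist(v),
    "not_in" = !(col %in% unlist(v)),
    "~" = grepl(v, as.character(col)),
    "in_wordset" = col %in% (wordsets[[v]] %||% character(0)),
    "is_null" = miss,
    "is_not_null" = !miss,
    vql_error(paste0("unknown operator: ", node$op), "vql_internal_error"))
  if (!node$op %in% c("is_null", "is_not_null")) res[miss] <- FALSE
  res[is.na(res)] <- FALSE
  res
}

#' Execute a compiled query plan
#'
#' Materializes the working table (variants of the source selection,
#' left-joined to annotations when `ann.*` fields are referenced, plus one
#' column per referenced `samples['S'].field`), applies the filter with
#' missing-fails-comparison semantics, deduplicates to one row per variant
#' unless annotation fields are selected, then sorts (stable) and applies
#' LIMIT/OFFSET.
#'
#' @param plan A `vql_plan` from [compile_select()].
#' @param store A `variant_store`.
#' @return A `data.table` with one column per select-list entry, in
#'   select-list order; without ORDER BY the row order is the store's
#'   (stable, but unspecified).
#' @export
execute_plan <- function(plan, store) {
  tab <- build_working_table(plan, store)
  if (!is.null(plan$filter)) {
    keep <- eval_filter_vec(plan$filter, tab, store$wordsets)
    tab <- tab[keep]
  }
  if (plan$dedupe) tab <- tab[!duplicated(variant_id)]
  if (length(plan$order_by)) {
    keys <- lapply(plan$order_by, function(o) plan_column(tab, o$field))
    decreasing <- vapply(plan$order_by, function(o) o$dir == "desc", logical(1))
    ord <- do.call(order, c(keys, list(decreasing = decreasing,
                                       method = "radix")))
    tab <- tab[ord]
  }
  if (!is.null(plan$offset)) tab <- tail(tab, max(0L, nrow(tab) - plan$offset))
  if (!is.null(plan$limit)) tab <- head(tab, plan$limit)
  out <- data.table::setDT(lapply(plan$select_list, plan_column, tab = tab))
  data.table::setnames(out, vapply(plan$select_list, plan_column_name,
                                   character(1)))
  out[]
}

# variants of the source selection, annotation-joined and sample-augmented
# as the plan requires
build_working_table <- function(plan, store) {
  ids <- get_selection_ids(store, plan$source)
  tab <- store$variants[variant_id %in% ids]
  if (plan$uses_ann) {
    ann <- store$annotations
    ann_cols <- setdiff(names(ann), "variant_id")
    if (length(ann_cols))
      ann <- data.table::setnames(data.table::copy(ann), ann_cols,
                                  paste0("ann.", ann_cols))
    tab <- ann[tab, on = "variant_id", allow.cartesian = TRUE]
  }
  for (sr in plan$sample_refs) {
    g <- store$genotypes[sample == sr$sample]
    nm <- plan_column_name(field_ref("sample", sr$name, sr$sample))
    src <- if (sr$name %in% names(g)) g[[sr$name]] else rep(NA, nrow(g))
    tab[[nm]] <- src[match(tab$variant_id, g$variant_id)]
  }
  tab
}
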