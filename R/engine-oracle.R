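# Reference brute-force evaluator: scalar, row-at-a-time semantics for the
# WHERE clause, deliberately sharing no code with the vectorized plan
# execution. The compiled path is tested against this one.

context_value <- function(f, context) {
  v <- switch(f$namespace,
    core = context$variant[[f$name]],
    ann = if (is.null(context$annotation)) NULL else context$annotation[[f$name]],
    sample = context$genotypes[[f$sample]][[f$name]])
  if (is.logical(v) && identical(f$value_type, "bool")) v <- as.numeric(v)
  v
}

#' Evaluate a filter node on a single variant context (reference semantics)
#'
#' Recursive scalar evaluation of a validated filter tree against one
#' variant, one optional annotation, and the variant's genotype map. This
#' is the reference implementation the compiled query plan is tested
#' against; comparisons and regexes against missing values return `FALSE`
#' (use `IS NULL` / `IS NOT NULL` for explicit missingness tests).
#'
#' @param node Validated filter tree (the `filter` of a checked AST).
#' @param context List with `variant` (named list of core/INFO/aggregate
#'   values), `annotation` (named list or `NULL`), `genotypes` (named list:
#'   sample name to named list of FORMAT values incl. `gt`).
#' @param wordsets Named list of word vectors, for `IN WORDSET`.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_filter <- function(node, context, wordsets = list()) {
  if (node$type == "and") {
    for (ch in node$children)
      if (!evaluate_filter(ch, context, wordsets)) return(FALSE)
    return(TRUE)
  }
  if (node$type == "or") {
    for (ch in node$children)
      if (evaluate_filter(ch, context, wordsets)) return(TRUE)
    return(FALSE)
  }
  if (node$type == "not")
    return(!evaluate_filter(node$child, context, wordsets))

  v <- context_value(node$field, context)
  if (node$op == "is_null") return(is_missing_value(v))
  if (node$op == "is_not_null") return(!is_missing_value(v))
  if (identical(node$field$value_type, "bool") && is_missing_value(v)) v <- 0
  if (is_missing_value(v)) return(FALSE)
  lit <- node$value
  out <- switch(node$op,
    "=" = v == lit,
    "!=" = v != lit,
    "<" = v < lit,
    "<=" = v <= lit,
    ">" = v > lit,
    ">=" = v >= lit,
    "in" = any(vapply(lit, function(x) isTRUE(v == x), logical(1))),
    "not_in" = !any(vapply(lit, function(x) isTRUE(v == x), logical(1))),
    "~" = grepl(lit, as.character(v)),
    "in_wordset" = v %in% (wordsets[[lit]] %||% character(0)),
    vql_error(paste0("unknown operator: ", node$op), "vql_internal_error"))
  isTRUE(out)
}

# Per-variant contexts are assembled once per store and cached (the cache
# lives under a dot-name, so it is neither persisted by save_store nor
# listed); import_vcf drops it. The cache holds plain row lists - the
# evaluation semantics stay entirely in evaluate_filter.
oracle_context_cache <- function(store) {
  cache <- store[[".oracle_cache"]]
  if (!is.null(cache)) return(cache)
  v <- store$variants
  a <- store$annotations
  g <- store$genotypes
  vrows <- lapply(seq_len(nrow(v)), function(i) as.list(v[i]))
  names(vrows) <- as.character(v$variant_id)
  arows <- list()
  if (nrow(a)) {
    by_vid <- split(seq_len(nrow(a)), a$variant_id)
    arows <- lapply(by_vid, function(idx)
      lapply(idx, function(i) as.list(a[i])))
  }
  grows <- list()
  if (nrow(g)) {
    gl <- lapply(seq_len(nrow(g)), function(i)
      as.list(g[i, !c("variant_id", "sample")]))
    by_vid <- split(seq_len(nrow(g)), g$variant_id)
    grows <- lapply(by_vid, function(idx)
      setNames(gl[idx], g$sample[idx]))
  }
  cache <- list(variants = vrows, annotations = arows, genotypes = grows)
  store[[".oracle_cache"]] <- cache
  cache
}

variant_context_list <- function(store, vid, need_ann) {
  cache <- oracle_context_cache(store)
  key <- as.character(vid)
  variant <- cache$variants[[key]]
  genotypes <- cache$genotypes[[key]] %||% list()
  anns <- if (need_ann) cache$annotations[[key]] else NULL
  if (is.null(anns))
    return(list(list(variant = variant, annotation = NULL,
                     genotypes = genotypes)))
  lapply(anns, function(ann)
    list(variant = variant, annotation = ann, genotypes = genotypes))
}

#' Brute-force reference execution of a SELECT statement
#'
#' Executes a SELECT by looping variant-by-variant (and annotation-by-
#' annotation when `ann.*` fields are referenced), calling
#' [evaluate_filter()] on each context, then assembling, sorting and
#' truncating rows with plain base-R code. Row semantics match
#' [execute_plan()] by construction of the same contexts, not by shared
#' code; this function is the test oracle for the compiled path.
#'
#' @param store A `variant_store`.
#' @param ast A SELECT AST (checked or not).
#' @return A `data.table` with the same shape as [execute_plan()]'s.
#' @export
oracle_query <- function(store, ast) {
  if (!isTRUE(ast$checked)) ast <- validate_ast(ast, store)
  refs <- ast_field_refs(ast)
  ns <- vapply(refs, `[[`, character(1), "namespace")
  need_ann <- any(ns == "ann")
  visible <- c(ast$select_list, lapply(ast$order_by, `[[`, "field"))
  per_annotation <- any(vapply(visible, `[[`, character(1),
                               "namespace") == "ann")
  ids <- get_selection_ids(store, ast$source)

  rows <- list()
  for (vid in ids) {
    contexts <- variant_context_list(store, vid, need_ann)
    hit <- vapply(contexts, function(ctx) {
      is.null(ast$filter) || evaluate_filter(ast$filter, ctx, store$wordsets)
    }, logical(1))
    keep <- if (per_annotation) contexts[hit]
      else if (any(hit)) contexts[which(hit)[1]] else list()
    for (ctx in keep) {
      vals <- lapply(c(ast$select_list, lapply(ast$order_by, `[[`, "field")),
                     function(f) context_value(f, ctx) %||% NA)
      rows[[length(rows) + 1L]] <- vals
    }
  }
  all_fields <- c(ast$select_list, lapply(ast$order_by, `[[`, "field"))
  nm <- vapply(all_fields, plan_column_name, character(1))
  n_sel <- length(ast$select_list)
  if (!length(rows)) {
    out <- data.table::setDT(setNames(rep(list(logical(0)), length(nm)),
                                      make.unique(nm)))
  } else {
    cols <- lapply(seq_along(nm), function(j)
      unlist(lapply(rows, function(r) if (is.null(r[[j]])) NA else r[[j]])))
    out <- data.table::setDT(setNames(cols, make.unique(nm)))
  }
  if (length(ast$order_by) && nrow(out)) {
    keys <- lapply(seq_along(ast$order_by), function(k) out[[n_sel + k]])
    decreasing <- vapply(ast$order_by, function(o) o$dir == "desc", logical(1))
    ord <- do.call(order, c(keys, list(decreasing = decreasing,
                                       method = "radix")))
    out <- out[ord]
  }
  if (!is.null(ast$offset)) out <- tail(out, max(0L, nrow(out) - ast$offset))
  if (!is.null(ast$limit)) out <- head(out, ast$limit)
  out <- out[, seq_len(n_sel), with = FALSE]
  data.table::setnames(out, vapply(ast$select_list, plan_column_name,
                                   character(1)))
  out[]
}
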