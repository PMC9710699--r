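# Top-level VQL execution: parse -> validate -> dispatch.

#' Parse, validate and execute one VQL statement
#'
#' The single entry point mirroring the interactive query box: SELECT
#' statements return a result table; CREATE statements create named
#' selections (from a filter, a set expression `a & b` / `a | b` /
#' `a - b`, or a BED intersection via `INTERSECT 'file.bed'`); DROP
#' removes selections or wordsets; `IMPORT WORDSET 'file' AS name` loads
#' a wordset from a one-term-per-line text file.
#'
#' @param store A `variant_store`.
#' @param text One VQL statement.
#' @param overwrite Allow CREATE/IMPORT to replace an existing object.
#' @return For SELECT, a `data.table` of results. For other statements, an
#'   invisible list describing what was done (`kind`, `name`, `n`).
#' @examples
#' \dontrun{
#' vql_exec(st, "SELECT chr, pos FROM variants WHERE ann.impact = 'HIGH'")
#' vql_exec(st, "CREATE rare_high FROM variants WHERE ann.impact = 'HIGH'")
#' vql_exec(st, "CREATE both = rare_high & in_panel")
#' }
#' @export
vql_exec <- function(store, text, overwrite = FALSE) {
  ast <- parse_vql(text)
  ast <- validate_ast(ast, store)
  switch(ast$kind,
    select = execute_plan(compile_select(ast, store), store),
    create_selection = {
      ids <- filtered_variant_ids(store, ast$source, ast$filter)
      create_selection(store, ast$name, ids, provenance = serialize_ast(ast),
                       overwrite = overwrite)
      invisible(list(kind = ast$kind, name = ast$name, n = length(ids)))
    },
    create_from_setop = {
      op <- c("&" = "intersection", "|" = "union", "-" = "difference")[ast$op]
      sel <- selection_set_op(store, ast$left, ast$right, op, ast$name,
                              overwrite = overwrite)
      invisible(list(kind = ast$kind, name = ast$name, n = length(sel$keys)))
    },
    create_from_bed = {
      ids <- filtered_variant_ids(store, ast$source, ast$filter)
      tmp_name <- ast$name
      if (!is.null(ast$filter)) {
        # filter first, then interval-intersect the filtered set
        iv <- read_bed(ast$bed_path)
        v <- store$variants[variant_id %in% ids]
        keep <- bed_member_ids(v, iv, store$chr_prefix)
        create_selection(store, ast$name, keep,
                         provenance = serialize_ast(ast), overwrite = overwrite)
        return(invisible(list(kind = ast$kind, name = ast$name,
                              n = length(keep))))
      }
      sel <- intersect_bed(store, ast$source, ast$bed_path, tmp_name,
                           overwrite = overwrite)
      invisible(list(kind = ast$kind, name = ast$name, n = length(sel$keys)))
    },
    drop = {
      if (ast$what == "selection") drop_selection(store, ast$name)
      else drop_wordset(store, ast$name)
      invisible(list(kind = ast$kind, name = ast$name, n = 0L))
    },
    import_wordset = {
      words <- create_wordset(store, ast$name, ast$path, overwrite = overwrite)
      invisible(list(kind = ast$kind, name = ast$name, n = length(words)))
    })
}

filtered_variant_ids <- function(store, source, filter) {
  ast <- list(kind = "select",
              select_list = list(field_ref("bare", "chrom")),
              source = source, filter = filter,
              order_by = list(), limit = NULL, offset = NULL)
  ast <- validate_ast(ast, store)
  plan <- compile_select(ast, store)
  tab <- build_working_table(plan, store)
  if (!is.null(plan$filter))
    tab <- tab[eval_filter_vec(plan$filter, tab, store$wordsets)]
  unique(tab$variant_id)
}

bed_member_ids <- function(v, iv, policy) {
  if (!nrow(iv) || !nrow(v)) return(integer(0))
  v <- data.table::copy(v)[, .(variant_id, chrom, pos)]
  v[, chrom := harmonize_chrom(chrom, policy)]
  v[, p0 := pos - 1L]
  iv <- data.table::copy(iv)
  iv[, chrom := harmonize_chrom(chrom, policy)]
  hits <- v[iv, on = .(chrom, p0 >= start, p0 < end), nomatch = NULL,
            .(variant_id = x.variant_id)]
  unique(hits$variant_id)
}
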