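# Set algebra over named selections ("sources").

#' Combine two selections with a set operation
#'
#' Computes the exact set-theoretic intersection, union or difference of
#' two named selections and stores the result as a new selection whose
#' provenance records the expression (e.g. `"rare & exonic"`).
#'
#' @param store A `variant_store`.
#' @param a,b Names of existing selections (the reserved selection
#'   `variants` is allowed as an operand).
#' @param op One of `"intersection"`, `"union"`, `"difference"` (a minus b).
#' @param name Name for the result; must not be reserved.
#' @param overwrite Replace an existing selection of the same name.
#' @return The new selection (list with `keys`, `provenance`), invisibly.
#' @export
selection_set_op <- function(store, a, b, op = c("intersection", "union",
                                                 "difference"),
                             name, overwrite = FALSE) {
  op <- match.arg(op)
  ka <- get_selection_ids(store, a)
  kb <- get_selection_ids(store, b)
  keys <- switch(op,
    intersection = intersect(ka, kb),
    union = union(ka, kb),
    difference = setdiff(ka, kb))
  sym <- switch(op, intersection = "&", union = "|", difference = "-")
  create_selection(store, name, keys,
                   provenance = paste(a, sym, b), overwrite = overwrite)
}
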