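# Trio transmission-mode filters, expressed as ordinary VQL filter trees
# over samples['X'].gt so they compose with any other clause.

#' Build a transmission-mode filter for a trio
#'
#' Returns an ordinary filter tree (usable as the WHERE clause of a
#' query, or combined with other clauses) implementing standard Mendelian
#' transmission rules on genotype dosage codes:
#' \describe{
#'   \item{denovo}{child carries the allele (`gt` 1 or 2), both parents
#'     are homozygous reference.}
#'   \item{autosomal_recessive}{child homozygous alternate (`gt` 2), both
#'     parents heterozygous carriers (`gt` 1).}
#'   \item{dominant}{child carries the allele and at least one parent
#'     carries it.}
#' }
#' Unknown genotypes (`-1`) fail every clause, so a variant with a
#' missing parental call is never reported.
#'
#' @param mode One of `"denovo"`, `"autosomal_recessive"`, `"dominant"`.
#' @param child,father,mother Sample names (must exist in the store when
#'   the filter is validated).
#' @return A filter tree suitable for [evaluate_filter()] or for
#'   splicing into a SELECT AST.
#' @examples
#' f <- transmission_filter("denovo", "KID", "DAD", "MOM")
#' @export
transmission_filter <- function(mode = c("denovo", "autosomal_recessive",
                                         "dominant"),
                                child, father, mother) {
  mode <- match.arg(mode)
  gt <- function(s) field_ref("sample", "gt", sample = s)
  carrier <- function(s) filter_leaf(gt(s), "in", list(1, 2))
  hom_ref <- function(s) filter_leaf(gt(s), "=", 0)
  het <- function(s) filter_leaf(gt(s), "=", 1)
  hom_alt <- function(s) filter_leaf(gt(s), "=", 2)
  switch(mode,
    denovo = filter_branch("and", list(
      carrier(child), hom_ref(father), hom_ref(mother))),
    autosomal_recessive = filter_branch("and", list(
      hom_alt(child), het(father), het(mother))),
    dominant = filter_branch("and", list(
      carrier(child),
      filter_branch("or", list(carrier(father), carrier(mother))))))
}

#' Run a trio transmission-mode query
#'
#' Convenience wrapper: executes
#' `SELECT chr, pos, ref, alt FROM <source>` with the
#' [transmission_filter()] for the given mode as WHERE clause.
#'
#' @inheritParams transmission_filter
#' @param store A `variant_store`.
#' @param source Source selection name (default all variants).
#' @return A `data.table` of matching variants.
#' @export
trio_query <- function(store, mode, child, father, mother,
                       source = "variants") {
  ast <- list(kind = "select",
              select_list = list(field_ref("bare", "chrom"),
                                 field_ref("bare", "pos"),
                                 field_ref("bare", "ref"),
                                 field_ref("bare", "alt")),
              source = source,
              filter = transmission_filter(mode, child, father, mother),
              order_by = list(), limit = NULL, offset = NULL)
  execute_plan(compile_select(validate_ast(ast, store), store), store)
}
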