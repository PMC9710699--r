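# Per-variant genotype-count aggregates.
#
# Materialized at import so cohort filters like
#   WHERE case_count_hom = 3 AND control_count_hom = 0
# are plain field comparisons, not per-query joins.

COUNT_FIELDS <- c("count_hom", "count_het", "count_ref", "count_var",
                  "case_count_hom", "case_count_het", "case_count_ref",
                  "control_count_hom", "control_count_het", "control_count_ref")

#' Compute genotype-count aggregates for one variant
#'
#' Counts samples by genotype code, globally and split by pedigree
#' phenotype: `case_*` counts cover affected samples (phenotype 2),
#' `control_*` counts unaffected samples (phenotype 1); samples with
#' unknown phenotype contribute only to the global counts, and unknown
#' genotypes (`-1`) to none. `count_var` is the number of carriers
#' (`gt` 1 or 2). With no pedigree, every `case_*`/`control_*` count is 0.
#'
#' @param gt Integer vector of genotype codes (`-1`, `0`, `1`, `2`), one
#'   per sample.
#' @param phenotype Optional integer vector aligned with `gt`
#'   (2 = case, 1 = control, anything else = unknown).
#' @return Named list of the ten aggregate counts.
#' @examples
#' compute_counts(c(2, 2, 2, rep(0, 14)), phenotype = c(2, 2, 2, rep(1, 14)))
#' @export
compute_counts <- function(gt, phenotype = NULL) {
  gt <- as.integer(gt)
  if (is.null(phenotype)) phenotype <- rep(0L, length(gt))
  stopifnot(length(phenotype) == length(gt))
  one <- function(mask) list(
    hom = sum(gt[mask] == 2L), het = sum(gt[mask] == 1L),
    ref = sum(gt[mask] == 0L))
  g <- one(rep(TRUE, length(gt)))
  ca <- one(phenotype == 2L)
  co <- one(phenotype == 1L)
  list(count_hom = g$hom, count_het = g$het, count_ref = g$ref,
       count_var = g$hom + g$het,
       case_count_hom = ca$hom, case_count_het = ca$het, case_count_ref = ca$ref,
       control_count_hom = co$hom, control_count_het = co$het,
       control_count_ref = co$ref)
}

# Vectorized materialization over the whole genotype table; one code path
# with compute_counts() via grouped sums, cross-checked in the test suite.
materialize_counts <- function(store) {
  v <- store$variants
  if (!nrow(v)) return(invisible(store))
  g <- store$genotypes
  phen <- setNames(store$samples$phenotype, store$samples$name)
  if (nrow(g)) {
    ph0 <- phen[g$sample]
    ph0[is.na(ph0)] <- 0L
    gtab <- data.table::data.table(variant_id = g$variant_id, gt = g$gt, ph = ph0)
    agg <- gtab[, .(
      count_hom = sum(gt == 2L), count_het = sum(gt == 1L),
      count_ref = sum(gt == 0L), count_var = sum(gt == 1L | gt == 2L),
      case_count_hom = sum(gt == 2L & ph == 2L),
      case_count_het = sum(gt == 1L & ph == 2L),
      case_count_ref = sum(gt == 0L & ph == 2L),
      control_count_hom = sum(gt == 2L & ph == 1L),
      control_count_het = sum(gt == 1L & ph == 1L),
      control_count_ref = sum(gt == 0L & ph == 1L)), by = variant_id]
  } else {
    agg <- data.table::data.table(variant_id = v$variant_id)
    for (f in COUNT_FIELDS) agg[[f]] <- 0L
  }
  for (f in COUNT_FIELDS) v[[f]] <- NULL
  store$variants <- merge(v, agg, by = "variant_id", all.x = TRUE, sort = TRUE)
  for (f in COUNT_FIELDS)
    data.table::set(store$variants, which(is.na(store$variants[[f]])), f, 0L)
  invisible(store)
}
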