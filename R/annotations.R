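# Transcript-level annotation parsing (SnpEff ANN / VEP CSQ).
#
# Both annotators pack per-transcript annotations into one INFO value:
# comma-separated entries, each pipe-separated with one position per column
# declared in the header's Format clause. Parsing is catalogue-driven: the
# column list discovered by parse_vcf_header() decides the field names.

parse_annotation_value <- function(value, columns) {
  if (is_missing_value(value)) {
    return(list(records = list(), warnings = character(0)))
  }
  warnings <- character(0)
  entries <- strsplit(value, ",", fixed = TRUE)[[1]]
  records <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    parts <- strsplit(entries[i], "|", fixed = TRUE)[[1]]
    if (length(parts) < length(columns)) {
      warnings <- c(warnings, sprintf(
        "annotation entry %d has %d of %d declared positions; padding with missing",
        i, length(parts), length(columns)))
      parts <- c(parts, rep(NA_character_, length(columns) - length(parts)))
    } else if (length(parts) > length(columns)) {
      warnings <- c(warnings, sprintf(
        "annotation entry %d has %d positions but %d declared; extras dropped",
        i, length(parts), length(columns)))
      parts <- parts[seq_along(columns)]
    }
    parts[!nzchar(parts) | is.na(parts)] <- NA_character_
    records[[i]] <- setNames(as.list(parts), columns)
  }
  list(records = records, warnings = warnings)
}

#' Parse a SnpEff ANN INFO value into annotation records
#'
#' Splits the raw `ANN` string into one record per comma-separated entry;
#' each entry is pipe-split against the declared column list. Empty pipe
#' positions become missing values; entries shorter than the declaration
#' are right-padded with missing values and a warning. Malformed entries
#' are never fatal: they are kept with whatever fields parsed.
#'
#' @param ann_value Raw `ANN` INFO string (e.g. `"G|missense_variant|MODERATE|CFTR"`).
#' @param columns Character vector of normalized annotation column names in
#'   declaration order, as returned by [parse_vcf_header()] in
#'   `annotation_columns` (e.g. `c("allele", "consequence", "impact", "gene")`).
#' @return A list with `records` (list of named lists, one per entry) and
#'   `warnings` (character vector).
#' @seealso [parse_vep_csq()], [parse_vcf_header()]
#' @export
parse_snpeff_ann <- function(ann_value, columns) {
  parse_annotation_value(ann_value, columns)
}

#' Parse a VEP CSQ INFO value into annotation records
#'
#' Identical contract to [parse_snpeff_ann()]; only the header declaration
#' the column list comes from differs (`CSQ` with a
#' `Format: Allele|Consequence|IMPACT|SYMBOL|...` Description). Column
#' names arrive already normalized (`SYMBOL` to `gene`, `Consequence` to
#' `consequence`, `IMPACT` to `impact`), so downstream queries use the same
#' `ann.*` names for both annotators.
#'
#' @inheritParams parse_snpeff_ann
#' @param csq_value Raw `CSQ` INFO string.
#' @return A list with `records` and `warnings`, as [parse_snpeff_ann()].
#' @export
parse_vep_csq <- function(csq_value, columns) {
  parse_annotation_value(csq_value, columns)
}
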