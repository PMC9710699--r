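# BED interval intersection.
#
# BED is 0-based half-open [start, end); VCF positions are 1-based, so a
# variant at pos p lies in an interval iff start <= p-1 < end. Only the
# variant start position is tested, not the REF span.

#' Read a BED file into an interval table
#'
#' @param bed Path to (or lines of) a tab-delimited BED file with at least
#'   3 columns; `#`, `track` and `browser` lines are skipped.
#' @return A `data.table` with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(bed) {
  lines <- read_text_input(bed, "BED")
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") &
    !startsWith(lines, "browser") & nzchar(trimws(lines))
  lines <- lines[keep]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) == 1L) parts <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(parts) < 3L)
      vql_error(sprintf("malformed BED line %d: fewer than 3 columns", i),
                "vql_bed_error")
    s <- suppressWarnings(as.integer(parts[2]))
    e <- suppressWarnings(as.integer(parts[3]))
    if (is.na(s) || is.na(e) || s < 0L || e < s)
      vql_error(sprintf("malformed BED line %d: bad interval [%s, %s)",
                        i, parts[2], parts[3]), "vql_bed_error")
    rows[[i]] <- data.table::data.table(chrom = parts[1], start = s, end = e)
  }
  if (!length(rows))
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0)))
  data.table::rbindlist(rows)
}

harmonize_chrom <- function(x, policy) {
  if (identical(policy, "strip")) sub("^chr", "", x) else x
}

#' Intersect a selection with BED intervals
#'
#' Keeps a variant iff its start position falls inside some interval on
#' the same chromosome: `(pos - 1)` in `[start, end)`. Chromosome names
#' are compared after applying the store's `chr_prefix` policy (default:
#' strip a leading `"chr"` from both sides, so `chr7` and `7` match).
#'
#' @param store A `variant_store`.
#' @param source Name of the source selection.
#' @param bed BED path, lines, or a table from [read_bed()].
#' @param name Name for the resulting selection.
#' @param overwrite Replace an existing selection of the same name.
#' @return The new selection, invisibly.
#' @export
intersect_bed <- function(store, source, bed, name, overwrite = FALSE) {
  iv <- if (is.data.frame(bed)) data.table::as.data.table(bed) else read_bed(bed)
  ids <- get_selection_ids(store, source)
  v <- store$variants[variant_id %in% ids, .(variant_id, chrom, pos)]
  keep <- integer(0)
  if (nrow(iv) && nrow(v)) {
    v[, chrom := harmonize_chrom(chrom, store$chr_prefix)]
    v[, p0 := pos - 1L]
    iv <- data.table::copy(iv)
    iv[, chrom := harmonize_chrom(chrom, store$chr_prefix)]
    hits <- v[iv, on = .(chrom, p0 >= start, p0 < end), nomatch = NULL,
              .(variant_id = x.variant_id)]
    keep <- unique(hits$variant_id)
  }
  create_selection(store, name, keep,
                   provenance = paste0(source, " INTERSECT bed"),
                   overwrite = overwrite)
}
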