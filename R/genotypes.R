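# Genotype dosage coding and multi-allelic decomposition.

#' Encode a VCF GT value as a dosage code
#'
#' Recodes a raw GT string to the store's genotype code: the number of
#' called alleles equal to the alternate allele of interest. Phased (`|`)
#' and unphased (`/`) separators are equivalent; a haploid call is treated
#' as homozygous for its allele; any missing allele (`.`) makes the whole
#' call unknown.
#'
#' Codes: `-1` unknown, `0` homozygous reference, `1` heterozygous,
#' `2` homozygous alternate.
#'
#' @param gt_string Raw GT value, e.g. `"0/1"`, `"1|1"`, `"./."`, `"1"`.
#' @param alt_index Which ALT allele (1-based VCF allele index) to count;
#'   relevant for multi-allelic records being decomposed.
#' @return Integer scalar in `c(-1L, 0L, 1L, 2L)`.
#' @examples
#' encode_genotype("0/1")        # 1
#' encode_genotype("1|1")        # 2
#' encode_genotype("./.")        # -1
#' encode_genotype("1/2", 2)     # 1
#' @export
encode_genotype <- function(gt_string, alt_index = 1L) {
  if (is_missing_value(gt_string)) return(-1L)
  alleles <- strsplit(gt_string, "[/|]")[[1]]
  if (length(alleles) == 0L) return(-1L)
  if (any(alleles == "." | alleles == "")) return(-1L)
  idx <- suppressWarnings(as.integer(alleles))
  if (anyNA(idx)) {
    warning("unparseable GT value: ", gt_string, call. = FALSE)
    return(-1L)
  }
  n_alt <- sum(idx == alt_index)
  if (length(idx) == 1L) {
    # haploid: homozygous for the called allele
    return(if (n_alt == 1L) 2L else 0L)
  }
  # polyploid calls collapse to the 0/1/2 coding: any dosage >= ploidy is hom
  if (n_alt == 0L) 0L else if (n_alt >= length(idx)) 2L else 1L
}

# Slice a Number=A INFO value (comma-separated, one per ALT) for one ALT.
slice_number_a <- function(value, alt_index, n_alt) {
  if (is_missing_value(value)) return(NA_character_)
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  if (length(parts) != n_alt) return(NA_character_)
  parts[alt_index]
}

convert_typed <- function(x, value_type) {
  switch(value_type,
    int = suppressWarnings(as.integer(x)),
    float = suppressWarnings(as.numeric(x)),
    bool = as.logical(x),
    as.character(x))
}

#' Decompose one VCF data line into single-ALT variant records
#'
#' Normalizes a raw multi-allelic VCF record into one record per ALT
#' allele, so `(chrom, pos, ref, alt)` is a primary key. For ALT index
#' `a`, each sample's genotype code counts how many of its called alleles
#' equal `a`; a missing allele in the GT makes the code `-1` for every
#' decomposed record. `Number=A` INFO fields are sliced to the matching
#' ALT; other multi-valued INFO fields are carried unsliced as strings.
#' Annotation entries attach to the decomposed record whose `alt` equals
#' their allele field; entries matching no ALT attach to all siblings
#' (annotator indel allele notation can differ from the VCF spelling).
#'
#' @param line One tab-separated VCF data line.
#' @param header Header object from [parse_vcf_header()].
#' @return A list with `variants` (list of named lists: `chrom`, `pos`,
#'   `ref`, `alt`, `qual`, `filter`, `info`, `annotations`, `genotypes`),
#'   and `warnings`. Records with ALT `.` yield an empty `variants` list.
#' @export
decompose_record <- function(line, header) {
  warnings <- character(0)
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 8L)
    vql_error(paste0("malformed VCF data line (<8 columns): ", substr(line, 1, 60)),
              "vql_import_error")
  chrom <- f[1]; pos <- as.integer(f[2]); ref <- f[4]
  qual <- if (f[6] == ".") NA_real_ else suppressWarnings(as.numeric(f[6]))
  filter <- f[7]
  if (f[5] == "." || !nzchar(f[5])) {
    return(list(variants = list(),
                warnings = sprintf("skipping record %s:%d with no ALT allele", chrom, pos)))
  }
  alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
  symbolic <- grepl("^<|\\[|\\]", alts)
  if (any(symbolic)) {
    warnings <- c(warnings, sprintf(
      "skipping %d symbolic/breakend ALT allele(s) at %s:%d", sum(symbolic), chrom, pos))
    alts <- alts[!symbolic]
    if (length(alts) == 0L) return(list(variants = list(), warnings = warnings))
  }
  n_alt <- length(alts)

  # INFO key=value pairs (Flags have no '=')
  info_raw <- list()
  if (f[8] != ".") {
    for (pair in strsplit(f[8], ";", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", pair, fixed = TRUE)
      if (eq > 0L) {
        info_raw[[substr(pair, 1L, eq - 1L)]] <- substr(pair, eq + 1L, nchar(pair))
      } else if (nzchar(pair)) {
        info_raw[[pair]] <- TRUE
      }
    }
  }
  info_fields <- header$fields[category == "info"]
  info_norm <- if (length(info_raw))
    setNames(info_raw, normalize_name(names(info_raw))) else list()

  # annotations parsed once per line, then routed per allele
  ann_records <- list()
  if (!is.na(header$annotation_source)) {
    raw <- info_raw[[header$annotation_source]]
    if (!is.null(raw) && !isTRUE(raw)) {
      parsed <- parse_annotation_value(raw, header$annotation_columns)
      ann_records <- parsed$records
      warnings <- c(warnings, parsed$warnings)
    }
  }

  # FORMAT layout
  format_keys <- if (length(f) >= 9L) strsplit(f[9], ":", fixed = TRUE)[[1]] else character(0)
  gt_pos <- match("GT", format_keys)
  sample_fields <- header$fields[category == "sample" & name != "gt"]
  sample_values <- if (length(header$samples))
    lapply(f[seq(10L, by = 1L, length.out = length(header$samples))],
           function(s) strsplit(s, ":", fixed = TRUE)[[1]])
  else list()

  variants <- vector("list", n_alt)
  for (a in seq_len(n_alt)) {
    info <- list()
    for (j in seq_len(nrow(info_fields))) {
      fd <- info_fields[j]
      raw <- info_norm[[fd$name]]
      if (is.null(raw)) next
      if (fd$value_type == "bool") { info[[fd$name]] <- TRUE; next }
      val <- if (fd$multiplicity == "A") slice_number_a(raw, a, n_alt) else raw
      info[[fd$name]] <- if (fd$multiplicity %in% c("1", "A", "0"))
        convert_typed(val, fd$value_type) else as.character(val)
    }

    # allele-matched annotations; fall back to all siblings when unmatched
    anns <- list()
    for (rec in ann_records) {
      allele <- rec[["allele"]] %||% rec[[1]]
      if (!is.na(allele) && allele %in% alts) {
        if (identical(allele, alts[a])) anns <- c(anns, list(rec))
      } else {
        anns <- c(anns, list(rec))  # dangling allele: attach everywhere
      }
    }
    if (length(ann_records) && a == 1L) {
      unmatched <- vapply(ann_records, function(rec) {
        al <- rec[["allele"]] %||% rec[[1]]
        is.na(al) || !(al %in% alts)
      }, logical(1))
      if (any(unmatched))
        warnings <- c(warnings, sprintf(
          "%d annotation entr%s at %s:%d match no ALT allele; attached to all decomposed records",
          sum(unmatched), if (sum(unmatched) == 1L) "y" else "ies", chrom, pos))
    }

    genotypes <- list()
    for (s in seq_along(header$samples)) {
      vals <- sample_values[[s]]
      gt_raw <- if (!is.na(gt_pos) && length(vals) >= gt_pos) vals[gt_pos] else NA_character_
      g <- list(gt = encode_genotype(gt_raw, alt_index = a))
      for (j in seq_len(nrow(sample_fields))) {
        fd <- sample_fields[j]
        k <- match(fd$name, normalize_name(format_keys))
        if (is.na(k) || length(vals) < k || vals[k] == ".") next
        g[[fd$name]] <- if (fd$multiplicity == "1")
          convert_typed(vals[k], fd$value_type) else vals[k]
      }
      genotypes[[header$samples[s]]] <- g
    }

    variants[[a]] <- list(chrom = chrom, pos = pos, ref = ref, alt = alts[a],
                          qual = qual, filter = filter, info = info,
                          annotations = anns, genotypes = genotypes)
  }
  list(variants = variants, warnings = warnings)
}
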