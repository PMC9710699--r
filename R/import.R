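# Import orchestration: VCF (+ optional PED) -> normalized store tables.

#' Import an annotated VCF (and optional PED) into a variant store
#'
#' Parses the header into the field catalogue, decomposes every data line
#' into single-ALT variant records, parses SnpEff `ANN` / VEP `CSQ`
#' annotations, recodes genotypes to dosage codes, links the pedigree and
#' materializes the per-variant genotype-count aggregates. The target
#' store is only modified if the whole import succeeds.
#'
#' @param vcf Path to a VCF 4.x file (plain or gzip), or a character
#'   vector of VCF lines.
#' @param ped Optional path to (or lines of) a PED pedigree file. PED
#'   individuals matching VCF sample names are linked; others produce
#'   warnings.
#' @param store Target [variant_store()]; a fresh one is created when
#'   omitted.
#' @return An `import_report`: list with `n_vcf_records`, `n_variants`
#'   (post-decomposition), `n_annotations`, `n_samples`, `n_genotypes`,
#'   `warnings`, and the populated store in `$store`.
#' @examples
#' \dontrun{
#' st <- variant_store()
#' rep <- import_vcf("cohort.vcf", ped = "cohort.ped", store = st)
#' }
#' @export
import_vcf <- function(vcf, ped = NULL, store = NULL) {
  lines <- read_text_input(vcf, "VCF")
  if (is.null(store)) store <- variant_store()

  hdr_mask <- startsWith(lines, "#")
  n_hdr <- match(FALSE, hdr_mask, nomatch = length(lines) + 1L) - 1L
  header <- parse_vcf_header(lines[seq_len(n_hdr)])
  warnings <- header$warnings
  data_lines <- lines[seq.int(n_hdr + 1L, length.out = length(lines) - n_hdr)]
  data_lines <- data_lines[nzchar(data_lines)]

  ped_tab <- NULL
  if (!is.null(ped)) {
    parsed <- parse_ped(read_text_input(ped, "PED"))
    ped_tab <- parsed$pedigree
    warnings <- c(warnings, parsed$warnings)
  }

  vrows <- vector("list", 0L)
  arows <- list()
  grows <- list()
  seen_keys <- new.env(parent = emptyenv())
  vid <- 0L
  for (line in data_lines) {
    dec <- decompose_record(line, header)
    warnings <- c(warnings, dec$warnings)
    for (rec in dec$variants) {
      key <- make_variant_key(rec$chrom, rec$pos, rec$ref, rec$alt)
      if (!is.null(seen_keys[[key]])) {
        warnings <- c(warnings, paste0("duplicate variant key skipped: ", key))
        next
      }
      assign(key, TRUE, envir = seen_keys)
      vid <- vid + 1L
      row <- c(list(variant_id = vid, chrom = rec$chrom, pos = rec$pos,
                    ref = rec$ref, alt = rec$alt, qual = rec$qual,
                    filter = rec$filter),
               rec$info)
      if (!is.null(rec$info$dp)) row$depth <- as.integer(rec$info$dp)
      vrows[[vid]] <- row
      for (ann in rec$annotations)
        arows[[length(arows) + 1L]] <- c(list(variant_id = vid), ann)
      if (length(rec$genotypes)) {
        gt_tab <- data.table::rbindlist(
          lapply(rec$genotypes, as.list), fill = TRUE, idcol = "sample")
        gt_tab[, variant_id := vid]
        grows[[length(grows) + 1L]] <- gt_tab
      }
    }
  }

  variants <- if (length(vrows)) data.table::rbindlist(vrows, fill = TRUE)
    else data.table::data.table(variant_id = integer(0), chrom = character(0),
                                pos = integer(0), ref = character(0),
                                alt = character(0), qual = numeric(0),
                                filter = character(0))
  annotations <- if (length(arows)) data.table::rbindlist(arows, fill = TRUE)
    else data.table::data.table(variant_id = integer(0))
  genotypes <- if (length(grows)) data.table::rbindlist(grows, fill = TRUE)
    else data.table::data.table(variant_id = integer(0), sample = character(0),
                                gt = integer(0))
  if (nrow(genotypes))
    data.table::setcolorder(genotypes, c("variant_id", "sample", "gt"))

  # samples table, pedigree-linked
  samples <- data.table::data.table(
    name = header$samples, family = NA_character_, father = NA_character_,
    mother = NA_character_, sex = 0L, phenotype = 0L)
  if (!is.null(ped_tab) && nrow(ped_tab)) {
    m <- match(samples$name, ped_tab$individual)
    hit <- !is.na(m)
    samples$family[hit] <- ped_tab$family[m[hit]]
    samples$father[hit] <- ped_tab$father[m[hit]]
    samples$mother[hit] <- ped_tab$mother[m[hit]]
    samples$sex[hit] <- ped_tab$sex[m[hit]]
    samples$phenotype[hit] <- ped_tab$phenotype[m[hit]]
    orphan <- setdiff(ped_tab$individual, samples$name)
    if (length(orphan))
      warnings <- c(warnings, paste0("PED individual(s) not in VCF: ",
                                     paste(orphan, collapse = ", ")))
  }

  fields <- rbind(header$fields, count_field_catalogue())
  fields <- unique(fields, by = c("category", "name"))

  store$fields <- fields
  store$samples <- samples
  store$variants <- variants
  store$annotations <- annotations
  store$genotypes <- genotypes
  store$annotation_source <- header$annotation_source
  store[[".oracle_cache"]] <- NULL
  materialize_counts(store)
  data.table::setkey(store$variants, variant_id)

  report <- structure(list(
    n_vcf_records = length(data_lines),
    n_variants = nrow(store$variants),
    n_annotations = nrow(store$annotations),
    n_samples = nrow(store$samples),
    n_genotypes = nrow(store$genotypes),
    warnings = warnings,
    store = store
  ), class = "import_report")
  report
}

#' @export
print.import_report <- function(x, ...) {
  cat(sprintf(
    "Imported %d VCF record(s): %d variant(s), %d annotation(s), %d sample(s), %d genotype(s)\n",
    x$n_vcf_records, x$n_variants, x$n_annotations, x$n_samples, x$n_genotypes))
  if (length(x$warnings)) {
    cat(sprintf("%d warning(s):\n", length(x$warnings)))
    for (w in head(x$warnings, 10)) cat("  - ", w, "\n", sep = "")
    if (length(x$warnings) > 10) cat("  ...\n")
  }
  invisible(x)
}

# Accept either a file path or already-split text lines.
read_text_input <- function(x, what) {
  if (length(x) == 1L && !grepl("\n", x)) {
    if (file.exists(x)) return(readLines(x, warn = FALSE))
    if (!grepl("[\t ]", x))
      vql_error(paste0(what, " file not found: ", x), "vql_import_error")
    return(x)  # a single delimited data line
  }
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  x
}
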