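# Field catalogue: discovery of queryable fields from the VCF header.
#
# Categories:
#   core       - fixed VCF columns (chrom, pos, ref, alt, qual, filter) plus
#                derived fields (depth, genotype-count aggregates)
#   info       - one per ##INFO declaration
#   annotation - pipe-separated subfields of the ANN (SnpEff) or CSQ (VEP)
#                INFO declaration
#   sample     - one per ##FORMAT declaration, addressed as samples['S'].name

# Annotator column names are normalized so the same query works against
# SnpEff and VEP output: ann.gene, ann.impact, ann.consequence, ann.transcript.
ANNOTATION_NAME_MAP <- c(
  annotation        = "consequence",  # SnpEff
  annotation_impact = "impact",
  gene_name         = "gene",
  feature_id        = "transcript",
  consequence       = "consequence",  # VEP
  impact            = "impact",
  symbol            = "gene",
  gene              = "gene_id",      # VEP 'Gene' is the Ensembl gene id
  feature           = "transcript"
)

normalize_annotation_name <- function(x) {
  n <- normalize_name(x)
  mapped <- ANNOTATION_NAME_MAP[n]
  ifelse(is.na(mapped), n, mapped)
}

vcf_type_map <- c(Integer = "int", Float = "float", Flag = "bool",
                  String = "string", Character = "string")

field_descriptor <- function(name, category, value_type, multiplicity = "1",
                             description = "") {
  data.table::data.table(
    name = name, category = category, value_type = value_type,
    multiplicity = as.character(multiplicity), description = description
  )
}

core_field_catalogue <- function() {
  rbind(
    field_descriptor("chrom",  "core", "string", "1", "Chromosome"),
    field_descriptor("pos",    "core", "int",    "1", "1-based position"),
    field_descriptor("ref",    "core", "string", "1", "Reference allele"),
    field_descriptor("alt",    "core", "string", "1", "Alternate allele (single, post-decomposition)"),
    field_descriptor("qual",   "core", "float",  "1", "Variant quality"),
    field_descriptor("filter", "core", "string", "1", "FILTER column")
  )
}

# genotype-count aggregates materialized at import time
count_field_catalogue <- function() {
  nm <- c("count_hom", "count_het", "count_ref", "count_var",
          "case_count_hom", "case_count_het", "case_count_ref",
          "control_count_hom", "control_count_het", "control_count_ref")
  field_descriptor(nm, "core", "int", "1",
                   "Per-variant genotype count (materialized at import)")
}

# Parse one ##INFO=<...> or ##FORMAT=<...> declaration body.
parse_structured_header_line <- function(line) {
  body <- sub("^##[A-Za-z]+=<", "", line)
  body <- sub(">\\s*$", "", body)
  # split on commas not inside a quoted Description
  chars <- strsplit(body, "")[[1]]
  in_q <- FALSE
  cut <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == '"') in_q <- !in_q
    else if (chars[i] == "," && !in_q) cut <- c(cut, i)
  }
  pieces <- substring(body, c(1L, cut + 1L), c(cut - 1L, nchar(body)))
  kv <- regmatches(pieces, regexec("^([A-Za-z]+)=(.*)$", pieces))
  out <- list()
  for (m in kv) {
    if (length(m) == 3L) out[[m[2]]] <- gsub('^"|"$', "", m[3])
  }
  out
}

# Extract the pipe-separated column list from an ANN/CSQ Description.
# SnpEff: Functional annotations: 'Allele | Annotation | ... '
# VEP:    Consequence annotations from Ensembl VEP. Format: Allele|Consequence|...
parse_annotation_format <- function(description) {
  fmt <- NULL
  m <- regmatches(description, regexec("Format:\\s*'?([^'\"]+)'?", description))[[1]]
  if (length(m) == 2L) {
    fmt <- m[2]
  } else {
    m <- regmatches(description, regexec("'([^']+)'", description))[[1]]
    if (length(m) == 2L) fmt <- m[2]
  }
  if (is.null(fmt)) return(NULL)
  cols <- trimws(strsplit(fmt, "|", fixed = TRUE)[[1]])
  cols[nzchar(cols)]
}

#' Parse a VCF header into a field catalogue
#'
#' Reads the `##`/`#CHROM` header lines of a VCF 4.x file and returns the
#' catalogue of queryable fields plus the sample names. Core fields
#' (`chrom`, `pos`, `ref`, `alt`, `qual`, `filter`) are always present;
#' every `##INFO` and `##FORMAT` declaration contributes one descriptor.
#' If an `ANN` (SnpEff) or `CSQ` (VEP) INFO declaration is found, its
#' pipe-separated Format clause is expanded into `category = "annotation"`
#' descriptors with annotator-specific column names normalized
#' (`Annotation`/`Consequence` to `consequence`, `Annotation_Impact`/
#' `IMPACT` to `impact`, `Gene_Name`/`SYMBOL` to `gene`). INFO `DP` is
#' additionally exposed as the core-namespace field `depth`.
#'
#' @param header_lines Character vector of header lines; all but the last
#'   start with `##`, the last is the `#CHROM` column line.
#' @return A list with `fields` (a `data.table` of descriptors: `name`,
#'   `category`, `value_type`, `multiplicity`, `description`), `samples`
#'   (character vector from `#CHROM` columns 10+), `annotation_source`
#'   (`"ANN"`, `"CSQ"` or `NA`), `annotation_columns` (normalized names in
#'   declaration order) and `warnings`.
#' @examples
#' hdr <- c("##fileformat=VCFv4.2",
#'          '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
#'          "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
#' parse_vcf_header(hdr)$samples
#' @export
parse_vcf_header <- function(header_lines) {
  warnings <- character(0)
  chrom_idx <- grep("^#CHROM\t", header_lines)
  if (length(chrom_idx) == 0L)
    chrom_idx <- which(startsWith(header_lines, "#CHROM"))
  if (length(chrom_idx) == 0L)
    vql_error("malformed VCF header: missing #CHROM line", "vql_import_error")
  chrom_line <- header_lines[chrom_idx[1]]
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) >= 10L) cols[10:length(cols)] else character(0)

  fields <- core_field_catalogue()
  ann_source <- NA_character_
  ann_columns <- character(0)

  for (line in header_lines[startsWith(header_lines, "##")]) {
    is_info <- startsWith(line, "##INFO=")
    is_fmt <- startsWith(line, "##FORMAT=")
    if (!is_info && !is_fmt) next
    decl <- tryCatch(parse_structured_header_line(line), error = function(e) NULL)
    if (is.null(decl) || is.null(decl$ID) || is.null(decl$Type)) {
      warnings <- c(warnings, paste0("skipping unparseable header declaration: ", line))
      next
    }
    vt <- vcf_type_map[decl$Type]
    if (is.na(vt)) {
      warnings <- c(warnings, paste0("unknown Type in header declaration: ", line))
      next
    }
    nm <- normalize_name(decl$ID)
    if (is_info && decl$ID %in% c("ANN", "CSQ")) {
      ann_cols_raw <- parse_annotation_format(decl$Description %||% "")
      if (is.null(ann_cols_raw)) {
        warnings <- c(warnings,
          paste0("could not find Format clause in ", decl$ID, " Description"))
      } else {
        ann_source <- decl$ID
        ann_columns <- make.unique(normalize_annotation_name(ann_cols_raw),
                                   sep = "_")
        fields <- rbind(fields, field_descriptor(
          ann_columns, "annotation", "string", "1",
          paste0(decl$ID, " subfield ", ann_cols_raw)))
      }
      next
    }
    fields <- rbind(fields, field_descriptor(
      nm, if (is_info) "info" else "sample", unname(vt),
      decl$Number %||% ".", decl$Description %||% ""))
    if (is_info && decl$ID == "DP")
      fields <- rbind(fields, field_descriptor(
        "depth", "core", "int", "1", "Read depth (INFO DP)"))
  }
  dup <- fields[, .N, by = .(category, name)][N > 1L]
  if (nrow(dup))
    warnings <- c(warnings, paste0("duplicate field declaration: ",
                                   paste(dup$name, collapse = ", ")))
  fields <- unique(fields, by = c("category", "name"))
  list(fields = fields, samples = samples, annotation_source = ann_source,
       annotation_columns = ann_columns, warnings = warnings)
}
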