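# Independent per-record cohort filter with SnpSift-style semantics.
#
# Mirrors the streaming filter
#   (Cases[0] = n_hom_cases) & (Controls[0] = n_hom_controls)
#     & (ANN[*].IMPACT in impacts)
# where Cases[0]/Controls[0] are the numbers of case/control samples
# homozygous for the alternate allele and ANN[*] quantifies existentially
# over annotation entries. It works directly on raw VCF + PED text, line
# by line, sharing no code with the import/query machinery: it is the
# cross-check that the store-backed query reproduces the streaming
# analysis.

#' Streaming SnpSift-style case/control filter over raw VCF text
#'
#' @param vcf_lines Character vector of VCF lines (or a file path).
#' @param ped_lines Character vector of PED lines (or a file path);
#'   phenotype 2 marks cases, 1 controls.
#' @param case_hom Required number of case samples homozygous for an
#'   alternate allele.
#' @param control_hom Required number of control samples homozygous for
#'   an alternate allele.
#' @param impacts Character vector of accepted `ANN` impact values.
#' @return Character vector of `"chrom:pos"` site keys of records passing
#'   the filter.
#' @export
snpsift_case_control_filter <- function(vcf_lines, ped_lines,
                                        case_hom = 3L, control_hom = 0L,
                                        impacts = c("HIGH", "MODERATE")) {
  vcf_lines <- read_text_input(vcf_lines, "VCF")
  ped_lines <- read_text_input(ped_lines, "PED")

  phen <- list()
  for (ln in ped_lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) >= 6L) phen[[parts[2]]] <- as.integer(parts[6])
  }

  chrom_line <- vcf_lines[startsWith(vcf_lines, "#CHROM")][1]
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  sample_names <- if (length(cols) >= 10L) cols[10:length(cols)] else character(0)

  # impact position within the ANN Format declaration
  ann_decl <- grep("^##INFO=<ID=ANN,", vcf_lines, value = TRUE)
  impact_pos <- NA_integer_
  if (length(ann_decl)) {
    m <- regmatches(ann_decl[1], regexec("'([^']*)'", ann_decl[1]))[[1]]
    if (length(m) == 2L) {
      fmt <- trimws(strsplit(m[2], "|", fixed = TRUE)[[1]])
      impact_pos <- match(TRUE, toupper(fmt) %in% c("ANNOTATION_IMPACT", "IMPACT"))
    }
  }

  hits <- character(0)
  for (line in vcf_lines[!startsWith(vcf_lines, "#")]) {
    if (!nzchar(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) next
    fmt_keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt_keys)
    if (is.na(gt_i)) next
    n_case_hom <- 0L; n_control_hom <- 0L
    for (s in seq_along(sample_names)) {
      ph <- phen[[sample_names[s]]]
      if (is.null(ph) || !(ph %in% c(1L, 2L))) next
      gt <- strsplit(f[9L + s], ":", fixed = TRUE)[[1]][gt_i]
      al <- strsplit(gt, "[/|]")[[1]]
      hom_alt <- length(al) > 0L && !any(al %in% c(".", "")) &&
        all(al == al[1]) && al[1] != "0"
      if (hom_alt) {
        if (ph == 2L) n_case_hom <- n_case_hom + 1L
        else n_control_hom <- n_control_hom + 1L
      }
    }
    if (n_case_hom != case_hom || n_control_hom != control_hom) next
    # existential ANN[*].IMPACT match
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    ann <- sub("^ANN=", "", grep("^ANN=", info, value = TRUE))
    impact_ok <- FALSE
    if (length(ann) && !is.na(impact_pos)) {
      for (entry in strsplit(ann[1], ",", fixed = TRUE)[[1]]) {
        parts <- strsplit(entry, "|", fixed = TRUE)[[1]]
        if (length(parts) >= impact_pos && parts[impact_pos] %in% impacts) {
          impact_ok <- TRUE
          break
        }
      }
    }
    if (impact_ok) hits <- c(hits, paste0(f[1], ":", f[2]))
  }
  unique(hits)
}
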