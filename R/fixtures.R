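# Deterministic synthetic-data generators: annotated VCF + PED cohorts,
# the SnpSift-style cohort worked example, and trio transmission fixtures.
# Every module is testable from these with no external download; expected
# answers are known by construction, never by running the query engine.

FIXTURE_GENES <- c(
  "CFTR", "BRCA1", "BRCA2", "TP53", "DMD", "FBN1", "MECP2", "PAH",
  "HBB", "F8", "LDLR", "MYH7", "PKD1", "SCN1A", "COL1A1", "RB1",
  "ATM", "MLH1", "MSH2", "NF1", "PTEN", "SMN1", "TSC1", "TSC2",
  "VHL", "WT1", "GBA", "HTT", "KCNQ1", "RYR1")

IMPACT_CONSEQUENCES <- list(
  HIGH = c("stop_gained", "frameshift_variant", "splice_acceptor_variant"),
  MODERATE = c("missense_variant", "inframe_deletion"),
  LOW = c("synonymous_variant", "splice_region_variant"),
  MODIFIER = c("intron_variant", "upstream_gene_variant", "intergenic_region"))

SNPEFF_ANN_COLUMNS <- c("Allele", "Annotation", "Annotation_Impact",
                        "Gene_Name", "Gene_ID", "Feature_ID")
VEP_CSQ_COLUMNS <- c("Allele", "Consequence", "IMPACT", "SYMBOL",
                     "Gene", "Feature")

fixture_vcf_header <- function(samples, dialect = c("ann", "csq")) {
  dialect <- match.arg(dialect)
  ann_line <- if (dialect == "ann") paste0(
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations: \'',
    paste(SNPEFF_ANN_COLUMNS, collapse = " | "), '\'">')
  else paste0(
    '##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence annotations from Ensembl VEP. Format: ',
    paste(VEP_CSQ_COLUMNS, collapse = "|"), '">')
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    ann_line,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Sample read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

fixture_ann_entry <- function(allele, consequence, impact, gene,
                              dialect = "ann") {
  tx <- paste0("NM_", sprintf("%06d", abs(utf8ToInt(substr(gene, 1, 1))) * 37), ".1")
  paste(c(allele, consequence, impact, gene, paste0("ENSG_", gene), tx),
        collapse = "|")
}

fixture_data_line <- function(chrom, pos, ref, alts, qual, dp, af,
                              ann_entries, gts, dialect = "ann",
                              sample_dp = NULL) {
  info <- c(sprintf("DP=%d", dp),
            paste0("AF=", paste(sprintf("%.3f", af), collapse = ",")))
  if (length(ann_entries))
    info <- c(info, paste0(toupper(dialect), "=",
                           paste(ann_entries, collapse = ",")))
  if (is.null(sample_dp)) sample_dp <- rep(dp, length(gts))
  paste(c(chrom, pos, ".", ref, paste(alts, collapse = ","),
          sprintf("%.1f", qual), "PASS", paste(info, collapse = ";"),
          "GT:DP", paste(gts, sample_dp, sep = ":")), collapse = "\t")
}

fixture_ped <- function(samples, n_cases, family = "FAM1") {
  vapply(seq_along(samples), function(i) {
    paste(family, samples[i], 0, 0, 1L + (i %% 2L),
          if (i <= n_cases) 2L else 1L, sep = "\t")
  }, character(1))
}

#' Specification for a synthetic annotated cohort
#'
#' Defaults emulate a small rare-disease cohort of the shape used in
#' case/control filtering: 17 individuals of which 3 are affected, a
#' severity mix dominated by low-impact annotations with a thin tail of
#' HIGH ones, a modest fraction of multi-allelic sites and a low
#' missing-genotype rate.
#'
#' @param n_variants Number of VCF data lines.
#' @param n_samples Number of samples.
#' @param n_cases Number of affected samples (first `n_cases` in the PED).
#' @param impact_probs Named probabilities over HIGH/MODERATE/LOW/MODIFIER;
#'   must sum to 1.
#' @param multiallelic_fraction Fraction of lines carrying two ALT alleles.
#' @param missing_rate Per-genotype probability of a missing call (`./.`).
#' @param dialect Annotation dialect: `"ann"` (SnpEff) or `"csq"` (VEP).
#' @param seed Integer seed; same seed, same bytes.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_variants = 200L, n_samples = 17L, n_cases = 3L,
                        impact_probs = c(HIGH = 0.05, MODERATE = 0.25,
                                         LOW = 0.35, MODIFIER = 0.35),
                        multiallelic_fraction = 0.1, missing_rate = 0.02,
                        dialect = c("ann", "csq"), seed = 1L) {
  dialect <- match.arg(dialect)
  if (n_cases > n_samples)
    vql_error("n_cases must not exceed n_samples", "vql_fixture_error")
  if (abs(sum(impact_probs) - 1) > 1e-8)
    vql_error("impact_probs must sum to 1", "vql_fixture_error")
  if (!all(names(impact_probs) %in% names(IMPACT_CONSEQUENCES)))
    vql_error("impact_probs names must be HIGH/MODERATE/LOW/MODIFIER",
              "vql_fixture_error")
  if (multiallelic_fraction < 0 || multiallelic_fraction > 1 ||
      missing_rate < 0 || missing_rate > 1)
    vql_error("fractions must lie in [0, 1]", "vql_fixture_error")
  if (n_variants < 1L || n_samples < 0L)
    vql_error("n_variants must be >= 1 and n_samples >= 0", "vql_fixture_error")
  structure(list(n_variants = as.integer(n_variants),
                 n_samples = as.integer(n_samples),
                 n_cases = as.integer(n_cases),
                 impact_probs = impact_probs,
                 multiallelic_fraction = multiallelic_fraction,
                 missing_rate = missing_rate, dialect = dialect,
                 seed = as.integer(seed)), class = "cohort_spec")
}

random_gt <- function(p_alt, missing_rate, n_alt = 1L) {
  if (runif(1) < missing_rate) return("./.")
  a <- sample(0:n_alt, 2L, replace = TRUE,
              prob = c(1 - p_alt, rep(p_alt / n_alt, n_alt)))
  paste(sort(a), collapse = "/")
}

#' Generate a synthetic annotated cohort (VCF + PED)
#'
#' Emits a VCF 4.2 text with an `ANN` (or `CSQ`) header declaration and
#' per-sample genotypes drawn under the spec, plus a PED marking the first
#' `n_cases` samples affected. Same seed, byte-identical output.
#'
#' @param spec A [cohort_spec()].
#' @return List with `vcf` and `ped`, each a character vector of lines.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    samples <- sprintf("S%02d", seq_len(spec$n_samples))
    n <- spec$n_variants
    chrom <- as.character(sample(1:22, n, replace = TRUE))
    pos <- sample.int(5e7, n) + 1e6L
    ord <- order(as.integer(chrom), pos, method = "radix")
    chrom <- chrom[ord]; pos <- pos[ord]
    bases <- c("A", "C", "G", "T")
    lines <- character(n)
    for (i in seq_len(n)) {
      ref <- sample(bases, 1L)
      n_alt <- if (runif(1) < spec$multiallelic_fraction) 2L else 1L
      alts <- sample(setdiff(bases, ref), n_alt)
      impact <- sample(names(spec$impact_probs), 1L,
                       prob = spec$impact_probs)
      gene <- sample(FIXTURE_GENES, 1L)
      cons <- sample(IMPACT_CONSEQUENCES[[impact]], 1L)
      ann <- vapply(alts, function(al)
        fixture_ann_entry(al, cons, impact, gene, spec$dialect), character(1))
      p_alt <- runif(1, 0.05, 0.5)
      gts <- vapply(seq_len(spec$n_samples), function(s)
        random_gt(p_alt, spec$missing_rate, n_alt), character(1))
      dp <- 20L + sample.int(60L, 1L)
      lines[i] <- fixture_data_line(
        chrom[i], pos[i], ref, alts, qual = round(runif(1, 20, 1000), 1),
        dp = dp, af = rep(round(p_alt, 3), n_alt), ann_entries = ann,
        gts = gts, dialect = spec$dialect,
        sample_dp = sample.int(80L, spec$n_samples))
    }
    list(vcf = c(fixture_vcf_header(samples, spec$dialect), lines),
         ped = fixture_ped(samples, spec$n_cases))
  })
}

#' Generate the cohort worked-example fixture
#'
#' Builds a 17-sample, 3-case cohort with one planted HIGH-impact CFTR
#' stop-gain variant that is homozygous in all three cases and not
#' homozygous in any control, among `n_decoys` decoy variants each of
#' which violates at least one clause of the cohort query
#' (`case_count_hom = 3 AND control_count_hom = 0 AND impact IN
#' ('HIGH', 'MODERATE')`) by construction: wrong case homozygote count,
#' at least one control homozygote, or only LOW/MODIFIER annotations.
#'
#' @param n_decoys Number of decoy variants (at least 200 by default).
#' @param seed Integer seed (decoy genotype noise only; the planted
#'   variant and the violated clauses are fixed by construction).
#' @return List with `vcf`, `ped`, `expected_key`
#'   (`"chrom:pos:ref:alt"`), and `expected_site` (`"chrom:pos"`).
#' @export
generate_snpsift_case <- function(n_decoys = 220L, seed = 1L) {
  stopifnot(n_decoys >= 3L)
  n_samples <- 17L; n_cases <- 3L
  samples <- sprintf("S%02d", seq_len(n_samples))
  with_seed(seed, {
    chrom_pool <- as.character(rep(1:22, length.out = n_decoys))
    pos_pool <- sort(sample.int(4e7, n_decoys + 1L) + 1e6L)

    planted_pos <- pos_pool[1]
    planted <- fixture_data_line(
      "7", planted_pos, "G", "A", qual = 831.2, dp = 54, af = 0.12,
      ann_entries = fixture_ann_entry("A", "stop_gained", "HIGH", "CFTR"),
      gts = c(rep("1/1", n_cases),
              rep(c("0/0", "0/1"), length.out = n_samples - n_cases)))

    control_gts <- function(n_hom) {
      n_ctl <- n_samples - n_cases
      gts <- rep(c("0/0", "0/1"), length.out = n_ctl)
      if (n_hom > 0L) gts[seq_len(n_hom)] <- "1/1"
      gts
    }
    case_gts <- function(n_hom) {
      gts <- rep("0/1", n_cases)
      if (n_hom > 0L) gts[seq_len(n_hom)] <- "1/1"
      gts
    }
    decoys <- character(n_decoys)
    for (i in seq_len(n_decoys)) {
      kind <- i %% 3L
      gene <- sample(setdiff(FIXTURE_GENES, "CFTR"), 1L)
      if (kind == 0L) {        # wrong case homozygote count
        impact <- sample(c("HIGH", "MODERATE"), 1L)
        gts <- c(case_gts(sample(0:2, 1L)), control_gts(0L))
      } else if (kind == 1L) { # a control is homozygous
        impact <- sample(c("HIGH", "MODERATE"), 1L)
        gts <- c(case_gts(3L), control_gts(sample(1:3, 1L)))
      } else {                 # only low-severity annotations
        impact <- sample(c("LOW", "MODIFIER"), 1L)
        gts <- c(case_gts(3L), control_gts(0L))
      }
      cons <- sample(IMPACT_CONSEQUENCES[[impact]], 1L)
      decoys[i] <- fixture_data_line(
        chrom_pool[i], pos_pool[i + 1L], "C", "T",
        qual = round(runif(1, 30, 900), 1), dp = 20L + sample.int(60L, 1L),
        af = round(runif(1, 0.05, 0.4), 3),
        ann_entries = fixture_ann_entry("T", cons, impact, gene), gts = gts)
    }
    list(vcf = c(fixture_vcf_header(samples), planted, decoys),
         ped = fixture_ped(samples, n_cases),
         expected_key = make_variant_key("7", planted_pos, "G", "A"),
         expected_site = paste0("7:", planted_pos))
  })
}

trio_mode_match <- function(mode, child, father, mother) {
  carrier <- function(g) g %in% c(1L, 2L)
  switch(mode,
    denovo = carrier(child) && father == 0L && mother == 0L,
    autosomal_recessive = child == 2L && father == 1L && mother == 1L,
    dominant = carrier(child) && (carrier(father) || carrier(mother)))
}

#' Generate a trio transmission-mode fixture
#'
#' Enumerates every genotype combination of (child, father, mother) over
#' codes -1/0/1/2 and emits one variant per combination: combinations
#' satisfying the requested mode are the planted (expected) variants, all
#' others are decoys. Expected keys are computed from the combination
#' table, not by running any filter.
#'
#' @param mode One of `"denovo"`, `"autosomal_recessive"`, `"dominant"`.
#' @return List with `vcf`, `ped`, `expected_keys` (character vector of
#'   `"chrom:pos:ref:alt"`), and `combos` (the genotype-combination table).
#' @export
generate_trio <- function(mode = c("denovo", "autosomal_recessive",
                                   "dominant")) {
  mode <- match.arg(mode)
  samples <- c("CHILD", "FATHER", "MOTHER")
  codes <- c(-1L, 0L, 1L, 2L)
  combos <- data.table::CJ(child = codes, father = codes, mother = codes)
  combos[, pos := 1e6L + 1000L * seq_len(.N)]
  gt_string <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- character(nrow(combos))
  expected <- character(0)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i]
    gts <- gt_string[as.character(c(cb$child, cb$father, cb$mother))]
    lines[i] <- fixture_data_line(
      "1", cb$pos, "A", "G", qual = 500, dp = 50, af = 0.1,
      ann_entries = fixture_ann_entry("G", "missense_variant", "MODERATE",
                                      FIXTURE_GENES[1L + i %% 25L]),
      gts = unname(gts))
    if (trio_mode_match(mode, cb$child, cb$father, cb$mother))
      expected <- c(expected, make_variant_key("1", cb$pos, "A", "G"))
  }
  ped <- c(paste("FAM1", "FATHER", 0, 0, 1, 1, sep = "\t"),
           paste("FAM1", "MOTHER", 0, 0, 2, 1, sep = "\t"),
           paste("FAM1", "CHILD", "FATHER", "MOTHER", 1, 2, sep = "\t"))
  list(vcf = c(fixture_vcf_header(samples), lines), ped = ped,
       expected_keys = expected, combos = combos)
}
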