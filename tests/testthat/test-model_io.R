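# VCF header parsing, decomposition, annotation parsing, PED, import.

test_that("header parsing discovers core, INFO, FORMAT and ANN fields", {
  hdr <- tiny_vcf()[1:7]
  cat <- parse_vcf_header(hdr)
  expect_identical(cat$samples, c("S1", "S2"))
  f <- cat$fields
  dp <- f[f$category == "info" & f$name == "dp"]
  expect_identical(dp$value_type, "int")
  expect_identical(dp$multiplicity, "1")
  # DP exposed as core 'depth' too
  expect_identical(nrow(f[f$category == "core" & f$name == "depth"]), 1L)
  # ANN Format expands to normalized annotation descriptors
  ann <- f[f$category == "annotation"]
  expect_identical(ann$name, c("allele", "consequence", "impact", "gene"))
  expect_identical(cat$annotation_source, "ANN")
})

test_that("VEP CSQ declarations normalize to the same annotation names", {
  hdr <- c("##fileformat=VCFv4.2",
           paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description=',
                  '"Consequence annotations from Ensembl VEP. Format: ',
                  'Allele|Consequence|IMPACT|SYMBOL|MOTIF">'),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  cat <- parse_vcf_header(hdr)
  ann <- cat$fields[cat$fields$category == "annotation"]
  expect_identical(ann$name, c("allele", "consequence", "impact", "gene",
                               "motif"))
  expect_identical(cat$annotation_source, "CSQ")
  expect_identical(cat$samples, character(0))
})

test_that("header without ANN/CSQ yields no annotation descriptors", {
  cat <- parse_vcf_header(c("##fileformat=VCFv4.2",
                            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  expect_identical(nrow(cat$fields[cat$fields$category == "annotation"]), 0L)
  expect_true(is.na(cat$annotation_source))
})

test_that("missing #CHROM line is a malformed-header error", {
  expect_error(parse_vcf_header("##fileformat=VCFv4.2"),
               class = "vql_import_error")
})

test_that("multi-allelic decomposition splits records and remaps genotypes", {
  hdr <- parse_vcf_header(tiny_vcf()[1:7])
  line <- paste("2", 300, ".", "A", "G,T", "10", "PASS", "DP=15;AF=0.3,0.1",
                "GT:DP", "1/2:12", "2/2:14", sep = "\t")
  dec <- decompose_record(line, hdr)
  expect_length(dec$variants, 2L)
  v1 <- dec$variants[[1]]; v2 <- dec$variants[[2]]
  expect_identical(c(v1$alt, v2$alt), c("G", "T"))
  # GT=1/2 counts one allele for each ALT; GT=2/2 only for the second
  expect_identical(v1$genotypes$S1$gt, 1L)
  expect_identical(v2$genotypes$S1$gt, 1L)
  expect_identical(v1$genotypes$S2$gt, 0L)
  expect_identical(v2$genotypes$S2$gt, 2L)
  # Number=A INFO sliced per ALT
  expect_equal(v1$info$af, 0.3)
  expect_equal(v2$info$af, 0.1)
  # shared fields copied to both
  expect_identical(v1$info$dp, 15L)
  expect_identical(v2$pos, 300L)
})

test_that("missing alleles and '.' ALT follow the stated rules", {
  hdr <- parse_vcf_header(tiny_vcf()[1:7])
  line <- paste("1", 10, ".", "A", "G", "5", "PASS", "DP=9",
                "GT", "./1", "0/1", sep = "\t")
  dec <- decompose_record(line, hdr)
  expect_identical(dec$variants[[1]]$genotypes$S1$gt, -1L)
  expect_identical(dec$variants[[1]]$genotypes$S2$gt, 1L)
  skip_line <- paste("1", 11, ".", "A", ".", "5", "PASS", "DP=9",
                     "GT", "0/0", "0/0", sep = "\t")
  dec2 <- decompose_record(skip_line, hdr)
  expect_length(dec2$variants, 0L)
  expect_match(dec2$warnings, "no ALT")
})

test_that("genotype encoding matches a brute-force allele-count oracle", {
  set.seed(421)
  for (rep in 1:1000) {
    ploidy <- sample(1:2, 1)
    alleles <- sample(c("0", "1", "2", "."), ploidy, replace = TRUE)
    sep <- sample(c("/", "|"), 1)
    gt <- paste(alleles, collapse = sep)
    alt <- sample(1:2, 1)
    # oracle: count alleles equal to alt; any '.' -> -1; haploid hom
    expected <- if (any(alleles == ".")) -1L else {
      n <- sum(alleles == as.character(alt))
      if (ploidy == 1L) (if (n == 1L) 2L else 0L)
      else if (n == 0L) 0L else if (n >= ploidy) 2L else 1L
    }
    expect_identical(encode_genotype(gt, alt), expected)
  }
  expect_identical(encode_genotype("0/1"), 1L)
  expect_identical(encode_genotype("1|1"), 2L)
  expect_identical(encode_genotype("0/0"), 0L)
  expect_identical(encode_genotype("./."), -1L)
  expect_identical(encode_genotype("1"), 2L)
})

test_that("ANN/CSQ values parse entry-by-entry with padding and missing", {
  cols <- c("allele", "consequence", "impact", "gene")
  one <- parse_snpeff_ann("G|missense_variant|MODERATE|CFTR", cols)
  expect_length(one$records, 1L)
  expect_identical(one$records[[1]]$gene, "CFTR")
  expect_identical(one$records[[1]]$consequence, "missense_variant")

  two <- parse_snpeff_ann("G|a|HIGH|X,T|b|LOW|Y", cols)
  expect_length(two$records, 2L)
  expect_identical(two$records[[2]]$allele, "T")

  gap <- parse_snpeff_ann("G||HIGH|X", cols)
  expect_true(is.na(gap$records[[1]]$consequence))

  short <- parse_snpeff_ann("G|only", cols)
  expect_true(is.na(short$records[[1]]$impact))
  expect_match(short$warnings, "padding")

  vep <- parse_vep_csq("T|stop_gained|HIGH|CFTR", cols)
  expect_identical(vep$records[[1]]$consequence, "stop_gained")
})

test_that("PED parsing follows column conventions and rejects bad lines", {
  ped <- parse_ped(c("FAM1 NA1223 0 0 1 2",
                     "FAM1 KID DAD 0 2 2",
                     "# comment",
                     "FAM1 DAD 0 0 1 -9"))
  expect_identical(nrow(ped$pedigree), 3L)
  na <- ped$pedigree[ped$pedigree$individual == "NA1223"]
  expect_true(is.na(na$father))
  expect_identical(na$phenotype, 2L)
  expect_identical(ped$pedigree[ped$pedigree$individual == "DAD"]$phenotype, 0L)
  # KID's mother unset, father present
  expect_identical(ped$pedigree[ped$pedigree$individual == "KID"]$father, "DAD")

  expect_error(parse_ped("FAM1 X 0 0 1"), class = "vql_ped_error")
  expect_error(parse_ped(c("F A 0 0 1 1", "F A 0 0 1 1")),
               class = "vql_ped_error")
  dangling <- parse_ped("FAM1 KID GHOST 0 1 2")
  expect_match(dangling$warnings, "GHOST")
})

test_that("import arithmetic, conservation and referential integrity hold", {
  st <- tiny_store(tiny_default_lines())
  rep <- attr(st, "report")
  v <- st$variants
  expect_identical(nrow(v), 4L)                      # 1 + 1 + 2 ALTs
  expect_identical(nrow(st$genotypes), 8L)           # 4 variants x 2 samples
  expect_identical(anyDuplicated(variant_keys(st)), 0L)
  expect_true(all(st$annotations$variant_id %in% v$variant_id))
  expect_true(all(st$genotypes$variant_id %in% v$variant_id))
  expect_true(all(v$pos >= 1L))
})

test_that("re-importing the same input is byte-identical (determinism)", {
  lines <- tiny_default_lines()
  a <- tiny_store(lines)
  b <- tiny_store(lines)
  for (tab in c("variants", "annotations", "genotypes", "samples", "fields"))
    expect_identical(a[[tab]], b[[tab]])
})

test_that("PED-linked import computes case aggregates over cases only", {
  ped <- c("FAM1 S1 0 0 1 2", "FAM1 S2 0 0 2 1")
  st <- tiny_store(tiny_default_lines(), ped = ped)
  v <- st$variants
  # brute-force recount straight from the genotype table
  for (i in seq_len(nrow(v))) {
    g <- st$genotypes[st$genotypes$variant_id == v$variant_id[i]]
    expect_identical(v$case_count_hom[i],
                     sum(g$gt[g$sample == "S1"] == 2L))
    expect_identical(v$control_count_het[i],
                     sum(g$gt[g$sample == "S2"] == 1L))
  }
})

test_that("zero-sample VCF imports with zero genotypes", {
  st <- variant_store()
  vcf <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="d">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "1\t100\t.\tA\tG\t50\tPASS\tDP=10")
  rep <- import_vcf(vcf, store = st)
  expect_identical(rep$n_genotypes, 0L)
  expect_identical(rep$n_variants, 1L)
  expect_error(vql_exec(st, "SELECT samples['S1'].gt FROM variants"),
               class = "vql_validation_error")
})

test_that("gzipped VCF files import identically to plain text", {
  lines <- tiny_vcf(tiny_default_lines())
  plain <- withr::local_tempfile(fileext = ".vcf")
  gz <- withr::local_tempfile(fileext = ".vcf.gz")
  writeLines(lines, plain)
  con <- gzfile(gz, "w"); writeLines(lines, con); close(con)
  a <- variant_store(); import_vcf(plain, store = a)
  b <- variant_store(); import_vcf(gz, store = b)
  expect_identical(a$variants, b$variants)
})

test_that("unmatched annotation alleles attach to all decomposed siblings", {
  line <- paste("3", 500, ".", "ATT", "A,ATTT", "40", "PASS",
                "DP=22;AF=0.1,0.2;ANN=TT|frameshift_variant|HIGH|DMD",
                "GT:DP", "0/1:9", "0/2:9", sep = "\t")
  st <- tiny_store(line)
  expect_identical(nrow(st$variants), 2L)
  expect_identical(nrow(st$annotations), 2L)  # one dangling entry, both rows
})
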