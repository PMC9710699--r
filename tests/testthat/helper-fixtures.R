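# Shared test helpers: a tiny hand-written VCF, a random query generator,
# and result-comparison utilities.

tiny_vcf <- function(extra_lines = character(0), samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    paste0('##INFO=<ID=ANN,Number=.,Type=String,Description="Functional ',
           "annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name'\">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    extra_lines)
}

tiny_store <- function(extra_lines, samples = c("S1", "S2"), ped = NULL) {
  st <- variant_store()
  import_vcf(tiny_vcf(extra_lines, samples), ped = ped, store = st)
  st
}

# default 3-line fixture: two biallelic + one 2-ALT multiallelic record
tiny_default_lines <- function() {
  c(paste("1", 100, ".", "A", "G", "50.0", "PASS", "DP=30;AF=0.2;ANN=G|missense_variant|MODERATE|CFTR",
          "GT:DP", "0/1:20", "0/0:25", sep = "\t"),
    paste("1", 200, ".", "C", "T", "99.0", "PASS", "DP=60;AF=0.1;ANN=T|stop_gained|HIGH|BRCA1",
          "GT:DP", "1/1:30", "0/1:31", sep = "\t"),
    paste("2", 300, ".", "A", "G,T", "10.0", "PASS", "DP=15;AF=0.3,0.1;ANN=G|synonymous_variant|LOW|TP53,T|intron_variant|MODIFIER|TP53",
          "GT:DP", "1/2:12", "2/2:14", sep = "\t"))
}

# ---- random query generation (ASTs built directly, no parsing) ----------

fr <- variantql:::field_ref
fleaf <- variantql:::filter_leaf
fbranch <- variantql:::filter_branch

random_leaf <- function(samples) {
  pick <- sample(1:10, 1)
  switch(pick,
    fleaf(fr("bare", "pos"), sample(c(">", "<", ">=", "<="), 1),
          as.numeric(sample.int(5e7, 1))),
    fleaf(fr("bare", "qual"), sample(c(">", "<="), 1),
          round(runif(1, 0, 1000), 1)),
    fleaf(fr("bare", "depth"), sample(c(">=", "<"), 1),
          as.numeric(sample(10:80, 1))),
    fleaf(fr("bare", "count_hom"), sample(c("=", ">="), 1),
          as.numeric(sample(0:5, 1))),
    fleaf(fr("bare", "case_count_hom"), "=", as.numeric(sample(0:3, 1))),
    if (runif(1) < 0.5)
      fleaf(fr("ann", "impact"), "=", sample(c("HIGH", "MODERATE", "LOW"), 1))
    else
      fleaf(fr("ann", "impact"), "in",
            as.list(sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), 2))),
    fleaf(fr("ann", "gene"), "~",
          paste0("^", sample(c("CF", "BR", "TP", "XX"), 1))),
    fleaf(fr("ann", "gene"), sample(c("=", "!="), 1),
          sample(c("CFTR", "BRCA1", "TP53", "NOPE"), 1)),
    if (runif(1) < 0.5)
      fleaf(fr("sample", "gt", sample = sample(samples, 1)), "=",
            as.numeric(sample(0:2, 1)))
    else
      fleaf(fr("sample", "gt", sample = sample(samples, 1)), "in",
            list(1, 2)),
    fleaf(fr("ann", "consequence"),
          sample(c("is_null", "is_not_null"), 1)))
}

random_filter <- function(samples, depth = 2) {
  if (depth == 0 || runif(1) < 0.4) return(random_leaf(samples))
  kind <- sample(c("and", "or", "not"), 1, prob = c(0.4, 0.4, 0.2))
  if (kind == "not")
    return(list(type = "not", child = random_filter(samples, depth - 1)))
  fbranch(kind, lapply(seq_len(sample(2:3, 1)), function(i)
    random_filter(samples, depth - 1)))
}

random_select_ast <- function(samples, with_filter = TRUE) {
  pool <- list(fr("bare", "chrom"), fr("bare", "pos"), fr("bare", "qual"),
               fr("bare", "count_het"), fr("ann", "gene"),
               fr("ann", "impact"),
               fr("sample", "gt", sample = sample(samples, 1)))
  sel <- pool[sample(seq_along(pool), sample(1:3, 1))]
  ob <- if (runif(1) < 0.4)
    list(list(field = fr("bare", "pos"),
              dir = sample(c("asc", "desc"), 1))) else list()
  list(kind = "select", select_list = sel, source = "variants",
       filter = if (with_filter) random_filter(samples) else NULL,
       order_by = ob,
       limit = if (runif(1) < 0.3) sample(5:50, 1) else NULL,
       offset = NULL)
}

# normalize a result table to comparable character form
res_canonical <- function(tab, sort_rows = TRUE) {
  df <- as.data.frame(tab)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.numeric(v)) v <- formatC(v, digits = 10, format = "g")
    df[[j]] <- as.character(v)
  }
  rows <- if (nrow(df)) do.call(paste, c(df, sep = "\x01")) else character(0)
  if (sort_rows) sort(rows) else rows
}

expect_same_result <- function(a, b, ordered = FALSE) {
  expect_identical(names(a), names(b))
  expect_identical(res_canonical(a, sort_rows = !ordered),
                   res_canonical(b, sort_rows = !ordered))
}
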