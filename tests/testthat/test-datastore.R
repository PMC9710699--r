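# Count aggregates, selections and set algebra, wordsets, BED intersection,
# store persistence.

test_that("compute_counts reproduces the cohort worked-example counts", {
  # 17 samples, 3 affected all hom-alt, 14 unaffected none hom-alt
  gt <- c(2, 2, 2, rep(c(0, 1), 7))
  ph <- c(2, 2, 2, rep(1, 14))
  cs <- compute_counts(gt, ph)
  expect_identical(cs$case_count_hom, 3L)
  expect_identical(cs$control_count_hom, 0L)
  expect_identical(cs$count_hom, 3L)
  expect_identical(cs$count_var, 3L + 7L)
  expect_identical(cs$control_count_het, 7L)
})

test_that("unknown genotypes and absent pedigrees yield zero counts", {
  cs <- compute_counts(rep(-1, 5), rep(2, 5))
  expect_true(all(unlist(cs) == 0L))
  cs2 <- compute_counts(c(0, 1, 2))
  expect_identical(cs2$count_het, 1L)
  expect_identical(cs2$case_count_hom, 0L)
  expect_identical(cs2$control_count_ref, 0L)
})

test_that("materialized aggregates equal brute-force recounts on random cohorts", {
  for (seed in c(11, 12)) {
    fx <- generate_cohort(cohort_spec(n_variants = 60, n_samples = 8,
                                      n_cases = 2, seed = seed))
    st <- variant_store()
    import_vcf(fx$vcf, ped = fx$ped, store = st)
    ph <- setNames(st$samples$phenotype, st$samples$name)
    for (vid in st$variants$variant_id) {
      g <- st$genotypes[st$genotypes$variant_id == vid]
      oracle <- compute_counts(g$gt, unname(ph[g$sample]))
      row <- st$variants[st$variants$variant_id == vid]
      for (f in names(oracle))
        expect_identical(row[[f]], oracle[[f]],
                         label = sprintf("%s of variant %d (seed %d)", f, vid, seed))
    }
    # phenotype-split counts never exceed globals
    v <- st$variants
    expect_true(all(v$case_count_hom + v$control_count_hom <= v$count_hom))
    expect_true(all(v$case_count_het + v$control_count_het <= v$count_het))
  }
})

test_that("selection set operations match set-theoretic results", {
  st <- tiny_store(tiny_default_lines())
  create_selection(st, "a", c(1L, 2L), "test")
  create_selection(st, "b", c(2L, 3L), "test")
  expect_identical(selection_set_op(st, "a", "b", "intersection", "i")$keys, 2L)
  expect_identical(selection_set_op(st, "a", "b", "union", "u")$keys, 1:3)
  expect_identical(selection_set_op(st, "a", "b", "difference", "d")$keys, 1L)
  # idempotence / annihilation
  expect_identical(selection_set_op(st, "a", "a", "intersection", "ii")$keys,
                   st$selections$a$keys)
  expect_identical(selection_set_op(st, "a", "a", "difference", "dd")$keys,
                   integer(0))
  # name collisions and reserved names are refused
  expect_error(selection_set_op(st, "a", "b", "union", "i"),
               class = "vql_validation_error")
  expect_error(create_selection(st, "variants", 1L),
               class = "vql_validation_error")
  expect_error(create_selection(st, "ghost", 999L),
               class = "vql_validation_error")
})

test_that("randomized set algebra matches the independent set oracle", {
  fx <- generate_cohort(cohort_spec(n_variants = 300, n_samples = 2,
                                    n_cases = 1, seed = 7,
                                    multiallelic_fraction = 0))
  st <- variant_store()
  import_vcf(fx$vcf, ped = fx$ped, store = st)
  ids <- st$variants$variant_id
  set.seed(99)
  for (i in 1:10) {
    a <- sample(ids, 200); b <- sample(ids, 200)
    create_selection(st, "a", a, overwrite = TRUE)
    create_selection(st, "b", b, overwrite = TRUE)
    i1 <- selection_set_op(st, "a", "b", "intersection", "x", overwrite = TRUE)$keys
    u1 <- selection_set_op(st, "a", "b", "union", "y", overwrite = TRUE)$keys
    d1 <- selection_set_op(st, "a", "b", "difference", "z", overwrite = TRUE)$keys
    expect_setequal(i1, base::intersect(a, b))
    expect_setequal(u1, base::union(a, b))
    expect_setequal(d1, base::setdiff(a, b))
    # commutativity and inclusion-exclusion
    expect_setequal(i1, selection_set_op(st, "b", "a", "intersection", "x2",
                                         overwrite = TRUE)$keys)
    expect_identical(length(u1), length(unique(a)) + length(unique(b)) -
                       length(i1))
    expect_true(all(base::setdiff(u1, b) %in% a))
  }
})

test_that("wordsets strip blanks, collapse duplicates and refuse emptiness", {
  st <- tiny_store(tiny_default_lines())
  ws <- create_wordset(st, "genes", c("CFTR", "BRCA1", "", "  CFTR  "))
  expect_setequal(ws, c("CFTR", "BRCA1"))
  expect_error(create_wordset(st, "empty", c("", "  ")),
               class = "vql_validation_error")
  big <- sprintf("GENE%05d", 1:10000)
  create_wordset(st, "big", big)
  expect_true(all(c("GENE00001", "GENE09999") %in% st$wordsets$big))
  expect_length(st$wordsets$big, 10000L)
})

test_that("BED intersection converts half-open intervals correctly", {
  lines <- vapply(c(99L, 100L, 200L, 201L), function(p)
    paste("1", p, ".", "A", "G", "50", "PASS", "DP=10;AF=0.1",
          "GT", "0/1", "0/0", sep = "\t"), character(1))
  st <- tiny_store(lines)
  sel <- intersect_bed(st, "variants", "1\t99\t200", "hits")
  kept <- sort(st$variants[st$variants$variant_id %in% sel$keys]$pos)
  expect_identical(kept, c(100L, 200L))
  # empty BED -> empty selection
  empty <- intersect_bed(st, "variants",
                         data.table::data.table(chrom = character(0),
                                                start = integer(0),
                                                end = integer(0)),
                         "none")
  expect_length(empty$keys, 0L)
  # chr prefix harmonization (default: strip)
  sel2 <- intersect_bed(st, "variants", "chr1\t99\t200", "hits2")
  expect_setequal(sel2$keys, sel$keys)
  expect_error(read_bed("1\t100"), class = "vql_bed_error")
  expect_error(read_bed("1\t200\t100"), class = "vql_bed_error")
})

test_that("BED intersection equals the quadratic membership oracle", {
  fx <- generate_cohort(cohort_spec(n_variants = 400, n_samples = 2,
                                    n_cases = 1, seed = 5,
                                    multiallelic_fraction = 0))
  st <- variant_store()
  import_vcf(fx$vcf, store = st)
  set.seed(31)
  n_iv <- 120
  iv <- data.table::data.table(
    chrom = as.character(sample(1:22, n_iv, replace = TRUE)),
    start = sample.int(5e7, n_iv))
  iv$end <- iv$start + sample.int(2e6, n_iv)
  sel <- intersect_bed(st, "variants", iv, "rand")
  v <- st$variants
  oracle <- v$variant_id[vapply(seq_len(nrow(v)), function(i) {
    any(iv$chrom == v$chrom[i] & iv$start <= v$pos[i] - 1L &
          v$pos[i] - 1L < iv$end)
  }, logical(1))]
  expect_setequal(sel$keys, oracle)
})

test_that("stores persist to one file and reopen without re-import", {
  st <- tiny_store(tiny_default_lines())
  create_selection(st, "keep", 1:2, "manual")
  create_wordset(st, "genes", c("CFTR"))
  path <- withr::local_tempfile(fileext = ".vstore")
  save_store(st, path)
  st2 <- open_store(path)
  expect_identical(st2$variants, st$variants)
  expect_identical(st2$selections$keep$keys, 1:2)
  expect_identical(st2$wordsets$genes, "CFTR")
  res <- vql_exec(st2, "SELECT chr, pos FROM keep")
  expect_identical(nrow(res), 2L)
})
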