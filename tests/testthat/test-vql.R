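# VQL lexer, parser, validator, serializer.

test_that("the flagship gene/impact query parses into the expected tree", {
  q <- paste0("SELECT chr, pos, ann.consequence, samples[‘NA1223’].gt ",
              "FROM variants WHERE ann.gene = ‘CFTR’ AND ann.impact = ‘HIGH’")
  ast <- parse_vql(q)
  expect_identical(ast$kind, "select")
  expect_length(ast$select_list, 4L)
  expect_identical(ast$select_list[[1]]$name, "chr")
  s <- ast$select_list[[4]]
  expect_identical(s$namespace, "sample")
  expect_identical(s$sample, "NA1223")
  expect_identical(s$name, "gt")
  expect_identical(ast$source, "variants")
  expect_identical(ast$filter$type, "and")
  expect_identical(ast$filter$children[[1]]$field$name, "gene")
  expect_identical(ast$filter$children[[1]]$value, "CFTR")
  expect_identical(ast$filter$children[[2]]$value, "HIGH")
})

test_that("the cohort query parses with bare fields, IN list and curly quotes", {
  q <- paste0("SELECT chr, pos FROM variants WHERE case_count_hom=3 ",
              "AND control_count_hom=0 AND impact IN ('HIGH', ‘MODERATE’)")
  ast <- parse_vql(q)
  expect_identical(ast$filter$type, "and")
  expect_length(ast$filter$children, 3L)
  leaf <- ast$filter$children[[3]]
  expect_identical(leaf$op, "in")
  expect_identical(unlist(leaf$value), c("HIGH", "MODERATE"))
  expect_identical(ast$filter$children[[1]]$field$namespace, "bare")
  expect_equal(ast$filter$children[[1]]$value, 3)
})

test_that("syntax errors carry location and offending token", {
  expect_error(parse_vql("SELECT FROM variants"), class = "vql_syntax_error")
  err <- tryCatch(parse_vql("SELEC chr FROM variants"),
                  vql_syntax_error = function(e) e)
  expect_match(conditionMessage(err), "line 1")
  expect_match(conditionMessage(err), "selec")
  expect_error(parse_vql(""), class = "vql_syntax_error")
  expect_error(parse_vql("SELECT chr FROM variants WHERE pos >"),
               class = "vql_syntax_error")
  expect_error(parse_vql("SELECT chr FROM variants extra"),
               class = "vql_syntax_error")
  expect_error(parse_vql("SELECT chr FROM variants WHERE qual ~ 3"),
               class = "vql_syntax_error")
  expect_error(parse_vql("SELECT chr FROM variants WHERE x IN ('a', 3)"),
               class = "vql_syntax_error")
})

test_that("operator precedence is NOT > AND > OR with parens overriding", {
  ast <- parse_vql("SELECT chr FROM variants WHERE NOT pos > 5 AND qual > 1 OR depth < 2")
  expect_identical(ast$filter$type, "or")
  left <- ast$filter$children[[1]]
  expect_identical(left$type, "and")
  expect_identical(left$children[[1]]$type, "not")
  expect_identical(left$children[[1]]$child$op, ">")
  ast2 <- parse_vql("SELECT chr FROM variants WHERE pos > 5 AND (qual > 1 OR depth < 2)")
  expect_identical(ast2$filter$type, "and")
  expect_identical(ast2$filter$children[[2]]$type, "or")
})

test_that("all statement kinds parse", {
  expect_identical(parse_vql("CREATE rare FROM variants WHERE qual > 30")$kind,
                   "create_selection")
  so <- parse_vql("CREATE both = rare & exonic")
  expect_identical(so$kind, "create_from_setop")
  expect_identical(so$op, "&")
  bed <- parse_vql("CREATE panel FROM variants INTERSECT 'genes.bed'")
  expect_identical(bed$kind, "create_from_bed")
  expect_identical(bed$bed_path, "genes.bed")
  expect_identical(parse_vql("DROP SELECTION rare")$what, "selection")
  expect_identical(parse_vql("DROP WORDSET genes")$what, "wordset")
  iw <- parse_vql("IMPORT WORDSET 'genes.txt' AS panel")
  expect_identical(iw$kind, "import_wordset")
  expect_identical(iw$path, "genes.txt")
  # other filter operators
  f <- parse_vql(paste0("SELECT chr FROM variants WHERE gene ~ '^CF' AND ",
                        "gene IN WORDSET 'panel' AND qual IS NOT NULL AND ",
                        "pos NOT IN (1, 2)"))$filter
  expect_identical(vapply(f$children, `[[`, character(1), "op"),
                   c("~", "in_wordset", "is_not_null", "not_in"))
})

test_that("validation resolves bare names core-first then annotation", {
  st <- tiny_store(tiny_default_lines())
  ast <- validate_ast(parse_vql("SELECT chr, impact FROM variants"), st)
  expect_identical(ast$select_list[[1]]$namespace, "core")
  expect_identical(ast$select_list[[1]]$name, "chrom")   # chr alias
  expect_identical(ast$select_list[[2]]$namespace, "ann")
  expect_identical(ast$select_list[[2]]$name, "impact")
  # bare dp resolves to the INFO field, depth to the core alias column
  ast2 <- validate_ast(parse_vql("SELECT dp, depth FROM variants"), st)
  expect_identical(vapply(ast2$select_list, `[[`, character(1), "namespace"),
                   c("core", "core"))
})

test_that("validation rejects unknown names and type mismatches", {
  st <- tiny_store(tiny_default_lines())
  bad <- list(
    "SELECT nope FROM variants",
    "SELECT chr FROM nope",
    "SELECT samples['NOPE'].gt FROM variants",
    "SELECT chr FROM variants WHERE qual > 'abc'",
    "SELECT chr FROM variants WHERE pos ~ 'x'",
    "SELECT chr FROM variants WHERE ann.gene IN WORDSET 'nope'",
    "SELECT ann.nope FROM variants",
    "SELECT chr FROM variants WHERE ann.gene = 3")
  for (q in bad)
    expect_error(validate_ast(parse_vql(q), st),
                 class = "vql_validation_error", label = q)
  # reserved words cannot name selections (refused at parse or validation)
  expect_error(vql_exec(st, "CREATE select FROM variants"),
               class = "vql_error")
  expect_error(create_selection(st, "where", 1L),
               class = "vql_validation_error")
})

test_that("serialization round-trips the printed queries and edge forms", {
  queries <- c(
    paste0("SELECT chr, pos, ann.consequence, samples[‘NA1223’].gt ",
           "FROM variants WHERE ann.gene = ‘CFTR’ AND ann.impact = ‘HIGH’"),
    paste0("SELECT chr, pos FROM variants WHERE case_count_hom=3 AND ",
           "control_count_hom=0 AND impact IN ('HIGH', ‘MODERATE’)"),
    "SELECT chr FROM variants",
    "select chr from variants where not (pos > 5 or pos < 2) limit 5 offset 2",
    "SELECT chr FROM variants WHERE gene IN WORDSET 'w' ORDER BY pos DESC, qual ASC",
    "CREATE x = a - b",
    "CREATE x FROM variants WHERE qual >= 12.5 INTERSECT 'p.bed'")
  for (q in queries) {
    ast <- parse_vql(q)
    expect_identical(parse_vql(serialize_ast(ast)), ast, label = q)
  }
  expect_identical(serialize_ast(parse_vql("select chr from variants")),
                   "SELECT chr FROM variants")
})

test_that("serialization round-trips 200 random ASTs (grammar totality)", {
  set.seed(20240917)
  samples <- c("S1", "S2")
  for (i in 1:200) {
    ast <- random_select_ast(samples)
    txt <- serialize_ast(ast)
    reparsed <- parse_vql(txt)
    expect_identical(reparsed, ast, label = txt)
    # idempotence of the canonical form
    expect_identical(serialize_ast(reparsed), txt)
  }
})
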