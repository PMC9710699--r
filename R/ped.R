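# PED pedigree parsing (PLINK-style 6+ column whitespace-delimited).

#' Parse a PED pedigree file
#'
#' Reads PLINK-style pedigree lines: `family individual father mother sex
#' phenotype`, whitespace-delimited, `#`-comment lines skipped. `0` in the
#' father/mother column means founder; phenotype `2` marks an affected
#' (case) sample, `1` unaffected (control), `0` or `-9` unknown. Parents
#' naming individuals absent from the file are kept as dangling references
#' with a warning, not an error.
#'
#' @param lines Character vector of PED lines, or a file path.
#' @return A list with `pedigree` (a `data.table`: `family`, `individual`,
#'   `father`, `mother`, `sex`, `phenotype`) and `warnings`.
#' @export
parse_ped <- function(lines) {
  if (length(lines) == 1L && !grepl("[\t\n ]", lines) && file.exists(lines))
    lines <- readLines(lines, warn = FALSE)
  warnings <- character(0)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) < 6L)
      vql_error(sprintf("PED line %d has %d columns; at least 6 required",
                        i, length(parts)), "vql_ped_error")
    sex <- suppressWarnings(as.integer(parts[5]))
    phen <- suppressWarnings(as.integer(parts[6]))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      family = parts[1], individual = parts[2],
      father = if (parts[3] == "0") NA_character_ else parts[3],
      mother = if (parts[4] == "0") NA_character_ else parts[4],
      sex = if (is.na(sex) || !sex %in% c(0L, 1L, 2L)) 0L else sex,
      phenotype = if (is.na(phen) || phen == -9L || !phen %in% c(0L, 1L, 2L)) 0L else phen
    )
  }
  ped <- if (length(rows)) data.table::rbindlist(rows) else data.table::data.table(
    family = character(0), individual = character(0), father = character(0),
    mother = character(0), sex = integer(0), phenotype = integer(0))
  if (anyDuplicated(ped$individual))
    vql_error(paste0("duplicate individual in PED: ",
                     paste(unique(ped$individual[duplicated(ped$individual)]),
                           collapse = ", ")), "vql_ped_error")
  for (col in c("father", "mother")) {
    dangling <- setdiff(stats::na.omit(ped[[col]]), ped$individual)
    if (length(dangling))
      warnings <- c(warnings, paste0("PED ", col, " reference(s) not in file: ",
                                     paste(dangling, collapse = ", ")))
  }
  list(pedigree = ped, warnings = warnings)
}
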