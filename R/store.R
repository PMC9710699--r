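# The embedded variant store: normalized tables held as data.tables inside
# an environment, persistable to a single file on disk.
#
# Tables:
#   fields      field catalogue (see fields.R)
#   samples     sample names + pedigree columns once a PED is linked
#   variants    one row per (chrom, pos, ref, alt) with core + INFO + count columns
#   annotations one row per transcript-level annotation, variant_id-linked
#   genotypes   one row per (variant_id, sample)
# plus named selections (sets of variant_ids) and wordsets (sets of strings).

RESERVED_SELECTION <- "variants"

#' Create an empty variant store
#'
#' The store is an environment holding the normalized tables produced by
#' [import_vcf()], plus named selections and wordsets. It can be persisted
#' to a single file with [save_store()] and reopened with [open_store()]
#' without re-importing.
#'
#' @param chr_prefix Chromosome-name harmonization policy used when
#'   intersecting with BED intervals: `"strip"` (default) compares names
#'   after removing a leading `"chr"`, `"keep"` compares verbatim.
#' @return An object of class `variant_store`.
#' @export
variant_store <- function(chr_prefix = c("strip", "keep")) {
  chr_prefix <- match.arg(chr_prefix)
  st <- new.env(parent = emptyenv())
  st$fields <- core_field_catalogue()[0]
  st$samples <- data.table::data.table(
    name = character(0), family = character(0), father = character(0),
    mother = character(0), sex = integer(0), phenotype = integer(0))
  st$variants <- data.table::data.table(variant_id = integer(0))
  st$annotations <- data.table::data.table(variant_id = integer(0))
  st$genotypes <- data.table::data.table(
    variant_id = integer(0), sample = character(0), gt = integer(0))
  st$selections <- list()   # name -> list(keys = integer ids, provenance = chr)
  st$wordsets <- list()     # name -> character vector
  st$chr_prefix <- chr_prefix
  st$annotation_source <- NA_character_
  class(st) <- "variant_store"
  st
}

#' @export
print.variant_store <- function(x, ...) {
  cat("<variant_store>\n")
  cat(sprintf("  variants:    %d\n", nrow(x$variants)))
  cat(sprintf("  annotations: %d\n", nrow(x$annotations)))
  cat(sprintf("  samples:     %d (%d cases, %d controls)\n", nrow(x$samples),
              sum(x$samples$phenotype == 2L), sum(x$samples$phenotype == 1L)))
  cat(sprintf("  selections:  %s\n",
              paste(c(RESERVED_SELECTION, names(x$selections)), collapse = ", ")))
  if (length(x$wordsets))
    cat(sprintf("  wordsets:    %s\n", paste(names(x$wordsets), collapse = ", ")))
  invisible(x)
}

#' Persist a variant store to a single file
#'
#' @param store A `variant_store`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "variant_store"))
  payload <- mget(ls(store), envir = store)
  saveRDS(payload, path)
  invisible(path)
}

#' Reopen a persisted variant store
#'
#' @param path File written by [save_store()].
#' @return A `variant_store`.
#' @export
open_store <- function(path) {
  payload <- readRDS(path)
  st <- new.env(parent = emptyenv())
  for (nm in names(payload)) assign(nm, payload[[nm]], envir = st)
  class(st) <- "variant_store"
  st
}

#' Variant identity keys for a set of internal ids
#'
#' Renders internal variant ids as stable `"chrom:pos:ref:alt"` identity
#' strings, the external representation of a variant's primary key.
#'
#' @param store A `variant_store`.
#' @param ids Integer variant ids (default: all variants).
#' @return Character vector of keys.
#' @export
variant_keys <- function(store, ids = NULL) {
  v <- store$variants
  if (!is.null(ids)) v <- v[match(ids, v$variant_id)]
  make_variant_key(v$chrom, v$pos, v$ref, v$alt)
}

# resolve a selection name to integer variant ids
get_selection_ids <- function(store, name) {
  if (identical(name, RESERVED_SELECTION)) return(store$variants$variant_id)
  sel <- store$selections[[name]]
  if (is.null(sel))
    vql_validation_error(paste0("unknown selection: ", sQuote(name)))
  sel$keys
}

#' List named selections in a store
#'
#' @param store A `variant_store`.
#' @return A `data.table` with `name`, `n_variants` and `provenance`; the
#'   reserved selection `variants` (all imported variants) is always first.
#' @export
list_selections <- function(store) {
  base <- data.table::data.table(
    name = RESERVED_SELECTION, n_variants = nrow(store$variants),
    provenance = "all imported variants")
  if (!length(store$selections)) return(base)
  rbind(base, data.table::rbindlist(lapply(names(store$selections), function(nm) {
    data.table::data.table(name = nm,
                           n_variants = length(store$selections[[nm]]$keys),
                           provenance = store$selections[[nm]]$provenance)
  })))
}

#' Create or replace a named selection
#'
#' @param store A `variant_store`.
#' @param name Selection name; the reserved name `variants` is refused, as
#'   are VQL keywords.
#' @param ids Integer variant ids; must all exist in the store.
#' @param provenance Free text recording how the selection was built
#'   (typically the VQL or set expression).
#' @param overwrite Replace an existing selection of the same name.
#' @return The selection (list with `keys`, `provenance`), invisibly.
#' @export
create_selection <- function(store, name, ids, provenance = "",
                             overwrite = FALSE) {
  check_selection_name(name)
  if (!overwrite && !is.null(store$selections[[name]]))
    vql_validation_error(paste0("selection ", sQuote(name),
                                " already exists (use overwrite)"))
  ids <- unique(as.integer(ids))
  bad <- setdiff(ids, store$variants$variant_id)
  if (length(bad))
    vql_validation_error(paste0("selection contains unknown variant ids: ",
                                paste(head(bad, 5), collapse = ", ")))
  store$selections[[name]] <- list(keys = sort(ids), provenance = provenance)
  invisible(store$selections[[name]])
}

check_selection_name <- function(name) {
  if (!grepl("^[a-zA-Z_][a-zA-Z0-9_]*$", name))
    vql_validation_error(paste0("invalid selection name: ", sQuote(name)))
  if (tolower(name) %in% c(RESERVED_SELECTION, VQL_KEYWORDS))
    vql_validation_error(paste0(sQuote(name), " is a reserved word"))
  invisible(name)
}

#' Drop a named selection
#'
#' @param store A `variant_store`.
#' @param name Selection name; `variants` cannot be dropped.
#' @return `TRUE` invisibly.
#' @export
drop_selection <- function(store, name) {
  if (identical(name, RESERVED_SELECTION))
    vql_validation_error("the reserved selection 'variants' cannot be dropped")
  if (is.null(store$selections[[name]]))
    vql_validation_error(paste0("unknown selection: ", sQuote(name)))
  store$selections[[name]] <- NULL
  invisible(TRUE)
}
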