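#' Construct a gene-set collection (classification framework)
#'
#' A classification framework is a named collection of gene sets tested
#' together and corrected for multiple testing together: examples are GO,
#' KEGG, data-driven network modules, or per-publication gene sets. Gene
#' identifier matching throughout the package is exact-string and
#' case-sensitive, so that mismatched identifier namespaces fail loudly
#' instead of silently shrinking sets.
#'
#' @param framework non-empty framework label (e.g. `"GO"`,
#'   `"network_modules"`, `"publications"`).
#' @param sets list of gene sets, each a list with elements `id` (unique
#'   within the collection), `description`, and `members` (non-empty
#'   character vector).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(framework, sets) {
  if (!is.character(framework) || length(framework) != 1L || !nzchar(framework)) {
    stop_input("framework label must be a non-empty string")
  }
  ids <- vapply(sets, function(s) as.character(s$id), "")
  if (anyDuplicated(ids)) {
    stop_input("duplicate gene-set id(s): %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(sets, function(s) {
    members <- unique(as.character(s$members))
    if (length(members) == 0L) stop_input("gene set '%s' has no members", s$id)
    list(id = as.character(s$id),
         description = if (is.null(s$description)) "" else as.character(s$description),
         members = members)
  })
  names(sets) <- ids
  structure(list(framework = framework, sets = sets),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(lapply(x$sets, `[[`, "members"))
  cat(sprintf("Gene-set collection '%s': %d sets", x$framework, length(x$sets)))
  if (length(sizes)) {
    cat(sprintf(" (sizes %d-%d, median %g)", min(sizes), max(sizes),
                stats::median(sizes)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a gene-set collection from a GMT file
#'
#' GMT (Broad dialect): one set per line, tab-separated fields
#' `id<TAB>description<TAB>member1<TAB>member2...`; at least one member is
#' required. The framework label defaults to the file name stem.
#'
#' @param path GMT file path.
#' @param framework optional framework label overriding the filename stem.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, framework = NULL) {
  if (!file.exists(path)) stop_input("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_input("line %d: GMT line needs at least 3 tab-separated fields (id, description, members...)",
               lineno[which(nf < 3L)[1]])
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    stop_input("duplicate gene-set id '%s' on lines %s", d,
               paste(lineno[ids == d], collapse = " and "))
  }
  sets <- lapply(fields, function(f) {
    list(id = f[1], description = f[2], members = f[-(1:2)][nzchar(f[-(1:2)])])
  })
  if (is.null(framework)) {
    framework <- sub("\\.[^.]*$", "", basename(path))
  }
  gene_set_collection(framework, sets)
}

#' Write a gene-set collection to a GMT file
#'
#' Members are written in canonical lexicographic order, so that
#' `read_gmt(write_gmt(x))` reproduces `x` exactly.
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$id, s$description, sort(s$members)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Load gene sets from a two-column mapping file
#'
#' Reads a two-column TSV mapping set identifiers to genes (for example,
#' publication identifier to gene: each published paper becomes one gene
#' set). Rows are grouped by the first column; repeated `(id, gene)` rows
#' are stored once. Singleton sets are retained — callers may filter.
#'
#' @param path two-column TSV path; a header row is detected and skipped
#'   when its first field is `set_id`, `id`, or `publication`.
#' @param framework framework label for the resulting collection.
#' @return a [gene_set_collection()]; an empty file yields an empty
#'   collection with a warning.
#' @export
load_mapping_sets <- function(path, framework) {
  if (!file.exists(path)) stop_input("mapping file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning(sprintf("mapping file '%s' is empty", path))
    return(gene_set_collection(framework, list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop_input("line %d: expected 2 tab-separated columns, found %d",
               lineno[which(nf != 2L)[1]], nf[which(nf != 2L)[1]])
  }
  ids <- vapply(fields, `[[`, "", 1L)
  genes <- vapply(fields, `[[`, "", 2L)
  if (tolower(ids[1]) %in% c("set_id", "id", "publication")) {
    ids <- ids[-1]
    genes <- genes[-1]
  }
  if (length(ids) == 0L) {
    warning(sprintf("mapping file '%s' has a header but no rows", path))
    return(gene_set_collection(framework, list()))
  }
  grouped <- split(genes, ids)
  sets <- lapply(names(grouped), function(id) {
    list(id = id, description = "", members = unique(grouped[[id]]))
  })
  gene_set_collection(framework, sets)
}
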