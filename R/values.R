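#' Read a genome-wide gene-value table
#'
#' Reads a two-column TSV mapping gene identifiers to numeric values — the
#' user's genome-scale measurement (log fold change, abundance, a statistic;
#' negative values signify depletion). A header row is auto-detected: if the
#' second field of the first row is not numeric it is treated as a header.
#' Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return named numeric vector (names = genes), validated by
#'   [validate_value_table()].
#' @export
read_value_table <- function(path) {
  if (!file.exists(path)) stop_input("value table not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_input("value table '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop_input("line %d: expected 2 tab-separated columns, found %d",
               lineno[which(nf != 2L)[1]], nf[which(nf != 2L)[1]])
  }
  first_val <- suppressWarnings(as.numeric(fields[[1]][2]))
  if (is.na(first_val)) { # header row
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  if (length(fields) == 0L) stop_input("value table '%s' has no data rows", path)
  genes <- vapply(fields, `[[`, "", 1L)
  raw <- vapply(fields, `[[`, "", 2L)
  values <- suppressWarnings(as.numeric(raw))
  if (anyNA(values)) {
    i <- which(is.na(values))[1]
    stop_input("line %d: non-numeric value '%s'", lineno[i], raw[i])
  }
  names(values) <- genes
  validate_value_table(values)
}

#' Validate a gene-value table
#'
#' @param values named numeric vector: unique gene names, finite values,
#'   at least 2 entries.
#' @return `values`, invisibly on error-free input.
#' @export
validate_value_table <- function(values) {
  if (!is.numeric(values) || is.null(names(values))) {
    stop_input("value table must be a named numeric vector")
  }
  if (length(values) < 2L) stop_input("value table needs at least 2 genes")
  if (any(!is.finite(values))) stop_input("value table contains non-finite values")
  if (anyDuplicated(names(values))) {
    stop_input("duplicate gene identifier(s) in value table: %s",
               paste(utils::head(unique(names(values)[duplicated(names(values))]), 5),
                     collapse = ", "))
  }
  if (any(!nzchar(names(values)))) stop_input("empty gene identifier in value table")
  values
}

#' Write a gene-value table as two-column TSV
#'
#' @param values named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_value_table <- function(values, path) {
  validate_value_table(values)
  utils::write.table(
    data.frame(gene = names(values), value = values),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
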