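#' Discover network modules from an association network
#'
#' End-to-end module discovery: optional confidence filtering, restriction
#' to the largest connected component, confidence-weighted diffusion state
#' distances, average-linkage (UPGMA) clustering, and extraction of all
#' clusters with sizes within the module bounds. A manifest recording every
#' parameter (and the package version) accompanies the result, so a run can
#' be reproduced exactly.
#'
#' @param net an [association_network()] or a path to an edge-list TSV.
#' @param cutoff optional combined-confidence cutoff or preset name applied
#'   before DSD (see [filter_by_confidence()]); `NULL` uses the full score
#'   range.
#' @param dsd_steps passed to [dsd_matrix()] as `steps`.
#' @param min_size,max_size module size bounds (defaults 5 and 200).
#' @param dialect edge-list dialect when `net` is a path.
#' @return list of class `module_discovery` with elements `network` (the
#'   analyzed component), `dsd`, `tree`, `modules` (a
#'   [gene_set_collection()]), and `manifest`.
#' @export
discover_modules <- function(net, cutoff = NULL, dsd_steps = "converged",
                             min_size = 5L, max_size = 200L,
                             dialect = "auto") {
  input_path <- if (is.character(net)) net else NA_character_
  if (is.character(net)) net <- read_network(net, dialect = dialect)
  stopifnot(inherits(net, "assoc_network"))
  n_input <- length(net$nodes)
  if (!is.null(cutoff)) net <- filter_by_confidence(net, cutoff)
  net <- suppressMessages(largest_component(net))
  d <- dsd_matrix(net, steps = dsd_steps)
  tree <- hcluster_average(d)
  modules <- extract_modules(tree, min_size = min_size, max_size = max_size)
  manifest <- list(
    tool = "netenrich", version = as.character(utils::packageVersion("netenrich")),
    command = "cluster", input = input_path,
    cutoff = if (is.null(cutoff)) "none" else cutoff,
    dsd_steps = dsd_steps, min_size = min_size, max_size = max_size,
    n_nodes_input = n_input, n_nodes_component = length(net$nodes),
    n_edges = nrow(net$edges), n_modules = length(modules)
  )
  structure(list(network = net, dsd = d, tree = tree, modules = modules,
                 manifest = manifest),
            class = "module_discovery")
}

#' @export
print.module_discovery <- function(x, ...) {
  cat(sprintf("Module discovery: %d-node component, %d modules of size %d-%d\n",
              length(x$network$nodes), length(x$modules),
              x$manifest$min_size, x$manifest$max_size))
  invisible(x)
}

#' Cluster pipeline with file outputs
#'
#' Runs [discover_modules()] and writes `modules.gmt`, `dsd.tsv`, and
#' `manifest.json` into `out_dir`. Rerunning with the same inputs and
#' parameters reproduces the outputs byte-identically.
#'
#' @inheritParams discover_modules
#' @param out_dir output directory, created if needed.
#' @return invisibly, the `module_discovery` result.
#' @export
cmd_cluster <- function(net, out_dir, cutoff = NULL, dsd_steps = "converged",
                        min_size = 5L, max_size = 200L, dialect = "auto") {
  res <- discover_modules(net, cutoff = cutoff, dsd_steps = dsd_steps,
                          min_size = min_size, max_size = max_size,
                          dialect = dialect)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_gmt(res$modules, file.path(out_dir, "modules.gmt"))
  write_dsd(res$dsd, file.path(out_dir, "dsd.tsv"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Enrichment pipeline with file outputs
#'
#' Reads a gene-value table and one or more gene-set files (GMT, or
#' two-column mapping TSV — detected by extension `.gmt` vs other), runs
#' [run_enrichment()], and writes `results.tsv` plus `manifest.json` into
#' `out_dir`. If no gene set of any collection shares a single identifier
#' with the input, the run aborts with a diagnostic listing example
#' identifiers from each side — the usual cause is mismatched identifier
#' namespaces, which must fail loudly.
#'
#' @param values_path two-column TSV of gene values.
#' @param set_paths character vector of gene-set file paths.
#' @param out_dir output directory, created if needed.
#' @inheritParams run_enrichment
#' @return invisibly, the `enrichment_result` data frame.
#' @export
cmd_enrich <- function(values_path, set_paths, out_dir,
                       large_set_threshold = 1000L, n_perm = 10000L,
                       seed = NULL, exhaustive_limit = 100000L,
                       ks_mode = "two_sample") {
  values <- read_value_table(values_path)
  collections <- lapply(set_paths, function(p) {
    if (grepl("\\.gmt$", p, ignore.case = TRUE)) read_gmt(p)
    else load_mapping_sets(p, framework = sub("\\.[^.]*$", "", basename(p)))
  })
  all_members <- unique(unlist(lapply(collections, function(col) {
    unlist(lapply(col$sets, `[[`, "members"), use.names = FALSE)
  })))
  if (length(intersect(all_members, names(values))) == 0L) {
    stop_input(
      "no gene identifier is shared between the value table and any gene set (namespace mismatch?); value-table examples: %s; gene-set examples: %s",
      paste(utils::head(names(values), 5), collapse = ", "),
      paste(utils::head(all_members, 5), collapse = ", ")
    )
  }
  results <- run_enrichment(values, collections,
                            large_set_threshold = large_set_threshold,
                            n_perm = n_perm, seed = seed,
                            exhaustive_limit = exhaustive_limit,
                            ks_mode = ks_mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_enrichment_results(results, file.path(out_dir, "results.tsv"))
  counts <- table(results$framework, results$method)
  manifest <- list(
    tool = "netenrich", version = as.character(utils::packageVersion("netenrich")),
    command = "enrich", values = values_path, sets = as.list(set_paths),
    large_set_threshold = large_set_threshold, n_perm = n_perm,
    seed = if (is.null(seed)) "none" else seed,
    exhaustive_limit = exhaustive_limit, ks_mode = ks_mode,
    n_genes = length(values), n_results = nrow(results),
    tested_per_framework = as.list(stats::setNames(
      as.integer(table(results$framework)), names(table(results$framework))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(paste(utils::capture.output(print(counts)), collapse = "\n"))
  invisible(results)
}

#' Parse a key = value configuration file
#'
#' Minimal TOML-style configuration: one `key = value` pair per line,
#' `#` comments, numeric and logical values auto-converted. Command-line
#' flags override configuration values.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3L) stop_input("config line %d is not 'key = value': %s", i, lines[i])
    key <- m[2]
    val <- gsub("^[\"']|[\"']$", "", trimws(m[3]))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(toupper(val))
      else val
  }
  out
}
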