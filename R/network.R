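#' Evidence channel names
#'
#' The seven independent evidence channels of a channel-scored association
#' network: conserved genomic neighborhood, gene fusion, phylogenetic
#' co-occurrence, co-expression, experimental/biochemical data, curated
#' pathway/complex databases, and literature text mining. Each channel may
#' additionally carry a `"<channel>_transferred"` sub-score for evidence
#' transferred from other organisms.
#'
#' @format Character vector of length 7.
#' @export
CHANNELS <- c(
  "neighborhood", "fusion", "cooccurrence", "coexpression",
  "experiments", "databases", "textmining"
)

#' Confidence cutoff presets
#'
#' Named confidence cutoffs conventionally used when filtering association
#' networks. Only `"highest"` (0.900) is a fixed constant of the scoring
#' scheme; `"high"`, `"medium"` and `"low"` are the customary defaults.
#'
#' @format Named numeric vector.
#' @export
CONFIDENCE_PRESETS <- c(highest = 0.900, high = 0.700, medium = 0.400, low = 0.150)

.transferred <- function(channel) paste0(channel, "_transferred")

.all_channel_cols <- function() c(CHANNELS, .transferred(CHANNELS))

# canonical unordered pair: lexicographically smaller identifier first
.canonicalize_pairs <- function(a, b) {
  swap <- b < a
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

#' Construct an association network
#'
#' An `assoc_network` holds an undirected, weighted graph of proteins. Edges
#' are stored canonically (lexicographically smaller identifier first), at
#' most one edge per unordered pair, with per-channel confidence scores in
#' \[0, 1\] and a `combined` confidence. Absent channel evidence is scored 0,
#' never `NA`. Nodes may be isolated.
#'
#' @param edges data frame with character columns `protein_a`, `protein_b`,
#'   optional per-channel score columns (see [CHANNELS]), and a numeric
#'   `combined` column. If `combined` is absent it is computed from the
#'   channel columns with [combine_channels()] at prior 0.
#' @param nodes character vector of node identifiers; defaults to the edge
#'   endpoints. May include isolated nodes.
#' @return An object of class `assoc_network`: a list with elements `nodes`
#'   (character) and `edges` (data frame).
#' @export
association_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("protein_a", "protein_b") %in% names(edges))) {
    stop_input("edges must have columns 'protein_a' and 'protein_b'")
  }
  edges$protein_a <- as.character(edges$protein_a)
  edges$protein_b <- as.character(edges$protein_b)
  if (any(edges$protein_a == edges$protein_b)) {
    stop_input("self-loops are not allowed in an association network")
  }
  cp <- .canonicalize_pairs(edges$protein_a, edges$protein_b)
  edges$protein_a <- cp$a
  edges$protein_b <- cp$b

  score_cols <- intersect(names(edges), c(.all_channel_cols(), "combined"))
  for (col in score_cols) {
    s <- edges[[col]]
    if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0 | s > 1)) {
      stop_input("score column '%s' must be finite and within [0, 1]", col)
    }
  }
  if (!"combined" %in% names(edges)) {
    chans <- intersect(names(edges), .all_channel_cols())
    if (length(chans) == 0L) {
      stop_input("edges need a 'combined' column or at least one channel column")
    }
    edges$combined <- combine_channels(edges[chans], prior = 0)
  }

  key <- paste(edges$protein_a, edges$protein_b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    # exact duplicates collapse silently; conflicting scores are an error
    for (k in dup) {
      rows <- edges[key == k, score_cols, drop = FALSE]
      if (nrow(unique(rows)) > 1L) {
        stop_input("conflicting duplicate scores for pair '%s'", gsub("\r", " - ", k))
      }
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL

  endpoints <- unique(c(edges$protein_a, edges$protein_b))
  if (is.null(nodes)) {
    nodes <- endpoints
  } else {
    nodes <- unique(as.character(nodes))
    if (!all(endpoints %in% nodes)) {
      stop_input("every edge endpoint must be listed in 'nodes'")
    }
  }
  structure(list(nodes = sort(nodes), edges = edges), class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf(
    "Association network: %d nodes, %d edges\n",
    length(x$nodes), nrow(x$edges)
  ))
  chans <- intersect(names(x$edges), .all_channel_cols())
  if (length(chans)) cat("  channels:", paste(chans, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    cat(sprintf(
      "  combined score range: [%.3f, %.3f]\n",
      min(x$edges$combined), max(x$edges$combined)
    ))
  }
  invisible(x)
}

# column-name aliases accepted in edge-list headers (STRING download dialect)
.protein_aliases <- list(
  protein_a = c("protein_a", "protein1", "node1", "item_id_a"),
  protein_b = c("protein_b", "protein2", "node2", "item_id_b")
)
.combined_aliases <- c("combined", "combined_score", "score")
.channel_aliases <- c(cooccurence = "cooccurrence") # historical spelling

.resolve_header <- function(header) {
  out <- character(length(header))
  h <- tolower(header)
  for (target in names(.protein_aliases)) {
    hit <- which(h %in% .protein_aliases[[target]])
    if (length(hit) != 1L) {
      stop_input("header must name exactly one '%s' column (aliases: %s)",
                 target, paste(.protein_aliases[[target]], collapse = ", "))
    }
    out[hit] <- target
  }
  for (i in which(out == "")) {
    nm <- h[i]
    if (nm %in% names(.channel_aliases)) nm <- .channel_aliases[[nm]]
    nm <- sub("^cooccurence_", "cooccurrence_", nm)
    if (nm %in% .combined_aliases) {
      out[i] <- "combined"
    } else if (nm %in% .all_channel_cols()) {
      out[i] <- nm
    } else {
      out[i] <- NA_character_ # unrecognized column, dropped with a warning
    }
  }
  out
}

#' Read a channel-scored association network from a TSV edge list
#'
#' Reads a tab- or whitespace-separated edge list with a header naming two
#' protein columns (`protein1`/`protein2`, `protein_a`/`protein_b`, ...) and
#' one or more score columns: per-channel scores named as in [CHANNELS]
#' (optionally with `_transferred` sub-scores) and/or a combined score
#' (`combined_score`, `combined`, or `score`). Lines starting with `#` are
#' ignored. Two score dialects are supported: `string1000` (integers 0-1000,
#' as in STRING download files; divided by 1000 on read) and `float`
#' (0-1). `auto` selects `string1000` iff any score exceeds 1.
#'
#' Self-loop rows are skipped with a warning. Rows with the wrong column
#' count or non-numeric scores raise a parse error naming the line.
#'
#' @param path file path.
#' @param dialect one of `"auto"`, `"string1000"`, `"float"`.
#' @return An [association_network()].
#' @export
read_network <- function(path, dialect = c("auto", "string1000", "float")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("network file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1L) stop_input("network file '%s' is empty", path)

  split_fields <- function(x) strsplit(x, "[\t ]+")[[1]]
  header <- split_fields(lines[1])
  cols <- .resolve_header(header)
  if (anyNA(cols)) {
    warning(sprintf("ignoring unrecognized column(s): %s",
                    paste(header[is.na(cols)], collapse = ", ")))
  }
  if (length(lines) < 2L) stop_input("network file '%s' has a header but no rows", path)

  rows <- lapply(lines[-1], split_fields)
  nf <- lengths(rows)
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop_input("line %d: expected %d fields, found %d",
               lineno[-1][bad[1]], length(header), nf[bad[1]])
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- cols

  score_cols <- cols[!is.na(cols) & !cols %in% c("protein_a", "protein_b")]
  if (length(score_cols) == 0L) stop_input("no score column found in header")
  scores <- matrix(NA_real_, nrow(mat), length(score_cols),
                   dimnames = list(NULL, score_cols))
  for (col in score_cols) {
    v <- suppressWarnings(as.numeric(mat[, col]))
    if (anyNA(v)) {
      stop_input("line %d: non-numeric score '%s' in column '%s'",
                 lineno[-1][which(is.na(v))[1]], mat[which(is.na(v))[1], col], col)
    }
    scores[, col] <- v
  }
  if (any(scores < 0 | scores > 1000)) {
    i <- which(scores < 0 | scores > 1000, arr.ind = TRUE)[1, ]
    stop_input("line %d: score %g outside [0, 1000]",
               lineno[-1][i[1]], scores[i[1], i[2]])
  }
  if (dialect == "auto") {
    dialect <- if (any(scores > 1)) "string1000" else "float"
  }
  if (dialect == "string1000") scores <- scores / 1000
  if (any(scores > 1)) {
    i <- which(scores > 1, arr.ind = TRUE)[1, ]
    stop_input("line %d: score %g outside [0, 1] in float dialect",
               lineno[-1][i[1]], scores[i[1], i[2]] )
  }

  edges <- data.frame(
    protein_a = mat[, "protein_a"], protein_b = mat[, "protein_b"],
    stringsAsFactors = FALSE
  )
  for (col in score_cols) edges[[col]] <- scores[, col]

  self <- edges$protein_a == edges$protein_b
  if (any(self)) {
    warning(sprintf("skipping %d self-loop row(s) (first at line %d)",
                    sum(self), lineno[-1][which(self)[1]]))
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop_input("network file '%s' contains no usable edges", path)
  association_network(edges)
}

#' Write an association network as a TSV edge list
#'
#' Inverse of [read_network()]. In `string1000` dialect scores are written as
#' round-trip-exact integers 0-1000; in `float` dialect with three decimals.
#'
#' @param net an [association_network()].
#' @param path output file path.
#' @param dialect `"string1000"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("string1000", "float")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(net, "assoc_network"))
  edges <- net$edges
  score_cols <- setdiff(names(edges), c("protein_a", "protein_b"))
  out <- edges[c("protein_a", "protein_b")]
  names(out) <- c("protein1", "protein2")
  for (col in score_cols) {
    out[[if (col == "combined") "combined_score" else col]] <-
      if (dialect == "string1000") {
        format(as.integer(round(edges[[col]] * 1000)), scientific = FALSE)
      } else {
        sprintf("%.3f", edges[[col]])
      }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combine per-channel confidence scores into one confidence
#'
#' Integrates the evidence channels of an association into a single
#' confidence using the noisy-OR rule of probabilistic score integration:
#' each enabled score is first corrected for the prior probability of a
#' random pair being functionally linked, `s' = max(0, (s - p) / (1 - p))`,
#' the corrected scores are combined as `1 - prod(1 - s'_i)`, and the prior
#' is restored: `S = 1 - (1 - p) * prod(1 - s'_i)`. Disabled channels
#' contribute nothing; a channel's `_transferred` sub-score, when present,
#' enters the product as an additional independent term whenever its channel
#' is enabled. The result is monotone non-decreasing in every enabled score
#' and, at prior 0, never below the maximum enabled score.
#'
#' @param channels a named numeric vector of channel scores, or a data frame
#'   of per-edge channel score columns (vectorized over rows). Names must be
#'   drawn from [CHANNELS] or their `_transferred` variants.
#' @param enabled character vector of enabled channel names (base names, not
#'   `_transferred`); defaults to all seven.
#' @param prior prior probability in \[0, 1) that a random pair is linked.
#' @return numeric confidence(s) in \[0, 1\].
#' @export
combine_channels <- function(channels, enabled = CHANNELS, prior = 0) {
  if (!is.numeric(prior) || length(prior) != 1L || prior < 0 || prior >= 1) {
    stop_input("prior must be a single value in [0, 1)")
  }
  unknown <- setdiff(enabled, CHANNELS)
  if (length(unknown)) {
    stop_input("unknown channel name(s): %s", paste(unknown, collapse = ", "))
  }
  if (length(enabled) == 0L) stop_input("at least one channel must be enabled")

  if (is.data.frame(channels)) {
    cols <- channels
  } else {
    if (is.null(names(channels))) stop_input("channel scores must be named")
    cols <- as.data.frame(as.list(channels))
  }
  bad <- setdiff(names(cols), .all_channel_cols())
  if (length(bad)) {
    stop_input("unknown channel name(s): %s", paste(bad, collapse = ", "))
  }
  use <- names(cols)[sub("_transferred$", "", names(cols)) %in% enabled]
  keep_prob <- rep(1, nrow(cols))
  for (col in use) {
    s <- cols[[col]]
    if (any(!is.finite(s)) || any(s < 0 | s > 1)) {
      stop_input("channel '%s' has scores outside [0, 1]", col)
    }
    keep_prob <- keep_prob * (1 - pmax(0, (s - prior) / (1 - prior)))
  }
  1 - (1 - prior) * keep_prob
}

#' Score the curated-database evidence channel
#'
#' The curated-database channel records co-membership of protein pairs in
#' expert-curated pathways or complexes. It is the one channel exempt from
#' benchmark calibration: every curated association receives the same high,
#' uniform confidence of 0.900. Duplicate records of the same unordered pair
#' (e.g. from two source databases) collapse to a single association;
#' self-pair records are skipped with a warning.
#'
#' @param records a two-column data frame (or matrix) of protein identifier
#'   pairs, one curated co-membership record per row.
#' @return data frame with columns `protein_a`, `protein_b`, `databases`
#'   (all 0.900), one row per distinct pair, canonically ordered.
#' @export
score_database_channel <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      databases = numeric()))
  }
  if (ncol(records) < 2L) stop_input("records must have two columns of protein ids")
  a <- as.character(records[[1]])
  b <- as.character(records[[2]])
  self <- a == b
  if (any(self)) {
    warning(sprintf("skipping %d self-pair record(s)", sum(self)))
    a <- a[!self]
    b <- b[!self]
  }
  cp <- .canonicalize_pairs(a, b)
  key <- !duplicated(paste(cp$a, cp$b, sep = "\r"))
  out <- data.frame(protein_a = cp$a[key], protein_b = cp$b[key],
                    databases = rep(0.900, sum(key)),
                    stringsAsFactors = FALSE)
  out[order(out$protein_a, out$protein_b), , drop = FALSE]
}

#' Filter a network by combined confidence
#'
#' Retains edges whose combined confidence is at least `cutoff`. The node
#' set is unchanged, so filtering can create isolated nodes. `cutoff` may be
#' a preset name (see [CONFIDENCE_PRESETS]); `"highest"` maps to 0.900.
#' Filtering is idempotent.
#'
#' @param net an [association_network()].
#' @param cutoff numeric in \[0, 1\] or a preset name.
#' @return the filtered `assoc_network`.
#' @export
filter_by_confidence <- function(net, cutoff) {
  stopifnot(inherits(net, "assoc_network"))
  if (is.character(cutoff)) {
    if (!cutoff %in% names(CONFIDENCE_PRESETS)) {
      stop_input("unknown confidence preset '%s' (known: %s)", cutoff,
                 paste(names(CONFIDENCE_PRESETS), collapse = ", "))
    }
    cutoff <- CONFIDENCE_PRESETS[[cutoff]]
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    stop_input("cutoff must be a single value in [0, 1] or a preset name")
  }
  net$edges <- net$edges[net$edges$combined >= cutoff, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[c("protein_a", "protein_b")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}

#' Restrict a network to its largest connected component
#'
#' Diffusion state distances are defined only on a connected graph; this
#' helper drops all nodes (and their edges) outside the largest connected
#' component. Isolated nodes count as singleton components.
#'
#' @param net an [association_network()].
#' @return the restricted `assoc_network`; a message reports how many nodes
#'   were dropped.
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  comp <- igraph::components(.as_igraph(net))
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  dropped <- setdiff(net$nodes, keep)
  if (length(dropped)) {
    message(sprintf("largest_component: dropped %d of %d nodes",
                    length(dropped), length(net$nodes)))
  }
  edges <- net$edges[net$edges$protein_a %in% keep &
                     net$edges$protein_b %in% keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(keep), edges = edges), class = "assoc_network")
}

.is_connected <- function(net) {
  igraph::is_connected(.as_igraph(net))
}
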