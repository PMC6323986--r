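#' Average-linkage hierarchical clustering of a DSD matrix
#'
#' Clusters network nodes by their diffusion state distances with
#' agglomerative average linkage (UPGMA): the distance between two clusters
#' is the unweighted mean over all cross-pair distances. Average linkage is
#' monotone, so merge heights are non-decreasing, and the result is
#' deterministic for a given input.
#'
#' @param d a `dsd_matrix` (see [dsd_matrix()]) or any symmetric,
#'   zero-diagonal, non-negative distance matrix with node labels; n >= 2.
#' @return an object of class `hclust` (see [stats::hclust()]) whose
#'   `labels` are the node identifiers.
#' @export
hcluster_average <- function(d) {
  m <- unclass(as.matrix(d))
  .validate_dsd(m)
  if (nrow(m) < 2L) stop_input("clustering needs at least 2 nodes")
  if (is.null(rownames(m))) stop_input("distance matrix must have node labels")
  stats::hclust(stats::as.dist(m), method = "average")
}

# leaf sets of every internal node of an hclust tree, in merge order
.merge_members <- function(hc) {
  n_merges <- nrow(hc$merge)
  members <- vector("list", n_merges)
  for (i in seq_len(n_merges)) {
    pick <- function(j) if (j < 0) hc$labels[-j] else members[[j]]
    members[[i]] <- c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))
  }
  members
}

#' Extract network-module gene sets from a dendrogram
#'
#' Every internal node of the dendrogram whose leaf set has a size within
#' `[min_size, max_size]` becomes one gene set — clusters are taken from all
#' hierarchy levels, not from a single cut, so the collection is
#' multi-scale and nested (laminar). The defaults 5 and 200 are the
#' conventional bounds for data-driven network modules entered into
#' enrichment testing: below 5 a module carries too little signal, above 200
#' it is too unspecific. Identical member sets (possible after user
#' post-processing of the tree) collapse to the instance with the lowest
#' merge height. An empty collection is a valid result.
#'
#' @param hc an `hclust` tree from [hcluster_average()].
#' @param min_size,max_size inclusive size bounds; `min_size >= 2`.
#' @param framework framework label of the emitted collection.
#' @return a [gene_set_collection()]; set ids are `M<k>` in order of merge
#'   height, descriptions record the linkage height and size.
#' @export
extract_modules <- function(hc, min_size = 5L, max_size = 200L,
                            framework = "network_modules") {
  stopifnot(inherits(hc, "hclust"))
  min_size <- as.integer(min_size)
  max_size <- as.integer(max_size)
  if (min_size < 2L) stop_input("min_size must be >= 2")
  if (max_size < min_size) stop_input("max_size must be >= min_size")
  members <- .merge_members(hc)
  sizes <- lengths(members)
  keep <- which(sizes >= min_size & sizes <= max_size)
  if (length(keep) == 0L) return(gene_set_collection(framework, list()))

  keep <- keep[order(hc$height[keep], keep)]
  canon <- vapply(members[keep], function(m) paste(sort(m), collapse = "\r"), "")
  first <- !duplicated(canon) # lowest height wins: keep is height-sorted
  keep <- keep[first]
  sets <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    list(id = sprintf("M%d", k),
         description = sprintf("height=%.8g;size=%d", hc$height[i], sizes[i]),
         members = sort(members[[i]]))
  })
  gene_set_collection(framework, sets)
}
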