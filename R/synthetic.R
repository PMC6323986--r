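#' Generate a planted-partition association network
#'
#' Synthetic stand-in for an organism-wide confidence-weighted network:
#' nodes are split into ground-truth blocks ("planted modules") plus
#' optional unassigned background nodes; each within-block pair is linked
#' with probability `p_in` and each other pair with probability `p_out`.
#' Edge confidences are drawn from Beta distributions — a high-mode
#' `Beta(8, 2)` within blocks and a low-mode `Beta(2, 8)` elsewhere — which
#' mimics the shape of confidence scores (bounded, skewed) without claiming
#' any database's empirical distribution. The defaults (two blocks of 20,
#' `p_in = 0.8`, `p_out = 0.05`) give strongly separated modules that a
#' correct module-discovery pipeline must recover.
#'
#' Only the largest connected component is returned (with its blocks
#' restricted accordingly), since diffusion state distances require a
#' connected graph; a message reports any restriction.
#'
#' @param block_sizes integer vector of planted block sizes.
#' @param n_background additional nodes belonging to no block.
#' @param p_in,p_out within-block / other edge probabilities, in \[0, 1\].
#' @param beta_in,beta_out length-2 shape parameters of the within/between
#'   Beta confidence distributions.
#' @param seed integer seed (mandatory: outputs are bit-reproducible given
#'   the spec and seed).
#' @return list with elements `network` (an [association_network()]),
#'   `blocks` (named list of member vectors, the ground truth restricted to
#'   retained nodes), and `params`.
#' @export
make_modular_network <- function(block_sizes = c(20L, 20L), n_background = 0L,
                                 p_in = 0.8, p_out = 0.05,
                                 beta_in = c(8, 2), beta_out = c(2, 8),
                                 seed) {
  if (missing(seed)) stop_input("seed is mandatory for synthetic networks")
  if (any(p_in < 0 | p_in > 1) || any(p_out < 0 | p_out > 1)) {
    stop_input("p_in and p_out must be in [0, 1]")
  }
  n <- sum(block_sizes) + n_background
  if (n < 2L) stop_input("spec yields an empty graph")
  set.seed(as.integer(seed))

  nodes <- sprintf("P%04d", seq_len(n))
  block_of <- rep(c(seq_along(block_sizes), NA), c(block_sizes, n_background))

  pairs <- utils::combn(n, 2L)
  same <- !is.na(block_of[pairs[1, ]]) & !is.na(block_of[pairs[2, ]]) &
    block_of[pairs[1, ]] == block_of[pairs[2, ]]
  p_edge <- ifelse(same, p_in, p_out)
  present <- stats::runif(ncol(pairs)) < p_edge
  if (!any(present)) stop_input("spec yields an empty graph (no edges drawn)")

  same <- same[present]
  a <- pairs[1, present]
  b <- pairs[2, present]
  w <- numeric(length(a))
  w[same] <- stats::rbeta(sum(same), beta_in[1], beta_in[2])
  w[!same] <- stats::rbeta(sum(!same), beta_out[1], beta_out[2])
  w <- pmin(pmax(w, 1e-6), 1)

  net <- association_network(data.frame(
    protein_a = nodes[a], protein_b = nodes[b], combined = w,
    stringsAsFactors = FALSE
  ), nodes = nodes)
  net <- largest_component(net)

  blocks <- lapply(seq_along(block_sizes), function(bl) {
    intersect(nodes[which(block_of == bl)], net$nodes)
  })
  names(blocks) <- sprintf("block_%d", seq_along(blocks))
  list(network = net, blocks = blocks,
       params = list(block_sizes = block_sizes, n_background = n_background,
                     p_in = p_in, p_out = p_out, beta_in = beta_in,
                     beta_out = beta_out, seed = seed))
}

#' Generate a gene-value table with planted enrichment signal
#'
#' Synthetic stand-in for a genome-wide measurement (e.g. log fold
#' changes): background genes receive `Normal(0, sd)` values and planted
#' genes `Normal(delta, sd)`, so the planted set carries a mean shift of
#' `delta` that an enrichment test should detect. `delta = 0` yields a pure
#' null table for type-I-error checks.
#'
#' @param genes character vector of gene identifiers.
#' @param planted subset of `genes` carrying the shifted signal (may be
#'   empty).
#' @param delta mean shift of planted values.
#' @param sd common standard deviation (> 0).
#' @param seed integer seed (mandatory).
#' @return named numeric vector (a valid gene-value table).
#' @export
make_value_table <- function(genes, planted = character(), delta = 2, sd = 1,
                             seed) {
  if (missing(seed)) stop_input("seed is mandatory for synthetic value tables")
  genes <- as.character(genes)
  planted <- as.character(planted)
  if (!all(planted %in% genes)) {
    stop_input("planted genes must be a subset of 'genes' (offending: %s)",
               paste(utils::head(setdiff(planted, genes), 5), collapse = ", "))
  }
  if (!is.numeric(sd) || sd <= 0) stop_input("sd must be > 0")
  set.seed(as.integer(seed))
  values <- stats::rnorm(length(genes), mean = 0, sd = sd)
  names(values) <- genes
  values[planted] <- stats::rnorm(length(planted), mean = delta, sd = sd)
  validate_value_table(values)
}

#' Write a complete synthetic fixture directory
#'
#' Generates a planted-partition network, a planted-signal value table over
#' its nodes, and writes everything in the dialects the package readers
#' consume: `network.tsv` (float dialect edge list), `values.tsv`,
#' `ground_truth.gmt` (the planted blocks), plus `params.json`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed (mandatory).
#' @param delta,sd value-table signal parameters; the first planted block is
#'   the signal carrier.
#' @inheritParams make_modular_network
#' @return invisibly, a named list of the written paths.
#' @export
write_fixture_dir <- function(dir, seed, block_sizes = c(20L, 20L),
                              n_background = 0L, p_in = 0.8, p_out = 0.05,
                              delta = 2, sd = 1) {
  if (missing(seed)) stop_input("seed is mandatory for fixture generation")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- make_modular_network(block_sizes = block_sizes,
                              n_background = n_background,
                              p_in = p_in, p_out = p_out, seed = seed)
  values <- make_value_table(sim$network$nodes, planted = sim$blocks[[1]],
                             delta = delta, sd = sd, seed = seed + 1L)
  truth <- gene_set_collection("ground_truth", lapply(names(sim$blocks), function(nm) {
    list(id = nm, description = "planted block", members = sim$blocks[[nm]])
  }))
  paths <- list(
    network = file.path(dir, "network.tsv"),
    values = file.path(dir, "values.tsv"),
    ground_truth = file.path(dir, "ground_truth.gmt"),
    params = file.path(dir, "params.json")
  )
  write_network(sim$network, paths$network, dialect = "float")
  write_value_table(values, paths$values)
  write_gmt(truth, paths$ground_truth)
  jsonlite::write_json(
    c(sim$params, list(delta = delta, sd = sd, value_seed = seed + 1L)),
    paths$params, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
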