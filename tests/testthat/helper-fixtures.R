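# Shared fixture builders; everything is generated in code, no stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random connected weighted network: spanning tree plus extra random edges
random_connected_network <- function(n, extra = n, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n))
  a <- integer(0); b <- integer(0)
  for (i in 2:n) { # random spanning tree
    a <- c(a, sample.int(i - 1, 1)); b <- c(b, i)
  }
  pairs <- utils::combn(n, 2)
  key_have <- paste(pmin(a, b), pmax(a, b))
  key_all <- paste(pairs[1, ], pairs[2, ])
  avail <- which(!(key_all %in% key_have))
  pick <- sample(avail, min(extra, length(avail)))
  a <- c(a, pairs[1, pick]); b <- c(b, pairs[2, pick])
  association_network(data.frame(
    protein_a = nodes[a], protein_b = nodes[b],
    combined = round(runif(length(a), 0.05, 1), 3)
  ))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# independent step-up BH oracle: q_i = min_{j: p_(j) >= p_(i)} min(1, p_(j) m / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

toy_gmt_collection <- function() {
  gene_set_collection("toy", list(
    list(id = "s1", description = "first", members = c("g1", "g2", "g3")),
    list(id = "s2", description = "second", members = c("g2", "g4", "g5", "g6"))
  ))
}
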