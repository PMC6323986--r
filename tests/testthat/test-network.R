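test_that("read_network handles both score dialects and canonicalizes edges", {
  p <- write_lines_tmp(c(
    "protein1\tprotein2\tcombined_score",
    "A\tB\t900", "B\tC\t400", "C\tD\t150"
  ))
  net <- read_network(p)
  expect_s3_class(net, "assoc_network")
  expect_equal(nrow(net$edges), 3)
  expect_equal(sort(net$edges$combined), c(0.150, 0.400, 0.900))

  # same pairs in reversed orientation collapse to single undirected edges
  p2 <- write_lines_tmp(c(
    "protein1\tprotein2\tcombined_score",
    "A\tB\t500", "B\tA\t500"
  ))
  net2 <- read_network(p2)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$protein_a, "A")

  # float dialect is kept as-is, auto-detected
  p3 <- write_lines_tmp(c("protein1\tprotein2\tcombined_score", "A\tB\t0.42"))
  expect_equal(read_network(p3)$edges$combined, 0.42)
})

test_that("read_network reports malformed rows with their line number", {
  p <- write_lines_tmp(c(
    "protein1\tprotein2\tcombined_score", "A\tB\tnotanumber"
  ))
  expect_error(read_network(p), "line 2.*notanumber")

  p2 <- write_lines_tmp(c(
    "protein1\tprotein2\tcombined_score", "A\tB\t500", "C\tD"
  ))
  expect_error(read_network(p2), "line 3")

  p3 <- write_lines_tmp(c("protein1\tprotein2\tcombined_score", "A\tB\t1500"))
  expect_error(read_network(p3), "outside \\[0, 1000\\]")

  # self-loops are skipped with a warning, not fatal
  p4 <- write_lines_tmp(c(
    "protein1\tprotein2\tcombined_score", "A\tA\t500", "A\tB\t500"
  ))
  expect_warning(net <- read_network(p4), "self-loop")
  expect_equal(nrow(net$edges), 1)
})

test_that("network round-trips through both writer dialects", {
  p <- write_lines_tmp(c(
    "protein1\tprotein2\tneighborhood\texperiments\tcombined_score",
    "A\tB\t100\t800\t823", "B\tC\t0\t400\t400", "A\tC\t50\t0\t50"
  ))
  net <- read_network(p)
  out1 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, out1, dialect = "string1000")
  rt <- read_network(out1)
  expect_identical(rt$edges, net$edges) # bit-exact in string1000

  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, out2, dialect = "float")
  rt2 <- read_network(out2)
  expect_equal(rt2$edges$combined, net$edges$combined, tolerance = 5e-4)
})

test_that("combine_channels is the prior-corrected noisy-OR", {
  expect_equal(combine_channels(c(experiments = 0, textmining = 0)), 0)
  # single enabled channel is the identity at prior 0
  expect_equal(combine_channels(c(coexpression = 0.37)), 0.37)
  expect_equal(combine_channels(c(coexpression = 0.5, experiments = 0.5)), 0.75)
  # permutation invariance over channels
  s <- c(neighborhood = 0.2, fusion = 0.6, textmining = 0.35)
  expect_equal(combine_channels(s), combine_channels(rev(s)))
  # never below the max enabled score at prior 0, monotone in each score
  expect_gte(combine_channels(s), max(s))
  s2 <- s; s2["fusion"] <- 0.7
  expect_gt(combine_channels(s2), combine_channels(s))
  # disabled channels contribute nothing
  expect_equal(combine_channels(s, enabled = "fusion"), 0.6)
  # prior is removed and restored: all-prior scores collapse to the prior
  expect_equal(
    combine_channels(c(experiments = 0.1, textmining = 0.1), prior = 0.1), 0.1
  )
  expect_error(combine_channels(s, enabled = "wiring"), "unknown channel")
})

test_that("transferred sub-scores merge into their channel by noisy-OR", {
  s <- c(coexpression = 0.5, coexpression_transferred = 0.5)
  expect_equal(combine_channels(s), 0.75)
  expect_equal(combine_channels(s, enabled = "experiments"), 0)
})

test_that("database channel scores every curated pair at exactly 0.900", {
  recs <- data.frame(a = c("P1", "P2", "P3"), b = c("P2", "P3", "P4"))
  out <- score_database_channel(recs)
  expect_equal(nrow(out), 3)
  expect_true(all(out$databases == 0.900))

  # duplicates from two source databases collapse; self-pairs warn
  recs2 <- data.frame(a = c("P1", "P2", "P5"), b = c("P2", "P1", "P5"))
  expect_warning(out2 <- score_database_channel(recs2), "self-pair")
  expect_equal(nrow(out2), 1)
  expect_equal(out2$databases, 0.900)

  expect_equal(nrow(score_database_channel(data.frame(a = character(),
                                                      b = character()))), 0)
})

test_that("confidence filtering honors presets and is idempotent", {
  net <- association_network(data.frame(
    protein_a = c("A", "B", "C"), protein_b = c("B", "C", "D"),
    combined = c(0.95, 0.90, 0.89)
  ))
  hi <- filter_by_confidence(net, "highest")
  expect_equal(nrow(hi$edges), 2) # 0.95 and 0.90 survive the 0.900 preset
  expect_setequal(hi$nodes, net$nodes) # node set unchanged
  expect_identical(filter_by_confidence(hi, "highest")$edges, hi$edges)

  expect_equal(nrow(filter_by_confidence(net, 0)$edges), 3)
  none <- filter_by_confidence(net, 1.0)
  expect_equal(nrow(none$edges), 0)
  expect_setequal(none$nodes, net$nodes)
  expect_error(filter_by_confidence(net, "ultra"), "unknown confidence preset")
})

test_that("association_network enforces its invariants", {
  expect_error(association_network(data.frame(
    protein_a = "A", protein_b = "A", combined = 0.5
  )), "self-loop")
  expect_error(association_network(data.frame(
    protein_a = "A", protein_b = "B", combined = 1.5
  )), "\\[0, 1\\]")
  expect_error(association_network(data.frame(
    protein_a = c("A", "B"), protein_b = c("B", "A"), combined = c(0.5, 0.6)
  )), "conflicting duplicate")
  # combined is computed from channels when absent
  net <- association_network(data.frame(
    protein_a = "A", protein_b = "B", experiments = 0.5, textmining = 0.5
  ))
  expect_equal(net$edges$combined, 0.75)
})

test_that("largest_component restricts nodes and edges consistently", {
  net <- association_network(data.frame(
    protein_a = c("A", "B", "X"), protein_b = c("B", "C", "Y"),
    combined = 0.5
  ), nodes = c("A", "B", "C", "X", "Y", "Z"))
  expect_message(lc <- largest_component(net), "dropped 3 of 6")
  expect_setequal(lc$nodes, c("A", "B", "C"))
  expect_equal(nrow(lc$edges), 2)
})
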