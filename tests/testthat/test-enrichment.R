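test_that("hypergeometric ORA matches direct binomial-coefficient arithmetic", {
  bg <- sprintf("g%02d", 1:20)
  # perfect 5-of-5 overlap out of 20: a single favorable draw
  res <- ora_hypergeometric(bg[1:5], list(id = "s", members = bg[1:5]), bg)
  expect_equal(res$p_raw, 1 / choose(20, 5))
  expect_equal(res$statistic, 5)
  # zero overlap: the upper tail includes k = 0, so p = 1
  res0 <- ora_hypergeometric(bg[1:5], list(id = "s", members = bg[6:10]),
                             bg[1:10])
  expect_equal(res0$p_raw, 1)
  # set equal to the background: overlap is forced, p = 1
  resbg <- ora_hypergeometric(bg[1:5], list(id = "s", members = bg), bg)
  expect_equal(resbg$p_raw, 1)
  expect_error(ora_hypergeometric(c(bg[1], "alien"), bg[1:3], bg), "subset")
})

test_that("exhaustive AFC enumerates the exact permutation null", {
  v <- c(a = 1, b = 2, c = 3, d = 4)
  res <- afc_test(v, c("c", "d"))
  # 6 subsets of size 2; only {c,d} has mean >= 3.5
  expect_equal(res$p_up, 1 / 6)
  expect_equal(res$p_down, 1) # every subset mean is <= 3.5
  expect_equal(res$p_raw, 2 / 6) # doubled smaller tail
  expect_equal(res$statistic, 3.5)
  expect_equal(res$direction, "up")
  expect_equal(res$method, "AFC")

  # all-identical values: every null mean ties the observed, p = 1 both tails
  res_flat <- afc_test(c(a = 2, b = 2, c = 2, d = 2), c("a", "b"))
  expect_equal(res_flat$p_up, 1)
  expect_equal(res_flat$p_down, 1)
  expect_equal(res_flat$p_raw, 1)
})

test_that("Monte-Carlo AFC is deterministic given a seed and uses add-one", {
  set.seed(99)
  v <- setNames(rnorm(60), sprintf("g%02d", 1:60))
  s <- sample(names(v), 6) # random set: tail counts vary between seeds
  r1 <- afc_test(v, s, n_perm = 500, seed = 7, exhaustive_limit = 10)
  r2 <- afc_test(v, s, n_perm = 500, seed = 7, exhaustive_limit = 10)
  expect_identical(r1, r2)
  r3 <- afc_test(v, s, n_perm = 500, seed = 8, exhaustive_limit = 10)
  expect_false(identical(r1$p_raw, r3$p_raw))
  # add-one correction bounds p away from 0
  expect_gte(r1$p_up, 1 / 501)
  expect_lte(r1$p_raw, 1)
})

test_that("Monte-Carlo AFC agrees with the exhaustive oracle", {
  set.seed(5)
  v <- setNames(rnorm(16), sprintf("g%02d", 1:16))
  s <- names(v)[1:4] # choose(16,4) = 1820 exhaustively enumerable
  exact <- afc_test(v, s) # exhaustive path
  mc <- afc_test(v, s, n_perm = 20000, seed = 3, exhaustive_limit = 100)
  expect_lt(abs(mc$p_up - exact$p_up), 0.02)
  expect_lt(abs(mc$p_down - exact$p_down), 0.02)
})

test_that("AFC p-values are invariant under constant shifts of all values", {
  set.seed(6)
  v <- setNames(rnorm(12), letters[1:12])
  s <- letters[1:3]
  r <- afc_test(v, s)
  r_shift <- afc_test(v + 100, s)
  expect_equal(r_shift$p_up, r$p_up)
  expect_equal(r_shift$p_down, r$p_down)
  expect_equal(r_shift$statistic, r$statistic + 100)
})

test_that("AFC skips non-intersecting sets with a warning, not an error", {
  v <- c(a = 1, b = 2, c = 3)
  expect_warning(res <- afc_test(v, c("x", "y")), "does not intersect")
  expect_null(res)
})

test_that("two-sample rank KS detects complete separation exactly", {
  v <- setNames(1:6, letters[1:6])
  res <- ks_rank_test(v, c("d", "e", "f"))
  expect_equal(res$statistic, 1)
  expect_equal(res$p_raw, 0.1) # 2 * 3! * 3! / 6!
  expect_equal(res$direction, "up")
  expect_equal(res$method, "KS")

  # identical in/out rank multisets via ties: D at its minimum, p = 1
  v_tie <- setNames(rep(c(1, 2), 3), letters[1:6])
  res_tie <- suppressWarnings(ks_rank_test(v_tie, c("a", "b")))
  expect_equal(res_tie$p_raw, 1)
})

test_that("one-sample KS compares in-set ranks to the pooled distribution", {
  v <- setNames(1:10, letters[1:10])
  res <- ks_rank_test(v, "j", mode = "one_sample")
  expect_equal(res$statistic, 0.9)
  # exhaustive over the 10 placements: only ranks 1 and 10 reach D >= 0.9
  expect_equal(res$p_raw, 0.2)
})

test_that("KS skips degenerate splits with a warning", {
  v <- setNames(1:4, letters[1:4])
  expect_warning(expect_null(ks_rank_test(v, letters[1:4])), "degenerate")
  expect_warning(expect_null(ks_rank_test(v, c("x", "y"))), "degenerate")
})

test_that("BH correction matches hand-computed and brute-force step-up", {
  r <- data.frame(framework = "f", p_raw = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_within_framework(r)$q_bh, rep(0.04, 4))
  r2 <- data.frame(framework = "f", p_raw = c(0.01, 0.04, 0.03))
  expect_equal(bh_within_framework(r2)$q_bh, c(0.03, 0.04, 0.04))
  r3 <- data.frame(framework = "f", p_raw = 0.2)
  expect_equal(bh_within_framework(r3)$q_bh, 0.2)

  set.seed(31)
  for (m in c(3, 17, 100)) {
    p <- runif(m)^2
    got <- bh_within_framework(data.frame(framework = "f", p_raw = p))$q_bh
    expect_equal(got, bh_oracle(p))
  }
})

test_that("BH is applied within each framework, never pooled", {
  p_a <- c(0.01, 0.5)
  p_b <- c(0.02, 0.04, 0.06, 0.5)
  r <- data.frame(framework = rep(c("A", "B"), c(2, 4)), p_raw = c(p_a, p_b))
  got <- bh_within_framework(r)
  expect_equal(got$q_bh[got$framework == "A"], bh_oracle(p_a))
  expect_equal(got$q_bh[got$framework == "B"], bh_oracle(p_b))
  # pooled correction would differ for the same p-values
  expect_false(isTRUE(all.equal(got$q_bh, bh_oracle(c(p_a, p_b)))))
})

test_that("run_enrichment routes small sets to AFC and large sets to KS", {
  set.seed(41)
  genes <- sprintf("g%04d", 1:300)
  v <- setNames(rnorm(300), genes)
  col <- gene_set_collection("fw", list(
    list(id = "small", members = genes[1:20]),
    list(id = "large", members = genes[1:250])
  ))
  res <- run_enrichment(v, col, large_set_threshold = 100, n_perm = 300,
                        seed = 1)
  expect_equal(res$method[res$set_id == "small"], "AFC")
  expect_equal(res$method[res$set_id == "large"], "KS")
  expect_true(all(res$q_bh >= res$p_raw - 1e-12 | res$q_bh == res$p_raw))
  # identical rerun under the same seed
  res2 <- run_enrichment(v, col, large_set_threshold = 100, n_perm = 300,
                         seed = 1)
  expect_identical(res, res2)
})

test_that("run_enrichment demands a seed only when Monte-Carlo AFC is needed", {
  genes <- sprintf("g%04d", 1:200)
  v <- setNames(seq_along(genes), genes)
  col_mc <- gene_set_collection("fw", list(
    list(id = "s", members = genes[1:20])
  ))
  expect_error(run_enrichment(v, col_mc), "seed")
  # an exhaustively enumerable set needs no seed
  v_small <- setNames(1:8, letters[1:8])
  col_ex <- gene_set_collection("fw", list(list(id = "s", members = letters[1:2])))
  expect_s3_class(run_enrichment(v_small, col_ex), "enrichment_result")
})

test_that("non-overlapping collections are skipped with warnings", {
  v <- setNames(1:10, sprintf("g%d", 1:10))
  col <- gene_set_collection("alien", list(
    list(id = "s", members = c("x1", "x2", "x3", "x4", "x5"))
  ))
  expect_warning(expect_warning(
    res <- run_enrichment(v, col, seed = 1),
    "do not intersect"), "omitted")
  expect_equal(nrow(res), 0)
})

test_that("enrichment is invariant under gene relabeling", {
  set.seed(55)
  genes <- sprintf("g%02d", 1:30)
  v <- setNames(rnorm(30), genes)
  s <- genes[1:5]
  map <- setNames(sprintf("z%02d", sample(30)), genes)
  v2 <- setNames(unname(v), unname(map[genes]))
  s2 <- unname(map[s])
  r1 <- afc_test(v, s, n_perm = 500, seed = 2, exhaustive_limit = 10)
  r2 <- afc_test(v2, s2, n_perm = 500, seed = 2, exhaustive_limit = 10)
  expect_equal(r2$p_raw, r1$p_raw)
  k1 <- ks_rank_test(v, s)
  k2 <- ks_rank_test(v2, s2)
  expect_equal(k2$statistic, k1$statistic)
  expect_equal(k2$p_raw, k1$p_raw)
})

test_that("gene-value tables read, validate and round-trip", {
  p <- write_lines_tmp(c("gene\tvalue", "g1\t1.5", "g2\t-0.25", "g3\t0"))
  v <- read_value_table(p)
  expect_equal(v, c(g1 = 1.5, g2 = -0.25, g3 = 0))
  # headerless variant
  p2 <- write_lines_tmp(c("g1\t1.5", "g2\t-2"))
  expect_equal(read_value_table(p2), c(g1 = 1.5, g2 = -2))
  p3 <- write_lines_tmp(c("gene\tvalue", "g1\t1.5", "g2\tbad"))
  expect_error(read_value_table(p3), "line 3")
  p4 <- write_lines_tmp(c("g1\t1", "g1\t2"))
  expect_error(read_value_table(p4), "duplicate")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_value_table(v, out)
  expect_equal(read_value_table(out), v)
})
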