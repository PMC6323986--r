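.set_members <- function(s) {
  if (is.list(s) && !is.null(s$members)) unique(as.character(s$members))
  else unique(as.character(s))
}

.set_id <- function(s, default = "set") {
  if (is.list(s) && !is.null(s$id)) as.character(s$id) else default
}

.result_row <- function(set_id, framework, description, n_members, statistic,
                        direction, method, p_raw, p_up = NA_real_,
                        p_down = NA_real_) {
  data.frame(
    framework = framework, set_id = set_id, description = description,
    n_members_in_input = n_members, statistic = statistic,
    direction = direction, method = method,
    p_raw = p_raw, p_up = p_up, p_down = p_down, q_bh = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric over-representation analysis
#'
#' Classical ORA: tests whether a query gene list overlaps a gene set more
#' than expected by chance, with the upper-tail hypergeometric probability
#' of observing at least the realized overlap given the query size, the set
#' size within the background, and the background size. The gene set is
#' intersected with the background before testing.
#'
#' @param query character vector of query genes; must be a subset of
#'   `background`.
#' @param s a gene set (list with `id`, `members`) or a character vector of
#'   members.
#' @param background character vector: the gene universe.
#' @param framework framework label recorded in the result.
#' @return a one-row enrichment result data frame (`statistic` = overlap
#'   count, `method` = `"ORA"`); `q_bh` is `NA` until
#'   [bh_within_framework()].
#' @export
ora_hypergeometric <- function(query, s, background, framework = "ORA") {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(query) == 0L) stop_input("query gene list is empty")
  if (length(background) == 0L) stop_input("background gene list is empty")
  if (!all(query %in% background)) {
    stop_input("query must be a subset of the background (offending: %s)",
               paste(utils::head(setdiff(query, background), 5), collapse = ", "))
  }
  members <- intersect(.set_members(s), background)
  m <- length(members)
  N <- length(background)
  k <- length(intersect(query, members))
  p <- stats::phyper(k - 1, m, N - m, length(query), lower.tail = FALSE)
  .result_row(.set_id(s), framework,
              if (is.list(s) && !is.null(s$description)) s$description else "",
              k, statistic = k, direction = "up", method = "ORA", p_raw = p)
}

#' Aggregate Fold Change permutation test
#'
#' A permutation-based, non-parametric gene-set enrichment test for
#' genome-wide value-annotated inputs. The observed statistic is the mean of
#' the user-supplied values over the genes of the set that are present in
#' the input; the null distribution is the mean of same-size gene sets drawn
#' uniformly without replacement from the genes of the input (the submitted
#' list is the randomization universe). When the number of possible subsets
#' `choose(n, k)` does not exceed `exhaustive_limit`, the null is enumerated
#' exactly and tail probabilities are exact subset fractions; otherwise
#' `n_perm` Monte-Carlo draws are used with the add-one correction
#' `p = (1 + #extreme) / (1 + n_perm)`. The reported two-sided p doubles the
#' smaller tail (capped at 1); both one-sided tails are returned, and the
#' reported `direction` is the smaller tail. Adding a constant to all values
#' shifts the statistic but leaves every p unchanged.
#'
#' @param values named numeric vector (see [validate_value_table()]).
#' @param s gene set (list with `members`) or character vector.
#' @param n_perm number of Monte-Carlo permutations (>= 100).
#' @param seed optional integer seed for the Monte-Carlo draws; when `NULL`
#'   the current RNG state is used.
#' @param exhaustive_limit largest subset count that is enumerated exactly.
#' @param framework framework label recorded in the result.
#' @return a one-row enrichment result data frame (`method` = `"AFC"`), or
#'   `NULL` with a warning when the set does not intersect the input.
#' @export
afc_test <- function(values, s, n_perm = 10000L, seed = NULL,
                     exhaustive_limit = 100000L, framework = "AFC") {
  validate_value_table(values)
  members <- .set_members(s)
  inset <- intersect(members, names(values))
  k <- length(inset)
  if (k == 0L) {
    warning(sprintf("gene set '%s' does not intersect the input; skipped",
                    .set_id(s)))
    return(NULL)
  }
  n <- length(values)
  obs <- mean(values[inset])
  tol <- 1e-9 * (1 + abs(obs))

  n_subsets <- choose(n, k)
  if (n_subsets <= exhaustive_limit) {
    null_means <- .afc_null_exhaustive(unname(values), k)
    p_up <- sum(null_means >= obs - tol) / length(null_means)
    p_down <- sum(null_means <= obs + tol) / length(null_means)
  } else {
    n_perm <- as.integer(n_perm)
    if (is.na(n_perm) || n_perm < 100L) stop_input("n_perm must be >= 100")
    if (!is.null(seed)) set.seed(as.integer(seed))
    v <- unname(values)
    null_means <- vapply(seq_len(n_perm),
                         function(i) mean(v[sample.int(n, k)]), 0)
    p_up <- (1 + sum(null_means >= obs - tol)) / (1 + n_perm)
    p_down <- (1 + sum(null_means <= obs + tol)) / (1 + n_perm)
  }
  p_two <- min(1, 2 * min(p_up, p_down))
  .result_row(.set_id(s), framework,
              if (is.list(s) && !is.null(s$description)) s$description else "",
              k, statistic = obs,
              direction = if (p_up <= p_down) "up" else "down",
              method = "AFC", p_raw = p_two, p_up = p_up, p_down = p_down)
}

# all means of size-k subsets of v, by direct enumeration
.afc_null_exhaustive <- function(v, k) {
  idx <- utils::combn(length(v), k)
  colMeans(matrix(v[idx], nrow = k))
}

#' Rank-based Kolmogorov-Smirnov enrichment test
#'
#' The fallback test for large gene sets, for which subset randomization is
#' prohibitively slow: user values are converted to ranks (ties receive the
#' average rank) and the in-set ranks are compared against the out-of-set
#' ranks with a two-sided two-sample Kolmogorov-Smirnov test. The exact
#' two-sample p-value is used when `k * (n - k) <= 10^4`, the asymptotic one
#' otherwise. An alternative one-sample mode compares the in-set rank
#' distribution against the pooled (discrete uniform) rank distribution of
#' all input genes; its p-value is exhaustive over subsets when feasible and
#' asymptotic otherwise.
#'
#' @param values named numeric vector (see [validate_value_table()]).
#' @param s gene set (list with `members`) or character vector.
#' @param mode `"two_sample"` (default) or `"one_sample"`.
#' @param exact_limit largest `k * (n - k)` (two-sample) or subset count
#'   (one-sample) for which the exact p-value is computed.
#' @param framework framework label recorded in the result.
#' @return a one-row enrichment result data frame (`statistic` = D,
#'   `method` = `"KS"`), or `NULL` with a warning on a degenerate split
#'   (k = 0 or k = n).
#' @export
ks_rank_test <- function(values, s, mode = c("two_sample", "one_sample"),
                         exact_limit = 10000L, framework = "KS") {
  mode <- match.arg(mode)
  validate_value_table(values)
  members <- .set_members(s)
  inset <- names(values) %in% members
  k <- sum(inset)
  n <- length(values)
  if (k == 0L || k == n) {
    warning(sprintf("gene set '%s' gives a degenerate split (k=%d of n=%d); skipped",
                    .set_id(s), k, n))
    return(NULL)
  }
  r <- rank(values, ties.method = "average")
  r_in <- r[inset]
  r_out <- r[!inset]

  if (mode == "two_sample") {
    exact <- (k * (n - k)) <= exact_limit
    kt <- suppressWarnings(
      stats::ks.test(r_in, r_out, alternative = "two.sided", exact = exact)
    )
    D <- unname(kt$statistic)
    p <- kt$p.value
    direction <- if (mean(r_in) >= mean(r_out)) "up" else "down"
  } else {
    # in-set ECDF vs pooled rank ECDF (discrete uniform over observed ranks)
    D <- .ks_one_sample_D(r_in, r)
    if (choose(n, k) <= exact_limit) {
      idx <- utils::combn(n, k)
      null_D <- apply(idx, 2, function(j) .ks_one_sample_D(r[j], r))
      p <- mean(null_D >= D - 1e-12)
    } else {
      z <- sqrt(k) * D
      p <- .kolmogorov_sf(z)
    }
    direction <- if (mean(r_in) >= mean(r)) "up" else "down"
  }
  .result_row(.set_id(s), framework,
              if (is.list(s) && !is.null(s$description)) s$description else "",
              k, statistic = D, direction = direction, method = "KS",
              p_raw = min(1, p))
}

# sup_t | ECDF_in(t) - ECDF_all(t) | over the pooled rank values
.ks_one_sample_D <- function(r_in, r_all) {
  t_grid <- sort(unique(r_all))
  F_in <- stats::ecdf(r_in)(t_grid)
  F_all <- stats::ecdf(r_all)(t_grid)
  max(abs(F_in - F_all))
}

# Kolmogorov distribution survival function, 2 * sum (-1)^(j-1) exp(-2 j^2 z^2)
.kolmogorov_sf <- function(z, terms = 100L) {
  if (z <= 0) return(1)
  j <- seq_len(terms)
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * z^2))))
}

#' Benjamini-Hochberg correction within each classification framework
#'
#' Fills the `q_bh` column with the Benjamini-Hochberg step-up false
#' discovery rate, applied separately within each classification framework
#' and never pooled across frameworks — frameworks overlap heavily, so
#' pooling would distort the correction. Results in other frameworks are
#' unaffected by a framework's p-values.
#'
#' @param results enrichment result data frame with `framework` and `p_raw`
#'   columns.
#' @return the same data frame with `q_bh` filled.
#' @export
bh_within_framework <- function(results) {
  stopifnot(is.data.frame(results), all(c("framework", "p_raw") %in% names(results)))
  if (nrow(results) == 0L) return(results)
  if (any(!is.finite(results$p_raw))) stop_input("p_raw must be present for all results")
  results$q_bh <- stats::ave(results$p_raw, results$framework,
                             FUN = function(p) stats::p.adjust(p, method = "BH"))
  results
}

#' Run value-based enrichment over one or more classification frameworks
#'
#' The orchestrator for genome-wide, value-annotated input: for every gene
#' set of every collection it computes the effective size (members present
#' in the input) and routes the set to the Aggregate Fold Change permutation
#' test ([afc_test()]) when the effective size is at most
#' `large_set_threshold`, and to the rank-based Kolmogorov-Smirnov fallback
#' ([ks_rank_test()]) otherwise. Benjamini-Hochberg correction is then
#' applied separately within each framework, and results are sorted by
#' `(framework, q_bh, p_raw)`. Sets that do not intersect the input are
#' skipped with a warning; a collection with no intersecting set is omitted
#' from the output with a warning. No significance filtering is applied —
#' thresholding (e.g. `q_bh < 0.05`) belongs to the reporting layer.
#'
#' @param values named numeric vector (see [validate_value_table()]).
#' @param collections a [gene_set_collection()] or a list of them.
#' @param large_set_threshold effective set size above which the KS fallback
#'   replaces AFC.
#' @param n_perm Monte-Carlo permutations for AFC.
#' @param seed integer seed; required whenever any set needs Monte-Carlo
#'   AFC, so that runs are reproducible.
#' @param exhaustive_limit passed to [afc_test()].
#' @param ks_mode passed to [ks_rank_test()] as `mode`.
#' @return data frame of class `enrichment_result`, one row per tested set.
#' @export
run_enrichment <- function(values, collections, large_set_threshold = 1000L,
                           n_perm = 10000L, seed = NULL,
                           exhaustive_limit = 100000L,
                           ks_mode = "two_sample") {
  validate_value_table(values)
  if (inherits(collections, "gene_set_collection")) collections <- list(collections)
  if (length(collections) == 0L) stop_input("at least one gene-set collection is required")
  stopifnot(all(vapply(collections, inherits, TRUE, "gene_set_collection")))

  n <- length(values)
  needs_mc <- any(vapply(collections, function(col) {
    any(vapply(col$sets, function(s) {
      k <- length(intersect(s$members, names(values)))
      k >= 1L && k <= large_set_threshold && choose(n, k) > exhaustive_limit
    }, TRUE))
  }, TRUE))
  if (needs_mc && is.null(seed)) {
    stop_input("Monte-Carlo AFC permutations are needed: supply a seed for reproducibility")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  rows <- list()
  for (col in collections) {
    fw_rows <- list()
    n_skipped <- 0L
    for (s in col$sets) {
      k <- length(intersect(s$members, names(values)))
      if (k == 0L) {
        n_skipped <- n_skipped + 1L
        next
      }
      res <- if (k <= large_set_threshold) {
        afc_test(values, s, n_perm = n_perm, seed = NULL,
                 exhaustive_limit = exhaustive_limit, framework = col$framework)
      } else {
        ks_rank_test(values, s, mode = ks_mode, framework = col$framework)
      }
      if (!is.null(res)) fw_rows[[length(fw_rows) + 1L]] <- res
    }
    if (n_skipped > 0L) {
      warning(sprintf("framework '%s': %d set(s) do not intersect the input; skipped",
                      col$framework, n_skipped))
    }
    if (length(fw_rows) == 0L) {
      warning(sprintf("framework '%s': no set intersects the input; omitted",
                      col$framework))
      next
    }
    rows <- c(rows, fw_rows)
  }
  if (length(rows) == 0L) {
    out <- data.frame(
      framework = character(), set_id = character(), description = character(),
      n_members_in_input = integer(), statistic = numeric(),
      direction = character(), method = character(), p_raw = numeric(),
      p_up = numeric(), p_down = numeric(), q_bh = numeric(),
      stringsAsFactors = FALSE
    )
  } else {
    out <- do.call(rbind, rows)
    out <- bh_within_framework(out)
    out <- out[order(out$framework, out$q_bh, out$p_raw), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Run over-representation analysis over one or more frameworks
#'
#' Applies [ora_hypergeometric()] to every set of every collection for a
#' plain (unvalued) query gene list, then corrects within each framework
#' with [bh_within_framework()].
#'
#' @param query character vector of query genes, a subset of `background`.
#' @param collections a [gene_set_collection()] or a list of them.
#' @param background character vector: the gene universe.
#' @return data frame of class `enrichment_result`.
#' @export
run_ora <- function(query, collections, background) {
  if (inherits(collections, "gene_set_collection")) collections <- list(collections)
  rows <- list()
  for (col in collections) {
    for (s in col$sets) {
      rows[[length(rows) + 1L]] <-
        ora_hypergeometric(query, s, background, framework = col$framework)
    }
  }
  if (length(rows) == 0L) stop_input("no gene sets to test")
  out <- bh_within_framework(do.call(rbind, rows))
  out <- out[order(out$framework, out$q_bh, out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat(sprintf("Enrichment results: %d sets across %d framework(s)\n",
              nrow(x), length(unique(x$framework))))
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[
      c("framework", "set_id", "n_members_in_input", "statistic",
        "direction", "method", "p_raw", "q_bh")], n)
    print(format(show, digits = 4))
    if (nrow(x) > n) cat(sprintf("... and %d more rows\n", nrow(x) - n))
  }
  invisible(x)
}

#' Write enrichment results as TSV
#'
#' @param results an `enrichment_result` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_results <- function(results, path) {
  cols <- c("framework", "set_id", "description", "n_members_in_input",
            "statistic", "direction", "method", "p_raw", "q_bh")
  utils::write.table(as.data.frame(results)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
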