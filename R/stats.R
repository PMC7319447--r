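# Upper-tail binomial probability P(X >= k), X ~ Binomial(n, p),
# summed in log space so that 1e-30-scale tails keep full precision.
binom_upper_tail <- function(k, n, p) {
  if (k <= 0L) return(1)
  if (k > n) return(0)
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  exp(logsumexp(stats::dbinom(k:n, n, p, log = TRUE)))
}

#' Local binomial enrichment test for a cluster or family
#'
#' Tests whether hits aggregate in one group of nodes (a family or
#' genomic cluster).  With `p = n_hits / n_nodes` the hit proportion
#' among measured nodes of the whole network, the number of hits in a
#' group of `n_cluster` measured nodes is Binomial(`n_cluster`, `p`)
#' under the null, and the P-value is the upper-tail probability of
#' observing at least the actual `k_hits`.  Only measured nodes (those
#' in `hits$measured_ids`) ever enter the counts.
#'
#' @param group character vector of node ids (the cluster/family).
#' @param hits a `hit_set` from [define_hits()].
#' @param network a `mirna_network`.
#' @param group_id label stored on the result.
#' @return a `local_test_result`: list with `group_id`, `n_nodes`,
#'   `n_hits`, `background_p`, `n_cluster`, `k_hits`, `pvalue`.
#' @examples
#' # a 4-node clique with 2 of 4 measured nodes hits, background 3/10
#' @export
local_binomial_test <- function(group, hits, network,
                                group_id = NA_character_) {
  stopifnot(inherits(hits, "hit_set"), inherits(network, "mirna_network"))
  measured_net <- intersect(hits$measured_ids, network$nodes)
  if (length(measured_net) == 0L) {
    stop("no measured nodes in the network")
  }
  hits_net <- intersect(hits$hit_ids, measured_net)
  n_nodes <- length(measured_net)
  n_hits <- length(hits_net)
  background_p <- n_hits / n_nodes
  group_measured <- intersect(group, measured_net)
  n_cluster <- length(group_measured)
  if (n_cluster == 0L) stop("no measured nodes in group")
  k_hits <- length(intersect(group_measured, hits_net))
  pvalue <- binom_upper_tail(k_hits, n_cluster, background_p)
  structure(list(group_id = group_id, n_nodes = n_nodes, n_hits = n_hits,
                 background_p = background_p, n_cluster = n_cluster,
                 k_hits = k_hits, pvalue = pvalue),
            class = "local_test_result")
}

#' @export
print.local_test_result <- function(x, ...) {
  cat(sprintf(
    "local binomial test%s: %d hits / %d measured in group; background %d/%d; P = %.3g\n",
    if (is.na(x$group_id)) "" else paste0(" [", x$group_id, "]"),
    x$k_hits, x$n_cluster, x$n_hits, x$n_nodes, x$pvalue))
  invisible(x)
}

#' Global hit-pair permutation test
#'
#' Counts hit pairs (edges whose two endpoints are both hits) and
#' compares the observed count to a null in which hit labels are
#' reassigned uniformly at random among the measured nodes, keeping the
#' total hit number constant.  The strict P-value is the fraction of
#' trials whose randomized count strictly exceeds the observed one
#' (ties count as not exceeding); because the strict rule can return an
#' exact 0, the add-one corrected estimate
#' `(n_exceeding + 1) / (n_trials + 1)` is reported alongside.
#'
#' @param network a `mirna_network`.
#' @param hits a `hit_set`.
#' @param n_trials number of randomization trials (default 1e5).
#' @param rng_seed integer seed recorded in the result; the caller's RNG
#'   state is left untouched.
#' @return a `global_test_result`: list with `observed_hit_pairs`,
#'   `n_trials`, `rng_seed`, `n_trials_exceeding`, `pvalue_strict`,
#'   `pvalue_corrected`, `n_measured`, `n_hits`.
#' @export
global_permutation_test <- function(network, hits, n_trials = 1e5L,
                                    rng_seed = 1L) {
  stopifnot(inherits(hits, "hit_set"), inherits(network, "mirna_network"),
            n_trials >= 1L)
  n_trials <- as.integer(n_trials)
  measured <- intersect(hits$measured_ids, network$nodes)
  hit_ids <- intersect(hits$hit_ids, measured)
  m <- length(measured)
  h <- length(hit_ids)
  e <- network$edges
  keep <- e[, 1L] %in% measured & e[, 2L] %in% measured
  e <- e[keep, , drop = FALSE]
  if (h < 2L) {
    warning("fewer than 2 hits among measured network nodes; ",
            "permutation test degenerate")
    return(structure(list(observed_hit_pairs = 0L, n_trials = n_trials,
                          rng_seed = rng_seed, n_trials_exceeding = 0L,
                          pvalue_strict = 1, pvalue_corrected = 1,
                          n_measured = m, n_hits = h),
                     class = "global_test_result"))
  }
  i1 <- match(e[, 1L], measured)
  i2 <- match(e[, 2L], measured)
  is_hit <- measured %in% hit_ids
  observed <- sum(is_hit[i1] & is_hit[i2])
  exceeding <- local_seed(rng_seed, {
    cnt <- 0L
    lab <- logical(m)
    for (t in seq_len(n_trials)) {
      lab[] <- FALSE
      lab[sample.int(m, h)] <- TRUE
      if (sum(lab[i1] & lab[i2]) > observed) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(observed_hit_pairs = as.integer(observed),
                 n_trials = n_trials, rng_seed = as.integer(rng_seed),
                 n_trials_exceeding = exceeding,
                 pvalue_strict = exceeding / n_trials,
                 pvalue_corrected = (exceeding + 1) / (n_trials + 1),
                 n_measured = m, n_hits = h),
            class = "global_test_result")
}

#' @export
print.global_test_result <- function(x, ...) {
  cat(sprintf(
    "global permutation test: %d hit pairs observed (%d hits / %d measured)\n",
    x$observed_hit_pairs, x$n_hits, x$n_measured))
  cat(sprintf("  P(strict) = %.3g, P(add-one) = %.3g  [%d trials, seed %d]\n",
              x$pvalue_strict, x$pvalue_corrected, x$n_trials, x$rng_seed))
  invisible(x)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on paired differences.  Zero
#' differences are dropped; absolute values are ranked with midranks on
#' ties.  When at most 25 differences remain and there are no ties, the
#' exact null distribution of the signed-rank sum W+ is computed by
#' dynamic programming over all 2^n sign assignments and the two-sided
#' P-value is twice the smaller tail (capped at 1).  Otherwise a normal
#' approximation with continuity and tie corrections is used, and the
#' method is recorded.
#'
#' @param differences numeric vector of paired differences.
#' @return a `wilcoxon_result`: list with `n_pairs_used`, `statistic`
#'   (W+), `pvalue_two_sided`, `method`, `n_zeros_dropped`.
#' @examples
#' exact_wilcoxon_signed_rank(c(1.2, 0.4, 2.2, 0.9, 1.7))
#' @export
exact_wilcoxon_signed_rank <- function(differences) {
  d <- differences[!is.na(differences)]
  nz <- d[d != 0]
  n_zero <- length(d) - length(nz)
  if (length(nz) == 0L) stop("all differences are zero")
  n <- length(nz)
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  ties <- anyDuplicated(abs(nz)) > 0L
  if (n <= 25L && !ties) {
    # exact: ranks are the integers 1..n; counts[w + 1] = #assignments
    # with signed-rank sum w, built by convolution
    M <- n * (n + 1L) / 2L
    counts <- c(1, numeric(M))
    for (rk in seq_len(n)) {
      shifted <- c(numeric(rk), counts[seq_len(M + 1L - rk)])
      counts <- counts + shifted
    }
    total <- 2^n
    p_ge <- sum(counts[(W + 1L):(M + 1L)]) / total
    p_le <- sum(counts[seq_len(W + 1L)]) / total
    pvalue <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    pvalue <- min(1, 2 * min(stats::pnorm(z),
                             stats::pnorm(z, lower.tail = FALSE)))
    method <- "normal-approximation"
  }
  structure(list(n_pairs_used = n, statistic = W,
                 pvalue_two_sided = pvalue, method = method,
                 n_zeros_dropped = n_zero),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("paired Wilcoxon signed-rank (%s): W+ = %g on %d pairs, two-sided P = %.3g\n",
              x$method, x$statistic, x$n_pairs_used, x$pvalue_two_sided))
  invisible(x)
}

#' Family export test across paired conditions
#'
#' For a miRNA family measured in paired conditions (e.g. vesicle vs
#' parental cell, in log2 units), builds one paired difference
#' (column A minus column B) per family member and condition pair,
#' concatenates them across condition pairs, and applies the exact
#' paired Wilcoxon signed-rank test.  Members missing in either column
#' of a pair contribute no difference for that pair and are reported.
#'
#' @param family character vector of mature ids.
#' @param condition_pairs list of 2-element character vectors
#'   `c(column_A, column_B)`; the difference is A - B.
#' @param scores a `score_table` containing all referenced columns.
#' @return a `wilcoxon_result` (see [exact_wilcoxon_signed_rank()]).
#' @export
family_export_test <- function(family, condition_pairs, scores) {
  stopifnot(inherits(scores, "score_table"))
  if (is.character(condition_pairs)) condition_pairs <- list(condition_pairs)
  fam_norm <- normalize_mirna_id(family)
  rows <- match(fam_norm, scores$id_norm)
  if (anyNA(rows)) {
    message(sum(is.na(rows)), " family member(s) absent from score table: ",
            paste(family[is.na(rows)], collapse = ", "))
    rows <- rows[!is.na(rows)]
  }
  diffs <- numeric(0)
  dropped <- 0L
  for (pair in condition_pairs) {
    stopifnot(length(pair) == 2L)
    missing_cols <- setdiff(pair, names(scores))
    if (length(missing_cols)) {
      stop("score column(s) not found: ", paste(missing_cols, collapse = ", "))
    }
    d <- scores[[pair[1L]]][rows] - scores[[pair[2L]]][rows]
    dropped <- dropped + sum(is.na(d))
    diffs <- c(diffs, d[!is.na(d)])
  }
  if (dropped > 0L) {
    message(dropped, " member/condition difference(s) dropped (missing values)")
  }
  if (length(diffs) < 2L) {
    stop("fewer than 2 usable paired differences")
  }
  exact_wilcoxon_signed_rank(diffs)
}

#' Run the local binomial test on every group
#'
#' Batch wrapper: one [local_binomial_test()] per group with at least
#' one measured node, with Benjamini-Hochberg adjusted P-values appended
#' (the adjustment is this package's addition; raw values remain the
#' primary readout).  `grouping = "components"` tests every connected
#' component — families on a seed network, clusters on a genomic one.
#'
#' @param network a `mirna_network`.
#' @param hits a `hit_set`.
#' @param grouping `"components"` or a (optionally named) list of node
#'   sets.
#' @return data.frame ordered by raw P-value with columns `group_id`,
#'   `n_nodes`, `n_hits`, `n_cluster`, `k_hits`, `background_p`,
#'   `pvalue`, `pvalue_BH`.
#' @export
run_local_tests_all_groups <- function(network, hits,
                                       grouping = "components") {
  if (identical(grouping, "components")) {
    groups <- connected_components(network)
    names(groups) <- vapply(groups, `[`, character(1), 1L)
  } else {
    groups <- grouping
    if (is.null(names(groups))) {
      names(groups) <- sprintf("group_%03d", seq_along(groups))
    }
  }
  measured_net <- intersect(hits$measured_ids, network$nodes)
  groups <- Filter(function(g) length(intersect(g, measured_net)) > 0L,
                   groups)
  res <- lapply(names(groups), function(nm) {
    r <- local_binomial_test(groups[[nm]], hits, network, group_id = nm)
    data.frame(group_id = nm, n_nodes = r$n_nodes, n_hits = r$n_hits,
               n_cluster = r$n_cluster, k_hits = r$k_hits,
               background_p = r$background_p, pvalue = r$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(group_id = character(), n_nodes = integer(),
                      n_hits = integer(), n_cluster = integer(),
                      k_hits = integer(), background_p = numeric(),
                      pvalue = numeric(), pvalue_BH = numeric()))
  }
  out$pvalue_BH <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric target-set enrichment per miRNA
#'
#' For each miRNA, tests whether its predicted targets (restricted to
#' the gene universe) are enriched for a gene set of interest, with the
#' upper-tail hypergeometric probability P(overlap >= observed) for a
#' draw of the miRNA's targets from the universe.
#'
#' @param targets a `target_table`.
#' @param gene_set character vector of genes of interest (must be a
#'   subset of `universe`).
#' @param universe character vector: the gene population.
#' @return data.frame with columns `id`, `n_targets_in_universe`,
#'   `overlap`, `pvalue`, `pvalue_BH`, ordered by raw P-value.
#' @export
target_set_enrichment <- function(targets, gene_set, universe) {
  stopifnot(inherits(targets, "target_table"))
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  if (length(universe) == 0L) stop("empty gene universe")
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    stop("gene_set contains genes outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  K <- length(gene_set)
  N <- length(universe)
  rows <- lapply(names(targets$targets), function(id) {
    tg <- intersect(targets$targets[[id]], universe)
    k <- length(intersect(tg, gene_set))
    pv <- stats::phyper(k - 1L, K, N - K, length(tg), lower.tail = FALSE)
    data.frame(id = id, n_targets_in_universe = length(tg), overlap = k,
               pvalue = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(id = character(), n_targets_in_universe = integer(),
                      overlap = integer(), pvalue = numeric(),
                      pvalue_BH = numeric()))
  }
  out$pvalue_BH <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a local-test result table as TSV
#'
#' Fixed column order: group_id, n_nodes, n_hits, n_cluster, k_hits,
#' background_p, pvalue, pvalue_BH.
#'
#' @param results data.frame from [run_local_tests_all_groups()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_local_results <- function(results, path) {
  cols <- c("group_id", "n_nodes", "n_hits", "n_cluster", "k_hits",
            "background_p", "pvalue", "pvalue_BH")
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a global-test result as JSON
#'
#' @param result a `global_test_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_global_result_json <- function(result, path) {
  stopifnot(inherits(result, "global_test_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
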