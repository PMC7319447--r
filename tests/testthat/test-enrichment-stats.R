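# a network is only a node-set for the local test; edges are irrelevant
flat_network <- function(n, prefix = "m") {
  mirna_network(sprintf("%s%03d", prefix, seq_len(n)))
}

test_that("local binomial test matches published cluster examples", {
  net <- flat_network(241)
  hits <- make_hits(net$nodes, net$nodes[1:44])
  # cluster of 48 measured containing 24 hits (poor-prognosis 14q32-like)
  group <- c(net$nodes[1:24], net$nodes[100:123])
  r <- local_binomial_test(group, hits, net)
  expect_identical(r$n_nodes, 241L)
  expect_identical(r$k_hits, 24L)
  expect_equal(signif(r$pvalue, 2), 6.1e-7)
  # cluster of 7 with 2 hits: unremarkable when 44/241 are hits overall
  group2 <- c(net$nodes[1:2], net$nodes[130:134])
  r2 <- local_binomial_test(group2, hits, net)
  expect_equal(round(r2$pvalue, 2), 0.37)
})

test_that("local binomial test agrees with a direct PMF-summation oracle", {
  # hand-derived case: background 3/10, cluster 4 with 2 hits
  net <- flat_network(10)
  hits <- make_hits(net$nodes, net$nodes[1:3])
  r <- local_binomial_test(c(net$nodes[1:2], net$nodes[5:6]), hits, net)
  expect_equal(r$pvalue, 0.3483, tolerance = 1e-12)
  # k = 0 gives pvalue 1
  r0 <- local_binomial_test(net$nodes[5:7], hits, net)
  expect_identical(r0$pvalue, 1)
  # oracle grid: n <= 60, all k, p across (0, 1)
  for (n in c(1L, 2L, 5L, 13L, 27L, 41L, 60L)) {
    for (p in c(0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99)) {
      for (k in 0:n) {
        got <- seednet:::binom_upper_tail(k, n, p)
        want <- oracle_binom_tail(k, n, p)
        expect_lt(abs(got - want) / max(want, 1e-300), 1e-10)
      }
    }
  }
})

test_that("local pvalue is non-increasing in k at fixed n and p", {
  for (p in c(0.05, 0.3, 0.7)) {
    pv <- vapply(0:20, seednet:::binom_upper_tail, numeric(1),
                 n = 20L, p = p)
    expect_true(all(diff(pv) <= 1e-15))
  }
})

test_that("local test counts only measured nodes and validates groups", {
  net <- flat_network(10)
  hits <- make_hits(net$nodes[1:6], net$nodes[1:2])  # 4 unmeasured
  r <- local_binomial_test(net$nodes[1:3], hits, net)
  expect_identical(r$n_nodes, 6L)
  expect_identical(r$n_cluster, 3L)
  expect_error(local_binomial_test(net$nodes[7:9], hits, net),
               "no measured nodes in group")
})

test_that("global permutation test matches exhaustive enumeration", {
  # path A-B-C-D, hits {A, C}: 3 of the 6 placements have 1 hit pair
  nodes <- c("A", "B", "C", "D")
  edges <- rbind(c("A", "B"), c("B", "C"), c("C", "D"))
  net <- mirna_network(nodes, edges)
  hits <- make_hits(nodes, c("A", "C"))
  r <- global_permutation_test(net, hits, n_trials = 40000L, rng_seed = 9)
  expect_identical(r$observed_hit_pairs, 0L)
  exact <- oracle_perm_tail(nodes, edges, 2L, 0L)
  expect_equal(exact, 0.5)
  se <- sqrt(exact * (1 - exact) / r$n_trials)
  expect_lt(abs(r$pvalue_strict - exact), 3 * se)

  # hits {A, B}: observed 1 is the maximum -> strict 0, corrected > 0
  hits2 <- make_hits(nodes, c("A", "B"))
  r2 <- global_permutation_test(net, hits2, n_trials = 5000L, rng_seed = 2)
  expect_identical(r2$observed_hit_pairs, 1L)
  expect_identical(r2$pvalue_strict, 0)
  expect_equal(r2$pvalue_corrected, 1 / 5001)

  # all measured nodes hits: randomization is invariant
  hits3 <- make_hits(nodes, nodes)
  r3 <- global_permutation_test(net, hits3, n_trials = 100L, rng_seed = 5)
  expect_identical(r3$pvalue_strict, 0)
  expect_equal(r3$pvalue_corrected, 1 / 101)

  # degenerate: fewer than 2 hits
  expect_warning(r4 <- global_permutation_test(
    net, make_hits(nodes, "A"), n_trials = 10L), "fewer than 2")
  expect_identical(r4$pvalue_strict, 1)
})

test_that("global test is reproducible for a fixed seed and leaves RNG alone", {
  net <- mirna_network(letters[1:8], t(combn(letters[1:4], 2)))
  hits <- make_hits(letters[1:8], letters[c(1, 2, 5)])
  set.seed(123); before <- runif(1)
  set.seed(123)
  r1 <- global_permutation_test(net, hits, n_trials = 2000L, rng_seed = 7)
  after <- runif(1)
  expect_identical(before, after)  # caller RNG stream undisturbed
  r2 <- global_permutation_test(net, hits, n_trials = 2000L, rng_seed = 7)
  expect_identical(r1, r2)
})

test_that("exact Wilcoxon reproduces the family-export P-values", {
  # 10 same-sign tie-free differences: minimal attainable two-sided p
  r10 <- exact_wilcoxon_signed_rank(1:10 + 0.1)
  expect_identical(r10$method, "exact")
  expect_equal(r10$pvalue_two_sided, 2 / 2^10)
  expect_equal(signif(r10$pvalue_two_sided, 1), 0.002)
  # 15 same-sign differences
  r15 <- exact_wilcoxon_signed_rank(seq(0.2, 3, length.out = 15))
  expect_equal(r15$pvalue_two_sided, 2 / 2^15)
  expect_equal(signif(r15$pvalue_two_sided, 1), 6e-5)
  # single non-zero difference: two outcomes, two-sided
  expect_equal(exact_wilcoxon_signed_rank(c(0, 3))$pvalue_two_sided, 1)
  expect_error(exact_wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("exact Wilcoxon equals 2^n enumeration for all sign patterns", {
  for (n in c(4L, 7L, 10L, 12L)) {
    mags <- seq_len(n) + 0.25   # distinct, tie-free magnitudes
    patterns <- expand.grid(rep(list(c(-1, 1)), n))
    # subsample large pattern sets for speed, keeping full coverage at n = 4
    take <- if (n <= 7L) seq_len(nrow(patterns)) else {
      set.seed(n); sample.int(nrow(patterns), 200L)
    }
    for (i in take) {
      s <- unlist(patterns[i, ])
      d <- s * mags
      got <- exact_wilcoxon_signed_rank(d)
      expect_identical(got$method, "exact")
      want <- oracle_wilcoxon(s, rank(mags))
      expect_equal(got$pvalue_two_sided, want)
      # symmetry: p(s) == p(-s)
      expect_equal(exact_wilcoxon_signed_rank(-d)$pvalue_two_sided, want)
    }
  }
})

test_that("ties trigger the corrected normal approximation", {
  d <- c(1, 1, 2, 3, 4, 5, 6, 7, -2, 2.5)  # tied |d| values
  r <- exact_wilcoxon_signed_rank(d)
  expect_identical(r$method, "normal-approximation")
  ref <- suppressWarnings(stats::wilcox.test(d, correct = TRUE))
  expect_equal(r$pvalue_two_sided, unname(ref$p.value), tolerance = 1e-8)
  # large n uses the approximation even without ties
  big <- exact_wilcoxon_signed_rank(seq(0.3, 30, length.out = 30))
  expect_identical(big$method, "normal-approximation")
  ref2 <- stats::wilcox.test(seq(0.3, 30, length.out = 30),
                             exact = FALSE, correct = TRUE)
  expect_equal(big$pvalue_two_sided, unname(ref2$p.value), tolerance = 1e-8)
})

test_that("family_export_test concatenates per-pair differences", {
  ids <- sprintf("syn-miR-320%s", letters[1:5])
  cell <- c(5, 6, 4, 7, 5)
  sc <- as_score_table(data.frame(
    id = ids, cell = cell,
    exoA = cell + c(1.3, 2.1, 1.7, 2.9, 2.45),
    exoB = cell + c(0.9, 1.1, 0.6, 1.55, 0.75),
    mv = cell + c(0.4, NA, 0.95, 1.15, 1.35)))
  r <- family_export_test(ids, list(c("exoA", "cell"), c("exoB", "cell")),
                          sc)
  expect_identical(r$n_pairs_used, 10L)
  expect_equal(r$pvalue_two_sided, 2 / 2^10)
  r3 <- suppressMessages(family_export_test(
    ids, list(c("exoA", "cell"), c("exoB", "cell"), c("mv", "cell")), sc))
  expect_identical(r3$n_pairs_used, 14L)  # one member missing in mv
  expect_error(family_export_test(ids[1], list(c("exoA", "cell")), sc),
               "fewer than 2")
  expect_error(family_export_test(ids, list(c("nope", "cell")), sc),
               "not found")
})

test_that("run_local_tests_all_groups adds BH adjustment and sorts", {
  # two groups with raw p {0.01, 0.04} -> BH {0.02, 0.04}
  net <- flat_network(1000)
  hits <- make_hits(net$nodes, net$nodes[1:100])  # background 0.1
  # find group configs with the desired raw p via the oracle
  g1 <- c(net$nodes[1:5], net$nodes[200:204])   # 5 hits of 10
  r1 <- local_binomial_test(g1, hits, net)
  res <- run_local_tests_all_groups(
    net, hits, grouping = list(a = g1, b = net$nodes[300:309]))
  expect_identical(res$group_id, c("a", "b"))
  expect_equal(res$pvalue_BH, stats::p.adjust(res$pvalue, "BH"))
  # single group: adjusted equals raw
  one <- run_local_tests_all_groups(net, hits, grouping = list(g = g1))
  expect_equal(one$pvalue_BH, one$pvalue)
  # BH arithmetic on the specified example
  expect_equal(stats::p.adjust(c(0.01, 0.04), "BH"), c(0.02, 0.04))
  # components grouping: one test per family on a seed network
  m <- make_matures(paste0("syn-miR-", 1:6),
                    c("AAAAAA", "AAAAAA", "AAAAAA", "CCCCCC", "CCCCCC",
                      "GGGGGG"))
  snet <- build_seed_network(m)
  shits <- make_hits(m$id, m$id[1:2])
  rc <- run_local_tests_all_groups(snet, shits)
  expect_identical(nrow(rc), 3L)
  expect_identical(sort(rc$n_cluster), c(1L, 2L, 3L))
})

test_that("target_set_enrichment matches the hypergeometric oracle", {
  universe <- sprintf("g%02d", 1:20)
  gene_set <- universe[1:5]
  tt <- structure(list(source_label = "t", targets = list(
    mA = c(universe[1:3], universe[10]),   # overlap 3 of 4 drawn
    mB = universe[10:13],                  # overlap 0, draws 4
    mC = character())), class = "target_table")
  res <- target_set_enrichment(tt, gene_set, universe)
  pA <- res$pvalue[res$id == "mA"]
  expect_equal(pA, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$pvalue[res$id == "mB"], 1)  # P(X >= 0) = 1
  expect_equal(res$pvalue[res$id == "mC"], 1)  # draws = 0
  # degenerate population: gene_set == universe
  res2 <- target_set_enrichment(
    structure(list(source_label = "t", targets = list(m = universe[1:4])),
              class = "target_table"), universe, universe)
  expect_equal(res2$pvalue, 1)
  expect_error(target_set_enrichment(tt, gene_set, character()), "empty")
  expect_error(target_set_enrichment(tt, c(gene_set, "zzz"), universe),
               "outside")
})

test_that("result writers emit the fixed export formats", {
  net <- flat_network(20)
  hits <- make_hits(net$nodes, net$nodes[1:5])
  res <- run_local_tests_all_groups(
    net, hits, grouping = list(a = net$nodes[1:4], b = net$nodes[5:10]))
  tsv <- tempfile(fileext = ".tsv")
  write_local_results(res, tsv)
  back <- read.delim(tsv)
  expect_identical(names(back),
                   c("group_id", "n_nodes", "n_hits", "n_cluster",
                     "k_hits", "background_p", "pvalue", "pvalue_BH"))
  g <- global_permutation_test(mirna_network(c("a", "b"),
                                             rbind(c("a", "b"))),
                               make_hits(c("a", "b"), c("a", "b")),
                               n_trials = 50L, rng_seed = 4)
  js <- tempfile(fileext = ".json")
  write_global_result_json(g, js)
  doc <- jsonlite::read_json(js)
  expect_identical(doc$rng_seed, 4L)
  expect_identical(doc$n_trials, 50L)
  expect_true(all(c("pvalue_strict", "pvalue_corrected") %in% names(doc)))
})
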