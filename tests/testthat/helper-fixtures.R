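# in-code fixture builders shared across the test files

# mature_set from ids + seeds (sequence = A + seed + poly-A tail)
make_matures <- function(ids, seeds) {
  seednet:::mature_set(ids, rep("syn", length(ids)),
                       paste0("A", seeds, strrep("A", 15)))
}

# locus_set with one locus per mature id (0-based half-open coords)
make_loci <- function(mature_ids, chrom, start, end,
                      locus_ids = paste0("pre-", mature_ids),
                      strand = rep("+", length(mature_ids))) {
  seednet:::locus_set(locus_ids, chrom, start, end, strand,
                      mature_ids = as.list(mature_ids))
}

make_hits <- function(measured, hits, desc = "test predicate") {
  structure(list(measured_ids = measured, hit_ids = hits,
                 predicate_description = desc),
            class = "hit_set")
}

# hand-written miRBase-dialect files (independent of the package writers)
write_fasta_text <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

write_gff3_text <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_line <- function(chrom, type, start, end, attrs, strand = "+") {
  paste(chrom, ".", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# --- independent oracles ------------------------------------------------

# naive direct PMF summation for the upper binomial tail
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# exact two-sided signed-rank p by brute-force enumeration of all 2^n
# sign assignments (distinct integer magnitudes assumed)
oracle_wilcoxon <- function(signs, ranks = seq_along(signs)) {
  n <- length(signs)
  W_obs <- sum(ranks[signs > 0])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  W_all <- apply(grid, 1L, function(pos) sum(ranks[unlist(pos)]))
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  min(1, 2 * min(p_ge, p_le))
}

# exhaustive tail of the hit-pair permutation null on a small graph
oracle_perm_tail <- function(nodes, edges, n_hits, observed) {
  placements <- utils::combn(length(nodes), n_hits)
  i1 <- match(edges[, 1L], nodes)
  i2 <- match(edges[, 2L], nodes)
  counts <- apply(placements, 2L, function(idx) {
    hit <- logical(length(nodes)); hit[idx] <- TRUE
    sum(hit[i1] & hit[i2])
  })
  mean(counts > observed)
}
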