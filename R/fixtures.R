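#' Specify a synthetic miRNA fixture
#'
#' Describes a fully deterministic synthetic world: miRNA families
#' realized as shared 6-mer seeds, genomic clusters realized as runs of
#' neighboring precursor loci, target sets with controlled within-family
#' overlap, and score tables with planted hit enrichment.  Everything
#' downstream (parsers, networks, overlays, tests) can run end-to-end on
#' the generated files with known ground truth.
#'
#' Defaults encode the reference world used throughout the test suite:
#' 200 matures in 20 families of 10, a background hit probability of
#' 0.1, and (when planted) one enriched group at hit probability 0.9.
#'
#' @param rng_seed integer seed; the truth is fully determined by the
#'   spec including this seed.
#' @param family_sizes integer vector, one entry per family (all >= 1).
#' @param n_singletons extra matures with unique seeds.
#' @param n_genomic_clusters number of genomic clusters; the first
#'   `n_genomic_clusters * genomic_cluster_size` precursors (in
#'   generation order) form the clusters, the rest are isolated loci.
#' @param genomic_cluster_size precursors per genomic cluster.
#' @param cluster_gap_bp intra-cluster gaps are kept strictly below this
#'   (generated at half of it).
#' @param inter_cluster_gap_bp gaps between clusters/isolated loci are
#'   kept strictly above this.
#' @param locus_length_bp length of each precursor locus.
#' @param target_universe_size,targets_per_mirna gene universe and
#'   per-miRNA target-set sizes.
#' @param shared_target_fraction_within_family fraction of each member's
#'   targets drawn from a family-specific pool (pools are disjoint
#'   across families), so within-family overlap is at least this
#'   fraction while between-family overlap stays near zero.
#' @param planted_groups list of `list(group = <truth label>,
#'   hit_probability = <p>)`; labels refer to `truth$family` or
#'   `truth$cluster` values (e.g. `"family_001"`).
#' @param background_hit_probability hit probability everywhere else.
#' @param hit_threshold scores are drawn so that `score > hit_threshold`
#'   recovers exactly the planted hit labels.
#' @param unmeasured_fraction fraction of matures given expression at or
#'   below the measurement cutoff (drawn in `[0, 9]` against the "> 10
#'   reads" convention).
#' @return a validated `fixture_spec` object.
#' @export
fixture_spec <- function(rng_seed = 1L,
                         family_sizes = rep(10L, 20L),
                         n_singletons = 0L,
                         n_genomic_clusters = 4L,
                         genomic_cluster_size = 5L,
                         cluster_gap_bp = 1000L,
                         inter_cluster_gap_bp = 100000L,
                         locus_length_bp = 80L,
                         target_universe_size = 2000L,
                         targets_per_mirna = 40L,
                         shared_target_fraction_within_family = 0.8,
                         planted_groups = list(),
                         background_hit_probability = 0.1,
                         hit_threshold = 1,
                         unmeasured_fraction = 0) {
  stopifnot(all(family_sizes >= 1L), n_singletons >= 0L,
            cluster_gap_bp > 0L, inter_cluster_gap_bp > 0L,
            locus_length_bp > 0L,
            shared_target_fraction_within_family >= 0,
            shared_target_fraction_within_family <= 1,
            background_hit_probability >= 0,
            background_hit_probability <= 1,
            unmeasured_fraction >= 0, unmeasured_fraction < 1)
  for (pg in planted_groups) {
    stopifnot(is.character(pg$group),
              pg$hit_probability >= 0, pg$hit_probability <= 1)
  }
  n_seeds_needed <- length(family_sizes) + n_singletons
  if (n_seeds_needed > 4^6) {
    stop("cannot generate ", n_seeds_needed, " distinct 6-mer seeds ",
         "(only 4^6 = 4096 exist)")
  }
  structure(list(rng_seed = as.integer(rng_seed),
                 family_sizes = as.integer(family_sizes),
                 n_singletons = as.integer(n_singletons),
                 n_genomic_clusters = as.integer(n_genomic_clusters),
                 genomic_cluster_size = as.integer(genomic_cluster_size),
                 cluster_gap_bp = as.integer(cluster_gap_bp),
                 inter_cluster_gap_bp = as.integer(inter_cluster_gap_bp),
                 locus_length_bp = as.integer(locus_length_bp),
                 target_universe_size = as.integer(target_universe_size),
                 targets_per_mirna = as.integer(targets_per_mirna),
                 shared_target_fraction_within_family =
                   shared_target_fraction_within_family,
                 planted_groups = planted_groups,
                 background_hit_probability = background_hit_probability,
                 hit_threshold = hit_threshold,
                 unmeasured_fraction = unmeasured_fraction),
            class = "fixture_spec")
}

# deterministic member suffix: a, b, ..., z, aa, ab, ...
member_suffix <- function(m) {
  if (m <= 26L) return(letters[m])
  paste0(letters[(m - 1L) %/% 26L], letters[(m - 1L) %% 26L + 1L])
}

#' Generate synthetic annotation files with known truth
#'
#' Realizes the families of a [fixture_spec()] as distinct shared seeds
#' at positions 2-7 of otherwise random 22-mers, and the genomic
#' clusters as runs of loci with intra-cluster gaps below
#' `cluster_gap_bp` and inter-cluster gaps above
#' `inter_cluster_gap_bp`.  The files are written through the package's
#' own writers, so they parse cleanly back through
#' [parse_mature_fasta()] and [parse_locus_gff3()].  The species code is
#' `syn` so accidental mixing with real annotation is visible.
#' Regeneration from the same spec is byte-identical.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return list with `matures` (`mature_set`), `loci` (`locus_set`),
#'   `fasta` and `gff3` (paths), and `truth` (`fixture_truth`: named
#'   family/cluster labels, seeds, loci).
#' @export
generate_annotation <- function(spec, dir = tempfile("seednet_fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_fam <- length(spec$family_sizes)
  n_groups <- n_fam + spec$n_singletons
  nt <- c("A", "C", "G", "U")
  res <- local_seed(spec$rng_seed, {
    all_seeds <- do.call(paste0, expand.grid(nt, nt, nt, nt, nt, nt,
                                             stringsAsFactors = FALSE))
    seeds <- sample(all_seeds, n_groups)
    sizes <- c(spec$family_sizes, rep(1L, spec$n_singletons))
    group_label <- c(sprintf("family_%03d", seq_len(n_fam)),
                     if (spec$n_singletons > 0L)
                       sprintf("singleton_%03d", seq_len(spec$n_singletons)))
    ids <- character(0); seqs <- character(0); fams <- character(0)
    for (g in seq_len(n_groups)) {
      for (m in seq_len(sizes[g])) {
        flank <- paste(sample(nt, 16L, replace = TRUE), collapse = "")
        seqs <- c(seqs, paste0(substr(flank, 1L, 1L), seeds[g],
                               substr(flank, 2L, 16L)))
        ids <- c(ids, sprintf("syn-miR-%d%s", g, member_suffix(m)))
        fams <- c(fams, group_label[g])
      }
    }
    list(ids = ids, seqs = seqs, fams = fams, seeds = seeds,
         group_label = group_label)
  })
  n <- length(res$ids)
  matures <- mature_set(res$ids, rep("syn", n), res$seqs)

  # genomic layout: clusters first, then isolated loci, all on chr1
  pre_ids <- sub("miR", "mir", res$ids, fixed = TRUE)
  n_clustered <- min(n, spec$n_genomic_clusters * spec$genomic_cluster_size)
  cluster_of <- rep(NA_character_, n)
  if (n_clustered > 0L && spec$n_genomic_clusters > 0L) {
    cluster_of[seq_len(n_clustered)] <-
      sprintf("gcluster_%03d",
              rep(seq_len(spec$n_genomic_clusters),
                  each = spec$genomic_cluster_size)[seq_len(n_clustered)])
  }
  intra <- spec$cluster_gap_bp %/% 2L
  inter <- spec$inter_cluster_gap_bp + spec$cluster_gap_bp
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    if (i > 1L) {
      same_cluster <- !is.na(cluster_of[i]) &&
        identical(cluster_of[i], cluster_of[i - 1L])
      pos <- pos + spec$locus_length_bp + if (same_cluster) intra else inter
    }
    starts[i] <- pos
  }
  loci <- locus_set(id = pre_ids, chrom = rep("chr1", n),
                    start = starts, end = starts + spec$locus_length_bp,
                    strand = rep("+", n),
                    mature_ids = as.list(res$ids))
  fasta <- file.path(dir, "matures.fa")
  gff3 <- file.path(dir, "loci.gff3")
  write_mature_fasta(matures, fasta)
  write_locus_gff3(loci, gff3)
  cluster_of[is.na(cluster_of)] <- "unclustered"
  truth <- structure(list(
    family = setNames(res$fams, res$ids),
    cluster = setNames(cluster_of, res$ids),
    seed_of_group = setNames(res$seeds, res$group_label),
    precursor = setNames(pre_ids, res$ids)),
    class = "fixture_truth")
  list(matures = matures, loci = loci, fasta = fasta, gff3 = gff3,
       truth = truth)
}

#' Generate synthetic target predictions
#'
#' Each family gets a disjoint pool of
#' `round(shared_target_fraction_within_family * targets_per_mirna)`
#' genes; every member's target set is that whole pool plus random genes
#' from outside all pools.  Within-family pairwise overlap (overlap
#' coefficient) is therefore at least the shared fraction by
#' construction, while between-family overlap stays near zero.
#'
#' @param spec a `fixture_spec`.
#' @param truth the `fixture_truth` from [generate_annotation()].
#' @return a `target_table`.
#' @export
generate_targets <- function(spec, truth) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(truth, "fixture_truth"))
  U <- spec$target_universe_size
  t_n <- spec$targets_per_mirna
  if (t_n > U) stop("targets_per_mirna exceeds the gene universe")
  ids <- names(truth$family)
  if (length(ids) == 0L) {
    return(structure(list(source_label = "synthetic", targets = list()),
                     empty_ids = character(), class = "target_table"))
  }
  groups <- unique(truth$family)
  pool_n <- round(spec$shared_target_fraction_within_family * t_n)
  if (length(groups) * pool_n + (t_n - pool_n) > U) {
    stop("gene universe too small for ", length(groups),
         " disjoint family pools of size ", pool_n)
  }
  universe <- sprintf("gene%05d", seq_len(U))
  if (pool_n > 0L) {
    pools <- split(universe[seq_len(length(groups) * pool_n)],
                   rep(seq_along(groups), each = pool_n))
    names(pools) <- groups
  } else {
    pools <- setNames(rep(list(character()), length(groups)), groups)
  }
  free <- universe[(length(groups) * pool_n + 1L):U]
  targets <- local_seed(spec$rng_seed + 1L, {
    lapply(setNames(ids, ids), function(id) {
      pool <- pools[[truth$family[[id]]]]
      extra <- sample(free, t_n - length(pool))
      c(pool, extra)
    })
  })
  structure(list(source_label = "synthetic", targets = targets),
            empty_ids = character(), class = "target_table")
}

#' Generate a synthetic score table with planted hits
#'
#' Each miRNA is labeled a hit with its planted group's probability
#' (the background probability elsewhere); the `score` column is drawn
#' so that the rule `score > hit_threshold` recovers exactly the
#' planted labels, and the `expression` column marks
#' `unmeasured_fraction` of the miRNAs as unexpressed (at or below 10
#' reads).  Setting every planted probability equal to the background
#' yields a null dataset for calibration.
#'
#' @param spec a `fixture_spec`.
#' @param truth the `fixture_truth` from [generate_annotation()].
#' @return a `score_table` with columns `score` and `expression` and
#'   attributes `planted_hit_ids` and `unmeasured_ids`.
#' @export
generate_scores <- function(spec, truth) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(truth, "fixture_truth"))
  ids <- names(truth$family)
  n <- length(ids)
  prob <- rep(spec$background_hit_probability, n)
  for (pg in spec$planted_groups) {
    in_group <- truth$family[ids] == pg$group | truth$cluster[ids] == pg$group
    prob[in_group] <- pg$hit_probability
  }
  res <- local_seed(spec$rng_seed + 2L, {
    hit <- stats::rbinom(n, 1L, prob) == 1L
    score <- ifelse(hit,
                    spec$hit_threshold + runif(n, 0.5, 3),
                    spec$hit_threshold - runif(n, 0.5, 3))
    expression <- runif(n, 50, 500)
    n_unmeasured <- floor(spec$unmeasured_fraction * n)
    unmeasured <- if (n_unmeasured > 0L) sample(ids, n_unmeasured)
                  else character()
    expression[ids %in% unmeasured] <- runif(length(unmeasured), 0, 9)
    list(hit = hit, score = score, expression = expression,
         unmeasured = unmeasured)
  })
  out <- as_score_table(data.frame(id = ids, score = res$score,
                                   expression = res$expression,
                                   stringsAsFactors = FALSE))
  attr(out, "planted_hit_ids") <- ids[res$hit]
  attr(out, "unmeasured_ids") <- res$unmeasured
  out
}

#' Serialize fixture truth as JSON
#'
#' @param truth a `fixture_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixture_truth <- function(truth, path) {
  stopifnot(inherits(truth, "fixture_truth"))
  jsonlite::write_json(lapply(unclass(truth), as.list), path,
                       auto_unbox = TRUE)
  invisible(path)
}
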