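#' Construct a miRNA network container
#'
#' Undirected simple graph over mature miRNA ids, together with the rule
#' and threshold that generated it.  Self-loops are forbidden; duplicate
#' and reversed edges are canonicalized away; nodes and edges are kept in
#' a deterministic sorted order so identical inputs always yield
#' identical objects.
#'
#' @param nodes character vector of mature ids.
#' @param edges two-column character matrix/data.frame of id pairs, or
#'   NULL for an edgeless network.
#' @param rule_name name of the generating rule (e.g. `"Seed2_7"`,
#'   `"Genomic_Distance_2k"`, `"TargetScan54"`, `"custom"`).
#' @param threshold numeric parameter of the rule (bp, fraction or
#'   degree), NA when not applicable.
#' @param species_code 3-letter species prefix, NA when mixed/unknown.
#' @return an object of class `mirna_network`.
#' @export
mirna_network <- function(nodes, edges = NULL, rule_name = "custom",
                          threshold = NA_real_,
                          species_code = NA_character_) {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L,
                 dimnames = list(NULL, c("from", "to")))
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    if (any(em[, 1L] == em[, 2L])) stop("self-loop edge(s) not allowed")
    unknown <- setdiff(c(em), nodes)
    if (length(unknown)) {
      stop("edge endpoint(s) not in node set: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    a <- pmin(em[, 1L], em[, 2L])
    b <- pmax(em[, 1L], em[, 2L])
    key <- paste(a, b, sep = "\r")
    keep <- !duplicated(key)
    em <- cbind(from = a[keep], b = b[keep])[order(a[keep], b[keep]), ,
                                             drop = FALSE]
    colnames(em) <- c("from", "to")
  }
  structure(list(nodes = nodes, edges = em, rule_name = rule_name,
                 threshold = threshold, species_code = species_code),
            class = "mirna_network")
}

#' @export
print.mirna_network <- function(x, ...) {
  cat("miRNA network [", x$rule_name,
      if (!is.na(x$threshold)) paste0(", threshold ", x$threshold), "]\n",
      sep = "")
  cat("  ", length(x$nodes), " nodes, ", nrow(x$edges), " edges, ",
      length(connected_components(x)), " components\n", sep = "")
  invisible(x)
}

#' Convert a miRNA network to an igraph graph
#'
#' @param network a `mirna_network`.
#' @return an undirected [igraph::graph] with the rule metadata as graph
#'   attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "mirna_network"))
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "rule_name", network$rule_name)
  g <- igraph::set_graph_attr(g, "threshold", network$threshold)
  g <- igraph::set_graph_attr(g, "species_code", network$species_code)
  g
}

#' Build the shared-seed family network
#'
#' Connects every pair of mature miRNAs with an identical seed
#' (nucleotides 2-7), so each connected component is a clique — one
#' miRNA family per seed.
#'
#' @param matures a `mature_set` (see [parse_mature_fasta()]).
#' @return a `mirna_network` with rule `Seed2_7`.
#' @export
build_seed_network <- function(matures) {
  stopifnot(inherits(matures, "mature_set"))
  sp <- unique(matures$species_code[!is.na(matures$species_code)])
  groups <- split(matures$id, matures$seed)
  edges <- do.call(rbind, lapply(groups, function(ids) {
    if (length(ids) < 2L) return(NULL)
    t(utils::combn(sort(ids), 2L))
  }))
  mirna_network(matures$id, edges, rule_name = "Seed2_7",
                species_code = if (length(sp) == 1L) sp else NA_character_)
}

# minimum genomic gap between two sets of half-open intervals on the same
# chromosome; overlapping or book-ended intervals have gap 0
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Build a genomic-distance network of miRNA loci
#'
#' Connects two mature miRNAs when any precursor locus of one lies closer
#' than `threshold_bp` (strict) to any precursor locus of the other on
#' the same chromosome.  The gap is measured between interval ends;
#' overlapping or book-ended loci (and matures sharing a precursor) have
#' gap 0 and always connect.  Strand is ignored by default: polycistrons
#' are single-strand, but the large-threshold use case targets genomic
#' reorganizations that need not respect strand.  Matures without any
#' locus are excluded (and reported).
#'
#' @param matures a `mature_set`.
#' @param loci a `locus_set` (see [parse_locus_gff3()]).
#' @param threshold_bp positive integer distance threshold; the
#'   polycistron-scale convention is 2000, the reorganization-scale one
#'   50000.
#' @param same_strand_only if TRUE, additionally require equal strand.
#' @return a `mirna_network` with rule `Genomic_Distance_<threshold>`.
#' @export
build_genomic_network <- function(matures, loci, threshold_bp,
                                  same_strand_only = FALSE) {
  stopifnot(inherits(matures, "mature_set"), inherits(loci, "locus_set"))
  if (!is.numeric(threshold_bp) || threshold_bp <= 0) {
    stop("threshold_bp must be a positive number")
  }
  # one row per (mature, locus) assignment
  n_mat <- vapply(loci$mature_ids, length, integer(1))
  tab <- data.frame(
    mature = unlist(loci$mature_ids, use.names = FALSE),
    chrom = rep(loci$chrom, n_mat),
    start = rep(loci$start, n_mat),
    end = rep(loci$end, n_mat),
    strand = rep(loci$strand, n_mat),
    stringsAsFactors = FALSE)
  tab <- tab[tab$mature %in% matures$id, , drop = FALSE]
  missing <- setdiff(matures$id, tab$mature)
  if (length(missing)) {
    message(length(missing), " mature(s) without genomic locus excluded: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  edges <- NULL
  for (chr in unique(tab$chrom)) {
    sub <- tab[tab$chrom == chr, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    idx <- utils::combn(n, 2L)
    i <- idx[1L, ]; j <- idx[2L, ]
    gap <- interval_gap(sub$start[i], sub$end[i], sub$start[j], sub$end[j])
    ok <- gap < threshold_bp & sub$mature[i] != sub$mature[j]
    if (same_strand_only) {
      ok <- ok & !is.na(sub$strand[i]) & sub$strand[i] == sub$strand[j]
    }
    if (any(ok)) {
      edges <- rbind(edges, cbind(sub$mature[i][ok], sub$mature[j][ok]))
    }
  }
  sp <- unique(matures$species_code[!is.na(matures$species_code)])
  mirna_network(unique(tab$mature), edges,
                rule_name = paste0("Genomic_Distance_", threshold_bp),
                threshold = as.numeric(threshold_bp),
                species_code = if (length(sp) == 1L) sp else NA_character_)
}

#' Build a target-overlap co-regulation network
#'
#' Connects two miRNAs when their predicted target sets overlap by more
#' than `threshold_fraction` (strict).  The default overlap measure is
#' the overlap coefficient |A n B| / min(|A|, |B|); Jaccard
#' |A n B| / |A u B| is available as an option.  miRNAs with empty
#' target sets become isolated nodes.
#'
#' @param targets a `target_table` (see [parse_target_table()]).
#' @param threshold_fraction overlap threshold in (0, 1); published
#'   conventions use 0.50 (Diana MicroT, TarBase) and 0.54 (TargetScan).
#' @param overlap_measure `"overlap"` (min-denominator coefficient,
#'   default) or `"jaccard"`.
#' @param rule_name stored rule label; defaults to a generic label
#'   carrying the measure and threshold.
#' @param species_code optional species code stored on the network.
#' @return a `mirna_network`.
#' @export
build_target_overlap_network <- function(targets, threshold_fraction,
                                         overlap_measure = c("overlap",
                                                             "jaccard"),
                                         rule_name = NULL,
                                         species_code = NA_character_) {
  stopifnot(inherits(targets, "target_table"))
  overlap_measure <- match.arg(overlap_measure)
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("threshold_fraction must be in (0, 1)")
  }
  ids <- names(targets$targets)
  sets <- targets$targets
  sizes <- vapply(sets, length, integer(1))
  nonempty <- which(sizes > 0L)
  edges <- NULL
  if (length(nonempty) >= 2L) {
    idx <- utils::combn(nonempty, 2L)
    ov <- vapply(seq_len(ncol(idx)), function(k) {
      a <- sets[[idx[1L, k]]]; b <- sets[[idx[2L, k]]]
      inter <- length(intersect(a, b))
      if (overlap_measure == "overlap") {
        inter / min(length(a), length(b))
      } else {
        inter / length(union(a, b))
      }
    }, numeric(1))
    ok <- ov > threshold_fraction
    if (any(ok)) {
      edges <- cbind(ids[idx[1L, ok]], ids[idx[2L, ok]])
    }
  }
  if (is.null(rule_name)) {
    rule_name <- sprintf("TargetOverlap_%s_%g", overlap_measure,
                         threshold_fraction)
  }
  mirna_network(ids, edges, rule_name = rule_name,
                threshold = threshold_fraction, species_code = species_code)
}

#' Connected components of a miRNA network
#'
#' @param network a `mirna_network`.
#' @return list of character vectors (each sorted), ordered by component
#'   size (decreasing) then by lexicographically smallest member.
#' @export
connected_components <- function(network) {
  stopifnot(inherits(network, "mirna_network"))
  if (length(network$nodes) == 0L) return(list())
  g <- as_igraph(network)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, sort)
  first <- vapply(comps, `[`, character(1), 1L)
  sizes <- vapply(comps, length, integer(1))
  unname(comps[order(-sizes, first)])
}

# induced subnetwork on a node subset, preserving metadata
induce_subnetwork <- function(network, keep, rule_name = network$rule_name,
                              threshold = network$threshold) {
  keep <- intersect(network$nodes, keep)
  e <- network$edges
  e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  mirna_network(keep, e, rule_name = rule_name, threshold = threshold,
                species_code = network$species_code)
}

#' Keep only components of a minimum size
#'
#' Retains exactly the nodes lying in connected components with at least
#' `min_size` nodes, with their induced edges — the "clusters of size 3
#' or more" simplification of the genomic-distance network.
#'
#' @param network a `mirna_network`.
#' @param min_size minimum component size (default 3).
#' @return a filtered `mirna_network`; the rule name gains a
#'   `_clusters_<min_size>+` suffix.
#' @export
filter_clusters_min_size <- function(network, min_size = 3L) {
  stopifnot(min_size >= 1L)
  comps <- connected_components(network)
  keep <- unlist(comps[vapply(comps, length, integer(1)) >= min_size])
  induce_subnetwork(network, keep %||% character(),
                    rule_name = paste0(network$rule_name, "_clusters_",
                                       min_size, "+"))
}

#' Remove low-degree nodes (single pass)
#'
#' Drops nodes whose degree in the *input* network is below `min_degree`,
#' together with their incident edges.  This is a single pass — not an
#' iterated k-core — so the surviving subgraph keeps the layout semantics
#' of the full network (the `degree_10+` simplification).
#'
#' @param network a `mirna_network`.
#' @param min_degree minimum degree to keep (default 10).
#' @return a filtered `mirna_network` with a `_degree_<min_degree>+`
#'   rule-name suffix.
#' @export
filter_min_degree <- function(network, min_degree = 10L) {
  stopifnot(min_degree >= 0L)
  deg <- setNames(numeric(length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    t1 <- table(network$edges[, 1L]); t2 <- table(network$edges[, 2L])
    deg[names(t1)] <- deg[names(t1)] + as.numeric(t1)
    deg[names(t2)] <- deg[names(t2)] + as.numeric(t2)
  }
  keep <- names(deg)[deg >= min_degree]
  induce_subnetwork(network, keep,
                    rule_name = paste0(network$rule_name, "_degree_",
                                       min_degree, "+"))
}

#' Summarize genomic clusters of a genomic-distance network
#'
#' One cluster per connected component, with the base-pair envelope
#' (maximum locus end minus minimum locus start over all member loci) as
#' its span.  All members of a component necessarily share a chromosome;
#' this is asserted and violations fail loudly.
#'
#' @param network a `mirna_network` built by [build_genomic_network()].
#' @param loci the `locus_set` the network was built from.
#' @return data.frame with columns `cluster_id`, `chrom`, `span_start`,
#'   `span_end` (0-based half-open), `span_bp`, `size` and list-column
#'   `members`; ordered by size (decreasing) then by span start.
#' @export
genomic_clusters <- function(network, loci) {
  stopifnot(inherits(network, "mirna_network"), inherits(loci, "locus_set"))
  n_mat <- vapply(loci$mature_ids, length, integer(1))
  tab <- data.frame(
    mature = unlist(loci$mature_ids, use.names = FALSE),
    chrom = rep(loci$chrom, n_mat),
    start = rep(loci$start, n_mat),
    end = rep(loci$end, n_mat), stringsAsFactors = FALSE)
  comps <- connected_components(network)
  rows <- lapply(comps, function(members) {
    sub <- tab[tab$mature %in% members, , drop = FALSE]
    chroms <- unique(sub$chrom)
    if (length(chroms) != 1L) {
      stop("genomic cluster spans multiple chromosomes (",
           paste(chroms, collapse = ", "),
           "); was this network built by build_genomic_network()?")
    }
    data.frame(chrom = chroms, span_start = min(sub$start),
               span_end = max(sub$end),
               span_bp = max(sub$end) - min(sub$start),
               size = length(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), span_start = integer(),
                      span_end = integer(), span_bp = integer(),
                      size = integer(), stringsAsFactors = FALSE)
    out$members <- list()
    out <- cbind(cluster_id = character(), out)
    return(out)
  }
  ord <- order(-out$size, out$span_start)
  out <- out[ord, , drop = FALSE]
  out$members <- comps[ord]
  out <- cbind(cluster_id = sprintf("cluster_%03d", seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
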