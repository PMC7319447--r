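#' Export a miRNA network as GraphML
#'
#' Rule name, threshold and species code are stored as graph attributes
#' and survive a round trip through [read_graphml()].
#'
#' @param network a `mirna_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a miRNA network from GraphML
#'
#' @param path a GraphML file written by [write_graphml()] (or any
#'   undirected GraphML graph with node names).
#' @return a `mirna_network`.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  e <- igraph::as_edgelist(g, names = TRUE)
  ga <- igraph::graph_attr(g)
  mirna_network(nodes, e,
                rule_name = ga$rule_name %||% "custom",
                threshold = as.numeric(ga$threshold %||% NA_real_),
                species_code = ga$species_code %||% NA_character_)
}

#' Export a miRNA network as JSON
#'
#' Small JSON graph dialect: `rule_name`, `threshold`, `species_code`,
#' `nodes` (array of ids) and `edges` (array of 2-element arrays).
#'
#' @param network a `mirna_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  doc <- list(rule_name = network$rule_name,
              threshold = network$threshold,
              species_code = network$species_code,
              nodes = network$nodes,
              edges = unname(apply(network$edges, 1L, function(r)
                list(r[[1L]], r[[2L]]))))
  if (nrow(network$edges) == 0L) doc$edges <- list()
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA)
  invisible(path)
}

#' Import a miRNA network from JSON
#'
#' @param path a JSON file written by [write_network_json()].
#' @return a `mirna_network`.
#' @export
read_network_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path)
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(doc$edges, function(e)
      c(as.character(e[[1L]]), as.character(e[[2L]]))))
  } else NULL
  mirna_network(unlist(doc$nodes) %||% character(), edges,
                rule_name = doc$rule_name %||% "custom",
                threshold = as.numeric(doc$threshold %||% NA_real_),
                species_code = doc$species_code %||% NA_character_)
}

#' Write a genomic-cluster table as TSV
#'
#' Columns: cluster_id, members (comma-joined), chrom, span_bp, size.
#'
#' @param clusters data.frame from [genomic_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  out <- data.frame(
    cluster_id = clusters$cluster_id,
    members = vapply(clusters$members, paste, character(1), collapse = ","),
    chrom = clusters$chrom,
    span_bp = clusters$span_bp,
    size = clusters$size, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# seeded Fruchterman-Reingold-style layout with a fixed iteration budget;
# deterministic for a given (nodes, edges, seed)
layout_force <- function(nodes, edges, seed, n_iter = 150L) {
  n <- length(nodes)
  if (n == 0L) return(matrix(numeric(), 0L, 2L))
  pos <- local_seed(seed, matrix(runif(2L * n, -1, 1), n, 2L))
  if (n == 1L) return(pos)
  i1 <- match(edges[, 1L], nodes)
  i2 <- match(edges[, 2L], nodes)
  k <- sqrt(4 / n)          # ideal edge length in a 2x2 canvas
  temp <- 0.5
  cool <- temp / n_iter
  for (it in seq_len(n_iter)) {
    disp <- matrix(0, n, 2L)
    # repulsion, all pairs
    for (d in 1:2) {
      dd <- outer(pos[, d], pos[, d], "-")
      if (d == 1L) dx <- dd else dy <- dd
    }
    dist2 <- dx^2 + dy^2
    diag(dist2) <- Inf
    dist2[dist2 < 1e-9] <- 1e-9
    f_rep <- k^2 / dist2
    disp[, 1L] <- rowSums(dx * f_rep)
    disp[, 2L] <- rowSums(dy * f_rep)
    # attraction along edges
    if (length(i1)) {
      ex <- pos[i1, 1L] - pos[i2, 1L]
      ey <- pos[i1, 2L] - pos[i2, 2L]
      ed <- sqrt(ex^2 + ey^2)
      ed[ed < 1e-6] <- 1e-6
      f_att <- ed / k
      fx <- ex * f_att; fy <- ey * f_att
      for (e in seq_along(i1)) {
        disp[i1[e], ] <- disp[i1[e], ] - c(fx[e], fy[e])
        disp[i2[e], ] <- disp[i2[e], ] + c(fx[e], fy[e])
      }
    }
    len <- sqrt(rowSums(disp^2))
    len[len < 1e-9] <- 1e-9
    step <- pmin(len, temp)
    pos <- pos + disp / len * step
    pos[pos > 1] <- 1; pos[pos < -1] <- -1
    temp <- temp - cool
  }
  pos
}

svg_num <- function(x) sprintf("%.2f", x)

#' Render a styled network as a static SVG document
#'
#' Deterministic force-directed layout (fixed iteration count, seeded
#' initialization): the same network, styles and `layout_seed` always
#' produce a byte-identical file.  Nodes are circles filled with the
#' color and alpha from [style_nodes()]; a legend shows the color-scale
#' anchors when a scale is given.  A 0-node network yields a valid SVG
#' with the legend only.
#'
#' @param network a `mirna_network`.
#' @param styles data.frame from [style_nodes()] covering all nodes.
#' @param layout_seed integer seed for the layout initialization.
#' @param path output path, or NULL to return the SVG text.
#' @param width,height canvas size in px.
#' @param labels draw node labels.
#' @param scale optional [color_scale()] rendered as a legend.
#' @return the SVG document as a character scalar (invisibly when
#'   written to `path`).
#' @export
render_svg <- function(network, styles, layout_seed = 1L, path = NULL,
                       width = 800, height = 600, labels = FALSE,
                       scale = NULL) {
  stopifnot(inherits(network, "mirna_network"))
  missing_nodes <- setdiff(network$nodes, styles$id)
  if (length(missing_nodes)) {
    stop("styles missing for node(s): ",
         paste(utils::head(missing_nodes, 5L), collapse = ", "))
  }
  pos <- layout_force(network$nodes, network$edges, layout_seed)
  margin <- 40
  px <- function(x) margin + (x + 1) / 2 * (width - 2 * margin)
  py <- function(y) margin + (y + 1) / 2 * (height - 60 - 2 * margin)
  st <- styles[match(network$nodes, styles$id), , drop = FALSE]
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height),
    sprintf('<title>%s network</title>', network$rule_name))
  if (nrow(network$edges)) {
    e1 <- match(network$edges[, 1L], network$nodes)
    e2 <- match(network$edges[, 2L], network$nodes)
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#999999" stroke-width="0.8"/>',
      svg_num(px(pos[e1, 1L])), svg_num(py(pos[e1, 2L])),
      svg_num(px(pos[e2, 1L])), svg_num(py(pos[e2, 2L]))))
  }
  if (length(network$nodes)) {
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="6" fill="%s" fill-opacity="%s" stroke="#333333" stroke-width="0.5"/>',
      svg_num(px(pos[, 1L])), svg_num(py(pos[, 2L])),
      st$color, svg_num(st$alpha)))
    if (labels) {
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="8" font-family="sans-serif">%s</text>',
        svg_num(px(pos[, 1L]) + 7), svg_num(py(pos[, 2L]) + 3),
        network$nodes))
    }
  }
  # legend
  ly <- height - 35
  if (!is.null(scale)) {
    out <- c(out,
      '<defs><linearGradient id="cs" x1="0" x2="1" y1="0" y2="0">',
      sprintf('<stop offset="0" stop-color="%s"/>', scale$low),
      sprintf('<stop offset="0.5" stop-color="%s"/>', scale$mid_color),
      sprintf('<stop offset="1" stop-color="%s"/>', scale$high),
      '</linearGradient></defs>',
      sprintf('<rect x="%d" y="%d" width="150" height="12" fill="url(#cs)" stroke="#333333" stroke-width="0.5"/>',
              margin, ly),
      sprintf('<text x="%d" y="%d" font-size="10" font-family="sans-serif">%g</text>',
              margin, ly + 24, scale$min),
      sprintf('<text x="%d" y="%d" font-size="10" font-family="sans-serif" text-anchor="middle">%g</text>',
              margin + 75L, ly + 24, scale$mid),
      sprintf('<text x="%d" y="%d" font-size="10" font-family="sans-serif" text-anchor="end">%g</text>',
              margin + 150L, ly + 24, scale$max))
  } else {
    out <- c(out, sprintf(
      '<text x="%d" y="%d" font-size="10" font-family="sans-serif">%d nodes, %d edges</text>',
      margin, ly + 10, length(network$nodes), nrow(network$edges)))
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
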