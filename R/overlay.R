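#' Define a hit rule
#'
#' A hit rule turns a numeric score column into a hit predicate:
#' a comparison threshold, a direction, and an optional expression
#' filter defining which miRNAs count as measured at all (e.g. "median
#' expression > 10 reads").  Direction `"greater"` and `"less"` give
#' directional hit sets (e.g. poor- vs good-prognosis);
#' `"absolute"` takes |value| > threshold.
#'
#' @param threshold numeric comparison threshold.
#' @param direction one of `"greater"`, `"less"`, `"absolute"`.
#' @param expression_column optional column name with expression values.
#' @param expression_threshold miRNAs with expression strictly greater
#'   than this count as measured (default 10, the "> 10 reads"
#'   convention); only used with `expression_column`.
#' @return a `hit_rule` object.
#' @export
hit_rule <- function(threshold, direction = c("greater", "less",
                                              "absolute"),
                     expression_column = NULL,
                     expression_threshold = 10) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  structure(list(threshold = threshold, direction = direction,
                 expression_column = expression_column,
                 expression_threshold = expression_threshold),
            class = "hit_rule")
}

#' Apply a hit rule to a score table
#'
#' Measured miRNAs are the rows with a non-missing value in
#' `value_column` that pass the rule's expression filter (if any); hits
#' are the measured rows passing the comparison.  The resulting hit set
#' records a textual predicate description from which the counts are
#' reproducible.
#'
#' @param scores a `score_table`.
#' @param value_column name of the numeric column the rule compares.
#' @param rule a [hit_rule()].
#' @return a `hit_set`: list with `measured_ids`, `hit_ids`,
#'   `predicate_description`.
#' @export
define_hits <- function(scores, value_column, rule) {
  stopifnot(inherits(scores, "score_table"), inherits(rule, "hit_rule"))
  if (!value_column %in% names(scores)) {
    stop("value column '", value_column, "' not found; available: ",
         paste(setdiff(names(scores), c("id", "id_norm")), collapse = ", "))
  }
  v <- scores[[value_column]]
  measured <- !is.na(v)
  expr_desc <- ""
  if (!is.null(rule$expression_column)) {
    if (!rule$expression_column %in% names(scores)) {
      stop("expression column '", rule$expression_column, "' not found")
    }
    e <- scores[[rule$expression_column]]
    measured <- measured & !is.na(e) & e > rule$expression_threshold
    expr_desc <- sprintf(" AND %s > %g", rule$expression_column,
                         rule$expression_threshold)
  }
  if (!any(measured)) stop("no measured rows under this rule")
  hit <- switch(rule$direction,
                greater = v > rule$threshold,
                less = v < rule$threshold,
                absolute = abs(v) > rule$threshold)
  hit <- measured & hit
  op <- switch(rule$direction, greater = ">", less = "<", absolute = "|x| >")
  desc <- sprintf("%s %s %g%s", value_column, op, rule$threshold, expr_desc)
  message(sum(hit), " hit(s) of ", sum(measured), " measured [", desc, "]")
  structure(list(measured_ids = scores$id[measured],
                 hit_ids = scores$id[hit],
                 predicate_description = desc),
            class = "hit_set")
}

#' Define a diverging color scale
#'
#' Two linear RGB gradients (low-to-mid and mid-to-high) anchored at
#' three values; values outside the anchors clamp to the end colors.
#' The default green-white-red convention paints repressed / good
#' prognosis green and overexpressed / poor prognosis red.
#'
#' @param min,mid,max numeric anchors (strictly increasing).
#' @param low,mid_color,high colors for the anchors.
#' @param na_color neutral fill for unmeasured nodes.
#' @param alpha_unmeasured semi-transparency for unmeasured/unexpressed
#'   nodes (default 0.25).
#' @return a `color_scale` object.
#' @export
color_scale <- function(min = -2, mid = 0, max = 2,
                        low = "#1A9641", mid_color = "#FFFFFF",
                        high = "#D7191C", na_color = "#B0B0B0",
                        alpha_unmeasured = 0.25) {
  if (!(min < mid && mid < max)) {
    stop("degenerate color scale: need min < mid < max")
  }
  structure(list(min = min, mid = mid, max = max, low = low,
                 mid_color = mid_color, high = high, na_color = na_color,
                 alpha_unmeasured = alpha_unmeasured),
            class = "color_scale")
}

# interpolate one value on a diverging scale -> hex color
scale_color <- function(v, scale) {
  if (is.na(v)) return(toupper(scale$na_color))
  if (v <= scale$mid) {
    t <- (v - scale$min) / (scale$mid - scale$min)
    ramp <- grDevices::colorRamp(c(scale$low, scale$mid_color))
  } else {
    t <- (v - scale$mid) / (scale$max - scale$mid)
    ramp <- grDevices::colorRamp(c(scale$mid_color, scale$high))
  }
  t <- min(1, max(0, t))
  rgbv <- ramp(t)
  toupper(grDevices::rgb(rgbv[1L], rgbv[2L], rgbv[3L],
                         maxColorValue = 255))
}

#' Compute per-node rendering attributes
#'
#' Maps one score column onto node colors with a diverging scale.
#' Nodes without a usable measurement (absent from the score table,
#' missing value, or outside `measured_ids` when given) get the neutral
#' color and the semi-transparent alpha.  Score rows absent from the
#' network are reported, never silently dropped.
#'
#' @param network a `mirna_network`.
#' @param scores a `score_table`.
#' @param value_column column to map.
#' @param scale a [color_scale()].
#' @param measured_ids optional character vector restricting which nodes
#'   count as measured (e.g. `hit_set$measured_ids` after an expression
#'   filter).
#' @return data.frame with columns `id`, `value`, `color` (hex),
#'   `alpha`.
#' @export
style_nodes <- function(network, scores, value_column,
                        scale = color_scale(), measured_ids = NULL) {
  stopifnot(inherits(network, "mirna_network"),
            inherits(scores, "score_table"),
            inherits(scale, "color_scale"))
  if (!value_column %in% names(scores)) {
    stop("value column '", value_column, "' not found")
  }
  node_norm <- normalize_mirna_id(network$nodes)
  m <- match(node_norm, scores$id_norm)
  value <- scores[[value_column]][m]
  measured <- !is.na(value)
  if (!is.null(measured_ids)) {
    measured <- measured & node_norm %in% normalize_mirna_id(measured_ids)
  }
  value[!measured] <- NA_real_
  extra <- sum(!scores$id_norm %in% node_norm)
  if (extra > 0L) {
    message(extra, " score row(s) not present in the network")
  }
  data.frame(
    id = network$nodes,
    value = value,
    color = vapply(value, scale_color, character(1), scale = scale),
    alpha = ifelse(measured, 1, scale$alpha_unmeasured),
    stringsAsFactors = FALSE)
}

#' Write a node-style table as TSV
#'
#' @param styles data.frame from [style_nodes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_styles <- function(styles, path) {
  utils::write.table(styles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
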