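# -- deterministic layout, visual scaling, graph-file export -------------

#' Deterministic circular layout
#'
#' Places the nodes on the unit circle, sorted by category rank (the order
#' given in `category_order`) then alphabetically by name, so that each
#' category occupies a contiguous arc. Placement starts at 90 degrees (top
#' of the circle) and proceeds counter-clockwise with equal angular gaps of
#' `2 * pi / n`.
#'
#' @param network a [connectivity_network()].
#' @param category_order character vector covering every node category, in
#'   the desired arc order.
#' @param start_degrees angle of the first node, degrees; default 90.
#' @param direction `"ccw"` (default) or `"cw"`.
#' @return data frame with columns `name`, `order` (0-based angular index),
#'   `angle` (radians), `x`, `y`.
#' @export
circular_layout <- function(network, category_order,
                            start_degrees = 90, direction = c("ccw", "cw")) {
  direction <- match.arg(direction)
  nodes <- network$nodes
  unknown <- setdiff(unique(nodes$category), category_order)
  if (length(unknown)) {
    stop("category not in category_order: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rank <- match(nodes$category, category_order)
  ord <- order(rank, nodes$name, method = "radix")
  n <- nrow(nodes)
  idx <- seq_len(n) - 1L
  step <- 2 * pi / n
  sign <- if (direction == "ccw") 1 else -1
  angle <- start_degrees * pi / 180 + sign * idx * step
  out <- data.frame(name = nodes$name[ord], order = idx, angle = angle,
                    x = cos(angle), y = sin(angle),
                    stringsAsFactors = FALSE)
  row.names(out) <- NULL
  out
}

# affine min-max scaling with midpoint convention for constant input
affine_scale <- function(v, range) {
  stopifnot(length(range) == 2L, range[1L] > 0, range[1L] < range[2L])
  if (!length(v)) return(numeric())
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(rep(mean(range), length(v)))
  range[1L] + (v - lo) / (hi - lo) * (range[2L] - range[1L])
}

#' Visual attribute scaling
#'
#' Maps weighted degrees to label sizes and edge connectivities to line
#' thicknesses by affine min-max scaling, so that "proportional to" holds as
#' order preservation. When all input values are equal, the midpoint of the
#' target range is used.
#'
#' @param network a [connectivity_network()].
#' @param size_range label-size range `c(min, max)`, `0 < min < max`.
#' @param width_range edge-thickness range, same constraints.
#' @return list with `label_size` (named by node) and `edge_thickness`
#'   (aligned with `network$edges` rows).
#' @export
scale_visuals <- function(network, size_range = c(8, 40),
                          width_range = c(0.5, 10)) {
  list(label_size = stats::setNames(
         affine_scale(network$nodes$weighted_degree, size_range),
         network$nodes$name),
       edge_thickness = affine_scale(network$edges$connectivity, width_range))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

# fixed 15-significant-digit formatting: deterministic (byte-identical
# re-export) while round-tripping doubles well below the 1e-9 contract
fmt_num <- function(x) sprintf("%.15g", x)

NODE_ATTRS <- c(category = "string", keyword_count = "integer",
                weighted_degree = "double", x = "double", y = "double",
                label_size = "double")
EDGE_ATTRS <- c(study_count = "integer", connectivity = "double",
                thickness = "double")

# assemble per-node / per-edge attribute value tables (character)
export_tables <- function(network, layout, visuals) {
  nodes <- network$nodes
  li <- match(nodes$name, layout$name)
  if (anyNA(li)) stop("layout does not cover all nodes", call. = FALSE)
  ls_ <- visuals$label_size[nodes$name]
  if (anyNA(ls_)) stop("visuals do not cover all nodes", call. = FALSE)
  if (length(visuals$edge_thickness) != nrow(network$edges)) {
    stop("visuals do not cover all edges", call. = FALSE)
  }
  list(
    nodes = data.frame(
      name = nodes$name,
      category = nodes$category,
      keyword_count = as.character(nodes$keyword_count),
      weighted_degree = fmt_num(nodes$weighted_degree),
      x = fmt_num(layout$x[li]),
      y = fmt_num(layout$y[li]),
      label_size = fmt_num(unname(ls_)),
      stringsAsFactors = FALSE),
    edges = data.frame(
      from = network$edges$from,
      to = network$edges$to,
      study_count = as.character(network$edges$study_count),
      connectivity = fmt_num(network$edges$connectivity),
      thickness = fmt_num(visuals$edge_thickness),
      stringsAsFactors = FALSE))
}

#' Write a connectivity network to a graph file
#'
#' Emits an undirected graph in GEXF 1.2draft (Gephi-native) or GraphML.
#' Node attributes: `category`, `keyword_count`, `weighted_degree`, `x`,
#' `y`, `label_size`; edge attributes: `study_count`, `connectivity`
#' (also carried as the edge weight) and `thickness`. Attribute order and
#' number formatting (15 significant digits) are fixed, so identical inputs
#' produce byte-identical files.
#'
#' @param network a [connectivity_network()].
#' @param layout a [circular_layout()] covering every node.
#' @param visuals a [scale_visuals()] result covering all nodes and edges.
#' @param path output path.
#' @param format `"gexf"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(network, layout, visuals, path,
                             format = c("gexf", "graphml")) {
  format <- match.arg(format)
  tab <- export_tables(network, layout, visuals)
  lines <- if (format == "gexf") gexf_lines(tab) else graphml_lines(tab)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

gexf_lines <- function(tab) {
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
           '  <graph defaultedgetype="undirected" mode="static">')
  attr_block <- function(class, attrs) {
    c(sprintf('    <attributes class="%s">', class),
      sprintf('      <attribute id="%d" title="%s" type="%s"/>',
              seq_along(attrs) - 1L, names(attrs), unname(attrs)),
      '    </attributes>')
  }
  out <- c(out, attr_block("node", NODE_ATTRS), attr_block("edge", EDGE_ATTRS))
  out <- c(out, '    <nodes>')
  for (i in seq_len(nrow(tab$nodes))) {
    r <- tab$nodes[i, ]
    id <- xml_escape(r$name)
    out <- c(out,
      sprintf('      <node id="%s" label="%s">', id, id),
      '        <attvalues>',
      sprintf('          <attvalue for="%d" value="%s"/>',
              seq_along(NODE_ATTRS) - 1L,
              xml_escape(unlist(r[names(NODE_ATTRS)], use.names = FALSE))),
      '        </attvalues>',
      '      </node>')
  }
  out <- c(out, '    </nodes>', '    <edges>')
  for (i in seq_len(nrow(tab$edges))) {
    r <- tab$edges[i, ]
    out <- c(out,
      sprintf('      <edge id="%d" source="%s" target="%s" weight="%s">',
              i - 1L, xml_escape(r$from), xml_escape(r$to), r$connectivity),
      '        <attvalues>',
      sprintf('          <attvalue for="%d" value="%s"/>',
              seq_along(EDGE_ATTRS) - 1L,
              xml_escape(unlist(r[names(EDGE_ATTRS)], use.names = FALSE))),
      '        </attvalues>',
      '      </edge>')
  }
  c(out, '    </edges>', '  </graph>', '</gexf>')
}

graphml_lines <- function(tab) {
  keys <- c(
    sprintf('  <key id="n_%s" for="node" attr.name="%s" attr.type="%s"/>',
            names(NODE_ATTRS), names(NODE_ATTRS),
            ifelse(NODE_ATTRS == "integer", "int",
                   ifelse(NODE_ATTRS == "double", "double", "string"))),
    sprintf('  <key id="e_%s" for="edge" attr.name="%s" attr.type="%s"/>',
            names(EDGE_ATTRS), names(EDGE_ATTRS),
            ifelse(EDGE_ATTRS == "integer", "int",
                   ifelse(EDGE_ATTRS == "double", "double", "string"))),
    '  <key id="e_weight" for="edge" attr.name="weight" attr.type="double"/>')
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
           keys,
           '  <graph id="G" edgedefault="undirected">')
  for (i in seq_len(nrow(tab$nodes))) {
    r <- tab$nodes[i, ]
    out <- c(out,
      sprintf('    <node id="%s">', xml_escape(r$name)),
      sprintf('      <data key="n_%s">%s</data>', names(NODE_ATTRS),
              xml_escape(unlist(r[names(NODE_ATTRS)], use.names = FALSE))),
      '    </node>')
  }
  for (i in seq_len(nrow(tab$edges))) {
    r <- tab$edges[i, ]
    out <- c(out,
      sprintf('    <edge source="%s" target="%s">', xml_escape(r$from),
              xml_escape(r$to)),
      sprintf('      <data key="e_%s">%s</data>', names(EDGE_ATTRS),
              xml_escape(unlist(r[names(EDGE_ATTRS)], use.names = FALSE))),
      sprintf('      <data key="e_weight">%s</data>', r$connectivity),
      '    </edge>')
  }
  c(out, '  </graph>', '</graphml>')
}

#' Re-parse a graph file written by [write_graph_file()]
#'
#' Reads either format back into plain data frames for verification and
#' round-trip testing.
#'
#' @param path path of a `.gexf` or `.graphml` file.
#' @param format `"auto"` (from extension), `"gexf"` or `"graphml"`.
#' @return list with `nodes` and `edges` data frames carrying the exported
#'   attributes as numeric/character columns.
#' @export
read_graph_file <- function(path, format = c("auto", "gexf", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path)) "graphml" else "gexf"
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  conv <- function(df, types) {
    for (nm in names(types)) {
      df[[nm]] <- if (types[[nm]] == "string") df[[nm]] else as.numeric(df[[nm]])
    }
    df
  }
  if (format == "gexf") {
    nseq <- xml2::xml_find_all(doc, ".//nodes/node")
    nodes <- data.frame(name = xml2::xml_attr(nseq, "id"),
                        stringsAsFactors = FALSE)
    for (j in seq_along(NODE_ATTRS)) {
      vals <- vapply(nseq, function(nd) {
        xml2::xml_attr(xml2::xml_find_first(
          nd, sprintf("./attvalues/attvalue[@for='%d']", j - 1L)), "value")
      }, "")
      nodes[[names(NODE_ATTRS)[j]]] <- vals
    }
    eseq <- xml2::xml_find_all(doc, ".//edges/edge")
    edges <- data.frame(from = xml2::xml_attr(eseq, "source"),
                        to = xml2::xml_attr(eseq, "target"),
                        weight = as.numeric(xml2::xml_attr(eseq, "weight")),
                        stringsAsFactors = FALSE)
    for (j in seq_along(EDGE_ATTRS)) {
      vals <- vapply(eseq, function(ed) {
        xml2::xml_attr(xml2::xml_find_first(
          ed, sprintf("./attvalues/attvalue[@for='%d']", j - 1L)), "value")
      }, "")
      edges[[names(EDGE_ATTRS)[j]]] <- vals
    }
  } else {
    nseq <- xml2::xml_find_all(doc, ".//graph/node")
    nodes <- data.frame(name = xml2::xml_attr(nseq, "id"),
                        stringsAsFactors = FALSE)
    for (nm in names(NODE_ATTRS)) {
      nodes[[nm]] <- vapply(nseq, function(nd) {
        xml2::xml_text(xml2::xml_find_first(
          nd, sprintf("./data[@key='n_%s']", nm)))
      }, "")
    }
    eseq <- xml2::xml_find_all(doc, ".//graph/edge")
    edges <- data.frame(from = xml2::xml_attr(eseq, "source"),
                        to = xml2::xml_attr(eseq, "target"),
                        stringsAsFactors = FALSE)
    for (nm in names(EDGE_ATTRS)) {
      edges[[nm]] <- vapply(eseq, function(ed) {
        xml2::xml_text(xml2::xml_find_first(
          ed, sprintf("./data[@key='e_%s']", nm)))
      }, "")
    }
    edges$weight <- as.numeric(vapply(eseq, function(ed) {
      xml2::xml_text(xml2::xml_find_first(ed, "./data[@key='e_weight']"))
    }, ""))
  }
  nodes <- conv(nodes, as.list(NODE_ATTRS))
  edges <- conv(edges, as.list(EDGE_ATTRS))
  list(nodes = nodes, edges = edges)
}
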