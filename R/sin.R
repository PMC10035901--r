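#' Build a social interaction network
#'
#' Constructs the weighted undirected social interaction network (SIN) for
#' one group: every fly in the roster is a node (flies that never interact
#' stay as isolated, degree-zero nodes), and each interacting pair carries
#' exactly one edge with two weights — `w_count`, the number of interaction
#' events, and `w_duration`, their total duration in seconds.
#'
#' @param events An `interaction_events` data.frame from [detect_events()].
#' @param roster Character vector of all fly ids in the group. Defaults to
#'   the ids appearing in `events`, but passing the full roster is what
#'   preserves isolated flies.
#' @param label Free-form group identifier stored on the graph.
#' @param condition Population label (e.g. `"CTRL"`, `"COC"`).
#' @param fps Frame rate to record on the graph; taken from the events
#'   attribute when available.
#' @return An object of class `sin` wrapping an igraph graph.
#' @examples
#' ev <- data.frame(fly_a = c("A", "A", "A"), fly_b = c("B", "B", "C"),
#'                  start_frame = c(0L, 50L, 0L), end_frame = c(24L, 98L, 14L),
#'                  duration_s = c(1, 2, 0.6))
#' attr(ev, "fps") <- 24
#' s <- build_sin(ev, roster = c("A", "B", "C", "D"))
#' sin_edges(s)
#' @export
build_sin <- function(events, roster = NULL, label = "", condition = "",
                      fps = attr(events, "fps")) {
  ev <- as.data.frame(events)
  if (is.null(roster)) roster <- sort(unique(c(ev$fly_a, ev$fly_b)))
  roster <- sort(unique(as.character(roster)))
  if (nrow(ev)) {
    bad <- setdiff(unique(c(ev$fly_a, ev$fly_b)), roster)
    if (length(bad))
      stop("event fly id(s) not in roster: ", paste(bad, collapse = ", "),
           call. = FALSE)
    # canonical unordered pair
    swap <- ev$fly_a > ev$fly_b
    tmp <- ev$fly_a[swap]; ev$fly_a[swap] <- ev$fly_b[swap]; ev$fly_b[swap] <- tmp
    agg <- stats::aggregate(
      cbind(w_count = rep(1L, nrow(ev)), w_duration = ev$duration_s),
      by = list(fly_a = ev$fly_a, fly_b = ev$fly_b), FUN = sum)
    g <- igraph::graph_from_data_frame(agg, directed = FALSE,
                                       vertices = data.frame(name = roster))
  } else {
    g <- igraph::make_empty_graph(n = length(roster), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = roster)
  }
  g <- igraph::set_graph_attr(g, "label", as.character(label))
  g <- igraph::set_graph_attr(g, "condition", as.character(condition))
  g <- igraph::set_graph_attr(g, "fps",
                              if (is.null(fps) || is.na(fps)) NA_real_ else fps)
  new_sin(g)
}

new_sin <- function(g) structure(list(graph = g), class = "sin")

#' @export
print.sin <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<sin> %s%s%d nodes, %d edges\n",
              igraph::graph_attr(g, "label"),
              if (nzchar(igraph::graph_attr(g, "label"))) ": " else "",
              igraph::vcount(g), igraph::ecount(g)))
  invisible(x)
}

#' Accessors for SIN nodes and edges
#'
#' @param sin A `sin` object.
#' @return `sin_nodes()`: character vector of fly ids. `sin_edges()`: a
#'   data.frame `fly_a,fly_b,w_count,w_duration` with `fly_a < fly_b`.
#' @export
sin_nodes <- function(sin) igraph::V(sin$graph)$name

#' @rdname sin_nodes
#' @export
sin_edges <- function(sin) {
  g <- sin$graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(fly_a = character(), fly_b = character(),
                      w_count = integer(), w_duration = numeric(),
                      stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  out <- data.frame(
    fly_a = pmin(el[, 1], el[, 2]), fly_b = pmax(el[, 1], el[, 2]),
    w_count = as.integer(igraph::E(g)$w_count),
    w_duration = igraph::E(g)$w_duration, stringsAsFactors = FALSE)
  out <- out[order(out$fly_a, out$fly_b), ]
  rownames(out) <- NULL
  out
}

# numeric edge weight vector for a weight kind, or NULL for unweighted
sin_weight <- function(sin, weight = c("none", "count", "duration")) {
  weight <- match.arg(weight)
  switch(weight,
         none = NULL,
         count = as.numeric(igraph::E(sin$graph)$w_count),
         duration = igraph::E(sin$graph)$w_duration)
}

#' Export / import a SIN
#'
#' Writes the network with both edge weights and its graph-level metadata
#' (label, condition, fps) in a Gephi-compatible format; `import_graph()`
#' reads it back so that `import_graph(export_graph(s, p, f), f)` equals
#' `s`.
#'
#' @param sin A `sin` object.
#' @param path Output file.
#' @param format One of `"graphml"`, `"gexf"`, `"edgelist-csv"`.
#' @return `path` invisibly for the writer; a `sin` for the reader.
#' @export
export_graph <- function(sin, path, format = c("graphml", "gexf", "edgelist-csv")) {
  format <- match.arg(format)
  g <- sin$graph
  switch(format,
    graphml = igraph::write_graph(g, path, format = "graphml"),
    gexf = write_gexf(sin, path),
    `edgelist-csv` = {
      con <- file(path, "w")
      on.exit(close(con))
      meta <- sprintf("# label=%s condition=%s fps=%s nodes=%s",
                      igraph::graph_attr(g, "label"),
                      igraph::graph_attr(g, "condition"),
                      igraph::graph_attr(g, "fps"),
                      paste(sin_nodes(sin), collapse = ";"))
      writeLines(meta, con)
      utils::write.csv(sin_edges(sin), con, row.names = FALSE, quote = FALSE)
    })
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "gexf", "edgelist-csv")) {
  format <- match.arg(format)
  sin <- switch(format,
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      if (!is.null(igraph::vertex_attr(g, "id")) &&
          is.null(igraph::vertex_attr(g, "name")))
        igraph::V(g)$name <- igraph::V(g)$id
      new_sin(g)
    },
    gexf = read_gexf(path),
    `edgelist-csv` = {
      first <- readLines(path, n = 1L)
      m <- regmatches(first,
        regexec("^# label=(.*) condition=(.*) fps=(\\S*) nodes=(\\S*)$", first))[[1]]
      if (length(m) != 5L)
        stop("edgelist CSV is missing its metadata header", call. = FALSE)
      edges <- utils::read.csv(path, comment.char = "#",
                               stringsAsFactors = FALSE)
      roster <- strsplit(m[5], ";", fixed = TRUE)[[1]]
      ev <- data.frame(fly_a = as.character(edges$fly_a),
                       fly_b = as.character(edges$fly_b))
      g <- if (nrow(ev)) {
        igraph::graph_from_data_frame(
          cbind(ev, w_count = as.integer(edges$w_count),
                w_duration = edges$w_duration),
          directed = FALSE, vertices = data.frame(name = roster))
      } else {
        gg <- igraph::make_empty_graph(length(roster), directed = FALSE)
        igraph::set_vertex_attr(gg, "name", value = roster)
      }
      g <- igraph::set_graph_attr(g, "label", m[2])
      g <- igraph::set_graph_attr(g, "condition", m[3])
      g <- igraph::set_graph_attr(g, "fps", as.numeric(m[4]))
      new_sin(g)
    })
  check_sin_weights(sin, path)
  sin
}

check_sin_weights <- function(sin, path) {
  g <- sin$graph
  if (igraph::ecount(g) > 0L) {
    for (w in c("w_count", "w_duration"))
      if (!w %in% igraph::edge_attr_names(g))
        stop("graph file ", path, " is missing edge weight attribute `",
             w, "`", call. = FALSE)
  }
  invisible(sin)
}

# Minimal GEXF 1.3 writer/reader (igraph has no GEXF support). Covers what
# a SIN needs: node ids/labels, two float edge attributes, graph metadata.
write_gexf <- function(sin, path, node_class = NULL) {
  g <- sin$graph
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  nodes <- sin_nodes(sin)
  edges <- sin_edges(sin)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://gexf.net/1.3" version="1.3">',
    sprintf('  <meta><creator>flysin</creator><description>label=%s condition=%s fps=%s</description></meta>',
            esc(igraph::graph_attr(g, "label")),
            esc(igraph::graph_attr(g, "condition")),
            igraph::graph_attr(g, "fps")),
    '  <graph defaultedgetype="undirected">',
    '    <attributes class="edge">',
    '      <attribute id="0" title="w_count" type="integer"/>',
    '      <attribute id="1" title="w_duration" type="double"/>',
    '    </attributes>')
  if (!is.null(node_class)) {
    lines <- c(lines,
      '    <attributes class="node">',
      '      <attribute id="n0" title="community" type="integer"/>',
      '    </attributes>')
  }
  lines <- c(lines, '    <nodes>')
  for (i in seq_along(nodes)) {
    if (is.null(node_class)) {
      lines <- c(lines, sprintf('      <node id="%s" label="%s"/>',
                                esc(nodes[i]), esc(nodes[i])))
    } else {
      lines <- c(lines, sprintf(
        '      <node id="%s" label="%s"><attvalues><attvalue for="n0" value="%d"/></attvalues></node>',
        esc(nodes[i]), esc(nodes[i]), node_class[[nodes[i]]]))
    }
  }
  lines <- c(lines, '    </nodes>', '    <edges>')
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    lines <- c(lines, sprintf(
      '      <edge id="%d" source="%s" target="%s" weight="%s"><attvalues><attvalue for="0" value="%d"/><attvalue for="1" value="%s"/></attvalues></edge>',
      i - 1L, esc(edges$fly_a[i]), esc(edges$fly_b[i]),
      format(edges$w_duration[i], digits = 15),
      edges$w_count[i], format(edges$w_duration[i], digits = 15)))
  }
  lines <- c(lines, '    </edges>', '  </graph>', '</gexf>')
  writeLines(lines, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = xml2::xml_ns(doc)[[1]])
  desc <- xml2::xml_text(xml2::xml_find_first(doc, ".//g:meta/g:description", ns))
  m <- regmatches(desc, regexec("label=(.*) condition=(.*) fps=(\\S*)", desc))[[1]]
  node_el <- xml2::xml_find_all(doc, ".//g:nodes/g:node", ns)
  roster <- xml2::xml_attr(node_el, "id")
  edge_el <- xml2::xml_find_all(doc, ".//g:edges/g:edge", ns)
  get_att <- function(e, id) {
    v <- xml2::xml_attr(
      xml2::xml_find_first(e, sprintf(".//g:attvalue[@for='%s']", id), ns),
      "value")
    v
  }
  if (length(edge_el)) {
    edges <- data.frame(
      fly_a = xml2::xml_attr(edge_el, "source"),
      fly_b = xml2::xml_attr(edge_el, "target"),
      w_count = as.integer(vapply(edge_el, get_att, "", id = "0")),
      w_duration = as.numeric(vapply(edge_el, get_att, "", id = "1")),
      stringsAsFactors = FALSE)
    if (anyNA(edges$w_count) || anyNA(edges$w_duration))
      stop("GEXF file ", path,
           " is missing edge weight attribute `w_count` or `w_duration`",
           call. = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = roster))
  } else {
    g <- igraph::make_empty_graph(length(roster), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = roster)
  }
  if (length(m) == 4L) {
    g <- igraph::set_graph_attr(g, "label", m[2])
    g <- igraph::set_graph_attr(g, "condition", m[3])
    g <- igraph::set_graph_attr(g, "fps", as.numeric(m[4]))
  }
  new_sin(g)
}
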