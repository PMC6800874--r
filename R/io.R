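#' Read a graph from an LGF edge-list file
#'
#' The LGF dialect stores one graph per UTF-8 file.  Lines are either
#' comments (starting `#`), blank, vertex declarations `V <id>` (unlabelled)
#' or `V <id> <label>`, or edge lines `E <id1> <id2>` (repeat a line for
#' parallel edges; `id1 == id2` declares a loop).  Identifiers are
#' whitespace-free strings.  Edges may only reference previously declared
#' vertices.
#'
#' @param path file to read.
#' @return An `lmg`.
#' @export
read_lgf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  vertices <- character()
  labels <- character()
  edges <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    raw <- trimws(raw)
    if (raw == "") next
    tok <- strsplit(raw, "[[:space:]]+")[[1]]
    if (tok[1] == "V" && length(tok) %in% c(2, 3)) {
      if (tok[2] %in% vertices) {
        stop(sprintf("line %d: duplicate vertex id '%s'", ln, tok[2]))
      }
      vertices <- c(vertices, tok[2])
      if (length(tok) == 3) labels[tok[2]] <- tok[3]
    } else if (tok[1] == "E" && length(tok) == 3) {
      undecl <- setdiff(tok[2:3], vertices)
      if (length(undecl)) {
        stop(sprintf("line %d: edge references undeclared vertex '%s'",
                     ln, undecl[1]))
      }
      edges[[length(edges) + 1]] <- tok[2:3]
    } else {
      stop(sprintf("line %d: malformed line '%s'", ln, lines[ln]))
    }
  }
  lmg(vertices, labels = labels,
      edges = if (length(edges)) do.call(rbind, edges) else NULL)
}

#' Write a graph to an LGF edge-list file
#'
#' Vertices are emitted sorted by id and edges sorted lexicographically,
#' with parallel edges as repeated lines, so write -> read -> write
#' round-trips byte-identically.
#'
#' @param g an `lmg`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_lgf <- function(g, path) {
  out <- "# LGF labelled multigraph"
  for (v in sort(g$vertices)) {
    out <- c(out, if (v %in% names(g$labels)) {
      paste("V", v, g$labels[[v]])
    } else {
      paste("V", v)
    })
  }
  if (length(g$edges)) {
    ep <- edge_endpoints(names(g$edges))
    lines <- paste("E", ep[, 1], ep[, 2])
    lines <- rep(lines, unname(g$edges))
    out <- c(out, sort(lines))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Export a graph to GraphML
#'
#' Labelled vertices carry the vertex attribute `"label"`; parallel edges
#' are written as separate edge elements and loops with identical source
#' and target.
#'
#' @param g an `lmg`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  key <- xml2::xml_add_child(doc, "key")
  xml2::xml_set_attrs(key, c(id = "d0", `for` = "node",
                             attr.name = "label", attr.type = "string"))
  gr <- xml2::xml_add_child(doc, "graph")
  xml2::xml_set_attrs(gr, c(id = "G", edgedefault = "undirected"))
  for (v in sort(g$vertices)) {
    nd <- xml2::xml_add_child(gr, "node")
    xml2::xml_set_attr(nd, "id", v)
    if (v %in% names(g$labels)) {
      dat <- xml2::xml_add_child(nd, "data", g$labels[[v]])
      xml2::xml_set_attr(dat, "key", "d0")
    }
  }
  if (length(g$edges)) {
    ep <- edge_endpoints(names(g$edges))
    for (k in seq_len(nrow(ep))) {
      for (rep_i in seq_len(g$edges[[k]])) {
        ed <- xml2::xml_add_child(gr, "edge")
        xml2::xml_set_attrs(ed, c(source = unname(ep[k, 1]),
                                  target = unname(ep[k, 2])))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
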