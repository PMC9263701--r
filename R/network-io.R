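#' Export a co-occurrence network for external tools
#'
#' Writes a correlation network (an igraph object as produced by
#' [build_network()]) in a Gephi-compatible format. Node attributes
#' `family`, `phylum` and `abundance` and edge attributes `rho`, `p_adj`
#' and `sign` are preserved. Numeric attributes are printed with full
#' double precision so that a write/read round trip is lossless.
#'
#' @param network an igraph graph.
#' @param path output file path.
#' @param format `"graphml"`, `"gexf"` or `"edgelist"` (TSV).
#' @return `path`, invisibly. An empty network yields a valid file with
#'   zero edges.
#' @export
write_network <- function(network, path,
                          format = c("graphml", "gexf", "edgelist")) {
  format <- match.arg(format)
  switch(format,
         graphml = write_graphml(network, path),
         gexf = write_gexf(network, path),
         edgelist = write_edgelist_tsv(network, path))
  invisible(path)
}

node_attr_frame <- function(g) {
  df <- igraph::as_data_frame(g, what = "vertices")
  if (!nrow(df) && !ncol(df)) df <- data.frame(name = character(0))
  if (is.null(df$name)) df$name <- as.character(seq_len(igraph::vcount(g)))
  df
}

fmt_attr <- function(v) {
  if (is.double(v)) vapply(v, format, character(1L), digits = 17L)
  else as.character(v)
}

graphml_type <- function(v) {
  if (is.double(v)) "double" else if (is.integer(v)) "int"
  else if (is.logical(v)) "boolean" else "string"
}

write_graphml <- function(g, path) {
  nodes <- node_attr_frame(g)
  edges <- igraph::as_data_frame(g, what = "edges")
  nattr <- setdiff(names(nodes), "name")
  eattr <- setdiff(names(edges), c("from", "to"))
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (a in nattr) {
    xml2::xml_add_child(doc, "key", id = paste0("n_", a), "for" = "node",
                        attr.name = a, attr.type = graphml_type(nodes[[a]]))
  }
  for (a in eattr) {
    xml2::xml_add_child(doc, "key", id = paste0("e_", a), "for" = "edge",
                        attr.name = a, attr.type = graphml_type(edges[[a]]))
  }
  gr <- xml2::xml_add_child(doc, "graph", id = "G",
                            edgedefault = "undirected")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(gr, "node", id = nodes$name[i])
    for (a in nattr) {
      xml2::xml_add_child(nd, "data", key = paste0("n_", a),
                          fmt_attr(nodes[[a]][i]))
    }
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(gr, "edge", source = edges$from[i],
                              target = edges$to[i])
    for (a in eattr) {
      xml2::xml_add_child(ed, "data", key = paste0("e_", a),
                          fmt_attr(edges[[a]][i]))
    }
  }
  xml2::write_xml(doc, path)
}

#' Read a network written by [write_network()] in GraphML format
#' @param path GraphML file path.
#' @return an igraph graph with attributes restored to their declared
#'   types.
#' @export
read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, "./key")
  kinfo <- data.frame(
    id = xml2::xml_attr(keys, "id"),
    domain = xml2::xml_attr(keys, "for"),
    name = xml2::xml_attr(keys, "attr.name"),
    type = xml2::xml_attr(keys, "attr.type"),
    stringsAsFactors = FALSE)
  cast <- function(v, type) {
    switch(type, double = as.double(v), int = as.integer(v),
           boolean = as.logical(v), v)
  }
  nd <- xml2::xml_find_all(doc, "./graph/node")
  nodes <- data.frame(name = xml2::xml_attr(nd, "id"),
                      stringsAsFactors = FALSE)
  for (i in which(kinfo$domain == "node")) {
    vals <- vapply(nd, function(n) {
      d <- xml2::xml_find_first(n, sprintf("./data[@key='%s']",
                                           kinfo$id[i]))
      if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
    }, character(1L))
    nodes[[kinfo$name[i]]] <- cast(vals, kinfo$type[i])
  }
  ed <- xml2::xml_find_all(doc, "./graph/edge")
  edges <- data.frame(from = xml2::xml_attr(ed, "source"),
                      to = xml2::xml_attr(ed, "target"),
                      stringsAsFactors = FALSE)
  for (i in which(kinfo$domain == "edge")) {
    vals <- vapply(ed, function(e) {
      d <- xml2::xml_find_first(e, sprintf("./data[@key='%s']",
                                           kinfo$id[i]))
      if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
    }, character(1L))
    edges[[kinfo$name[i]]] <- cast(vals, kinfo$type[i])
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

write_gexf <- function(g, path) {
  nodes <- node_attr_frame(g)
  edges <- igraph::as_data_frame(g, what = "edges")
  nattr <- setdiff(names(nodes), "name")
  eattr <- setdiff(names(edges), c("from", "to"))
  gexf_type <- function(v) {
    if (is.double(v)) "double" else if (is.integer(v)) "integer"
    else if (is.logical(v)) "boolean" else "string"
  }
  doc <- xml2::xml_new_root("gexf", xmlns = "http://gexf.net/1.3",
                            version = "1.3")
  gr <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  add_decl <- function(class, attrs, df) {
    if (!length(attrs)) return(NULL)
    decl <- xml2::xml_add_child(gr, "attributes", class = class)
    for (i in seq_along(attrs)) {
      xml2::xml_add_child(decl, "attribute", id = as.character(i - 1L),
                          title = attrs[i], type = gexf_type(df[[attrs[i]]]))
    }
  }
  add_decl("node", nattr, nodes)
  add_decl("edge", eattr, edges)
  nds <- xml2::xml_add_child(gr, "nodes")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(nds, "node", id = nodes$name[i],
                              label = nodes$name[i])
    if (length(nattr)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (j in seq_along(nattr)) {
        xml2::xml_add_child(av, "attvalue", "for" = as.character(j - 1L),
                            value = fmt_attr(nodes[[nattr[j]]][i]))
      }
    }
  }
  eds <- xml2::xml_add_child(gr, "edges")
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(eds, "edge", id = as.character(i - 1L),
                              source = edges$from[i], target = edges$to[i])
    if (length(eattr)) {
      av <- xml2::xml_add_child(ed, "attvalues")
      for (j in seq_along(eattr)) {
        xml2::xml_add_child(av, "attvalue", "for" = as.character(j - 1L),
                            value = fmt_attr(edges[[eattr[j]]][i]))
      }
    }
  }
  xml2::write_xml(doc, path)
}

write_edgelist_tsv <- function(g, path) {
  edges <- igraph::as_data_frame(g, what = "edges")
  if (!nrow(edges)) {
    edges <- data.frame(from = character(0), to = character(0))
  }
  num <- vapply(edges, is.double, logical(1L))
  edges[num] <- lapply(edges[num], function(v)
    vapply(v, format, character(1L), digits = 17L))
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
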