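# Network export for visualization tools (Gephi reads both formats).
# GraphML goes through igraph's writer; GEXF is written and read directly
# as XML since no installed package handles it.

#' Write a disease network to GraphML
#'
#' Node attributes: `label`, `prevalence` (node size in visualization tools
#' is conventionally mapped to prevalence); edge attributes: `rho`,
#' `p_value`, `weight` (edge width maps to the correlation).
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  if (nrow(net$nodes)) {
    g <- igraph::set_vertex_attr(g, "label", value = net$nodes$disease)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML disease network back
#'
#' @param path A file written by [write_network_graphml()].
#' @return A `disease_network` with the same nodes, edges and attributes.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(disease = igraph::V(g)$name,
                      prevalence = igraph::V(g)$prevalence,
                      stringsAsFactors = FALSE)
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(from = ed$from, to = ed$to,
                      rho = if (nrow(ed)) ed$rho else numeric(),
                      p_value = if (nrow(ed)) ed$p_value else numeric(),
                      weight = if (nrow(ed)) ed$weight else numeric(),
                      stringsAsFactors = FALSE)
  structure(list(sex = igraph::graph_attr(g, "sex"),
                 age_band = igraph::graph_attr(g, "age_band"),
                 n_patients = as.integer(igraph::graph_attr(g, "n_patients")),
                 nodes = nodes, edges = edges,
                 alpha = NA_real_,
                 skipped = data.frame(from = character(), to = character(),
                                      reason = character())),
            class = "disease_network")
}

#' Write a disease network to GEXF
#'
#' Same attribute scheme as [write_network_graphml()]: node `prevalence`,
#' edge `rho` and `p_value`, edge `weight` on the GEXF edge element itself.
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_gexf <- function(net, path) {
  stopifnot(inherits(net, "disease_network"))
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                               mode = "static")
  xml2::xml_set_attr(graph, "sex", net$sex)
  xml2::xml_set_attr(graph, "age_band", net$age_band)
  xml2::xml_set_attr(graph, "n_patients", as.character(net$n_patients))

  nattrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(nattrs, "attribute", id = "prevalence",
                      title = "prevalence", type = "double")
  eattrs <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattrs, "attribute", id = "rho", title = "rho",
                      type = "double")
  xml2::xml_add_child(eattrs, "attribute", id = "p_value", title = "p_value",
                      type = "double")

  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node", id = net$nodes$disease[i],
                              label = net$nodes$disease[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "prevalence",
                        value = format(net$nodes$prevalence[i], digits = 17))
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                              source = net$edges$from[i],
                              target = net$edges$to[i],
                              weight = format(net$edges$weight[i], digits = 17))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "rho",
                        value = format(net$edges$rho[i], digits = 17))
    xml2::xml_add_child(av, "attvalue", `for` = "p_value",
                        value = format(net$edges$p_value[i], digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GEXF disease network back
#'
#' @param path A file written by [write_network_gexf()].
#' @return A `disease_network` with the same nodes, edges and attributes.
#' @export
read_network_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)

  node_els <- xml2::xml_find_all(doc, ".//g:nodes/g:node", ns)
  att <- function(el, name) {
    v <- xml2::xml_find_first(el, sprintf(".//g:attvalue[@for='%s']", name), ns)
    as.numeric(xml2::xml_attr(v, "value"))
  }
  nodes <- data.frame(
    disease = xml2::xml_attr(node_els, "id"),
    prevalence = vapply(node_els, att, numeric(1), name = "prevalence"),
    stringsAsFactors = FALSE)

  edge_els <- xml2::xml_find_all(doc, ".//g:edges/g:edge", ns)
  edges <- data.frame(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    rho = vapply(edge_els, att, numeric(1), name = "rho"),
    p_value = vapply(edge_els, att, numeric(1), name = "p_value"),
    weight = as.numeric(xml2::xml_attr(edge_els, "weight")),
    stringsAsFactors = FALSE)

  structure(list(sex = xml2::xml_attr(graph, "sex"),
                 age_band = xml2::xml_attr(graph, "age_band"),
                 n_patients = as.integer(xml2::xml_attr(graph, "n_patients")),
                 nodes = nodes, edges = edges, alpha = NA_real_,
                 skipped = data.frame(from = character(), to = character(),
                                      reason = character())),
            class = "disease_network")
}

#' Write the adjacency matrix of a network as CSV
#'
#' Square matrix of signed tetrachoric correlations (0 where no edge),
#' diseases in rows and columns, for spreadsheet inspection.
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(net, path) {
  stopifnot(inherits(net, "disease_network"))
  d <- net$nodes$disease
  A <- matrix(0, length(d), length(d), dimnames = list(d, d))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, d)
    j <- match(net$edges$to, d)
    A[cbind(i, j)] <- net$edges$rho
    A[cbind(j, i)] <- net$edges$rho
  }
  utils::write.csv(A, path)
  invisible(path)
}
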