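#' Export a clustering as a Gephi-loadable GEXF graph
#'
#' Writes a GEXF 1.2 XML file in which each individual is a node annotated
#' with its predicted cluster (and, when a panel is supplied, its annotated
#' population label), connected to one hub node per cluster. Edge weights
#' are `1 / (1 + d)` where `d` is the sample's Euclidean distance to its
#' cluster centroid, so tighter cluster members pull closer to the hub
#' under force-directed layouts. Node ordering is deterministic (samples in
#' matrix order, hubs last) and no timestamps are written, so identical
#' inputs yield byte-identical files.
#'
#' @param model a fitted `popclust_km` model.
#' @param gm the [genotype_matrix] the model was fitted on.
#' @param truth optional named character vector mapping sample ID to
#'   population label; when given, a `true_label` node attribute is
#'   declared, otherwise it is omitted from the schema.
#' @param dest output path.
#' @return list with `n_nodes` (`n_samples + k`) and `n_edges`
#'   (`n_samples`), invisibly.
#' @export
export_gexf <- function(model, gm, truth = NULL, dest) {
  stopifnot(inherits(model, "popclust_km"), inherits(gm, "genotype_matrix"))
  n <- length(gm$sample_ids)
  if (length(model$assignments) != n) {
    stop_param("model was fitted on ", length(model$assignments),
               " samples but the matrix has ", n)
  }
  X <- gm$dosage
  d2 <- sq_dist_to_centroids(X, Matrix::rowSums(X^2), model$centroids)
  dist_to_own <- sqrt(d2[cbind(seq_len(n), model$assignments)])
  weights <- 1 / (1 + dist_to_own)
  labels <- if (!is.null(truth)) truth_for_samples(truth, gm$sample_ids)

  doc <- xml2::xml_new_root(
    "gexf",
    xmlns = "http://www.gexf.net/1.2draft",
    version = "1.2"
  )
  meta <- xml2::xml_add_child(doc, "meta")
  xml2::xml_add_child(meta, "creator", "popclust")
  xml2::xml_add_child(meta, "description",
                      paste0("k-means genotype clustering, k=", model$k,
                             ", seed=", model$seed))
  graph <- xml2::xml_add_child(doc, "graph", mode = "static",
                               defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "cluster", title = "cluster",
                      type = "integer")
  if (!is.null(truth)) {
    xml2::xml_add_child(attrs, "attribute", id = "true_label",
                        title = "true_label", type = "string")
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(n)) {
    node <- xml2::xml_add_child(nodes, "node", id = gm$sample_ids[i],
                                label = gm$sample_ids[i])
    av <- xml2::xml_add_child(node, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "cluster",
                        value = as.character(model$assignments[i] - 1L))
    if (!is.null(truth)) {
      xml2::xml_add_child(av, "attvalue", `for` = "true_label",
                          value = labels[i])
    }
  }
  for (c in seq_len(model$k)) {
    hub_id <- paste0("cluster_", c - 1L)
    node <- xml2::xml_add_child(nodes, "node", id = hub_id, label = hub_id)
    av <- xml2::xml_add_child(node, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "cluster",
                        value = as.character(c - 1L))
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(n)) {
    xml2::xml_add_child(edges, "edge",
                        id = paste0("e", i - 1L),
                        source = gm$sample_ids[i],
                        target = paste0("cluster_", model$assignments[i] - 1L),
                        weight = format(weights[i], digits = 15L,
                                        scientific = FALSE, trim = TRUE))
  }
  status <- tryCatch(xml2::write_xml(doc, dest),
                     error = function(e) stop_io("cannot write ", dest),
                     warning = function(w) stop_io("cannot write ", dest))
  invisible(list(n_nodes = n + model$k, n_edges = n))
}
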