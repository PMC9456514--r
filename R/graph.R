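#' Build the crosslink interaction graph
#'
#' Collapses crosslink records into an undirected weighted graph: nodes are
#' alias-resolved proteins (ambiguity groups such as shared-peptide paralog
#' pairs stay single nodes), edges carry the supporting records and the
#' maximum score. Clusters are the connected components, optionally after
#' restricting nodes to registry members (core subunits, PAPs and
#' candidates); components are ordered by size, ties by first node name.
#' Self links (both sites on one node) are excluded from cluster statistics
#' by default.
#'
#' @param records An `xlms_records` data.frame.
#' @param registry A `pep_registry` for alias resolution and membership.
#' @param restrict_to_members Drop nodes that are not registry members before
#'   computing clusters.
#' @param include_self_links Keep self links as graph loops (default FALSE).
#' @return Object of class `xlms_graph`: list with `nodes` (data.frame:
#'   `label`, `member`, `role`), `edges` (data.frame: `node_a`, `node_b`,
#'   `n_records`, `max_score`, `rows`), `clusters` (list of sorted node-label
#'   vectors), `restricted`.
#' @export
build_graph <- function(records, registry, restrict_to_members = FALSE,
                        include_self_links = FALSE) {
  if (nrow(records) == 0L)
    return(structure(list(nodes = data.frame(label = character(0),
                                             member = logical(0),
                                             role = character(0)),
                          edges = data.frame(node_a = character(0),
                                             node_b = character(0),
                                             n_records = integer(0),
                                             max_score = numeric(0),
                                             rows = character(0)),
                          clusters = list(),
                          restricted = restrict_to_members),
                     class = "xlms_graph"))
  r1 <- resolve_proteins(records$protein_1, registry)
  r2 <- resolve_proteins(records$protein_2, registry)
  self <- r1$label == r2$label
  use <- if (include_self_links) rep(TRUE, nrow(records)) else !self
  if (!any(use)) return(build_graph(records[0, ], registry, restrict_to_members))
  nodes <- unique(rbind(r1[use, c("label", "member", "role")],
                        r2[use, c("label", "member", "role")]))
  nodes <- nodes[order(nodes$label), , drop = FALSE]
  rownames(nodes) <- NULL
  a <- pmin(r1$label[use], r2$label[use])
  b <- pmax(r1$label[use], r2$label[use])
  ekey <- paste(a, b, sep = "|")
  idx <- split(which(use), ekey)
  edges <- do.call(rbind, lapply(names(idx), function(k) {
    ii <- idx[[k]]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(node_a = parts[1L], node_b = parts[2L],
               n_records = length(ii),
               max_score = max(records$score[ii]),
               rows = paste(records$row[ii], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  if (restrict_to_members) {
    nodes <- nodes[nodes$member, , drop = FALSE]
    edges <- edges[edges$node_a %in% nodes$label &
                   edges$node_b %in% nodes$label, , drop = FALSE]
  }
  clusters <- graph_components(nodes$label, edges)
  structure(list(nodes = nodes, edges = edges, clusters = clusters,
                 restricted = restrict_to_members),
            class = "xlms_graph")
}

# connected components via igraph; deterministic ordering by size desc then
# first (alphabetical) node label
graph_components <- function(node_labels, edges) {
  if (length(node_labels) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = node_labels))
  comp <- igraph::components(g)
  clusters <- split(names(comp$membership), comp$membership)
  clusters <- lapply(clusters, function(x) sort(unname(x)))
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, `[`, character(1), 1L))
  unname(clusters[ord])
}

#' @export
print.xlms_graph <- function(x, ...) {
  cat("Crosslink interaction graph:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges,", length(x$clusters), "clusters",
      if (x$restricted) "(restricted to registry members)" else "", "\n")
  for (i in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %s\n", i, paste(x$clusters[[i]], collapse = ", ")))
  invisible(x)
}

#' Serialize an interaction graph to JSON
#'
#' @param graph An `xlms_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  payload <- list(nodes = graph$nodes, edges = graph$edges,
                  clusters = graph$clusters, restricted = graph$restricted)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
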