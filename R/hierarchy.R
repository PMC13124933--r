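#' Position genes within a pathway DAG
#'
#' Computes, for each node of a directed acyclic pathway graph, the mean finite
#' shortest-path distance to reachable leaves (out-degree 0, following the
#' original edge direction) and to reachable roots (in-degree 0, following the
#' edge-reversed direction), together with in/out/total degree and unnormalised
#' directed betweenness centrality. A node that is itself a root or a leaf
#' contributes its own zero distance; nodes from which no target is reachable
#' get a missing mean. Disconnected targets (infinite distances) are excluded
#' from the means.
#'
#' The input is simplified first (self-loops and multi-edges removed); a cyclic
#' input is an error naming the offending nodes.
#'
#' @param dag a directed igraph object with named vertices.
#' @return data frame with columns `gene`, `root_mean`, `leaf_mean`,
#'   `in_degree`, `out_degree`, `all_degree`, `betweenness`.
#' @export
hierarchy_distances <- function(dag) {
  stopifnot(igraph::is_igraph(dag), igraph::is_directed(dag))
  dag <- igraph::simplify(dag)
  if (!igraph::is_dag(dag)) {
    comp <- igraph::components(dag, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    stop("input graph is cyclic; one cycle involves: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  genes <- igraph::V(dag)$name
  indeg <- igraph::degree(dag, mode = "in")
  outdeg <- igraph::degree(dag, mode = "out")
  roots <- genes[indeg == 0]
  leaves <- genes[outdeg == 0]

  finite_row_means <- function(d) {
    apply(d, 1, function(x) {
      x <- x[is.finite(x)]
      if (length(x) == 0) NA_real_ else mean(x)
    })
  }
  leaf_mean <- finite_row_means(igraph::distances(dag, v = genes, to = leaves,
                                                  mode = "out"))
  root_mean <- finite_row_means(igraph::distances(dag, v = genes, to = roots,
                                                  mode = "in"))
  data.frame(
    gene = genes,
    root_mean = root_mean,
    leaf_mean = leaf_mean,
    in_degree = as.integer(indeg),
    out_degree = as.integer(outdeg),
    all_degree = as.integer(indeg + outdeg),
    betweenness = igraph::betweenness(dag, directed = TRUE, normalized = FALSE),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
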