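#' Threshold a coexpression matrix into an unweighted network layer
#'
#' Creates an undirected simple graph with an edge between two distinct genes
#' whenever their absolute coexpression is at least `cutoff`. Genes with no
#' qualifying edge are dropped, so every node of the resulting layer has at
#' least one edge. Raising the cutoff never adds edges.
#'
#' @param coexpr gene-labelled symmetric matrix of absolute correlations.
#' @param cutoff threshold in `[0, 1]`.
#' @return an igraph undirected simple graph.
#' @export
threshold_coexpression <- function(coexpr, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(is.matrix(coexpr), nrow(coexpr) == ncol(coexpr),
            !is.null(rownames(coexpr)))
  idx <- which(abs(coexpr) >= cutoff & upper.tri(coexpr), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(coexpr)[idx[, 1]],
               to = colnames(coexpr)[idx[, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE
  )
  igraph::simplify(g)
}

#' Restrict gene sets to the genes present in a network layer
#'
#' @param sets named list of gene sets.
#' @param layer an igraph layer with named vertices.
#' @return the list with every set intersected with the layer's node set;
#'   empty intersections are allowed and reported with a warning.
#' @export
restrict_sets_to_network <- function(sets, layer) {
  nodes <- igraph::V(layer)$name
  out <- lapply(sets, function(s) intersect(s, nodes))
  empty <- names(out)[vapply(out, length, 1L) == 0 & vapply(sets, length, 1L) > 0]
  if (length(empty) > 0) {
    warning("gene set(s) with no member in the layer: ",
            paste(empty, collapse = ", "))
  }
  out
}

#' First-order neighbours of a target gene set
#'
#' Returns every node adjacent to at least one target gene. A node that is
#' itself a target is included whenever it is adjacent to another target.
#'
#' @param layer an igraph layer with named vertices.
#' @param targets character vector of target genes (silently intersected with
#'   the layer's nodes).
#' @return sorted character vector of neighbour genes.
#' @export
neighbours_of_set <- function(layer, targets) {
  targets <- intersect(targets, igraph::V(layer)$name)
  if (length(targets) == 0) return(character(0))
  nb <- igraph::adjacent_vertices(layer, targets)
  sort(unique(unlist(lapply(nb, function(v) v$name), use.names = FALSE)))
}
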