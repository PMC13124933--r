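#' Bounded proximity transform of a shortest-path distance
#'
#' `Proximity = 1 / (distance + 1)`: equal to 1 when two genes coincide
#' (distance 0), 0.5 at distance 1, and 0 for disconnected pairs (infinite
#' distance).
#'
#' @param distance numeric vector of non-negative (possibly infinite) edge
#'   counts.
#' @return proximity values in `[0, 1]`.
#' @export
proximity <- function(distance) {
  if (any(distance < 0, na.rm = TRUE)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  out <- 1 / (distance + 1)
  out[is.infinite(distance)] <- 0
  out
}

#' Invert a mean proximity back to a bounded distance
#'
#' Averages per-cluster proximities and converts the mean back to distance
#' units via `Distance = 1 / Proximity - 1`. A mean proximity of 0 (fully
#' disconnected) gives an infinite distance.
#'
#' @param per_arc_proximities non-empty numeric vector of proximities in
#'   `[0, 1]` (one per disease cluster).
#' @return a single distance (possibly `Inf`).
#' @export
mean_arc_distance <- function(per_arc_proximities) {
  stopifnot(length(per_arc_proximities) > 0,
            all(per_arc_proximities >= 0), all(per_arc_proximities <= 1))
  p <- mean(per_arc_proximities)
  if (p == 0) return(Inf)
  1 / p - 1
}

#' Shortest- and average-path proximity of genes to a target gene set
#'
#' For each query gene, `shortest` is the maximum proximity over the target
#' genes (the nearest connection; 1 when the gene is itself a target) and
#' `average` is the mean proximity over ALL target genes present in the layer,
#' with disconnected pairs contributing zero.
#'
#' @param layer an igraph layer with named vertices.
#' @param genes query genes (must be nodes of the layer).
#' @param target_set target gene set; members absent from the layer are
#'   dropped.
#' @return data frame with columns `gene`, `shortest`, `average`, and
#'   `in_target` flagging query genes that are themselves targets (so callers
#'   can recompute leave-self-out variants if desired). Both proximities are
#'   `NA` when no target gene is present in the layer.
#' @export
set_proximities <- function(layer, genes, target_set) {
  nodes <- igraph::V(layer)$name
  if (!all(genes %in% nodes)) {
    stop("query gene(s) absent from the layer: ",
         paste(setdiff(genes, nodes), collapse = ", "), call. = FALSE)
  }
  targets <- intersect(target_set, nodes)
  if (length(targets) == 0) {
    warning("no target gene present in the layer; proximities are NA")
    return(data.frame(gene = genes, shortest = NA_real_, average = NA_real_,
                      in_target = genes %in% target_set))
  }
  d <- igraph::distances(layer, v = genes, to = targets)
  p <- proximity(d)
  data.frame(
    gene = genes,
    shortest = apply(p, 1, max),
    average = rowMeans(p),
    in_target = genes %in% targets,
    stringsAsFactors = FALSE
  )
}

#' Per-cluster proximity matrices for all genes of a layer
#'
#' Computes, for every gene in the layer, the shortest- or average-path
#' proximity to each disease (ARD) or disease-cluster (ARC) gene set. This is
#' the feature block used by downstream statistics and the classifier.
#'
#' @param layer an igraph layer.
#' @param assoc a `gene_trait_associations` object.
#' @param level `"arc"` or `"ard"`: which target sets to use.
#' @param metric `"shortest"` or `"average"`.
#' @param genes query genes; defaults to all layer nodes.
#' @return a gene-by-target matrix of proximities (targets with no gene in the
#'   layer give a zero column).
#' @export
trait_proximity_matrix <- function(layer, assoc,
                                   level = c("arc", "ard"),
                                   metric = c("shortest", "average"),
                                   genes = igraph::V(layer)$name) {
  level <- match.arg(level)
  metric <- match.arg(metric)
  sets <- trait_gene_sets(assoc, level)
  nodes <- igraph::V(layer)$name
  stopifnot(all(genes %in% nodes))
  target_union <- intersect(unique(unlist(sets)), nodes)
  out <- matrix(0, nrow = length(genes), ncol = length(sets),
                dimnames = list(genes, names(sets)))
  if (length(target_union) == 0) return(out)
  d <- igraph::distances(layer, v = genes, to = target_union)
  p <- proximity(d)
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], nodes)
    if (length(members) == 0) next
    block <- p[, members, drop = FALSE]
    out[, nm] <- if (metric == "shortest") {
      apply(block, 1, max)
    } else {
      rowMeans(block)
    }
  }
  out
}

trait_gene_sets <- function(assoc, level = c("arc", "ard")) {
  level <- match.arg(level)
  stopifnot(inherits(assoc, "gene_trait_associations"))
  if (level == "arc") {
    if (is.null(assoc$arc)) stop("associations carry no ARC level", call. = FALSE)
    split(assoc$arc$gene, assoc$arc$arc_id)
  } else {
    split(assoc$ard$gene, assoc$ard$ard_id)
  }
}

# gene -> set of associated clusters (character list), on a fixed gene vector
membership_list <- function(assoc, level, genes) {
  df <- if (level == "arc") assoc$arc else assoc$ard
  key <- if (level == "arc") "arc_id" else "ard_id"
  m <- split(df[[key]], df$gene)
  out <- vector("list", length(genes))
  names(out) <- genes
  hit <- intersect(genes, names(m))
  out[hit] <- m[hit]
  out
}

#' Indirect disease-cluster interactions through first-order neighbours
#'
#' For each gene, counts the number of distinct ARCs (or ARDs) containing at
#' least one gene that directly interacts with it in the layer. A gene's own
#' direct associations do not contribute: the count is purely
#' neighbour-mediated. Genes absent from the layer are not scored.
#'
#' @param layer an igraph layer.
#' @param assoc a `gene_trait_associations` object.
#' @param genes genes to score (must be layer nodes; default all nodes).
#' @param level `"arc"` (ARC-Interactions) or `"ard"` (ARD-Interactions).
#' @return named integer vector of interaction counts.
#' @export
count_arc_interactions <- function(layer, assoc,
                                   genes = igraph::V(layer)$name,
                                   level = c("arc", "ard")) {
  level <- match.arg(level)
  nodes <- igraph::V(layer)$name
  if (!all(genes %in% nodes)) {
    stop("gene(s) absent from the layer: ",
         paste(setdiff(genes, nodes), collapse = ", "), call. = FALSE)
  }
  member <- membership_list(assoc, level, nodes)
  adj <- igraph::adjacent_vertices(layer, genes)
  counts <- vapply(adj, function(v) {
    length(unique(unlist(member[v$name], use.names = FALSE)))
  }, integer(1))
  stats::setNames(counts, genes)
}

#' Per-cluster counts of disease-associated neighbours
#'
#' For each gene and each ARC (or ARD), the number of adjacent genes associated
#' with that cluster.
#'
#' @inheritParams count_arc_interactions
#' @return a gene-by-cluster integer matrix.
#' @export
count_disease_neighbours <- function(layer, assoc,
                                     genes = igraph::V(layer)$name,
                                     level = c("arc", "ard")) {
  level <- match.arg(level)
  nodes <- igraph::V(layer)$name
  if (!all(genes %in% nodes)) {
    stop("gene(s) absent from the layer: ",
         paste(setdiff(genes, nodes), collapse = ", "), call. = FALSE)
  }
  sets <- trait_gene_sets(assoc, level)
  out <- matrix(0L, nrow = length(genes), ncol = length(sets),
                dimnames = list(genes, names(sets)))
  adj <- igraph::adjacent_vertices(layer, genes)
  nb_names <- lapply(adj, function(v) v$name)
  for (nm in names(sets)) {
    members <- unique(sets[[nm]])
    out[, nm] <- vapply(nb_names, function(nb) sum(nb %in% members), integer(1))
  }
  out
}
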