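#' Random-walk-with-restart configuration
#'
#' @param r restart probability in (0, 1); the walker returns to the seed set
#'   with probability `r` at each step and otherwise explores neighbours. When
#'   restarting, the restart mass is shared equally among all seeds.
#' @param tau per-layer preference weights for the multiplex walk (normalised
#'   internally to sum 1); `NULL` means equal weight for every layer.
#' @param tol L1 convergence tolerance for the iterative solver.
#' @param max_iter iteration cap for the iterative solver.
#' @param exact_dim exact dense linear solve is used whenever the (supra-)
#'   transition dimension is at most this; larger systems are power-iterated.
#' @return an object of class `rwr_config`.
#' @export
rwr_config <- function(r = 0.7, tau = NULL, tol = 1e-10, max_iter = 1000L,
                       exact_dim = 2000L) {
  if (!(r > 0 && r < 1)) stop("restart probability r must be in (0, 1)", call. = FALSE)
  if (!is.null(tau)) {
    if (any(tau < 0) || sum(tau) <= 0) {
      stop("tau entries must be >= 0 with at least one positive", call. = FALSE)
    }
  }
  structure(list(r = r, tau = tau, tol = tol, max_iter = as.integer(max_iter),
                 exact_dim = as.integer(exact_dim)),
            class = "rwr_config")
}

# Column-normalised sparse transition matrix of a layer on a fixed gene order.
# Genes isolated in the layer (or absent from it) get a self-loop column, so
# the walker remains in place until a restart or layer change.
layer_transition <- function(layer, genes) {
  n <- length(genes)
  A <- Matrix::Matrix(0, n, n, sparse = TRUE, dimnames = list(genes, genes))
  present <- intersect(igraph::V(layer)$name, genes)
  if (length(present) > 0) {
    sub <- igraph::induced_subgraph(layer, present)
    Asub <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    idx <- match(rownames(Asub), genes)
    A[idx, idx] <- Asub
  }
  deg <- Matrix::colSums(A)
  dangling <- which(deg == 0)
  if (length(dangling) > 0) {
    A <- A + Matrix::sparseMatrix(i = dangling, j = dangling,
                                  x = 1, dims = c(n, n))
    deg[dangling] <- 1
  }
  A %*% Matrix::Diagonal(x = 1 / deg)
}

rwr_restart_vector <- function(seeds, genes, replicas = 1L) {
  seeds <- intersect(seeds, genes)
  if (length(seeds) == 0) {
    stop("no seed gene is present in the network", call. = FALSE)
  }
  n <- length(genes)
  p0 <- numeric(n * replicas)
  idx <- match(seeds, genes)
  for (l in seq_len(replicas)) {
    p0[(l - 1L) * n + idx] <- 1 / (length(seeds) * replicas)
  }
  p0
}

solve_rwr <- function(S, p0, config) {
  n <- length(p0)
  r <- config$r
  if (n <= config$exact_dim) {
    A <- diag(n) - (1 - r) * as.matrix(S)
    return(drop(solve(A, r * p0)))
  }
  p <- p0
  for (i in seq_len(config$max_iter)) {
    p_new <- as.numeric((1 - r) * (S %*% p)) + r * p0
    if (sum(abs(p_new - p)) < config$tol) return(p_new)
    p <- p_new
  }
  warning("RWR did not reach tolerance within max_iter; returning last iterate")
  p
}

#' Random walk with restart on a single network layer
#'
#' Solves the stationary distribution `p = (1 - r) W p + r p0`, where `W` is
#' the column-normalised adjacency of the layer and `p0` is uniform over the
#' seed genes present in the layer. Solved exactly by a dense linear solve for
#' small layers and by power iteration otherwise.
#'
#' @param layer an igraph layer with named vertices.
#' @param seeds seed gene set (at least one member must be in the layer).
#' @param config an [rwr_config()].
#' @return named numeric vector of steady-state visiting probabilities over
#'   the layer's genes (sums to 1).
#' @export
run_rwr_monoplex <- function(layer, seeds, config = rwr_config()) {
  genes <- igraph::V(layer)$name
  W <- layer_transition(layer, genes)
  p0 <- rwr_restart_vector(seeds, genes)
  stats::setNames(solve_rwr(W, p0, config), genes)
}

# One dense factorisation, many seed sets: returns gene x seed-set matrix.
run_rwr_monoplex_multi <- function(layer, seed_sets, config = rwr_config()) {
  genes <- igraph::V(layer)$name
  W <- layer_transition(layer, genes)
  n <- length(genes)
  P0 <- vapply(seed_sets, rwr_restart_vector, numeric(n), genes = genes)
  if (n <= config$exact_dim) {
    A <- diag(n) - (1 - config$r) * as.matrix(W)
    out <- solve(A, config$r * P0)
  } else {
    out <- vapply(seq_along(seed_sets), function(j) {
      solve_rwr(W, P0[, j], config)
    }, numeric(n))
  }
  dimnames(out) <- list(genes, names(seed_sets))
  out
}

#' Build the supra-transition matrix of a multiplex network
#'
#' The state space is (gene, layer) over the union gene set of all layers;
#' genes missing from a layer are present as isolated replicas (self-loop
#' columns). From state (g, l) the walker, when exploring, first picks a
#' destination layer with probability proportional to `tau` and then takes one
#' within-layer step in that layer from gene g's replica; an isolated replica
#' holds the walker in place. Inter-layer moves therefore happen only between
#' replicas of the same gene, and with a single layer the walk reduces exactly
#' to the monoplex.
#'
#' @param layers named list of igraph layers.
#' @param tau layer preference weights (length = number of layers); normalised
#'   to sum 1.
#' @return a list with the sparse column-stochastic supra matrix `S`, the
#'   union gene vector `genes`, and the layer count `L`.
#' @export
build_supra_transition <- function(layers, tau = NULL) {
  L <- length(layers)
  stopifnot(L >= 1)
  if (is.null(tau)) tau <- rep(1, L)
  if (length(tau) != L) {
    stop("tau must have one weight per layer", call. = FALSE)
  }
  if (any(tau < 0) || sum(tau) <= 0) {
    stop("tau entries must be >= 0 with at least one positive", call. = FALSE)
  }
  tau <- tau / sum(tau)
  genes <- sort(unique(unlist(lapply(layers, function(l) igraph::V(l)$name))))
  Ws <- lapply(layers, layer_transition, genes = genes)
  B <- do.call(rbind, Map(function(W, t) t * W, Ws, tau))
  S <- do.call(cbind, rep(list(B), L))
  list(S = S, genes = genes, L = L)
}

#' Random walk with restart on a multiplex network
#'
#' Runs the restart walk on the supra-transition matrix of
#' [build_supra_transition()], with the restart mass shared equally over all
#' seed replicas across layers, and aggregates each gene's replica
#' probabilities by summation (so the gene-level scores again sum to 1;
#' ranking and z-scores are identical to a mean aggregation).
#'
#' @param layers named list of igraph layers sharing a gene universe.
#' @param seeds seed gene set.
#' @param config an [rwr_config()]; `config$tau` defaults to equal weights.
#' @return named numeric vector of gene-level steady-state probabilities over
#'   the union gene set.
#' @export
run_rwr_multiplex <- function(layers, seeds, config = rwr_config()) {
  mux <- build_supra_transition(layers, config$tau)
  p0 <- rwr_restart_vector(seeds, mux$genes, replicas = mux$L)
  p <- solve_rwr(mux$S, p0, config)
  agg <- rowSums(matrix(p, nrow = length(mux$genes), ncol = mux$L))
  stats::setNames(agg, mux$genes)
}

run_rwr_multiplex_multi <- function(layers, seed_sets, config = rwr_config()) {
  mux <- build_supra_transition(layers, config$tau)
  n <- length(mux$genes)
  out <- vapply(seed_sets, function(s) {
    p0 <- rwr_restart_vector(s, mux$genes, replicas = mux$L)
    p <- solve_rwr(mux$S, p0, config)
    rowSums(matrix(p, nrow = n, ncol = mux$L))
  }, numeric(n))
  dimnames(out) <- list(mux$genes, names(seed_sets))
  out
}

#' Run the full battery of seeded walks on a layer or multiplex
#'
#' One walk per ARD and/or per ARC seed set (the genes associated with that
#' disease or cluster), producing a gene-by-seed-set score matrix.
#'
#' @param network an igraph layer, or a named list of layers (multiplex mode).
#' @param assoc a `gene_trait_associations` object providing the seed sets.
#' @param level `"arc"`, `"ard"`, or `"both"`.
#' @param config an [rwr_config()].
#' @return a gene-by-seed-set matrix of steady-state probabilities.
#' @export
run_rwr_battery <- function(network, assoc, level = c("arc", "ard", "both"),
                            config = rwr_config()) {
  level <- match.arg(level)
  sets <- switch(level,
                 arc = trait_gene_sets(assoc, "arc"),
                 ard = trait_gene_sets(assoc, "ard"),
                 both = c(trait_gene_sets(assoc, "ard"),
                          trait_gene_sets(assoc, "arc")))
  if (igraph::is_igraph(network)) {
    nodes <- igraph::V(network)$name
    sets <- Filter(function(s) length(intersect(s, nodes)) > 0, sets)
    run_rwr_monoplex_multi(network, sets, config)
  } else {
    genes <- unique(unlist(lapply(network, function(l) igraph::V(l)$name)))
    sets <- Filter(function(s) length(intersect(s, genes)) > 0, sets)
    run_rwr_multiplex_multi(network, sets, config)
  }
}

#' Standardise RWR scores within each seed set
#'
#' Z-standardises each seed-set column of a score matrix, and summarises each
#' gene by its mean association across seed sets and its top-scoring seed set.
#' Zero-variance columns give all-zero z-scores with a warning.
#'
#' @param scores gene-by-seed-set score matrix.
#' @return a list with `scores` (the input), `z` (column-standardised matrix),
#'   and `summary` (data frame `gene`, `mean_score`, `mean_z`, `top`).
#' @export
standardize_scores <- function(scores) {
  stopifnot(is.matrix(scores))
  mu <- colMeans(scores)
  sdv <- apply(scores, 2, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    warning("zero-variance seed-set column(s): ",
            paste(colnames(scores)[zero], collapse = ", "),
            "; their z-scores are set to 0")
    sdv[zero] <- 1
  }
  z <- sweep(sweep(scores, 2, mu, "-"), 2, sdv, "/")
  z[, zero] <- 0
  top <- colnames(scores)[apply(z, 1, which.max)]
  list(
    scores = scores,
    z = z,
    summary = data.frame(
      gene = rownames(scores),
      mean_score = rowMeans(scores),
      mean_z = rowMeans(z),
      top = top,
      stringsAsFactors = FALSE
    )
  )
}
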