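# Independent brute-force oracles used to check the package's graph and
# set statistics. These deliberately avoid the code paths under test.

# undirected BFS distances from `source` over a two-column edge matrix
bfs_distances <- function(edges, nodes, source) {
  ends <- c(edges[, 1], edges[, 2])
  starts <- c(edges[, 2], edges[, 1])
  adj <- split(ends, factor(starts, levels = nodes))
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  frontier <- source
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# directed BFS distances from `source`, following edges from -> to
bfs_distances_directed <- function(edges, nodes, source) {
  adj <- split(edges[, 2], factor(edges[, 1], levels = nodes))
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  frontier <- source
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

graph_edge_matrix <- function(g) {
  e <- igraph::as_data_frame(g, "edges")
  cbind(e$from, e$to)
}

# mean coexpression over all unordered pairs {x in A, y in B, x != y},
# each pair counted once
pair_mean_oracle <- function(M, A, B) {
  A <- intersect(unique(A), rownames(M))
  B <- intersect(unique(B), rownames(M))
  seen <- character(0)
  vals <- numeric(0)
  for (x in A) {
    for (y in B) {
      if (x == y) next
      key <- paste(sort(c(x, y)), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      vals <- c(vals, M[x, y])
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# dense closed-form RWR oracle: p = r (I - (1-r) W)^-1 p0, with W built by
# explicit column normalisation of the adjacency matrix
rwr_dense_oracle <- function(g, seeds, r = 0.7) {
  nodes <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  for (j in seq_len(ncol(A))) {
    s <- sum(A[, j])
    if (s == 0) A[j, j] <- 1 else A[, j] <- A[, j] / s
  }
  p0 <- stats::setNames(rep(0, length(nodes)), nodes)
  seeds <- intersect(seeds, nodes)
  p0[seeds] <- 1 / length(seeds)
  drop(r * solve(diag(length(nodes)) - (1 - r) * A, p0))
}

# dense supra-matrix oracle for the multiplex walk: explicit loops over
# (gene, layer) states; exploration picks a layer ~ tau then steps within it
rwr_supra_oracle <- function(layers, seeds, r = 0.7, tau = NULL) {
  L <- length(layers)
  if (is.null(tau)) tau <- rep(1, L)
  tau <- tau / sum(tau)
  genes <- sort(unique(unlist(lapply(layers, function(l) igraph::V(l)$name))))
  n <- length(genes)
  Ws <- lapply(layers, function(l) {
    A <- matrix(0, n, n, dimnames = list(genes, genes))
    present <- igraph::V(l)$name
    e <- igraph::as_data_frame(l, "edges")
    for (k in seq_len(nrow(e))) {
      A[e$from[k], e$to[k]] <- 1
      A[e$to[k], e$from[k]] <- 1
    }
    for (j in seq_len(n)) {
      s <- sum(A[, j])
      if (s == 0) A[j, j] <- 1 else A[, j] <- A[, j] / s
    }
    A
  })
  S <- matrix(0, n * L, n * L)
  for (l_from in seq_len(L)) {
    for (l_to in seq_len(L)) {
      S[(l_to - 1) * n + seq_len(n), (l_from - 1) * n + seq_len(n)] <-
        tau[l_to] * Ws[[l_to]]
    }
  }
  p0 <- rep(0, n * L)
  idx <- match(intersect(seeds, genes), genes)
  for (l in seq_len(L)) p0[(l - 1) * n + idx] <- 1 / (length(idx) * L)
  p <- drop(r * solve(diag(n * L) - (1 - r) * S, p0))
  stats::setNames(rowSums(matrix(p, n, L)), genes)
}

random_layer <- function(n, p = 0.1, prefix = "g") {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  igraph::simplify(g)
}

random_coexpr <- function(n, prefix = "g") {
  M <- matrix(stats::runif(n * n), n, n)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  dimnames(M) <- list(paste0(prefix, seq_len(n)), paste0(prefix, seq_len(n)))
  M
}

# small fast study for module tests; the default-size study (used by the
# acceptance suite) is cached so it is generated once per test run
small_study_config <- function(seed = 11, ...) {
  study_config(n_genes = 150, n_ards = 12, n_arcs = 4, snps_per_ard = 5,
               planted_ageing_size = 10, planted_pleio_size = 8, seed = seed,
               ...)
}

.study_cache <- new.env(parent = emptyenv())

small_study <- function(seed = 11) {
  key <- paste0("small", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- generate_study(small_study_config(seed))
  }
  .study_cache[[key]]
}

default_study <- function() {
  if (is.null(.study_cache$default)) {
    .study_cache$default <- generate_study(study_config())
  }
  .study_cache$default
}

study_assoc <- function(study, flank = 10000) {
  key <- paste0("assoc", substr(digest_of(study$snp_table), 1, 8), flank)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- map_snps_to_genes(study$snp_table, study$gene_ranges,
                                             flank = flank,
                                             arc_map = study$arc_map)
  }
  .study_cache[[key]]
}

digest_of <- function(x) {
  paste(format(utils::object.size(x)), nrow(x), collapse = "")
}

# flatten a study into comparable plain data for determinism checks
study_fingerprint <- function(study) {
  list(
    ranges = study$gene_ranges,
    snps = study$snp_table,
    arc_map = study$arc_map,
    layers = lapply(study$layers, function(l) {
      e <- igraph::as_data_frame(l, "edges")
      e[order(e$from, e$to), ]
    }),
    dag = {
      e <- igraph::as_data_frame(study$kegg_dag, "edges")
      e[order(e$from, e$to), ]
    },
    coexpr = study$coexpr,
    expression = study$expression,
    ageing = study$ageing_like,
    pleio = study$pleio_like,
    truth = study$truth
  )
}
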