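#' Generate a complete synthetic study with planted signal
#'
#' Produces every input the analysis pipeline consumes: gene genomic ranges,
#' per-ARD significant SNP tables, an ARD-to-ARC map, four network layers
#' (`PPI`, `COX90`, `COX95`, `KEGG`), a pathway DAG, a gene-labelled absolute
#' coexpression matrix, a gene-by-tissue expression matrix, and two planted
#' gene sets with opposite architecture:
#'
#' * `ageing_like` genes carry no direct GWAS signal but receive elevated
#'   connectivity to disease-associated genes in the interaction-style layers,
#'   strong mutual coexpression, and near-uniform tissue expression;
#' * `pleio_like` genes carry direct SNP associations spread over at least four
#'   ARCs, few network edges, weak coexpression, and expression concentrated in
#'   a single dominant tissue.
#'
#' The generator is fully deterministic: the same configuration and seed yield
#' a bit-identical study.
#'
#' @param config a [study_config()].
#' @return an object of class `synthetic_study`: a list with elements
#'   `gene_ranges`, `snp_table`, `arc_map`, `layers` (named list of igraph
#'   objects), `kegg_dag`, `coexpr`, `expression`, `ageing_like`, `pleio_like`,
#'   `truth` (the planted gene-to-ARD associations backed by SNP placement),
#'   and `config`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  validate_study_config(config)
  set.seed(config$seed)

  genes <- gene_names(config$n_genes)
  ards <- ard_names(config$n_ards)
  arcs <- arc_names(config$n_arcs)

  ## ARD -> ARC map: skewed partition with at least one ARD per ARC
  extra <- stats::rmultinom(1, config$n_ards - config$n_arcs,
                            prob = rev(seq_len(config$n_arcs)))[, 1]
  arc_sizes <- extra + 1L
  arc_map <- data.frame(
    ard_id = ards,
    arc_id = rep(arcs, times = arc_sizes),
    stringsAsFactors = FALSE
  )
  arc_of <- stats::setNames(arc_map$arc_id, arc_map$ard_id)

  ## gene universe: 1-based inclusive intervals, spaced so the +/-10 kb flank
  ## never bridges two genes
  chrom <- paste0("chr", 1L + (seq_len(config$n_genes) - 1L) %% 22L)
  idx_on_chrom <- stats::ave(seq_len(config$n_genes), chrom, FUN = seq_along)
  width <- sample(5000:80000, config$n_genes, replace = TRUE)
  start <- 1L + (idx_on_chrom - 1L) * 200000L
  gene_ranges <- data.frame(
    gene = genes, chrom = chrom, start = start, end = start + width - 1L,
    stringsAsFactors = FALSE
  )

  ## planted sets (disjoint)
  planted <- sample(genes, config$planted_ageing_size + config$planted_pleio_size)
  ageing_like <- sort(planted[seq_len(config$planted_ageing_size)])
  pleio_like <- sort(planted[config$planted_ageing_size + seq_len(config$planted_pleio_size)])

  ## disease-associated genes: disjoint slices of the non-planted pool so that
  ## with pleiotropy_rate = 0 every associated gene maps to exactly one ARD
  pool <- setdiff(genes, c(ageing_like, pleio_like))
  gpa <- config$genes_per_ard
  if (is.null(gpa)) gpa <- max(3L, floor(0.45 * length(pool) / config$n_ards))
  if (gpa * config$n_ards > length(pool)) {
    stop("not enough non-planted genes for the requested genes_per_ard", call. = FALSE)
  }
  shuffled <- sample(pool)
  ard_targets <- split(shuffled[seq_len(gpa * config$n_ards)],
                       rep(ards, each = gpa))

  ## SNPs: round-robin over each ARD's target slice, positions inside gene body
  assoc <- list()
  for (d in ards) {
    tg <- ard_targets[[d]][((seq_len(config$snps_per_ard) - 1L) %% gpa) + 1L]
    assoc[[d]] <- data.frame(gene = tg, ard_id = d, stringsAsFactors = FALSE)
  }
  assoc <- do.call(rbind, assoc)

  ## extra ARDs: pleiotropy_rate chance per associated gene of one extra ARD
  assoc_genes <- unique(assoc$gene)
  gains <- assoc_genes[stats::runif(length(assoc_genes)) < config$pleiotropy_rate]
  if (length(gains) > 0) {
    assoc <- rbind(assoc, data.frame(gene = gains,
                                     ard_id = sample(ards, length(gains), replace = TRUE),
                                     stringsAsFactors = FALSE))
  }

  ## pleio-like genes: direct associations spanning >= 4 distinct ARCs
  k_floor <- min(4L, config$n_arcs)
  k_choices <- seq(k_floor, min(k_floor + 2L, config$n_arcs))
  for (g in pleio_like) {
    k <- k_choices[sample.int(length(k_choices), 1)]
    chosen_arcs <- sample(arcs, k)
    chosen_ards <- vapply(chosen_arcs, function(a) {
      cand <- arc_map$ard_id[arc_map$arc_id == a]
      cand[sample.int(length(cand), 1)]
    }, character(1))
    assoc <- rbind(assoc, data.frame(gene = g, ard_id = unname(chosen_ards),
                                     stringsAsFactors = FALSE))
  }
  assoc <- unique(assoc)
  truth <- assoc[order(assoc$gene, assoc$ard_id), , drop = FALSE]
  rownames(truth) <- NULL

  ## one SNP per planted (gene, ARD) association, inside the gene body
  rng <- gene_ranges[match(truth$gene, gene_ranges$gene), ]
  pos <- rng$start + floor(stats::runif(nrow(truth)) * (rng$end - rng$start + 1L))
  snp_table <- data.frame(
    snp = sprintf("rs%06d", seq_len(nrow(truth))),
    chrom = rng$chrom,
    pos = as.integer(pos),
    ard_id = truth$ard_id,
    stringsAsFactors = FALSE
  )

  disease_genes <- unique(truth$gene)
  arcs_of_gene <- lapply(split(arc_of[truth$ard_id], truth$gene), unique)

  ## ---- PPI layer: preferential attachment over non-pleio genes, planted
  ## ageing edges across ARCs, pleio genes attached peripherally (degree 1)
  ppi <- build_ppi_layer(genes, ageing_like, pleio_like, truth, arc_of,
                         config$layer_specs$ppi)

  ## ---- coexpression matrix with planted modules
  cox_spec <- config$layer_specs$cox
  arc_modules <- lapply(arcs, function(a) {
    members <- setdiff(unique(truth$gene[arc_of[truth$ard_id] == a]), pleio_like)
    if (length(members) > cox_spec$module_size) {
      members <- sample(members, cox_spec$module_size)
    }
    members
  })
  names(arc_modules) <- arcs
  modules <- c(list(ageing = ageing_like), arc_modules)
  coexpr <- generate_coexpression_matrix(
    config, modules,
    within = c(cox_spec$ageing_within, rep(cox_spec$arc_within, config$n_arcs)),
    between = cox_spec$background,
    .reseed = FALSE
  )
  ## light planted cross-correlation: each ageing gene to a few disease genes
  if (cox_spec$cross_links > 0 && length(disease_genes) > 0) {
    for (g in ageing_like) {
      partner <- sample(disease_genes, min(cox_spec$cross_links, length(disease_genes)))
      val <- stats::runif(length(partner), 0.91, 0.95)
      coexpr[g, partner] <- val
      coexpr[partner, g] <- val
    }
  }

  cox90 <- threshold_coexpression(coexpr, 0.90)
  cox95 <- threshold_coexpression(coexpr, 0.95)

  ## ---- pathway DAG: ageing genes mid-hierarchy with cross-edges to disease
  ## genes across ARCs, pleio genes as terminal leaves
  kegg_spec <- config$layer_specs$kegg
  n_kegg <- max(kegg_spec$depth,
                ceiling(kegg_spec$prop_genes * config$n_genes))
  other_pool <- setdiff(genes, c(ageing_like, pleio_like))
  n_other <- min(length(other_pool),
                 max(0L, n_kegg - length(ageing_like) - length(pleio_like)))
  dag_genes <- c(sample(other_pool, n_other), ageing_like, pleio_like)
  kegg_dag <- generate_kegg_dag(config, genes = dag_genes,
                                mid_set = ageing_like, leaf_set = pleio_like)
  kegg_dag <- plant_dag_cross_edges(kegg_dag, ageing_like, truth, arc_of,
                                    kegg_spec$planted_arcs)
  kegg_layer <- igraph::as_undirected(igraph::simplify(kegg_dag), mode = "collapse")
  kegg_layer <- igraph::delete_vertices(kegg_layer,
                                        which(igraph::degree(kegg_layer) == 0))

  layers <- list(PPI = ppi, COX90 = cox90, COX95 = cox95, KEGG = kegg_layer)

  ## ---- tissue expression
  expr_spec <- config$layer_specs$expr
  expression <- matrix(stats::rgamma(config$n_genes * config$n_tissues,
                                     shape = 0.7, scale = 10),
                       nrow = config$n_genes,
                       dimnames = list(genes, sprintf("tissue%02d", seq_len(config$n_tissues))))
  ## ageing-like: near-uniform high expression -> Tau close to 0
  expression[ageing_like, ] <- 100 * matrix(
    stats::runif(length(ageing_like) * config$n_tissues, expr_spec$uniform_low, 1),
    nrow = length(ageing_like))
  ## pleio-like: one dominant tissue -> Tau close to 1
  dom <- sample.int(config$n_tissues, length(pleio_like), replace = TRUE)
  base <- matrix(stats::runif(length(pleio_like) * config$n_tissues, 0.5, 1.5),
                 nrow = length(pleio_like))
  base[cbind(seq_along(pleio_like), dom)] <- expr_spec$dominant_fold
  expression[pleio_like, ] <- base

  study <- list(
    gene_ranges = gene_ranges,
    snp_table = snp_table,
    arc_map = arc_map,
    layers = layers,
    kegg_dag = kegg_dag,
    coexpr = coexpr,
    expression = expression,
    ageing_like = ageing_like,
    pleio_like = pleio_like,
    truth = truth,
    config = config
  )
  class(study) <- "synthetic_study"
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study\n")
  cat(sprintf("  %d genes, %d ARDs in %d ARCs, %d SNPs\n",
              nrow(x$gene_ranges), x$config$n_ards, x$config$n_arcs,
              nrow(x$snp_table)))
  for (nm in names(x$layers)) {
    cat(sprintf("  layer %-6s %5d nodes %7d edges\n", nm,
                igraph::vcount(x$layers[[nm]]), igraph::ecount(x$layers[[nm]])))
  }
  cat(sprintf("  planted: %d ageing-like, %d pleiotropic-like\n",
              length(x$ageing_like), length(x$pleio_like)))
  invisible(x)
}

build_ppi_layer <- function(genes, ageing_like, pleio_like, truth, arc_of, spec) {
  base_nodes <- setdiff(genes, pleio_like)
  g <- igraph::sample_pa(length(base_nodes), m = spec$m, directed = FALSE)
  igraph::V(g)$name <- sample(base_nodes)

  disease_by_arc <- split(truth$gene, arc_of[truth$ard_id])
  disease_by_arc <- lapply(disease_by_arc,
                           function(v) intersect(unique(v), base_nodes))
  disease_by_arc <- disease_by_arc[vapply(disease_by_arc, length, 1L) > 0]
  edges <- character(0)
  for (gene in ageing_like) {
    n_arc <- min(spec$planted_arcs, length(disease_by_arc))
    chosen <- sample(names(disease_by_arc), n_arc)
    per_arc <- max(1L, spec$planted_degree %/% n_arc)
    for (a in chosen) {
      cand <- setdiff(disease_by_arc[[a]], gene)
      if (length(cand) == 0) next
      partners <- cand[sample.int(length(cand), min(per_arc, length(cand)))]
      edges <- c(edges, rbind(gene, partners))
    }
  }
  g <- igraph::add_edges(g, edges)

  ## pleiotropic-like genes: one peripheral edge to a non-disease gene
  disease_genes <- unique(truth$gene)
  periph_pool <- setdiff(base_nodes, c(disease_genes, ageing_like))
  if (length(periph_pool) == 0) periph_pool <- base_nodes
  g <- igraph::add_vertices(g, length(pleio_like), name = pleio_like)
  anchors <- sample(periph_pool, length(pleio_like), replace = TRUE)
  g <- igraph::add_edges(g, rbind(pleio_like, anchors))
  igraph::simplify(g)
}

#' Generate a layered pathway-like directed acyclic graph
#'
#' Builds a simple DAG (no self-loops, no multi-edges) over gene labels by
#' assigning nodes to `depth` ordered layers and drawing each node's parents
#' from the preceding layer, so every root-to-leaf path has at most
#' `depth - 1` edges. Nodes in `mid_set` are pinned to the middle layer and
#' nodes in `leaf_set` to the terminal layer (where they receive exactly one
#' parent and no children, making them leaves).
#'
#' @param config a [study_config()]; supplies the default node count
#'   (`layer_specs$kegg$prop_genes * n_genes`) and depth.
#' @param genes optional character vector of node labels; defaults to a
#'   deterministic sample of the configured gene universe.
#' @param mid_set,leaf_set gene labels pinned to the middle / terminal layer.
#' @param depth number of layers; defaults to `config$layer_specs$kegg$depth`.
#' @return an igraph directed acyclic graph with a `layer` vertex attribute.
#' @export
generate_kegg_dag <- function(config = study_config(), genes = NULL,
                              mid_set = character(), leaf_set = character(),
                              depth = config$layer_specs$kegg$depth) {
  stopifnot(inherits(config, "study_config"), depth >= 1)
  if (is.null(genes)) {
    set.seed(config$seed)
    universe <- gene_names(config$n_genes)
    n <- min(config$n_genes,
             max(1L, ceiling(config$layer_specs$kegg$prop_genes * config$n_genes)))
    genes <- sample(universe, n)
  }
  genes <- unique(genes)
  n <- length(genes)
  if (n == 1) {
    return(igraph::make_empty_graph(directed = TRUE) +
             igraph::vertices(genes, layer = 1L))
  }
  depth <- min(depth, n)

  layer <- sample.int(depth, n, replace = TRUE)
  names(layer) <- genes
  layer[intersect(mid_set, genes)] <- max(1L, ceiling(depth / 2))
  layer[intersect(leaf_set, genes)] <- depth
  ## layer 1 must be populated so roots exist
  if (!any(layer == 1L)) {
    movable <- setdiff(genes, c(mid_set, leaf_set))
    if (length(movable) == 0) movable <- genes
    layer[movable[1]] <- 1L
  }

  from <- character(0); to <- character(0)
  for (j in seq(2L, depth)) {
    here <- genes[layer == j]
    parents_pool <- genes[layer == j - 1L]
    if (length(here) == 0) next
    if (length(parents_pool) == 0) parents_pool <- genes[layer < j]
    if (length(parents_pool) == 0) next
    for (g in here) {
      k <- if (g %in% leaf_set) 1L else sample.int(3L, 1)
      p <- parents_pool[sample.int(length(parents_pool), min(k, length(parents_pool)))]
      from <- c(from, p); to <- c(to, rep(g, length(p)))
    }
  }
  dag <- igraph::graph_from_data_frame(data.frame(from, to), directed = TRUE,
                                       vertices = data.frame(name = genes))
  igraph::V(dag)$layer <- as.integer(layer[igraph::V(dag)$name])
  igraph::simplify(dag)
}

# Planted DAG cross-edges from ageing genes to disease genes across distinct
# ARCs; edges always run from the strictly lower layer to the higher one, so
# acyclicity and the layered path bound are preserved.
plant_dag_cross_edges <- function(dag, ageing_like, truth, arc_of, n_arcs_touch) {
  nodes <- igraph::V(dag)$name
  layer <- stats::setNames(igraph::V(dag)$layer, nodes)
  disease_by_arc <- split(truth$gene, arc_of[truth$ard_id])
  disease_by_arc <- lapply(disease_by_arc, function(v) intersect(unique(v), nodes))
  disease_by_arc <- disease_by_arc[vapply(disease_by_arc, length, 1L) > 0]
  if (length(disease_by_arc) == 0) return(dag)

  from <- character(0); to <- character(0)
  for (g in intersect(ageing_like, nodes)) {
    chosen <- sample(names(disease_by_arc),
                     min(n_arcs_touch, length(disease_by_arc)))
    for (a in chosen) {
      cand <- setdiff(disease_by_arc[[a]], g)
      cand <- cand[layer[cand] != layer[g]]
      if (length(cand) == 0) next
      partner <- cand[sample.int(length(cand), 1)]
      if (layer[g] < layer[partner]) {
        from <- c(from, g); to <- c(to, partner)
      } else {
        from <- c(from, partner); to <- c(to, g)
      }
    }
  }
  if (length(from) > 0) {
    dag <- igraph::add_edges(dag, rbind(from, to))
  }
  igraph::simplify(dag)
}

#' Generate a symmetric absolute-coexpression matrix with planted modules
#'
#' Background entries are drawn uniformly on `[0, 2*between]` (mean `between`)
#' and within-module blocks uniformly on `within +/- 0.04` (clamped to
#' `[0, 1]`), so the expected within-module coexpression exceeds the
#' between-module expectation by `within - between`. The matrix is symmetric
#' with a unit diagonal. With `within == between` the block means coincide and
#' the construction is a null.
#'
#' @param config a [study_config()]; supplies the gene universe and seed.
#' @param modules list of gene sets (subsets of the universe) to plant as
#'   coexpression modules.
#' @param within planted within-module mean absolute correlation; recycled over
#'   modules.
#' @param between mean background absolute correlation (must satisfy
#'   `2 * between <= 1`).
#' @param .reseed reset the random state from `config$seed` (set `FALSE` when
#'   called inside a larger generator).
#' @return a gene-labelled symmetric matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @export
generate_coexpression_matrix <- function(config = study_config(),
                                         modules = list(),
                                         within = 0.9, between = 0.15,
                                         .reseed = TRUE) {
  stopifnot(inherits(config, "study_config"),
            between >= 0, 2 * between <= 1,
            all(within >= 0), all(within <= 1))
  if (.reseed) set.seed(config$seed)
  genes <- gene_names(config$n_genes)
  n <- length(genes)
  within <- rep_len(within, max(1L, length(modules)))

  M <- matrix(0, n, n, dimnames = list(genes, genes))
  ut <- upper.tri(M)
  M[ut] <- stats::runif(sum(ut), 0, 2 * between)
  for (i in seq_along(modules)) {
    mem <- intersect(modules[[i]], genes)
    if (length(mem) < 2) next
    k <- length(mem)
    block <- matrix(stats::runif(k * k,
                                 max(0, within[i] - 0.04),
                                 min(1, within[i] + 0.04)), k, k)
    idx <- match(mem, genes)
    cur <- M[idx, idx]
    cur[upper.tri(cur)] <- block[upper.tri(block)]
    M[idx, idx] <- cur
  }
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  M
}
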