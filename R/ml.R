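#' Enumerate the classifier dataset grid
#'
#' The feature datasets systematically cover local, path-based and
#' diffusion-based connectivity: every metric-by-network combination in both
#' target modes (4 metrics x 4 networks x 2 modes = 32), per-network
#' integrations of all four metrics (4 x 2 = 8), per-metric integrations
#' across all four networks for the three path/neighbour metrics (3 x 2 = 6;
#' the cross-network integration of the diffusion metric is represented by the
#' multiplex dataset instead), and the multiplex random-walk dataset seeded on
#' individual diseases (1) — 47 datasets in total with the default arguments.
#'
#' @param networks network layer names.
#' @param metrics connectivity metric names.
#' @param modes target modes (`"ARC"` cluster-level, `"ARD"` disease-level).
#' @return data frame with columns `dataset_id`, `type`, `network`, `metric`,
#'   `mode`.
#' @export
dataset_grid <- function(networks = c("PPI", "COX90", "COX95", "KEGG"),
                         metrics = c("proximity_shortest", "proximity_average",
                                     "neighbour_counts", "rwr"),
                         modes = c("ARC", "ARD")) {
  mn <- expand.grid(network = networks, metric = metrics, mode = modes,
                    stringsAsFactors = FALSE)
  mn$type <- "metric_network"
  pn <- expand.grid(network = networks, metric = "all", mode = modes,
                    stringsAsFactors = FALSE)
  pn$type <- "per_network"
  pm <- expand.grid(network = "all", metric = setdiff(metrics, "rwr"),
                    mode = modes, stringsAsFactors = FALSE)
  pm$type <- "per_metric"
  mx <- data.frame(network = "multiplex", metric = "rwr", mode = "ARD",
                   type = "multiplex_rwr", stringsAsFactors = FALSE)
  out <- rbind(mn, pn, pm, mx)[, c("type", "network", "metric", "mode")]
  out$dataset_id <- sprintf("%s__%s__%s__%s", out$type, out$network,
                            out$metric, out$mode)
  rownames(out) <- NULL
  out[, c("dataset_id", "type", "network", "metric", "mode")]
}

#' Compute every connectivity feature block of a study
#'
#' For each network layer and each target mode, computes the four connectivity
#' metrics as gene-by-target matrices (8 targets per metric in ARC mode, one
#' per disease in ARD mode): shortest-path proximity, average-path proximity,
#' per-cluster disease-neighbour counts, and random-walk-with-restart scores
#' seeded on each target's gene set. Optionally also the multiplex
#' random-walk block over all layers.
#'
#' @param layers named list of igraph layers.
#' @param assoc a `gene_trait_associations` object.
#' @param modes target modes to compute (`"ARC"`, `"ARD"`).
#' @param config an [rwr_config()].
#' @param multiplex_modes modes for which the multiplex RWR block is computed
#'   (`character(0)` to skip).
#' @return a nested list `store$features[[network]][[metric]][[mode]]` plus
#'   `store$multiplex[[mode]]`.
#' @export
compute_feature_store <- function(layers, assoc, modes = c("ARC", "ARD"),
                                  config = rwr_config(),
                                  multiplex_modes = "ARD") {
  features <- lapply(layers, function(layer) {
    per_metric <- list()
    for (mode in modes) {
      lvl <- tolower(mode)
      per_metric[["proximity_shortest"]][[mode]] <-
        trait_proximity_matrix(layer, assoc, level = lvl, metric = "shortest")
      per_metric[["proximity_average"]][[mode]] <-
        trait_proximity_matrix(layer, assoc, level = lvl, metric = "average")
      per_metric[["neighbour_counts"]][[mode]] <-
        count_disease_neighbours(layer, assoc, level = lvl)
      per_metric[["rwr"]][[mode]] <-
        run_rwr_battery(layer, assoc, level = lvl, config = config)
    }
    per_metric
  })
  multiplex <- list()
  for (mode in multiplex_modes) {
    multiplex[[mode]] <- run_rwr_battery(layers, assoc, level = tolower(mode),
                                         config = config)
  }
  list(features = features, multiplex = multiplex, networks = names(layers))
}

#' Assemble one classifier dataset from the feature store
#'
#' Single-network datasets contain one row per gene present in that network;
#' aggregated datasets cover the union of the member networks' genes, with a
#' gene's missing blocks imputed at the metric's disconnected value (0) and a
#' 0/1 presence-indicator column per network. The label is 1 for genes in the
#' positive (ageing) set.
#'
#' @param store a [compute_feature_store()] result.
#' @param spec one row of [dataset_grid()] (or a list with the same fields).
#' @param positives positive gene set; must intersect the dataset's genes.
#' @return data frame with `gene`, `label`, and numeric feature columns.
#' @export
build_feature_table <- function(store, spec, positives) {
  if (length(positives) == 0) stop("empty positive set", call. = FALSE)
  get_block <- function(network, metric, mode) {
    m <- store$features[[network]][[metric]][[mode]]
    if (is.null(m)) {
      stop(sprintf("feature block %s/%s/%s missing from store",
                   network, metric, mode), call. = FALSE)
    }
    colnames(m) <- sprintf("%s.%s.%s", network, metric, colnames(m))
    m
  }
  type <- spec$type
  if (type == "metric_network") {
    X <- get_block(spec$network, spec$metric, spec$mode)
  } else if (type == "per_network") {
    metrics <- names(store$features[[spec$network]])
    X <- do.call(cbind, lapply(metrics, get_block, network = spec$network,
                               mode = spec$mode))
  } else if (type == "per_metric") {
    blocks <- lapply(store$networks, get_block, metric = spec$metric,
                     mode = spec$mode)
    names(blocks) <- store$networks
    genes <- sort(unique(unlist(lapply(blocks, rownames))))
    X <- do.call(cbind, lapply(store$networks, function(nw) {
      b <- blocks[[nw]]
      full <- matrix(0, length(genes), ncol(b),
                     dimnames = list(genes, colnames(b)))
      full[rownames(b), ] <- b
      cbind(full, matrix(as.numeric(genes %in% rownames(b)), ncol = 1,
                         dimnames = list(genes, paste0("present.", nw))))
    }))
  } else if (type == "multiplex_rwr") {
    X <- store$multiplex[[spec$mode]]
    if (is.null(X)) stop("multiplex block missing from store", call. = FALSE)
    colnames(X) <- sprintf("multiplex.rwr.%s", colnames(X))
  } else {
    stop("unknown dataset type: ", type, call. = FALSE)
  }
  genes <- rownames(X)
  label <- as.integer(genes %in% positives)
  if (sum(label) == 0) {
    stop("no positive gene present in the dataset", call. = FALSE)
  }
  out <- data.frame(gene = genes, label = label, X, check.names = TRUE,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# area under the ROC curve via the rank statistic, midranks for ties
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

balanced_fractions <- function(y) {
  tab <- table(y)
  nmin <- min(tab)
  as.numeric(nmin / tab)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_brf <- function(X, y, n_trees, mtry, max_depth, seed) {
  ranger::ranger(
    x = X, y = factor(y, levels = c(0, 1)),
    num.trees = n_trees,
    mtry = mtry,
    max.depth = max_depth,
    probability = TRUE,
    replace = TRUE,
    sample.fraction = balanced_fractions(y),
    seed = seed,
    num.threads = 1
  )
}

predict_brf <- function(fit, X) {
  stats::predict(fit, data = X, num.threads = 1)$predictions[, "1"]
}

#' Default hyperparameter grid for the balanced random forest
#'
#' Tree depth unlimited/10/20 crossed with square-root and log2
#' features-per-split.
#'
#' @param p number of features.
#' @return data frame with columns `max_depth`, `mtry`.
#' @export
brf_grid <- function(p) {
  expand.grid(max_depth = c(0L, 10L, 20L),
              mtry = unique(c(max(1L, floor(sqrt(p))), max(1L, floor(log2(p))))))
}

#' Evaluate ageing-gene prediction under nested cross-validation
#'
#' Balanced random forest (class-balanced per-tree sampling) with
#' hyperparameters tuned by inner-fold AUC, evaluated on pooled out-of-fold
#' probability scores from stratified outer folds. No gene's score comes from
#' a model whose training fold contained it.
#'
#' @param table a [build_feature_table()] result.
#' @param outer_folds,inner_folds fold counts of the nested cross-validation.
#' @param n_trees trees per forest.
#' @param seed random seed controlling folds and forests.
#' @param grid hyperparameter grid (data frame `max_depth`, `mtry`); defaults
#'   to [brf_grid()] on the table's feature count.
#' @return a list with `auc` (pooled out-of-fold AUC), `scores` (named
#'   per-gene out-of-fold probabilities), `fold` (outer fold of each gene),
#'   `chosen` (per-fold selected hyperparameters).
#' @export
evaluate_classifier <- function(table, outer_folds = 10L, inner_folds = 5L,
                                n_trees = 500L, seed = 42L, grid = NULL) {
  stopifnot(all(c("gene", "label") %in% names(table)))
  y <- table$label
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  X <- as.matrix(table[, setdiff(names(table), c("gene", "label")), drop = FALSE])
  rownames(X) <- table$gene
  if (is.null(grid)) grid <- brf_grid(ncol(X))

  set.seed(seed)
  outer <- stratified_folds(y, outer_folds)
  scores <- rep(NA_real_, nrow(X))
  chosen <- vector("list", outer_folds)

  for (o in seq_len(outer_folds)) {
    tr <- outer != o
    if (length(unique(y[tr])) < 2) {
      stop("an outer training fold lost a class; reduce outer_folds", call. = FALSE)
    }
    inner <- stratified_folds(y[tr], inner_folds)
    grid_auc <- vapply(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(seq_len(inner_folds), function(i) {
        itr <- inner != i
        if (length(unique(y[tr][itr])) < 2 || length(unique(y[tr][!itr])) < 2) {
          return(NA_real_)
        }
        fit <- fit_brf(X[tr, , drop = FALSE][itr, , drop = FALSE],
                       y[tr][itr], n_trees, grid$mtry[g], grid$max_depth[g],
                       seed = seed + 1000L * o + 10L * i + g)
        auc_rank(predict_brf(fit, X[tr, , drop = FALSE][!itr, , drop = FALSE]),
                 y[tr][!itr])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(grid_auc)
    chosen[[o]] <- data.frame(fold = o, grid[best, , drop = FALSE],
                              inner_auc = grid_auc[best])
    fit <- fit_brf(X[tr, , drop = FALSE], y[tr], n_trees,
                   grid$mtry[best], grid$max_depth[best],
                   seed = seed + 1000L * o)
    scores[!tr] <- predict_brf(fit, X[!tr, , drop = FALSE])
  }
  list(
    auc = auc_rank(scores, y),
    scores = stats::setNames(scores, table$gene),
    fold = stats::setNames(outer, table$gene),
    chosen = do.call(rbind, chosen)
  )
}

#' Rank novel candidate genes from classifier scores
#'
#' Genes outside the positive set with an out-of-fold probability above the
#' decision threshold, sorted by descending score (ties broken by gene
#' identifier), truncated to the top `top_k`.
#'
#' @param scores named per-gene probability scores.
#' @param positives known positive gene set (excluded from candidates).
#' @param threshold decision threshold (default 0.5).
#' @param top_k number of candidates returned (default 30).
#' @return data frame with columns `gene`, `score`, ranked.
#' @export
rank_candidates <- function(scores, positives, threshold = 0.5, top_k = 30L) {
  stopifnot(!is.null(names(scores)))
  cand <- scores[!(names(scores) %in% positives)]
  cand <- cand[!is.na(cand) & cand > threshold]
  ord <- order(-cand, names(cand))
  out <- data.frame(gene = names(cand)[ord], score = unname(cand[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, top_k)
}
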