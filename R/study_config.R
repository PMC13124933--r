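#' Configuration for a synthetic study
#'
#' Collects the dimensions and planted-signal parameters of a synthetic study:
#' a gene universe with genomic intervals, per-disease significant SNPs with a
#' controllable pleiotropy distribution, an ARD-to-ARC cluster map, four
#' network layers (protein interaction, two coexpression thresholds, pathway),
#' a pathway DAG, a coexpression matrix with planted modules, tissue expression
#' with controllable specificity, and two planted gene sets: a
#' broadly-connected, broadly-expressed "ageing-like" set and a
#' tissue-restricted, network-peripheral "pleiotropic-like" set.
#'
#' @param n_genes number of genes in the universe.
#' @param n_ards number of ageing-related diseases (ARDs).
#' @param n_arcs number of disease clusters (ARCs); must not exceed `n_ards`.
#' @param snps_per_ard number of significant SNPs simulated per ARD.
#' @param pleiotropy_rate probability that a gene associated with one ARD gains
#'   one additional, randomly chosen ARD association.
#' @param n_tissues number of tissues in the expression matrix.
#' @param genes_per_ard number of target genes per ARD; `NULL` picks a value so
#'   that roughly 45% of the non-planted universe is disease-associated.
#' @param planted_ageing_size,planted_pleio_size sizes of the two planted sets.
#' @param layer_specs per-layer generator parameters; see Details.
#' @param seed integer random seed; identical config + seed gives a
#'   bit-identical study.
#'
#' @details `layer_specs` is a list with components
#'   `ppi` (`m`: preferential-attachment edges per node; `planted_degree`:
#'   planted edges from each ageing-like gene to disease genes; `planted_arcs`:
#'   distinct ARCs those edges cover),
#'   `cox` (`background`: mean background absolute correlation;
#'   `ageing_within`, `arc_within`: planted within-module correlations;
#'   `module_size`: genes per ARC module; `cross_links`: planted
#'   ageing-to-disease correlations per ageing gene),
#'   `kegg` (`depth`: number of DAG layers; `prop_genes`: fraction of the
#'   universe annotated to the pathway DAG; `planted_arcs`: distinct ARCs the
#'   planted ageing cross-edges cover), and
#'   `expr` (`dominant_fold`: fold-enrichment of the single dominant tissue of
#'   pleiotropic-like genes; `uniform_low`: lower bound of the near-uniform
#'   expression of ageing-like genes, relative to their maximum).
#'
#' @return an object of class `study_config` (a validated list).
#' @seealso [generate_study()]
#' @export
study_config <- function(n_genes = 1000L,
                         n_ards = 57L,
                         n_arcs = 8L,
                         snps_per_ard = 12L,
                         pleiotropy_rate = 0.15,
                         n_tissues = 30L,
                         genes_per_ard = NULL,
                         planted_ageing_size = 60L,
                         planted_pleio_size = 40L,
                         layer_specs = list(),
                         seed = 42L) {
  defaults <- list(
    ppi  = list(m = 3L, planted_degree = 12L, planted_arcs = 6L),
    cox  = list(background = 0.15, ageing_within = 0.97, arc_within = 0.93,
                module_size = 30L, cross_links = 2L),
    kegg = list(depth = 6L, prop_genes = 0.5, planted_arcs = 4L),
    expr = list(dominant_fold = 50, uniform_low = 0.92)
  )
  for (nm in names(layer_specs)) {
    defaults[[nm]][names(layer_specs[[nm]])] <- layer_specs[[nm]]
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_ards = as.integer(n_ards),
    n_arcs = as.integer(n_arcs),
    snps_per_ard = as.integer(snps_per_ard),
    pleiotropy_rate = pleiotropy_rate,
    n_tissues = as.integer(n_tissues),
    genes_per_ard = if (is.null(genes_per_ard)) NULL else as.integer(genes_per_ard),
    planted_ageing_size = as.integer(planted_ageing_size),
    planted_pleio_size = as.integer(planted_pleio_size),
    layer_specs = defaults,
    seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_ards, cfg$n_arcs, cfg$snps_per_ard,
              cfg$n_tissues, cfg$planted_ageing_size, cfg$planted_pleio_size)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("all study_config counts must be positive", call. = FALSE)
  }
  if (cfg$n_arcs > cfg$n_ards) {
    stop("n_arcs must not exceed n_ards", call. = FALSE)
  }
  if (cfg$pleiotropy_rate < 0 || cfg$pleiotropy_rate > 1) {
    stop("pleiotropy_rate must be a probability in [0, 1]", call. = FALSE)
  }
  if (cfg$planted_ageing_size + cfg$planted_pleio_size > cfg$n_genes) {
    stop("planted set sizes exceed n_genes", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  genes: %d  ARDs: %d  ARCs: %d  tissues: %d\n",
              x$n_genes, x$n_ards, x$n_arcs, x$n_tissues))
  cat(sprintf("  SNPs/ARD: %d  pleiotropy rate: %.2f  seed: %d\n",
              x$snps_per_ard, x$pleiotropy_rate, x$seed))
  cat(sprintf("  planted sets: %d ageing-like, %d pleiotropic-like\n",
              x$planted_ageing_size, x$planted_pleio_size))
  invisible(x)
}

# Deterministic identifier vocabularies shared by generator and readers.
gene_names <- function(n) sprintf("G%05d", seq_len(n))
ard_names <- function(n) sprintf("ARD%02d", seq_len(n))
arc_names <- function(n) sprintf("ARC%d", seq_len(n))
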