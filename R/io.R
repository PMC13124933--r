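#' Write a synthetic study to disk in the pipeline's plain-text formats
#'
#' Writes the same file formats the real-data mode reads: gene ranges
#' (BED-like TSV with 1-based inclusive coordinates), SNP table TSV, ARC map
#' TSV, one edge-list TSV per network layer, a directed edge list for the
#' pathway DAG, the coexpression matrix TSV, the gene-by-tissue expression TSV
#' and one plain-text gene-set file per planted set.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the character vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "layers"), showWarnings = FALSE)
  files <- c(
    gene_ranges = file.path(dir, "gene_ranges.tsv"),
    snp_table = file.path(dir, "snp_table.tsv"),
    arc_map = file.path(dir, "arc_map.tsv"),
    kegg_dag = file.path(dir, "kegg_dag.tsv"),
    coexpr = file.path(dir, "coexpression_matrix.tsv"),
    expression = file.path(dir, "expression.tsv"),
    ageing_like = file.path(dir, "ageing_like.txt"),
    pleio_like = file.path(dir, "pleio_like.txt")
  )
  write_tsv(study$gene_ranges, files["gene_ranges"])
  write_tsv(study$snp_table, files["snp_table"])
  write_tsv(study$arc_map, files["arc_map"])
  write_tsv(igraph::as_data_frame(study$kegg_dag, "edges"), files["kegg_dag"])
  write_matrix_tsv(study$coexpr, files["coexpr"])
  write_matrix_tsv(study$expression, files["expression"])
  writeLines(study$ageing_like, files["ageing_like"])
  writeLines(study$pleio_like, files["pleio_like"])
  for (nm in names(study$layers)) {
    f <- file.path(dir, "layers", paste0(nm, ".tsv"))
    write_edge_list(study$layers[[nm]], f)
    files[paste0("layer_", nm)] <- f
  }
  invisible(files)
}

#' Read a study back from the files written by [write_study()]
#'
#' This is the package's "real-data mode" entry point: any directory holding
#' files in these formats (GWAS SNP tables, gene ranges, disease cluster map,
#' per-layer edge lists, coexpression and expression matrices, gene-set lists)
#' can be loaded and run through the pipeline.
#'
#' @param dir directory containing the study files.
#' @return a list with the same components as a [generate_study()] result
#'   (minus `truth` and `config`).
#' @export
read_study <- function(dir) {
  need <- file.path(dir, c("gene_ranges.tsv", "snp_table.tsv", "arc_map.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("missing study input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  layer_files <- list.files(file.path(dir, "layers"), pattern = "\\.tsv$",
                            full.names = TRUE)
  layers <- lapply(layer_files, read_edge_list)
  names(layers) <- sub("\\.tsv$", "", basename(layer_files))
  out <- list(
    gene_ranges = read_tsv(file.path(dir, "gene_ranges.tsv")),
    snp_table = read_tsv(file.path(dir, "snp_table.tsv")),
    arc_map = read_tsv(file.path(dir, "arc_map.tsv")),
    layers = layers,
    kegg_dag = if (file.exists(file.path(dir, "kegg_dag.tsv"))) {
      igraph::graph_from_data_frame(read_tsv(file.path(dir, "kegg_dag.tsv")),
                                    directed = TRUE)
    },
    coexpr = if (file.exists(file.path(dir, "coexpression_matrix.tsv"))) {
      read_matrix_tsv(file.path(dir, "coexpression_matrix.tsv"))
    },
    expression = if (file.exists(file.path(dir, "expression.tsv"))) {
      read_matrix_tsv(file.path(dir, "expression.tsv"))
    },
    ageing_like = if (file.exists(file.path(dir, "ageing_like.txt"))) {
      readLines(file.path(dir, "ageing_like.txt"))
    },
    pleio_like = if (file.exists(file.path(dir, "pleio_like.txt"))) {
      readLines(file.path(dir, "pleio_like.txt"))
    }
  )
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read an undirected network layer as a two-column edge-list TSV
#'
#' @param layer an igraph object with named vertices.
#' @param path file path.
#' @return `write_edge_list` invisibly returns `path`; `read_edge_list` returns
#'   an undirected simple igraph object (an optional third weight column is
#'   ignored).
#' @export
write_edge_list <- function(layer, path) {
  write_tsv(igraph::as_data_frame(layer, "edges")[, c("from", "to")], path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- read_tsv(path)
  igraph::simplify(igraph::graph_from_data_frame(df[, 1:2], directed = FALSE))
}

#' Summarise a network layer (node/edge counts and gene-set coverage)
#'
#' @param layer an igraph layer.
#' @param sets optional named list of gene sets; coverage (members present in
#'   the layer) is reported for each.
#' @return a list suitable for JSON serialisation.
#' @export
layer_summary <- function(layer, sets = list()) {
  nodes <- igraph::V(layer)$name
  list(
    nodes = igraph::vcount(layer),
    edges = igraph::ecount(layer),
    coverage = lapply(sets, function(s) {
      list(size = length(s), present = sum(s %in% nodes))
    })
  )
}
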