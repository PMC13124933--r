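#' Map significant SNPs to genes within the gene body or a flanking window
#'
#' A SNP is assigned to a gene when its position falls inside the gene body or
#' within `flank` base pairs of either boundary (boundaries inclusive, 1-based
#' coordinates). A SNP overlapping several genes is assigned to all of them,
#' and a gene is associated with every disease any of its SNPs carries.
#' Duplicate (gene, disease) pairs are collapsed: pleiotropy counts distinct
#' traits.
#'
#' @param snps data frame with columns `snp`, `chrom`, `pos`, `ard_id`.
#' @param ranges data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param flank flanking window in base pairs (default 10 kb).
#' @param arc_map optional data frame `ard_id`, `arc_id`; when supplied,
#'   gene-to-ARC associations are derived by aggregating ARDs through the map.
#' @return an object of class `gene_trait_associations`: a list with `ard`
#'   (data frame `gene`, `ard_id`) and `arc` (data frame `gene`, `arc_id`, or
#'   `NULL` when no `arc_map` was given).
#' @export
map_snps_to_genes <- function(snps, ranges, flank = 10000, arc_map = NULL) {
  stopifnot(all(c("snp", "chrom", "pos", "ard_id") %in% names(snps)),
            all(c("gene", "chrom", "start", "end") %in% names(ranges)))
  if (flank < 0) stop("flank must be non-negative", call. = FALSE)
  if (any(!is.finite(ranges$start)) || any(!is.finite(ranges$end)) ||
      any(ranges$start > ranges$end)) {
    stop("malformed gene coordinates: need finite start <= end", call. = FALSE)
  }
  if (any(!is.finite(snps$pos))) {
    stop("malformed SNP coordinates", call. = FALSE)
  }
  ranges <- unique(ranges[, c("gene", "chrom", "start", "end")])

  known <- snps$chrom %in% unique(ranges$chrom)
  if (any(!known)) {
    warning(sprintf("skipping %d SNP(s) on chromosome(s) absent from the gene ranges: %s",
                    sum(!known),
                    paste(unique(snps$chrom[!known]), collapse = ", ")))
    snps <- snps[known, , drop = FALSE]
  }

  assoc <- if (nrow(snps) == 0) {
    data.frame(gene = character(0), ard_id = character(0),
               stringsAsFactors = FALSE)
  } else {
    gr_genes <- GenomicRanges::GRanges(
      seqnames = ranges$chrom,
      ranges = IRanges::IRanges(start = pmax(1L, ranges$start - as.integer(flank)),
                                end = ranges$end + as.integer(flank))
    )
    gr_snps <- GenomicRanges::GRanges(
      seqnames = snps$chrom,
      ranges = IRanges::IRanges(start = snps$pos, width = 1L)
    )
    hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes, ignore.strand = TRUE)
    unique(data.frame(
      gene = ranges$gene[S4Vectors::subjectHits(hits)],
      ard_id = snps$ard_id[S4Vectors::queryHits(hits)],
      stringsAsFactors = FALSE
    ))
  }
  assoc <- assoc[order(assoc$gene, assoc$ard_id), , drop = FALSE]
  rownames(assoc) <- NULL

  arc <- NULL
  if (!is.null(arc_map)) {
    stopifnot(all(c("ard_id", "arc_id") %in% names(arc_map)))
    missing_ards <- setdiff(unique(assoc$ard_id), arc_map$ard_id)
    if (length(missing_ards) > 0) {
      stop("arc_map does not cover ARD(s): ",
           paste(missing_ards, collapse = ", "), call. = FALSE)
    }
    arc <- unique(data.frame(
      gene = assoc$gene,
      arc_id = arc_map$arc_id[match(assoc$ard_id, arc_map$ard_id)],
      stringsAsFactors = FALSE
    ))
    arc <- arc[order(arc$gene, arc$arc_id), , drop = FALSE]
    rownames(arc) <- NULL
  }
  structure(list(ard = assoc, arc = arc), class = "gene_trait_associations")
}

#' @export
print.gene_trait_associations <- function(x, ...) {
  cat(sprintf("gene-trait associations: %d gene-ARD pairs over %d genes",
              nrow(x$ard), length(unique(x$ard$gene))))
  if (!is.null(x$arc)) {
    cat(sprintf("; %d gene-ARC pairs", nrow(x$arc)))
  }
  cat("\n")
  invisible(x)
}

#' Build associations directly from gene/trait pair tables
#'
#' Convenience constructor used when associations are already known (e.g. toy
#' examples or planted truth) rather than derived from SNP positions.
#'
#' @param ard data frame with columns `gene`, `ard_id`.
#' @param arc_map optional data frame `ard_id`, `arc_id`.
#' @return a `gene_trait_associations` object.
#' @export
associations_from_pairs <- function(ard, arc_map = NULL) {
  ard <- unique(ard[, c("gene", "ard_id")])
  arc <- NULL
  if (!is.null(arc_map)) {
    arc <- unique(data.frame(
      gene = ard$gene,
      arc_id = arc_map$arc_id[match(ard$ard_id, arc_map$ard_id)],
      stringsAsFactors = FALSE
    ))
  }
  structure(list(ard = ard, arc = arc), class = "gene_trait_associations")
}

#' Direct pleiotropy profiles at disease and disease-cluster level
#'
#' For every associated gene, counts the number of distinct ARDs
#' (ARD-Pleiotropy) and distinct ARCs (ARC-Pleiotropy) it is directly
#' associated with through GWAS, and classifies genes associated with four or
#' more ARCs as `high` ARC-Pleiotropy (otherwise `low`). Genes with no
#' association are absent from the output.
#'
#' @param assoc a [map_snps_to_genes()] result with ARC aggregation.
#' @param high_cutoff minimum number of distinct ARCs for the `high` class.
#' @return data frame with columns `gene`, `ard_pleiotropy`, `arc_pleiotropy`,
#'   `pleiotropy_class`.
#' @export
compute_pleiotropy <- function(assoc, high_cutoff = 4L) {
  stopifnot(inherits(assoc, "gene_trait_associations"))
  if (is.null(assoc$arc)) {
    stop("ARC-level associations are required; supply arc_map to map_snps_to_genes()",
         call. = FALSE)
  }
  ard_n <- table(assoc$ard$gene)
  arc_n <- table(assoc$arc$gene)
  genes <- sort(names(ard_n))
  out <- data.frame(
    gene = genes,
    ard_pleiotropy = as.integer(ard_n[genes]),
    arc_pleiotropy = as.integer(arc_n[genes]),
    stringsAsFactors = FALSE
  )
  out$pleiotropy_class <- ifelse(out$arc_pleiotropy >= high_cutoff, "high", "low")
  stopifnot(all(out$arc_pleiotropy <= out$ard_pleiotropy))
  rownames(out) <- NULL
  out
}
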