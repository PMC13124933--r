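#' Mean absolute coexpression within a gene set
#'
#' Mean of the `n (n - 1) / 2` off-diagonal lower-triangle entries of the
#' set's submatrix of the coexpression matrix; the unit diagonal is ignored.
#' Genes absent from the matrix are dropped.
#'
#' @param coexpr gene-labelled symmetric matrix of absolute correlations.
#' @param genes gene set.
#' @return the mean, or `NA` with a warning when fewer than two members are
#'   present in the matrix.
#' @export
intra_set_coexpression <- function(coexpr, genes) {
  present <- intersect(unique(genes), rownames(coexpr))
  if (length(present) < 2) {
    warning("fewer than 2 set members present in the coexpression matrix")
    return(NA_real_)
  }
  sub <- coexpr[present, present]
  mean(sub[lower.tri(sub)])
}

#' Mean absolute coexpression between two (possibly overlapping) gene sets
#'
#' Every unordered gene pair with one member in each set is counted exactly
#' once, and self-pairs are excluded. The mean is assembled from three
#' components: (i) pairs among the overlapping genes (upper triangle of the
#' overlap submatrix), (ii) pairs of genes exclusive to the first set with all
#' genes of the second, and (iii) pairs of genes exclusive to the second set
#' with the overlapping genes of the first (their pairs with the first set's
#' exclusive genes are already covered by component ii). With `A == B` the
#' result equals [intra_set_coexpression()].
#'
#' @param coexpr gene-labelled symmetric matrix of absolute correlations.
#' @param A,B gene sets (genes absent from the matrix are dropped).
#' @return the mean over all valid pairs, or `NA` with a warning when no valid
#'   pair exists.
#' @export
inter_set_coexpression <- function(coexpr, A, B) {
  genes <- rownames(coexpr)
  A <- intersect(unique(A), genes)
  B <- intersect(unique(B), genes)
  if (length(A) == 0 || length(B) == 0) {
    warning("a set has no member present in the coexpression matrix")
    return(NA_real_)
  }
  overlap <- intersect(A, B)
  a_only <- setdiff(A, B)
  b_only <- setdiff(B, A)

  vals <- numeric(0)
  if (length(overlap) >= 2) {
    sub <- coexpr[overlap, overlap]
    vals <- c(vals, sub[upper.tri(sub)])
  }
  if (length(a_only) > 0 && length(B) > 0) {
    vals <- c(vals, as.vector(coexpr[a_only, B, drop = FALSE]))
  }
  if (length(b_only) > 0 && length(overlap) > 0) {
    vals <- c(vals, as.vector(coexpr[b_only, overlap, drop = FALSE]))
  }
  if (length(vals) == 0) {
    warning("no valid gene pair between the two sets")
    return(NA_real_)
  }
  mean(vals)
}

#' Group-by-group coexpression matrix
#'
#' Intra-set means on the diagonal and inter-set means off the diagonal, over
#' an arbitrary collection of (possibly overlapping) gene groups.
#'
#' @param coexpr gene-labelled symmetric matrix of absolute correlations.
#' @param groups named list of gene sets.
#' @return symmetric numeric matrix of group-level mean coexpression.
#' @export
coexpression_set_matrix <- function(coexpr, groups) {
  k <- length(groups)
  out <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) {
    out[i, i] <- suppressWarnings(intra_set_coexpression(coexpr, groups[[i]]))
    if (i < k) {
      for (j in seq(i + 1L, k)) {
        v <- suppressWarnings(inter_set_coexpression(coexpr, groups[[i]], groups[[j]]))
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  out
}
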