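#' Tau tissue-specificity index
#'
#' The standard specificity index over a gene-by-tissue expression matrix:
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)` over `N` tissues. Tau is 0 for
#' perfectly uniform expression, 1 for expression restricted to a single
#' tissue, and is invariant to rescaling a gene's expression row.
#'
#' @param expression gene-by-tissue matrix of non-negative expression values
#'   (RPKM-like); rows with all-zero expression are excluded with a message.
#' @param log_transform apply `log2(x + 1)` before computing Tau.
#' @return named numeric vector of Tau values in `[0, 1]`.
#' @export
compute_tau <- function(expression, log_transform = FALSE) {
  stopifnot(is.matrix(expression))
  if (ncol(expression) < 2) {
    stop("Tau requires at least two tissues", call. = FALSE)
  }
  if (any(expression < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  zero <- rowSums(expression) == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with all-zero expression excluded from Tau")
    expression <- expression[!zero, , drop = FALSE]
  }
  if (log_transform) expression <- log2(expression + 1)
  mx <- apply(expression, 1, max)
  tau <- rowSums(1 - expression / mx) / (ncol(expression) - 1)
  stats::setNames(tau, rownames(expression))
}
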