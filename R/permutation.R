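#' Empirical two-tailed permutation p-value
#'
#' Counts the permuted values at least as far from the null mean as the
#' observation and applies the add-one correction `(r + 1) / (n + 1)`, so the
#' smallest achievable p-value with `n` permutations is `1 / (n + 1)` and the
#' p-value is 1 when the observation sits exactly at the null mean.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of permuted statistics.
#' @param null_mean centre of the null; defaults to `mean(null_values)`.
#' @return the empirical two-tailed probability.
#' @export
empirical_p_two_tailed <- function(observed, null_values,
                                   null_mean = mean(null_values)) {
  stopifnot(length(null_values) > 0)
  r <- sum(abs(null_values - null_mean) >= abs(observed - null_mean))
  (r + 1) / (length(null_values) + 1)
}

#' Size-matched permutation test of a gene-set mean
#'
#' Compares the mean of a per-gene statistic over an observed gene set against
#' a null distribution of means over `n_perm` random sets of the same size
#' drawn without replacement from a background universe.
#'
#' @param values named numeric vector: the statistic for every gene of the
#'   universe.
#' @param observed_set gene set whose mean is tested (must be contained in the
#'   universe).
#' @param universe background gene universe; defaults to `names(values)`.
#' @param n_perm number of permutations (default 10,000).
#' @param seed random seed (default 42).
#' @param alternative `"two.sided"` (absolute deviation from the null mean) or
#'   `"greater"` / `"less"` one-tailed variants.
#' @param family_size Bonferroni family size used for `p_adj` (declared by the
#'   caller, never inferred; default 1).
#' @param label optional statistic label carried into the result.
#' @return an object of class `permutation_result`: a list with `statistic`,
#'   `observed`, `null_mean`, `null_sd`, `difference`, `z`, `p`, `p_adj`,
#'   `n_perm`, `n_set`.
#' @export
permutation_null_mean <- function(values, observed_set,
                                  universe = names(values),
                                  n_perm = 10000L, seed = 42L,
                                  alternative = c("two.sided", "greater", "less"),
                                  family_size = 1L,
                                  label = "mean") {
  alternative <- match.arg(alternative)
  stopifnot(!is.null(names(values)))
  universe <- intersect(universe, names(values))
  observed_set <- unique(observed_set)
  if (!all(observed_set %in% universe)) {
    stop("observed_set must be contained in the universe", call. = FALSE)
  }
  k <- length(observed_set)
  if (k > length(universe)) {
    stop("observed set larger than the universe", call. = FALSE)
  }
  v <- values[universe]
  observed <- mean(values[observed_set])

  set.seed(seed)
  nulls <- vapply(seq_len(n_perm), function(i) {
    mean(v[sample.int(length(v), k)])
  }, numeric(1))

  null_mean <- mean(nulls)
  null_sd <- stats::sd(nulls)
  p <- switch(alternative,
    two.sided = empirical_p_two_tailed(observed, nulls, null_mean),
    greater = (sum(nulls >= observed) + 1) / (n_perm + 1),
    less = (sum(nulls <= observed) + 1) / (n_perm + 1)
  )
  structure(list(
    statistic = label,
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    difference = observed - null_mean,
    z = if (is.finite(null_sd) && null_sd > 0) (observed - null_mean) / null_sd else NA_real_,
    p = p,
    p_adj = min(1, p * family_size),
    n_perm = as.integer(n_perm),
    n_set = k
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s): observed %.4g vs null %.4g (sd %.3g), p = %.3g, p_adj = %.3g [%d perms, set size %d]\n",
              x$statistic, x$observed, x$null_mean, x$null_sd,
              x$p, x$p_adj, x$n_perm, x$n_set))
  invisible(x)
}

#' Convert permutation results to a results table
#'
#' @param results list of `permutation_result` objects (optionally named).
#' @return data frame mirroring the layout used in the group-comparison
#'   tables: label, observed, null mean/sd, difference, z, p, p_adj.
#' @export
permutation_table <- function(results) {
  do.call(rbind, lapply(seq_along(results), function(i) {
    x <- results[[i]]
    data.frame(
      statistic = if (!is.null(names(results))) names(results)[i] else x$statistic,
      observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
      difference = x$difference, z = x$z, p = x$p, p_adj = x$p_adj,
      n_perm = x$n_perm, n_set = x$n_set,
      stringsAsFactors = FALSE
    )
  }))
}

#' Pairwise rank-sum comparisons between gene groups
#'
#' Two-sided Wilcoxon rank-sum tests over all unordered pairs of groups, with
#' Bonferroni correction over a caller-declared family size (default: the
#' number of testable pairs, e.g. 10 for five groups). Groups may overlap;
#' every gene assigned to a group enters that group's sample. Pairs in which
#' either group has fewer than two genes with values are skipped and reported.
#'
#' @param values named numeric vector of the per-gene statistic.
#' @param groups named list of gene sets.
#' @param family_size Bonferroni family size; `NULL` uses the number of tested
#'   pairs.
#' @return data frame with columns `group1`, `group2`, `n1`, `n2`, `W`, `p`,
#'   `p_adj`, `skipped`.
#' @export
pairwise_group_tests <- function(values, groups, family_size = NULL) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- values[intersect(groups[[g1]], names(values))]
    y <- values[intersect(groups[[g2]], names(values))]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
                        W = NA_real_, p = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
               W = unname(wt$statistic), p = wt$p.value, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(family_size)) family_size <- sum(!out$skipped)
  out$p_adj <- pmin(1, out$p * family_size)
  out
}
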