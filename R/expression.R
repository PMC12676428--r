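#' Assign genes to targeting groups
#'
#' Partitions the genes of an expression table into `top_targets` (the
#' cumulative-coverage top set intersected with expressed genes),
#' `lower_targets` (remaining genes with targeting weight) and `non_targets`
#' (expressed genes with zero targeting weight).
#'
#' @param rank_table rank table from [aggregate_by_gene()].
#' @param expression_table data.frame with columns `gene_id`, `log2fc` (and
#'   optionally `padj`).
#' @param coverage cumulative-coverage threshold for the top set.
#' @return named list of character vectors `top_targets`, `lower_targets`,
#'   `non_targets` (a partition of the expression table's genes).
#' @export
assign_groups <- function(rank_table, expression_table, coverage = 0.70) {
  expressed <- expression_table$gene_id
  top <- intersect(top_target_set(rank_table, coverage), expressed)
  if (!length(intersect(rank_table$gene_id, expressed))) {
    stop("assign_groups: no overlap between ranked and expressed genes")
  }
  lower <- setdiff(intersect(rank_table$gene_id, expressed), top)
  non <- setdiff(expressed, rank_table$gene_id)
  list(top_targets = top, lower_targets = lower, non_targets = non)
}

# Kolmogorov distribution function K(x) = P(sup|B(t)| <= x), evaluated to
# machine precision via the two Jacobi theta representations.
pkolmogorov <- function(x) {
  if (x < 0.05) return(0)
  if (x < 1) {
    k <- 1:20
    sqrt(2 * pi) / x * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * x^2)))
  } else {
    k <- 1:100
    1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  }
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is computed exactly by evaluating both empirical cumulative
#' distribution functions at every sample point (ties handled by evaluating
#' the supremum at the pooled unique values); the two-sided p-value comes
#' from the asymptotic Kolmogorov distribution with effective size
#' `n1 * n2 / (n1 + n2)`. A warning is issued below 8 observations per
#' sample, where the asymptotic approximation is poor.
#'
#' @param a,b numeric samples.
#' @return list of class `ks_result`: `D`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("ks_two_sample: empty sample")
  if (n1 < 8L || n2 < 8L) {
    warning("ks_two_sample: fewer than 8 observations per sample; asymptotic p unreliable")
  }
  z <- sort(unique(c(a, b)))
  f1 <- findInterval(z, sort(a)) / n1
  f2 <- findInterval(z, sort(b)) / n2
  D <- max(abs(f1 - f2))
  n_eff <- n1 * n2 / (n1 + n2)
  p <- 1 - pkolmogorov(sqrt(n_eff) * D)
  structure(list(D = D, p_value = min(max(p, 0), 1), n1 = n1, n2 = n2),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.3g (n1 = %d, n2 = %d)\n",
              x$D, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' ECDF table of expression changes by group
#'
#' Convenience export of group-wise empirical cumulative distribution
#' functions for plotting.
#'
#' @param expression_table data.frame with `gene_id`, `log2fc`.
#' @param groups list from [assign_groups()].
#' @return data.frame with `group`, `log2fc`, `ecdf`.
#' @export
group_ecdf_table <- function(expression_table, groups) {
  out <- lapply(names(groups), function(g) {
    v <- expression_table$log2fc[expression_table$gene_id %in% groups[[g]]]
    if (!length(v)) return(NULL)
    v <- sort(v)
    data.frame(group = g, log2fc = v, ecdf = seq_along(v) / length(v))
  })
  do.call(rbind, out)
}
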