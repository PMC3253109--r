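#' Per-sample normalization factor
#'
#' The normalization factor (NF) of a sample is the geometric mean of the
#' selected reference genes' relative quantities in that sample; with a
#' single reference gene the NF is just that gene's quantity profile.
#'
#' @param qm a `quantity_matrix`.
#' @param genes non-empty subset of reference genes in `qm`.
#' @return positive numeric vector named by sample.
#' @export
normalization_factor <- function(qm, genes) {
  stopifnot(inherits(qm, "quantity_matrix"))
  if (length(genes) == 0L) stop("empty reference-gene subset", call. = FALSE)
  absent <- setdiff(genes, qm$genes)
  if (length(absent) > 0L) {
    stop("gene(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  2^colMeans(log2(qm$q[genes, , drop = FALSE]))
}

#' Pairwise variation V_n/n+1 between consecutive normalization factors
#'
#' Measures how much the normalization factor changes when the (n+1)-th
#' ranked reference gene is added: the dispersion across samples of
#' log2(NF_n / NF_{n+1}), where NF_n uses the top-n genes of the
#' stability-ordered list.  The default dispersion is the sample standard
#' deviation (the geNorm convention); `metric = "variance"` squares it.
#'
#' @param qm a `quantity_matrix`.
#' @param genes stability-ordered reference genes (rank 1 first); a
#'   `stability_ranking` is accepted.
#' @param n number of genes in the smaller normalizer, `1 <= n <= G - 1`.
#' @param metric `"sd"` (default) or `"variance"`.
#' @return non-negative scalar.
#' @export
pairwise_variation <- function(qm, genes, n, metric = c("sd", "variance")) {
  metric <- match.arg(metric)
  genes <- ranked_genes(genes)
  if (n < 1L || n > length(genes) - 1L) {
    stop("n must satisfy 1 <= n <= ", length(genes) - 1L, call. = FALSE)
  }
  nf_n <- normalization_factor(qm, genes[seq_len(n)])
  nf_n1 <- normalization_factor(qm, genes[seq_len(n + 1L)])
  v <- stats::sd(log2(nf_n / nf_n1))
  if (metric == "variance") v^2 else v
}

#' The full pairwise-variation series V_1/2 .. V_{G-1}/G
#'
#' Computes [pairwise_variation()] for every n from 1 upward, including
#' genes strictly in stability-rank order.  Starting the series at V_1/2
#' (rather than V_3/4) preserves the possibility that one or two properly
#' validated reference genes already suffice for normalization.
#'
#' @inheritParams pairwise_variation
#' @param ranking a `stability_ranking` or stability-ordered character
#'   vector of at least 2 genes.
#' @return a `pairwise_variation_series` data frame with columns `n`,
#'   `label` (e.g. `"V_5/6"`), `v`; attributes `ranked_genes`, `metric`.
#' @export
pairwise_variation_series <- function(qm, ranking,
                                      metric = c("sd", "variance")) {
  metric <- match.arg(metric)
  genes <- ranked_genes(ranking)
  G <- length(genes)
  if (G < 2L) stop("need >= 2 ranked genes", call. = FALSE)
  n <- seq_len(G - 1L)
  v <- vapply(n, function(k) pairwise_variation(qm, genes, k, metric),
              numeric(1L))
  out <- data.frame(n = n, label = sprintf("V_%d/%d", n, n + 1L), v = v,
                    stringsAsFactors = FALSE)
  attr(out, "ranked_genes") <- genes
  attr(out, "metric") <- metric
  class(out) <- c("pairwise_variation_series", "data.frame")
  out
}

#' Optimal number of reference genes
#'
#' The n whose V_n/n+1 is minimal: adding the (n+1)-th gene past this point
#' no longer stabilizes the normalization factor.  Ties go to the smallest
#' n, favoring the more parsimonious normalizer.
#'
#' @param series a [pairwise_variation_series()] result.
#' @return integer n.
#' @export
optimal_reference_count <- function(series) {
  stopifnot(inherits(series, "pairwise_variation_series") ||
              (is.data.frame(series) && all(c("n", "v") %in% names(series))))
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  series$n[which.min(series$v)]
}
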