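#' Efficiency-corrected delta-delta-Ct normalization of target genes
#'
#' For each target gene and unknown sample the normalized relative
#' expression is
#' \deqn{value[t, s] = q_t[s] / NF[s]}
#' where quantities q use the control-mean calibrator (each gene's Ct is
#' referenced to its mean Ct over control-type samples, the delta-delta-Ct
#' construct) and NF is the geometric mean of the top `n_refs` reference
#' genes' quantities.  By construction the control-type geometric mean of
#' `value` is exactly 1 for every gene, so values read directly as fold
#' change relative to the control condition.
#'
#' @param table a `ct_table`.
#' @param control control `type` label.
#' @param ref_genes ordered reference-gene list (most stable first, e.g.
#'   from the top of the M-value sheet, or user-chosen).
#' @param n_refs how many of `ref_genes` to use (default: all).
#' @param targets target genes to normalize (default: every unknown-record
#'   gene not among the used references).  A reference gene listed among
#'   targets is an error.
#' @param efficiencies per-gene PCR efficiency as in
#'   [build_quantity_matrix()]; default E = 1.
#' @return a `normalized_expression` data frame: `gene`, `sample`, `type`,
#'   `value`, `log2_value`, one row per target x sample.
#' @export
normalize_targets <- function(table, control, ref_genes,
                              n_refs = length(ref_genes), targets = NULL,
                              efficiencies = NULL) {
  stopifnot(inherits(table, "ct_table"))
  if (n_refs < 1L || n_refs > length(ref_genes)) {
    stop("n_refs must be between 1 and length(ref_genes)", call. = FALSE)
  }
  refs <- ref_genes[seq_len(n_refs)]
  unk_genes <- unique(table$gene[table$role == "unknown"])
  if (is.null(targets)) targets <- setdiff(unk_genes, ref_genes)
  if (length(targets) == 0L) stop("no target genes to normalize",
                                  call. = FALSE)
  overlap <- intersect(refs, targets)
  if (length(overlap) > 0L) {
    stop("gene(s) listed as both reference and target: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  qm <- build_quantity_matrix(table, genes = union(refs, targets),
                              efficiencies = efficiencies,
                              calibrator = "control_mean", control = control)
  missing_refs <- setdiff(refs, qm$genes)
  if (length(missing_refs) > 0L) {
    stop("reference gene(s) lost to missing data: ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  }
  targets <- intersect(targets, qm$genes)
  nf <- normalization_factor(qm, refs)
  vals <- sweep(qm$q[targets, , drop = FALSE], 2L, nf, `/`)
  out <- data.frame(
    gene = rep(targets, times = length(qm$samples)),
    sample = rep(qm$samples, each = length(targets)),
    type = rep(unname(qm$sample_types[qm$samples]), each = length(targets)),
    value = as.vector(vals),
    stringsAsFactors = FALSE
  )
  out$log2_value <- log2(out$value)
  out <- out[order(match(out$gene, targets), match(out$sample, qm$samples)), ]
  rownames(out) <- NULL
  attr(out, "control") <- control
  attr(out, "ref_genes") <- refs
  class(out) <- c("normalized_expression", "data.frame")
  out
}

#' Expression ratios with t-tests and FDR adjustment
#'
#' For every (target gene, non-control treatment type) pair, compares the
#' log2 normalized expression between treated and control samples:
#' the fold change is \eqn{R = 2^d} with d the difference of group means on
#' the log2 scale; its standard error is the delta-method back-transform
#' \eqn{SE_R = R \ln 2 \, SE(d)}; the p value is a two-tailed two-sample
#' Student's t-test on the log2 values (pooled variance by default, Welch
#' with `var_equal = FALSE`); and p values are Benjamini-Hochberg adjusted
#' across all rows produced by the call.
#'
#' @param normed a [normalize_targets()] result.
#' @param targets genes to report (default: all in `normed`).
#' @param control control `type` label (default: recorded in `normed`).
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return an `expression_ratio_table` data frame: `gene`, `type`, `ratio`,
#'   `se_ratio`, `log2_ratio`, `se_log2`, `t`, `p`, `p_adj`, `n_control`,
#'   `n_treated`.
#' @export
expression_ratios <- function(normed, targets = NULL, control = NULL,
                              var_equal = TRUE) {
  stopifnot(inherits(normed, "normalized_expression") ||
              (is.data.frame(normed) &&
                 all(c("gene", "type", "log2_value") %in% names(normed))))
  if (is.null(control)) control <- attr(normed, "control")
  if (is.null(control)) stop("control type label required", call. = FALSE)
  if (is.null(targets)) targets <- unique(normed$gene)
  treatments <- setdiff(unique(normed$type), control)
  if (length(treatments) == 0L) stop("no non-control treatment types",
                                     call. = FALSE)
  rows <- list()
  for (g in targets) {
    ctrl <- normed$log2_value[normed$gene == g & normed$type == control]
    if (length(ctrl) < 2L) {
      stop("gene '", g, "', type '", control, "': < 2 samples", call. = FALSE)
    }
    for (tr in treatments) {
      trt <- normed$log2_value[normed$gene == g & normed$type == tr]
      if (length(trt) < 2L) {
        stop("gene '", g, "', type '", tr, "': < 2 samples", call. = FALSE)
      }
      n1 <- length(ctrl); n2 <- length(trt)
      d <- mean(trt) - mean(ctrl)
      if (var_equal) {
        sp2 <- ((n1 - 1L) * stats::var(ctrl) + (n2 - 1L) * stats::var(trt)) /
          (n1 + n2 - 2L)
        se_d <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2L
      } else {
        v1 <- stats::var(ctrl) / n1; v2 <- stats::var(trt) / n2
        se_d <- sqrt(v1 + v2)
        df <- (v1 + v2)^2 / (v1^2 / (n1 - 1L) + v2^2 / (n2 - 1L))
      }
      tstat <- if (se_d == 0) {
        if (d == 0) 0 else sign(d) * Inf   # degenerate zero-variance groups
      } else d / se_d
      p <- if (se_d == 0 && d == 0) 1 else
        2 * stats::pt(-abs(tstat), df = df)
      R <- 2^d
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, type = tr, ratio = R, se_ratio = R * log(2) * se_d,
        log2_ratio = d, se_log2 = se_d, t = tstat, p = p,
        n_control = n1, n_treated = n2, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[, c("gene", "type", "ratio", "se_ratio", "log2_ratio",
                 "se_log2", "t", "p", "p_adj", "n_control", "n_treated")]
  rownames(out) <- NULL
  class(out) <- c("expression_ratio_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted p value of the i-th smallest p is `min over j >= i of
#' (m * p_(j) / j)`, clipped at 1, returned in the original input order.
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @return numeric vector of the same length.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0L))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  o <- order(pvalues)
  adj_sorted <- rev(cummin(rev(m * pvalues[o] / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Export the per-sample normalized expression table
#'
#' Writes the normalized expression dataset (one row per target gene and
#' sample) for user-defined downstream analyses such as clustering.
#'
#' @param normed a [normalize_targets()] result.
#' @param dir output directory.
#' @param sheet output name (default `"Exp_R"`).
#' @return the path written, invisibly.
#' @export
export_exp_dataset <- function(normed, dir, sheet = "Exp_R") {
  stopifnot(inherits(normed, "normalized_expression"))
  write_stage_output(as.data.frame(normed), dir, sheet)
}

#' Re-import a normalized expression table written by [export_exp_dataset()]
#'
#' @param dir directory holding the export.
#' @param control control `type` label to re-attach.
#' @param sheet export name (default `"Exp_R"`).
#' @return a `normalized_expression` data frame.
#' @export
read_exp_dataset <- function(dir, control = NULL, sheet = "Exp_R") {
  df <- read_stage_output(dir, sheet)
  attr(df, "control") <- control
  class(df) <- c("normalized_expression", "data.frame")
  df
}
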