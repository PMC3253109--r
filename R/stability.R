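#' Build a matrix of efficiency-corrected relative quantities
#'
#' Converts mean Ct values of unknown samples into relative quantities
#' \deqn{q[g, s] = (1 + E_g)^{Ct_{cal}(g) - Ct[g, s]}}
#' where \eqn{E_g} is the gene's PCR efficiency (default 1, i.e. perfect
#' doubling) and \eqn{Ct_{cal}} is the gene's calibrator Ct: its minimum Ct
#' across samples (default, so the most-expressed sample has q = 1) or the
#' mean Ct over control-type samples (so the control geometric mean of q is
#' exactly 1).  Standard (dilution-series) records are excluded; technical
#' replicates are collapsed by mean Ct per (gene, sample) first.
#'
#' @param table a `ct_table`.
#' @param genes genes to include (default: every gene with unknown records).
#'   A listed gene absent from the table is an error naming the gene.
#' @param efficiencies per-gene efficiency: a named numeric vector, an
#'   `efficiency_table`, a single number recycled, or `NULL` for E = 1.
#' @param calibrator `"min_ct"` (default) or `"control_mean"`.
#' @param control control `type` label, required for `"control_mean"`.
#' @return a `quantity_matrix`: list with `q` (genes x samples matrix of
#'   positive quantities), `genes`, `samples`, `sample_types` (named by
#'   sample), `efficiencies` (named by gene).
#' @export
build_quantity_matrix <- function(table, genes = NULL, efficiencies = NULL,
                                  calibrator = c("min_ct", "control_mean"),
                                  control = NULL) {
  stopifnot(inherits(table, "ct_table"))
  calibrator <- match.arg(calibrator)
  unk <- collapse_ct(table)$unknown
  if (nrow(unk) == 0L) stop("no unknown records in table", call. = FALSE)
  if (is.null(genes)) genes <- unique(unk$gene)
  absent <- setdiff(genes, unique(unk$gene))
  if (length(absent) > 0L) {
    stop("gene(s) not present in table: ", paste(absent, collapse = ", "),
         "; input names must exactly match those in the dataset",
         call. = FALSE)
  }
  samples <- unique(unk$sample)
  sample_types <- unk$type[match(samples, unk$sample)]
  names(sample_types) <- samples

  ctm <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  sub <- unk[unk$gene %in% genes, , drop = FALSE]
  ctm[cbind(match(sub$gene, genes), match(sub$sample, samples))] <- sub$ct
  incomplete <- rownames(ctm)[rowSums(is.na(ctm)) > 0L]
  if (length(incomplete) > 0L) {
    warning("excluding gene(s) with missing samples: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
    ctm <- ctm[!rownames(ctm) %in% incomplete, , drop = FALSE]
    genes <- rownames(ctm)
  }
  if (nrow(ctm) == 0L) stop("no gene has complete Ct coverage", call. = FALSE)
  if (ncol(ctm) < 2L) stop("need Ct for >= 2 samples", call. = FALSE)

  eff <- resolve_efficiencies(efficiencies, genes)
  if (calibrator == "min_ct") {
    ct_cal <- apply(ctm, 1L, min)
  } else {
    if (is.null(control)) {
      stop("control type label required for control_mean calibrator",
           call. = FALSE)
    }
    ctrl_samples <- samples[sample_types[samples] == control]
    if (length(ctrl_samples) == 0L) {
      stop("no samples of control type '", control, "'", call. = FALSE)
    }
    ct_cal <- rowMeans(ctm[, ctrl_samples, drop = FALSE])
  }
  q <- (1 + eff[genes])^(ct_cal - ctm)
  structure(list(q = q, genes = genes, samples = colnames(q),
                 sample_types = sample_types, efficiencies = eff[genes]),
            class = "quantity_matrix")
}

# Normalize the several accepted efficiency inputs to a named vector over
# `genes`; unlisted genes default to E = 1 (perfect doubling).
resolve_efficiencies <- function(efficiencies, genes) {
  eff <- rep(1, length(genes))
  names(eff) <- genes
  if (is.null(efficiencies)) return(eff)
  if (is.data.frame(efficiencies)) {
    ev <- efficiencies$efficiency
    names(ev) <- efficiencies$gene
    efficiencies <- ev
  }
  if (is.null(names(efficiencies))) {
    if (length(efficiencies) == 1L) {
      eff[] <- efficiencies
      return(eff)
    }
    stop("efficiencies must be named by gene", call. = FALSE)
  }
  hit <- intersect(genes, names(efficiencies))
  vals <- efficiencies[hit]
  if (anyNA(vals)) {
    warning("undefined efficiency for gene(s) ",
            paste(hit[is.na(vals)], collapse = ", "),
            "; using E = 1", call. = FALSE)
    vals[is.na(vals)] <- 1
  }
  eff[hit] <- vals
  eff
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat("quantity_matrix:", length(x$genes), "gene(s) x",
      length(x$samples), "sample(s)\n")
  invisible(x)
}

#' Standard deviation of pairwise log-ratios between two genes
#'
#' The building block of the M value: the sample standard deviation (n-1
#' denominator) across samples of log2(q[g1, s] / q[g2, s]).  Symmetric in
#' its arguments; zero when the two genes' quantity profiles are
#' proportional.
#'
#' @param qm a [build_quantity_matrix()] result.
#' @param g1,g2 gene names present in `qm`.
#' @return non-negative scalar, in log2 units.
#' @export
pairwise_sd <- function(qm, g1, g2) {
  stopifnot(inherits(qm, "quantity_matrix"))
  for (g in c(g1, g2)) {
    if (!g %in% qm$genes) stop("gene not in matrix: ", g, call. = FALSE)
  }
  if (length(qm$samples) < 2L) stop("need >= 2 samples", call. = FALSE)
  stats::sd(log2(qm$q[g1, ] / qm$q[g2, ]))
}

#' geNorm expression-stability M value
#'
#' The M value of gene `g` within a candidate panel is the arithmetic mean
#' of [pairwise_sd()] between `g` and every other gene remaining in the
#' panel.  Smaller M means more stable expression relative to the panel.
#'
#' @param qm a `quantity_matrix`.
#' @param gene gene to score.
#' @param panel character vector of panel genes including `gene`
#'   (default: all genes in `qm`).
#' @return non-negative scalar, log2 units.
#' @export
m_value <- function(qm, gene, panel = qm$genes) {
  stopifnot(inherits(qm, "quantity_matrix"))
  if (!gene %in% panel) stop("gene must be a member of the panel",
                             call. = FALSE)
  if (length(panel) < 2L) stop("panel must contain >= 2 genes",
                               call. = FALSE)
  others <- setdiff(panel, gene)
  mean(vapply(others, function(k) pairwise_sd(qm, gene, k), numeric(1L)))
}

# All panel M values at once (vectorized over the log2 matrix); equivalent
# to m_value() per gene but O(G^2) rather than O(G^3) per ranking.
panel_m_values <- function(qm, panel) {
  lq <- log2(qm$q[panel, , drop = FALSE])
  G <- length(panel)
  sds <- matrix(0, G, G, dimnames = list(panel, panel))
  for (i in seq_len(G - 1L)) {
    d <- lq[rep(i, G - i), , drop = FALSE] -
      lq[(i + 1L):G, , drop = FALSE]
    sds[i, (i + 1L):G] <- apply(d, 1L, stats::sd)
  }
  sds <- sds + t(sds)
  rowSums(sds) / (G - 1L)
}

#' Rank candidate reference genes by stepwise M-value exclusion
#'
#' Iteratively computes M values for the current panel and removes the gene
#' with the highest M (the least stable), recording its exclusion round and
#' its M at exclusion time, until three genes remain.  Stability rank is the
#' reverse of exclusion order — the first-excluded gene gets rank G — and
#' within the final trio ranks 1..3 follow the final-panel M ascending, so
#' rank 1 is the single most stable gene.  Because each reported M value is
#' taken from a different (shrinking) panel, the rank order and the M-value
#' sort order need not coincide; reference-gene selection should follow the
#' rank.
#'
#' Ties on the maximal M within a round exclude the lexicographically later
#' gene name (deterministic reproducibility); final-trio M ties are likewise
#' broken lexicographically, earlier name ranking better.
#'
#' @param qm a `quantity_matrix` with at least 3 genes and 2 samples.
#' @return a `stability_ranking` data frame, one row per gene, sorted by
#'   rank: columns `gene`, `m_value` (M at exclusion time; final-panel M for
#'   the last trio), `rank`, `exclusion_round` (0 for the final trio).
#' @export
rank_stability <- function(qm) {
  stopifnot(inherits(qm, "quantity_matrix"))
  G <- length(qm$genes)
  if (G < 3L) {
    stop("stability ranking needs >= 3 candidate genes; ",
         "with 2 genes use pairwise_sd() directly", call. = FALSE)
  }
  panel <- qm$genes
  rows <- list()
  round_i <- 0L
  while (length(panel) > 3L) {
    round_i <- round_i + 1L
    m <- panel_m_values(qm, panel)
    worst <- max(m)
    cand <- sort(names(m)[m == worst])     # lexicographically later excluded
    out_gene <- cand[length(cand)]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = out_gene, m_value = unname(m[out_gene]),
      rank = length(panel), exclusion_round = round_i,
      stringsAsFactors = FALSE)
    panel <- setdiff(panel, out_gene)
  }
  m_final <- panel_m_values(qm, panel)
  trio <- names(m_final)[order(m_final, names(m_final))]
  rows[[length(rows) + 1L]] <- data.frame(
    gene = trio, m_value = unname(m_final[trio]),
    rank = seq_along(trio), exclusion_round = 0L,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stability_ranking", "data.frame")
  out
}

#' Stability-ordered gene names of a ranking
#'
#' @param ranking a [rank_stability()] result (or a plain character vector,
#'   returned as is).
#' @return character vector of genes, most stable first.
#' @export
ranked_genes <- function(ranking) {
  if (is.character(ranking)) return(ranking)
  stopifnot(inherits(ranking, "stability_ranking"))
  ranking$gene[order(ranking$rank)]
}
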