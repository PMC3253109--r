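#' Describe a serial-dilution standard design
#'
#' A standard curve is built from serially diluted standard cDNA: `grad`
#' dilution levels separated by a constant factor `dilut`.  Serial index 1
#' is the undiluted (most concentrated) level; increasing serial means
#' further dilution.
#'
#' @param dilut dilution factor between consecutive standards (> 1).
#' @param grad number of dilution levels (integer >= 3).
#' @return a `dilution_design` list with elements `dilut`, `grad`.
#' @export
dilution_design <- function(dilut, grad) {
  if (!is.numeric(dilut) || length(dilut) != 1L || dilut <= 1) {
    stop("dilut must be a single number > 1", call. = FALSE)
  }
  grad <- as.integer(grad)
  if (is.na(grad) || grad < 3L) {
    stop("grad must be an integer >= 3", call. = FALSE)
  }
  structure(list(dilut = as.numeric(dilut), grad = grad),
            class = "dilution_design")
}

#' Relative concentrations of a dilution series
#'
#' @param design a [dilution_design()].
#' @return numeric vector `dilut^0, dilut^-1, ..., dilut^-(grad-1)`; the
#'   undiluted first level has relative concentration 1.
#' @export
relative_concentrations <- function(design) {
  stopifnot(inherits(design, "dilution_design"))
  design$dilut^(-(seq_len(design$grad) - 1L))
}

#' Fit a standard curve and estimate PCR efficiency
#'
#' Ordinary least squares of Ct (response) on x = log10(relative
#' concentration) over the dilution series.  The amplification efficiency is
#' the per-cycle fraction of template successfully duplicated, recovered
#' from the slope as
#' \deqn{E = 10^{-1/slope} - 1}
#' so that perfect doubling (E = 1, amplification factor 2) corresponds to a
#' slope of -log2(10) = -3.3219 Ct per 10-fold dilution.  A meaningful E
#' requires a negative slope; a non-negative slope yields `efficiency = NA`
#' with a warning.
#'
#' @param points data frame with columns `serial` (dilution level, 1 =
#'   undiluted) and `ct`.  Replicates within a level are averaged to a mean
#'   Ct before regression unless `average_replicates = FALSE`, in which case
#'   all points enter the fit.
#' @param design a [dilution_design()].
#' @param gene optional gene label carried into the result.
#' @param average_replicates collapse replicate Ct per level first (default
#'   `TRUE`, weighting all levels equally).
#' @return one-row data frame: `gene`, `slope`, `intercept`, `efficiency`
#'   (fraction, 1.0 = 100\%), `r_squared`, `n_points`.
#' @export
fit_standard_curve <- function(points, design, gene = NA_character_,
                               average_replicates = TRUE) {
  stopifnot(is.data.frame(points), inherits(design, "dilution_design"))
  pts <- points[!is.na(points$ct), c("serial", "ct")]
  if (average_replicates && nrow(pts)) {
    pts <- stats::aggregate(ct ~ serial, data = pts, FUN = mean)
  }
  if (length(unique(pts$serial)) < 3L) {
    stop("insufficient data: need >= 3 distinct dilution levels",
         call. = FALSE)
  }
  if (any(pts$serial < 1L | pts$serial > design$grad)) {
    stop("serial outside 1..grad of the dilution design", call. = FALSE)
  }
  conc <- relative_concentrations(design)
  x <- log10(conc[pts$serial])
  if (stats::var(x) == 0) {
    stop("degenerate design: zero variance in log-concentration",
         call. = FALSE)
  }
  fit <- stats::lm(ct ~ x, data = data.frame(x = x, ct = pts$ct))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # R^2 from sums of squares directly (summary.lm's value is identical but
  # warns about perfect fits in some edge cases).
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pts$ct - mean(pts$ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  if (slope >= 0) {
    warning("non-negative standard-curve slope",
            if (!is.na(gene)) paste0(" for gene '", gene, "'") else "",
            ": efficiency undefined", call. = FALSE)
    eff <- NA_real_
  } else {
    eff <- 10^(-1 / slope) - 1
  }
  data.frame(gene = gene, slope = slope, intercept = intercept,
             efficiency = eff, r_squared = r2, n_points = nrow(pts),
             stringsAsFactors = FALSE)
}

#' Estimate PCR efficiencies for all genes with standard reactions
#'
#' Runs [fit_standard_curve()] per gene over the standard (dilution-series)
#' records of a Ct table.  Technical replicates are collapsed to a mean Ct
#' per (gene, dilution level) first.  Genes without standard records are
#' listed in a warning and receive no result.
#'
#' @param table a `ct_table`.
#' @param design a [dilution_design()].
#' @return an `efficiency_table` data frame, one row per gene with
#'   standards, columns as in [fit_standard_curve()].
#' @export
estimate_efficiencies <- function(table, design) {
  stopifnot(inherits(table, "ct_table"))
  std <- collapse_ct(table)$standard
  if (nrow(std) == 0L) {
    stop("no standard (dilution-series) records in table", call. = FALSE)
  }
  genes_std <- unique(std$gene)
  all_genes <- unique(table$gene)
  without <- setdiff(all_genes, genes_std)
  if (length(without) > 0L) {
    warning("no standard records for gene(s): ",
            paste(without, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(genes_std, function(g) {
    fit_standard_curve(std[std$gene == g, , drop = FALSE], design, gene = g)
  }))
  rownames(out) <- NULL
  class(out) <- c("efficiency_table", "data.frame")
  out
}

#' Filter genes by amplification efficiency
#'
#' Genes whose estimated efficiency falls below the threshold are excluded
#' from downstream reference-gene analysis; a gene at exactly the threshold
#' is retained.  Genes with undefined efficiency are excluded.
#'
#' @param results an `efficiency_table` (or data frame with `gene`,
#'   `efficiency`).
#' @param threshold efficiency as a fraction in (0, 2]; default 0.95.
#' @return character vector of retained gene names, in input order.
#' @export
filter_genes_by_efficiency <- function(results, threshold = 0.95) {
  stopifnot(is.data.frame(results),
            all(c("gene", "efficiency") %in% names(results)))
  if (threshold < 0 || threshold > 2) {
    stop("threshold must be within [0, 2]", call. = FALSE)
  }
  keep <- !is.na(results$efficiency) & results$efficiency >= threshold
  results$gene[keep]
}
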