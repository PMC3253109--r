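# Default gene panels emulating a typical invertebrate neurodegeneration
# RT-qPCR study: 19 candidate reference genes and 9 target genes measured
# across 3 treatment types with one control.
DEFAULT_REF_GENES <- c(
  "14-3-3e", "Act5C", "Appl", "CG13220", "Cyp1", "Ef1a48D", "Elav", "Exba",
  "Gapdh2", "GstD1", "Rap2l", "Robl", "RpL13A", "RpL32", "Sdha", "Su(Tpl)",
  "aTub84B", "eIF-1A", "l(3)02640")
DEFAULT_TARGET_GENES <- c(
  "Atg1", "Ab42", "CathD", "Hsp70", "InR", "Lamp1", "Rab5", "Tor", "Hu_tau")

#' Describe a synthetic RT-qPCR experiment
#'
#' Collects every ground-truth parameter of a simulated Ct dataset: gene
#' panels, treatment structure, per-gene true PCR efficiencies, per-gene
#' biological noise (log2-quantity scale), designed fold changes, the
#' dilution design of the standard series, technical-replicate Ct noise and
#' the per-sample loading offset magnitude.  Defaults emulate the shape of
#' a real study — 19 candidate reference genes plus 9 targets across 3
#' treatment types, standard series of 5 ten-fold dilutions — with a
#' designed 6-fold induction of `Hsp70` under the `T05` treatment as the
#' known true effect.
#'
#' @param ref_genes candidate reference gene names (default: 19 names).
#' @param target_genes target gene names (default: 9 names).
#' @param types treatment type labels; first is conventional order only.
#' @param control which type is the untreated control.
#' @param n_samples_per_type biological samples per treatment type.
#' @param n_tech_reps technical replicates per reaction (default 2).
#' @param true_efficiencies per-gene true E, named vector or single number;
#'   default evenly spaced over \[0.97, 1.05\] across all genes (assays
#'   passing a standard 95\% efficiency QC cut).
#' @param ref_noise_sds per-reference-gene biological noise SD in log2
#'   units, strictly increasing by default (`seq(0.05, 0.6)`), which defines
#'   the designed stability order.
#' @param target_noise_sd biological noise SD of target genes (log2 units).
#' @param fold_changes data frame `gene`, `type`, `fold` of designed
#'   expression changes relative to control; unlisted pairs have fold 1.
#' @param dilution a [dilution_design()] for the standard series.
#' @param ct_noise_sd technical replicate noise SD, Ct cycles.
#' @param load_sd SD of the per-sample loading offset shared by all genes
#'   (Ct cycles); 0.5 by default, large enough that unnormalized analysis
#'   visibly fails.
#' @param baseline_ct range of per-gene baseline Ct values.
#' @param n_stable optional count of designed ultra-stable references
#'   (metadata used by recovery reports; `NA` when not designed).
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(ref_genes = DEFAULT_REF_GENES,
                              target_genes = DEFAULT_TARGET_GENES,
                              types = c("C05", "A05", "T05"),
                              control = "C05",
                              n_samples_per_type = 3L,
                              n_tech_reps = 2L,
                              true_efficiencies = NULL,
                              ref_noise_sds = NULL,
                              target_noise_sd = 0.25,
                              fold_changes = NULL,
                              dilution = dilution_design(10, 5),
                              ct_noise_sd = 0.1,
                              load_sd = 0.5,
                              baseline_ct = c(20, 28),
                              n_stable = NA_integer_) {
  stopifnot(length(ref_genes) >= 3L, length(target_genes) >= 1L,
            control %in% types, n_samples_per_type >= 2L, n_tech_reps >= 1L,
            target_noise_sd >= 0, ct_noise_sd >= 0, load_sd >= 0,
            inherits(dilution, "dilution_design"))
  genes <- c(ref_genes, target_genes)
  if (anyDuplicated(genes)) stop("duplicated gene names", call. = FALSE)
  if (is.null(true_efficiencies)) {
    # assays that pass standard primer QC: amplification 97-105%
    true_efficiencies <- seq(0.97, 1.05, length.out = length(genes))
  }
  if (is.null(names(true_efficiencies)) &&
      length(true_efficiencies) == length(genes)) {
    names(true_efficiencies) <- genes
  }
  eff <- resolve_efficiencies(true_efficiencies, genes)
  if (is.null(ref_noise_sds)) {
    ref_noise_sds <- seq(0.05, 0.6, length.out = length(ref_genes))
  }
  stopifnot(length(ref_noise_sds) == length(ref_genes),
            all(ref_noise_sds >= 0))
  names(ref_noise_sds) <- ref_genes
  if (is.null(fold_changes)) {
    fold_changes <- data.frame(gene = "Hsp70", type = "T05", fold = 6,
                               stringsAsFactors = FALSE)
    fold_changes <- fold_changes[fold_changes$gene %in% target_genes &
                                   fold_changes$type %in% types, ,
                                 drop = FALSE]
  }
  stopifnot(is.data.frame(fold_changes),
            all(c("gene", "type", "fold") %in% names(fold_changes)))
  if (any(fold_changes$fold <= 0)) stop("folds must be > 0", call. = FALSE)
  if (any(fold_changes$type == control & fold_changes$fold != 1)) {
    stop("control type must have all folds = 1", call. = FALSE)
  }
  structure(list(
    ref_genes = ref_genes, target_genes = target_genes, types = types,
    control = control, n_samples_per_type = as.integer(n_samples_per_type),
    n_tech_reps = as.integer(n_tech_reps), true_efficiencies = eff,
    ref_noise_sds = ref_noise_sds, target_noise_sd = target_noise_sd,
    fold_changes = fold_changes, dilution = dilution,
    ct_noise_sd = ct_noise_sd, load_sd = load_sd,
    baseline_ct = baseline_ct, n_stable = n_stable
  ), class = "simulation_design")
}

#' Generate a synthetic Ct dataset with known ground truth
#'
#' Simulates the raw Ct table of a complete RT-qPCR experiment under a
#' [simulation_design()].  For unknown reactions the expected Ct of gene g
#' in sample s is
#' \deqn{Ct = B_g - \log_{1+E_g}(F_{g,type(s)}) + L_s - z_{gs}/\log_2(1+E_g)}
#' with gene baseline B, designed fold change F, a per-sample loading
#' offset L shared by every gene (the confounding variation that
#' normalization must remove), and biological noise z on the log2-quantity
#' scale with the gene's designed SD; technical replicates add Gaussian Ct
#' noise.  Standard reactions follow the dilution design with the slope
#' implied by the gene's true efficiency
#' (`-1 / log10(1 + E)` Ct per log10 concentration).
#'
#' @param design a [simulation_design()].
#' @param seed integer RNG seed; a fixed seed reproduces the table exactly.
#' @return list with `table` (a `ct_table`) and `truth` (a `ground_truth`
#'   list: design, per-gene efficiencies/baselines/noise SDs, fold matrix,
#'   per-sample loading offsets and types, and `designed_order`, the
#'   reference genes sorted by designed noise ascending).
#' @export
generate_dataset <- function(design = simulation_design(), seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  genes <- c(design$ref_genes, design$target_genes)
  eff <- design$true_efficiencies[genes]
  noise_sd <- c(design$ref_noise_sds,
                stats::setNames(rep(design$target_noise_sd,
                                    length(design$target_genes)),
                                design$target_genes))[genes]
  baseline <- stats::setNames(
    stats::runif(length(genes), design$baseline_ct[1L],
                 design$baseline_ct[2L]), genes)

  samples <- as.vector(vapply(design$types, function(tp) {
    sprintf("%s_%02d", tp, seq_len(design$n_samples_per_type))
  }, character(design$n_samples_per_type)))
  sample_type <- stats::setNames(
    rep(design$types, each = design$n_samples_per_type), samples)
  load <- stats::setNames(
    stats::rnorm(length(samples), 0, design$load_sd), samples)

  folds <- matrix(1, nrow = length(genes), ncol = length(design$types),
                  dimnames = list(genes, design$types))
  fc <- design$fold_changes
  if (nrow(fc)) folds[cbind(match(fc$gene, genes),
                            match(fc$type, design$types))] <- fc$fold

  log2_amp <- log2(1 + eff)            # log2 quantity units per Ct cycle
  z <- matrix(stats::rnorm(length(genes) * length(samples), 0,
                           rep(noise_sd, times = length(samples))),
              nrow = length(genes),
              dimnames = list(genes, samples))
  mu <- outer(baseline, rep(0, length(samples)), `+`) -
    log2(folds[, sample_type[samples], drop = FALSE]) / log2_amp +
    matrix(load[samples], nrow = length(genes), ncol = length(samples),
           byrow = TRUE) -
    z / log2_amp

  unk <- do.call(rbind, lapply(seq_len(design$n_tech_reps), function(r) {
    data.frame(
      gene = rep(genes, times = length(samples)),
      sample = rep(samples, each = length(genes)),
      type = rep(unname(sample_type[samples]), each = length(genes)),
      serial = r,
      ct = as.vector(mu) + stats::rnorm(length(mu), 0, design$ct_noise_sd),
      role = "unknown", stringsAsFactors = FALSE)
  }))

  grad <- design$dilution$grad
  slope <- -1 / log10(1 + eff)         # Ct per log10 relative concentration
  conc <- relative_concentrations(design$dilution)
  std <- do.call(rbind, lapply(seq_len(design$n_tech_reps), function(r) {
    data.frame(
      gene = rep(genes, each = grad),
      sample = sprintf("Std%02d", r),
      type = "standard",
      serial = rep(seq_len(grad), times = length(genes)),
      ct = rep(baseline, each = grad) +
        rep(slope, each = grad) * log10(conc)[rep(seq_len(grad),
                                                  length(genes))] +
        stats::rnorm(grad * length(genes), 0, design$ct_noise_sd),
      role = "standard", stringsAsFactors = FALSE)
  }))

  tab <- as_ct_table(rbind(unk, std))
  ord <- order(design$ref_noise_sds, names(design$ref_noise_sds))
  truth <- structure(list(
    design = design, efficiencies = eff, baselines = baseline,
    noise_sds = noise_sd, folds = folds, load = load,
    sample_types = sample_type,
    designed_order = design$ref_genes[ord], seed = seed
  ), class = "ground_truth")
  list(table = tab, truth = truth)
}

#' Recovery metrics against simulation ground truth
#'
#' Compares stage outputs with the known truth of a [generate_dataset()]
#' run: per-gene absolute efficiency error, Spearman correlation between
#' the designed stability order and the recovered ranking, designed vs
#' estimated optimal reference count, and per-target log2 fold-change
#' error.  Pure: calling twice on the same inputs gives identical output.
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param results named list of stage outputs, any subset of:
#'   `efficiency` (an `efficiency_table`), `ranking` (a
#'   `stability_ranking`), `optimal_n` (integer), `ratios` (an
#'   `expression_ratio_table`).
#' @return a `recovery_report` list with elements `efficiency_error`
#'   (named vector), `stability_spearman` (scalar), `optimal_n`
#'   (list estimated/designed), `fold_log2_error` (data frame), whichever
#'   inputs were supplied.
#' @export
ground_truth_report <- function(truth, results) {
  stopifnot(inherits(truth, "ground_truth"), is.list(results))
  out <- list()
  if (!is.null(results$efficiency)) {
    er <- results$efficiency
    unknown <- setdiff(er$gene, names(truth$efficiencies))
    if (length(unknown) > 0L) {
      stop("efficiency results name gene(s) absent from truth: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out$efficiency_error <- stats::setNames(
      abs(er$efficiency - truth$efficiencies[er$gene]), er$gene)
  }
  if (!is.null(results$ranking)) {
    rk <- results$ranking
    refs <- intersect(truth$designed_order, rk$gene)
    if (length(refs) < 3L) {
      stop("ranking does not cover the designed reference panel",
           call. = FALSE)
    }
    designed_pos <- match(refs, truth$designed_order)
    recovered_pos <- rk$rank[match(refs, rk$gene)]
    out$stability_spearman <- stats::cor(designed_pos, recovered_pos,
                                         method = "spearman")
  }
  if (!is.null(results$optimal_n)) {
    out$optimal_n <- list(estimated = as.integer(results$optimal_n),
                          designed_stable = truth$design$n_stable)
  }
  if (!is.null(results$ratios)) {
    rt <- results$ratios
    bad <- setdiff(rt$gene, rownames(truth$folds))
    if (length(bad) > 0L) {
      stop("ratio results name gene(s) absent from truth: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    designed <- log2(truth$folds[cbind(rt$gene, rt$type)])
    out$fold_log2_error <- data.frame(
      gene = rt$gene, type = rt$type, designed_log2 = designed,
      estimated_log2 = rt$log2_ratio,
      error = abs(rt$log2_ratio - designed), stringsAsFactors = FALSE)
  }
  class(out) <- "recovery_report"
  out
}
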