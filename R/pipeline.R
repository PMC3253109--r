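#' Run the full five-stage analysis pipeline
#'
#' Executes the stages in workflow order — efficiency estimation, reference
#' stability ranking, pairwise-variation normalizer optimization,
#' delta-delta-Ct normalization, expression-ratio statistics — writing one
#' output sheet per stage (`Efficiency.tsv`, `M_value.tsv`,
#' `Pairwise_V.tsv`, `Exp_ratio.tsv`, plus the per-sample `Exp_R.tsv`
#' export) into `config$outdir`, together with a provenance sidecar
#' `run_info.json` holding the package version and the parameters used.
#' Unless overridden, each stage feeds the next: reference genes surviving
#' the efficiency cut enter the stability ranking, and normalization uses
#' the top-n ranked genes with n the pairwise-variation argmin.
#'
#' @param config named list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{input}{path to the raw Ct table (CSV/TSV), or `table`: a
#'       `ct_table` supplied directly.}
#'     \item{outdir}{output directory.}
#'     \item{control}{control `type` label (required).}
#'     \item{references}{candidate reference gene names (required).}
#'     \item{dilut, grad}{dilution design of the standards (default 10, 5).}
#'     \item{e_excluded}{efficiency exclusion threshold (default 0.95).}
#'     \item{targets}{target genes (default: all non-reference genes).}
#'     \item{opt_ref}{optional user-chosen reference list overriding the
#'       ranked selection.}
#'     \item{n}{optional reference count overriding the V-series argmin.}
#'     \item{v_metric}{`"sd"` (default) or `"variance"`.}
#'     \item{standard_type}{`type` label marking standards
#'       (default `"standard"`).}
#'     \item{use_efficiency}{correct quantities with the estimated
#'       per-gene E (default `TRUE`); `FALSE` forces E = 1.}
#'   }
#' @return invisibly, a list with every intermediate result: `table`,
#'   `validation`, `efficiency`, `kept_refs`, `ranking`, `series`, `n_opt`,
#'   `refs_used`, `normalized`, `ratios`, `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(dilut = 10, grad = 5, e_excluded = 0.95,
                   v_metric = "sd", standard_type = "standard",
                   use_efficiency = TRUE)
  config <- utils::modifyList(defaults, config)
  for (req in c("outdir", "control", "references")) {
    if (is.null(config[[req]])) {
      stop("pipeline config missing '", req, "'", call. = FALSE)
    }
  }
  tab <- if (!is.null(config$table)) {
    config$table
  } else if (!is.null(config$input)) {
    read_ct_table(config$input, standard_type = config$standard_type)
  } else {
    stop("pipeline config needs 'input' (file) or 'table'", call. = FALSE)
  }

  rep <- validate_ct_table(tab)
  if (nrow(rep$errors) > 0L) {
    stop("input validation failed with ", nrow(rep$errors),
         " error(s); first: ", rep$errors$message[1L], call. = FALSE)
  }

  design <- dilution_design(config$dilut, config$grad)
  eff <- estimate_efficiencies(tab, design)
  eff_out <- data.frame(gene = eff$gene, slope = eff$slope,
                        intercept = eff$intercept,
                        efficiency = eff$efficiency,
                        efficiency_pct = 100 * eff$efficiency,
                        r_squared = eff$r_squared, n_points = eff$n_points,
                        stringsAsFactors = FALSE)
  write_stage_output(eff_out, config$outdir, "Efficiency")

  eff_used <- if (isTRUE(config$use_efficiency)) eff else NULL
  kept <- intersect(
    filter_genes_by_efficiency(eff, config$e_excluded), config$references)
  dropped <- setdiff(intersect(config$references, eff$gene), kept)
  if (length(dropped) > 0L) {
    message("reference gene(s) excluded by efficiency < ",
            100 * config$e_excluded, "%: ", paste(dropped, collapse = ", "))
  }
  # candidates never measured on standards stay in (no evidence against)
  kept <- intersect(config$references,
                    union(kept, setdiff(config$references, eff$gene)))
  if (length(kept) < 3L) {
    stop("fewer than 3 candidate reference genes survive the efficiency ",
         "filter", call. = FALSE)
  }

  qm <- build_quantity_matrix(tab, genes = kept, efficiencies = eff_used)
  ranking <- rank_stability(qm)
  write_stage_output(as.data.frame(ranking), config$outdir, "M_value")

  series <- pairwise_variation_series(qm, ranking, metric = config$v_metric)
  write_stage_output(as.data.frame(series), config$outdir, "Pairwise_V")
  n_opt <- optimal_reference_count(series)

  refs_used <- if (!is.null(config$opt_ref)) config$opt_ref
               else ranked_genes(ranking)
  n_used <- if (!is.null(config$n)) as.integer(config$n)
            else if (!is.null(config$opt_ref)) length(refs_used)
            else n_opt
  normed <- normalize_targets(tab, control = config$control,
                              ref_genes = refs_used, n_refs = n_used,
                              targets = config$targets,
                              efficiencies = eff_used)
  export_exp_dataset(normed, config$outdir)
  ratios <- expression_ratios(normed, control = config$control)
  write_stage_output(as.data.frame(ratios), config$outdir, "Exp_ratio")

  info <- list(
    package = "qpcrkit",
    version = as.character(utils::packageVersion("qpcrkit")),
    parameters = config[setdiff(names(config), c("table"))],
    n_opt = n_opt, refs_used = refs_used[seq_len(n_used)])
  jsonlite::write_json(info, file.path(config$outdir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(table = tab, validation = rep, efficiency = eff,
                 kept_refs = kept, qm = qm, ranking = ranking,
                 series = series, n_opt = n_opt,
                 refs_used = refs_used[seq_len(n_used)],
                 normalized = normed, ratios = ratios,
                 outdir = config$outdir))
}
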