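#' @title Workflow drivers and TSV reports
#' @description Thin orchestration over the data, stability, ranking and
#'   quantification layers: each function runs one stage of the study
#'   workflow end to end and writes tab-separated report tables mirroring
#'   the usual presentation (one ranking table per condition with the four
#'   method columns plus the average ranking; a panel table with
#'   regions / genotypes / combination rows; expression and comparison
#'   tables for the target genes).
#' @name workflows
NULL

ranking_table <- function(r) {
  pm <- r$per_method_ranks
  genes <- colnames(pm)
  score <- ranking_score(r)[genes]
  d <- data.frame(
    Gene = genes,
    `Delta Ct` = unname(pm["delta_ct", ]),
    BestKeeper = unname(pm["bestkeeper", ]),
    Normfinder = unname(pm["normfinder", ]),
    Genorm = unname(pm["genorm", ]),
    `Avg. ranking` = unname(score),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  d[order(d$`Avg. ranking`, d$Gene), , drop = FALSE]
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

safe_name <- function(x) gsub("[^[:alnum:]]+", "_", x)

#' Run the two-axis stability ranking and write per-condition reports
#'
#' Collapses technical replicates if needed, sweeps the comprehensive
#' ranking along both design axes, and writes one TSV per condition
#' (`ranking_genotype_<genotype>.tsv` for the across-regions axis,
#' `ranking_region_<region>.tsv` for the across-genotypes axis) with
#' columns `Gene`, `Delta Ct`, `BestKeeper`, `Normfinder`, `Genorm`,
#' `Avg. ranking`.
#'
#' @param x A `cq_table` or `collapsed_cq_table`.
#' @param out_dir Output directory (created if missing).
#' @param genes Optional candidate subset to rank.
#' @param mode Sweep mode, see [condition_sweep()].
#' @param bestkeeper_rank_by Passed through.
#' @return Invisibly, a list with the two sweeps (`region_axis`,
#'   `genotype_axis`) and the written `files`.
#' @export
run_ranking_workflow <- function(x, out_dir, genes = NULL,
                                 mode = "per_cell_averaged",
                                 bestkeeper_rank_by = "sd") {
  x <- collapse_technical_replicates(x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  region_axis <- condition_sweep(x, "within_genotype_across_regions",
                                 mode = mode, genes = genes,
                                 bestkeeper_rank_by = bestkeeper_rank_by)
  genotype_axis <- condition_sweep(x, "within_region_across_genotypes",
                                   mode = "pooled", genes = genes,
                                   bestkeeper_rank_by = bestkeeper_rank_by)
  files <- character(0)
  for (g in names(region_axis)) {
    f <- file.path(out_dir, sprintf("ranking_genotype_%s.tsv", safe_name(g)))
    write_tsv(ranking_table(region_axis[[g]]), f)
    files <- c(files, f)
  }
  for (r in names(genotype_axis)) {
    f <- file.path(out_dir, sprintf("ranking_region_%s.tsv", safe_name(r)))
    write_tsv(ranking_table(genotype_axis[[r]]), f)
    files <- c(files, f)
  }
  invisible(list(region_axis = region_axis, genotype_axis = genotype_axis,
                 files = files))
}

#' Compile the reference panel and write the combination report
#'
#' Runs [run_ranking_workflow()] internals and [compile_panel()], then
#' writes `panel.tsv` with one row per axis -- `regions` (average rank from
#' the across-regions assessments), `genotypes` (average rank from the
#' across-genotypes assessments) and `combination` (the weighted average) --
#' and one column per gene; the selected panel is recorded in a trailing
#' `panel` column of the combination row report.
#'
#' @inheritParams run_ranking_workflow
#' @param weights,k Passed to [compile_panel()].
#' @return Invisibly, a list with the `panel_spec`, the sweeps and `files`.
#' @export
run_panel_workflow <- function(x, out_dir, genes = NULL, weights = c(0.5, 0.5),
                               k = 3, mode = "per_cell_averaged",
                               bestkeeper_rank_by = "sd") {
  rk <- run_ranking_workflow(x, out_dir, genes = genes, mode = mode,
                             bestkeeper_rank_by = bestkeeper_rank_by)
  spec <- compile_panel(rk$region_axis, rk$genotype_axis,
                        weights = weights, k = k)
  genes_out <- names(sort(spec$combined_rank))
  d <- data.frame(
    axis = c("regions", "genotypes", "combination"),
    rbind(spec$axis_region_rank[genes_out],
          spec$axis_genotype_rank[genes_out],
          spec$combined_rank[genes_out]),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(d)[-1] <- genes_out
  d$panel <- c("", "", paste(spec$panel, collapse = ","))
  f <- file.path(out_dir, "panel.tsv")
  write_tsv(d, f)
  invisible(list(panel = spec, region_axis = rk$region_axis,
                 genotype_axis = rk$genotype_axis,
                 files = c(rk$files, f)))
}

#' Quantify target genes against a panel and write expression reports
#'
#' For every target, computes the per-condition relative expression
#' (`2^-dCq` against the panel average) and the per-region genotype
#' comparison, writing `expression.tsv` (gene, region, genotype, n, mean,
#' sd) and `comparisons.tsv` (gene, region, fold_change, p_value, label,
#' normality p-values).
#'
#' @param x A `cq_table` or `collapsed_cq_table`.
#' @param targets Character vector of target gene symbols.
#' @param panel Reference-panel gene symbols.
#' @param out_dir Output directory.
#' @param genotypes Reference group first.
#' @param var_equal,alpha_levels,p_adjust Passed to [compare_by_region()].
#' @return Invisibly, a list with `expression`, `comparisons` and `files`.
#' @export
run_quantification_workflow <- function(x, targets, panel, out_dir,
                                        genotypes = c("WT", "PWScr"),
                                        var_equal = TRUE,
                                        alpha_levels = c(0.05, 0.01, 0.001),
                                        p_adjust = "none") {
  x <- collapse_technical_replicates(x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expr <- isoform_profile(x, targets, panel)
  comparisons <- do.call(rbind, lapply(targets, function(tg) {
    compare_by_region(expr[expr$gene == tg, , drop = FALSE],
                      genotypes = genotypes, alpha_levels = alpha_levels,
                      var_equal = var_equal, p_adjust = p_adjust)
  }))
  rownames(comparisons) <- NULL
  expr_out <- expr[, c("gene", "region", "genotype", "n", "mean", "sd")]
  f1 <- file.path(out_dir, "expression.tsv")
  f2 <- file.path(out_dir, "comparisons.tsv")
  write_tsv(expr_out, f1)
  write_tsv(comparisons, f2)
  invisible(list(expression = expr, comparisons = comparisons,
                 files = c(f1, f2)))
}
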