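#' Comprehensive ranking: geometric mean of the four method ranks
#'
#' Combines the four stability estimators into a single ordering by taking,
#' per gene, the geometric mean of its (possibly tied, fractional) ranks
#' under comparative Delta Ct, geNorm, BestKeeper and NormFinder. Genes are
#' ordered ascending by the geometric-mean rank; ties are broken
#' alphabetically by gene symbol for determinism.
#'
#' @param results A list of exactly four `stability_result`s, one per method
#'   (any order; e.g. the output of [stability_suite()]).
#' @return A `comprehensive_ranking`: list with `per_method_ranks` (method x
#'   gene matrix), `geomean_rank` (named numeric), `final_order` (character).
#' @export
comprehensive_rank <- function(results) {
  if (!is.list(results) || length(results) != 4) {
    stop("need exactly four stability results")
  }
  methods <- vapply(results, function(r) r$method, character(1))
  expected <- c("delta_ct", "genorm", "bestkeeper", "normfinder")
  if (!setequal(methods, expected)) {
    stop("missing method(s): ", paste(setdiff(expected, methods), collapse = ", "))
  }
  results <- results[match(expected, methods)]
  genes <- sort(names(results[[1]]$ranks))
  for (r in results[-1]) {
    other <- sort(names(r$ranks))
    if (!identical(genes, other)) {
      diff <- union(setdiff(genes, other), setdiff(other, genes))
      stop("stability results cover different gene sets; symmetric difference: ",
           paste(diff, collapse = ", "))
    }
  }
  pm <- do.call(rbind, lapply(results, function(r) r$ranks[genes]))
  rownames(pm) <- expected
  geomean <- apply(pm, 2, function(v) exp(mean(log(v))))
  final_order <- genes[order(geomean, genes)]
  structure(
    list(per_method_ranks = pm, geomean_rank = geomean, final_order = final_order),
    class = "comprehensive_ranking"
  )
}

#' @export
print.comprehensive_ranking <- function(x, ...) {
  cat("<comprehensive_ranking>\n")
  print(round(x$geomean_rank[x$final_order], 3))
  invisible(x)
}

#' The aggregate rank score of a ranking object
#'
#' For a [comprehensive_rank()] result this is the geometric-mean rank; for a
#' per-cell-averaged ranking (see [condition_sweep()]) it is the arithmetic
#' mean of the per-cell geometric-mean ranks.
#'
#' @param r A `comprehensive_ranking` or `averaged_ranking`.
#' @return Named numeric vector, one score per gene (lower = more stable).
#' @export
ranking_score <- function(r) {
  if (inherits(r, "comprehensive_ranking")) return(r$geomean_rank)
  if (inherits(r, "averaged_ranking")) return(r$score)
  stop("not a ranking object")
}

average_rankings <- function(per_cell) {
  genes <- sort(names(per_cell[[1]]$geomean_rank))
  score <- rowMeans(vapply(per_cell, function(r) r$geomean_rank[genes],
                           numeric(length(genes))))
  names(score) <- genes
  pm <- Reduce(`+`, lapply(per_cell, function(r) r$per_method_ranks[, genes])) /
    length(per_cell)
  structure(
    list(score = score, per_method_ranks = pm,
         final_order = genes[order(score, genes)], per_cell = per_cell),
    class = "averaged_ranking"
  )
}

#' @export
print.averaged_ranking <- function(x, ...) {
  cat(sprintf("<averaged_ranking over %d cells>\n", length(x$per_cell)))
  print(round(x$score[x$final_order], 3))
  invisible(x)
}

#' Sweep the comprehensive ranking over one design axis
#'
#' Repeats the four-method comprehensive ranking for every condition along
#' one axis of the region x genotype design:
#' `within_genotype_across_regions` yields one ranking per genotype
#' (stability across regions; 2 under the default design), and
#' `within_region_across_genotypes` one per region (stability across
#' genotypes; 9 under the default design).
#'
#' In `pooled` mode all samples of a condition enter a single estimation; for
#' the genotype-within-region axis NormFinder is then grouped by genotype
#' (overridable via `normfinder_grouped`). In `per_cell_averaged` mode each
#' cell of the crossed factor is ranked on its own and the condition's score
#' is the arithmetic mean of the per-cell geometric-mean ranks (the
#' "average ranking position across regions" reading of the design).
#'
#' @param x A `collapsed_cq_table`.
#' @param axis `"within_genotype_across_regions"` or
#'   `"within_region_across_genotypes"`.
#' @param mode `"per_cell_averaged"` or `"pooled"`.
#' @param genes Optional subset of genes to rank.
#' @param normfinder_grouped For pooled mode: group NormFinder by the crossed
#'   factor. Default: `TRUE` for the across-genotypes axis (genotype as
#'   group), `FALSE` for the across-regions axis.
#' @param bestkeeper_rank_by Passed through to [bestkeeper_stability()].
#' @return Named list (one element per condition) of `comprehensive_ranking`
#'   (pooled) or `averaged_ranking` (per-cell) objects.
#' @export
condition_sweep <- function(x,
                            axis = c("within_genotype_across_regions",
                                     "within_region_across_genotypes"),
                            mode = c("per_cell_averaged", "pooled"),
                            genes = NULL,
                            normfinder_grouped = NULL,
                            bestkeeper_rank_by = "sd") {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  if (!is.null(genes)) x <- subset_condition(x, genes = genes)
  cond_col <- if (axis == "within_genotype_across_regions") "genotype" else "region"
  cell_col <- if (cond_col == "genotype") "region" else "genotype"
  if (is.null(normfinder_grouped)) {
    normfinder_grouped <- axis == "within_region_across_genotypes"
  }
  conds <- unique(as.character(x$samples[[cond_col]]))
  if (length(unique(as.character(x$samples[[cell_col]]))) < 2) {
    stop("swept factor '", cell_col, "' has fewer than 2 levels")
  }
  out <- vector("list", length(conds))
  names(out) <- conds
  for (cond in conds) {
    sub <- if (cond_col == "genotype") subset_condition(x, genotype = cond)
           else subset_condition(x, region = cond)
    res <- tryCatch({
      if (mode == "pooled") {
        nf_groups <- if (normfinder_grouped) as.character(sub$samples[[cell_col]]) else NULL
        comprehensive_rank(stability_suite(sub, normfinder_groups = nf_groups,
                                           bestkeeper_rank_by = bestkeeper_rank_by))
      } else {
        cells <- unique(as.character(sub$samples[[cell_col]]))
        per_cell <- lapply(cells, function(cl) {
          cell_tab <- if (cell_col == "region") subset_condition(sub, region = cl)
                      else subset_condition(sub, genotype = cl)
          comprehensive_rank(stability_suite(cell_tab,
                                             bestkeeper_rank_by = bestkeeper_rank_by))
        })
        names(per_cell) <- cells
        average_rankings(per_cell)
      }
    }, error = function(e) {
      stop(sprintf("condition '%s' (%s): %s", cond, cond_col, conditionMessage(e)),
           call. = FALSE)
    })
    out[[cond]] <- res
  }
  out
}

#' Compile the reference-gene panel from the two axis sweeps
#'
#' Each axis score is the arithmetic mean, over that axis's conditions, of
#' the per-condition rank scores; the two axes are combined as a weighted
#' arithmetic mean (default 50%/50%) and the `k` genes with the smallest
#' combined score form the panel. Ties are broken alphabetically.
#'
#' @param region_axis Sweep over `within_genotype_across_regions` (list of
#'   rankings, one per genotype): the inter-regional stability axis.
#' @param genotype_axis Sweep over `within_region_across_genotypes` (list of
#'   rankings, one per region): the intra-regional (between-genotype) axis.
#' @param weights Two non-negative weights summing to 1 for
#'   (region axis, genotype axis).
#' @param k Panel size (default 3).
#' @return A `panel_spec`: list with `axis_region_rank`, `axis_genotype_rank`,
#'   `combined_rank`, `weights`, `k` and `panel` (character vector of the k
#'   selected genes, best first).
#' @export
compile_panel <- function(region_axis, genotype_axis, weights = c(0.5, 0.5), k = 3) {
  if (length(weights) != 2 || any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be two non-negative numbers summing to 1")
  }
  axis_score <- function(sweep) {
    scores <- lapply(sweep, ranking_score)
    genes <- sort(names(scores[[1]]))
    for (s in scores[-1]) {
      if (!setequal(names(s), genes)) {
        stop("gene-set mismatch across conditions: ",
             paste(union(setdiff(genes, names(s)), setdiff(names(s), genes)),
                   collapse = ", "))
      }
    }
    rowMeans(vapply(scores, function(s) s[genes], numeric(length(genes))))
  }
  ar <- axis_score(region_axis)
  ag <- axis_score(genotype_axis)
  if (!setequal(names(ar), names(ag))) {
    stop("gene-set mismatch between axes: ",
         paste(union(setdiff(names(ar), names(ag)), setdiff(names(ag), names(ar))),
               collapse = ", "))
  }
  ag <- ag[names(ar)]
  combined <- weights[1] * ar + weights[2] * ag
  if (k < 1 || k > length(combined)) {
    stop(sprintf("k must be between 1 and %d", length(combined)))
  }
  ord <- names(combined)[order(combined, names(combined))]
  structure(
    list(axis_region_rank = ar, axis_genotype_rank = ag,
         combined_rank = combined, weights = weights, k = k,
         panel = ord[seq_len(k)]),
    class = "panel_spec"
  )
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("<panel_spec> k = %d, weights = %.2f/%.2f\n",
              x$k, x$weights[1], x$weights[2]))
  cat("panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Screen candidates: keep the best genes of a comprehensive ranking
#'
#' Truncates the final ordering to the `keep` most stable genes, mirroring an
#' initial screen that drops unstable candidates before panel compilation.
#'
#' @param r A `comprehensive_ranking` or `averaged_ranking`.
#' @param keep Number of genes to retain (0 gives an empty list).
#' @return Character vector of gene symbols, most stable first.
#' @export
screen_candidates <- function(r, keep) {
  score <- ranking_score(r)
  if (keep > length(score)) {
    stop(sprintf("keep = %d exceeds the %d ranked genes", keep, length(score)))
  }
  if (keep <= 0) return(character(0))
  r$final_order[seq_len(keep)]
}
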