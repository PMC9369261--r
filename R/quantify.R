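#' Relative expression of a target gene against the reference panel
#'
#' Per biological replicate, `dCq = Cq_target - mean(Cq of panel genes)`
#' (arithmetic mean of Cq, i.e. the geometric mean of linear quantities,
#' assuming perfect doubling per cycle) and the relative expression is
#' `2^-dCq`. Replicates are aggregated per (region, genotype) condition.
#' Replicates missing the target Cq are dropped with a warning; a condition
#' left with no usable replicate is an error.
#'
#' @param x A `collapsed_cq_table` containing the target and panel genes.
#' @param target Gene symbol of the target.
#' @param panel Character vector of reference-panel gene symbols (must not
#'   contain the target).
#' @return An `expression_result` data frame with one row per condition:
#'   `gene`, `region`, `genotype`, `n`, `mean`, `sd` and a list column `rel`
#'   of the per-replicate `2^-dCq` values (named by biological replicate).
#' @export
relative_expression <- function(x, target, panel) {
  stopifnot(inherits(x, "cq_table"))
  if (target %in% panel) stop("target gene must not be part of the panel: ", target)
  missing_genes <- setdiff(c(target, panel), x$genes)
  if (length(missing_genes)) {
    stop("gene(s) absent from table: ", paste(missing_genes, collapse = ", "))
  }
  tcq <- x$cq[target, ]
  pcq <- x$cq[panel, , drop = FALSE]
  panel_mean <- colMeans(pcq, na.rm = TRUE)
  panel_n <- colSums(!is.na(pcq))
  usable <- !is.na(tcq) & panel_n >= 1
  n_drop <- sum(!usable)
  if (n_drop) {
    warning(sprintf("%s: dropping %d replicate(s) with missing target or panel Cq",
                    target, n_drop))
  }
  rel <- 2^(-(tcq - panel_mean))
  s <- x$samples
  conds <- unique(s[, c("region", "genotype")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- usable & s$region == conds$region[i] & s$genotype == conds$genotype[i]
    if (!any(sel)) {
      stop(sprintf("condition (%s, %s) has no usable replicate for %s",
                   conds$region[i], conds$genotype[i], target))
    }
    v <- stats::setNames(rel[sel], s$bio_rep[sel])
    data.frame(gene = target, region = conds$region[i],
               genotype = conds$genotype[i], n = length(v),
               mean = mean(v), sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               rel = I(list(v)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("expression_result", class(out))
  out
}

expr_condition <- function(res, region, genotype) {
  row <- res[res$region == region & res$genotype == genotype, , drop = FALSE]
  if (nrow(row) != 1) {
    stop(sprintf("no unique expression entry for (%s, %s)", region, genotype))
  }
  row
}

significance_label <- function(p, alpha_levels = c(0.05, 0.01, 0.001)) {
  a <- sort(alpha_levels, decreasing = TRUE)
  if (is.na(p)) return(NA_character_)
  if (p <= a[3]) "***" else if (p <= a[2]) "**" else if (p <= a[1]) "*" else "ns"
}

#' Compare relative expression between two groups
#'
#' Two-sided unpaired two-sample t-test on the per-replicate `2^-dCq` values
#' of the same gene and region in two groups (classical Student equal
#' variance by default, as commonly reported; Welch via
#' `var_equal = FALSE`). Normality of each group is checked with the
#' Shapiro-Wilk test when `n >= 3` (verification only: a failed check
#' attaches a warning but never switches the test). Significance labels use
#' the conventional thresholds `* p <= 0.05`, `** p <= 0.01`,
#' `*** p <= 0.001`.
#'
#' @param a,b Single-condition rows of an [relative_expression()] result for
#'   the same gene and region (`a` the reference group, e.g. WT; `b` the
#'   comparison group). The fold change is `mean(b) / mean(a)`.
#' @param alpha_levels Three descending significance thresholds.
#' @param var_equal Logical; `TRUE` for Student's pooled-variance test.
#' @return A `group_comparison` data frame row: `gene`, `region`,
#'   `mean_a`, `mean_b`, `fold_change`, `normality_p_a`, `normality_p_b`,
#'   `p_value`, `label`.
#' @export
compare_groups <- function(a, b, alpha_levels = c(0.05, 0.01, 0.001),
                           var_equal = TRUE) {
  for (r in list(a, b)) {
    if (!is.data.frame(r) || nrow(r) != 1 || is.null(r$rel)) {
      stop("a and b must be single-condition expression rows")
    }
  }
  if (a$gene != b$gene || a$region != b$region) {
    stop(sprintf("mismatched comparison: (%s, %s) vs (%s, %s)",
                 a$gene, a$region, b$gene, b$region))
  }
  va <- a$rel[[1]]; vb <- b$rel[[1]]
  if (length(va) < 2 || length(vb) < 2) stop("need n >= 2 replicates in each group")
  shap <- function(v) {
    if (length(v) < 3) {
      warning("n < 3: Shapiro-Wilk normality check skipped")
      return(NA_real_)
    }
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  pa <- shap(va); pb <- shap(vb)
  if (!is.na(pa) && pa < 0.05 || !is.na(pb) && pb < 0.05) {
    warning(sprintf("%s / %s: Shapiro-Wilk indicates non-normality (p = %.3g, %.3g)",
                    a$gene, a$region, pa, pb))
  }
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    if (isTRUE(all.equal(mean(va), mean(vb)))) {
      warning("both groups constant and equal; reporting p = 1")
      p <- 1
    } else {
      p <- 0
    }
  } else {
    p <- stats::t.test(va, vb, var.equal = var_equal)$p.value
  }
  out <- data.frame(
    gene = a$gene, region = a$region,
    mean_a = mean(va), mean_b = mean(vb),
    fold_change = mean(vb) / mean(va),
    normality_p_a = pa, normality_p_b = pb,
    p_value = p, label = significance_label(p, alpha_levels),
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' Genotype comparison of one target across all regions
#'
#' Runs [compare_groups()] per region on the two genotypes of an
#' [relative_expression()] result. No multiple-testing correction is applied
#' by default (per-region stars); `p_adjust = "BH"` switches on
#' Benjamini-Hochberg adjusted labels.
#'
#' @param res An `expression_result` covering both genotypes.
#' @param genotypes Length-2 character: reference group first (fold change is
#'   second over first).
#' @param p_adjust `"none"` (default) or a method accepted by
#'   [stats::p.adjust()].
#' @inheritParams compare_groups
#' @return A `group_comparison` data frame, one row per region.
#' @export
compare_by_region <- function(res, genotypes = c("WT", "PWScr"),
                              alpha_levels = c(0.05, 0.01, 0.001),
                              var_equal = TRUE, p_adjust = "none") {
  regions <- unique(res$region)
  rows <- lapply(regions, function(rg) {
    compare_groups(expr_condition(res, rg, genotypes[1]),
                   expr_condition(res, rg, genotypes[2]),
                   alpha_levels = alpha_levels, var_equal = var_equal)
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
    out$label <- vapply(out$p_adjusted, significance_label, character(1),
                        alpha_levels = alpha_levels)
  }
  rownames(out) <- NULL
  out
}

#' Batched relative expression for a set of assays (e.g. mRNA isoforms)
#'
#' Runs [relative_expression()] for each named target assay against the same
#' reference panel and binds the per-condition results, e.g. for total,
#' exon-specific and exon-excluding isoform assays of one gene.
#'
#' @param x A `collapsed_cq_table`.
#' @param isoform_assays Character vector of target assay names present in
#'   the table (optionally named with display labels).
#' @param panel Reference-panel gene symbols.
#' @return An `expression_result` data frame over all assays and conditions,
#'   with an `assay` column.
#' @export
isoform_profile <- function(x, isoform_assays, panel) {
  absent <- setdiff(isoform_assays, x$genes)
  if (length(absent)) stop("assay(s) absent from table: ", paste(absent, collapse = ", "))
  labels <- if (is.null(names(isoform_assays))) isoform_assays else
    ifelse(names(isoform_assays) == "", isoform_assays, names(isoform_assays))
  out <- do.call(rbind, lapply(seq_along(isoform_assays), function(i) {
    r <- relative_expression(x, isoform_assays[i], panel)
    r$assay <- labels[i]
    r
  }))
  rownames(out) <- NULL
  out
}
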