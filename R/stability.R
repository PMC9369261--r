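#' @title Reference-gene stability estimators
#' @description The four standard estimators of reference-gene expression
#'   stability, each implemented from its original formulation. All return a
#'   `stability_result` whose `values` are method-specific (lower = more
#'   stable) and whose `ranks` are ascending average ranks of the values.
#' @name stability
NULL

new_stability_result <- function(method, values, ranks, diagnostics = list()) {
  structure(
    list(method = method, values = values, ranks = ranks, diagnostics = diagnostics),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result: %s>\n", x$method))
  print(data.frame(gene = names(x$values),
                   value = unname(x$values),
                   rank = unname(x$ranks[names(x$values)]),
                   row.names = NULL))
  invisible(x)
}

#' Export a stability result as a data frame
#'
#' One row per gene with the stability value, its rank, and any per-gene
#' diagnostic columns the method produced (e.g. BestKeeper's CV% and r).
#'
#' @param x A `stability_result`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A `data.frame` ordered by rank.
#' @export
as.data.frame.stability_result <- function(x, row.names = NULL, optional = FALSE, ...) {
  d <- data.frame(gene = names(x$values), value = unname(x$values),
                  rank = unname(x$ranks[names(x$values)]),
                  stringsAsFactors = FALSE)
  for (nm in names(x$diagnostics)) {
    v <- x$diagnostics[[nm]]
    if (is.numeric(v) && !is.null(names(v)) && all(d$gene %in% names(v))) {
      d[[nm]] <- unname(v[d$gene])
    }
  }
  d[order(d$rank, d$gene), , drop = FALSE]
}

rank_stability_values <- function(values) {
  r <- rank(values, ties.method = "average")
  names(r) <- names(values)
  r
}

collapsed_matrix <- function(x) {
  stopifnot(inherits(x, "cq_table"))
  x$cq
}

# SD of Cq differences for every gene pair, pairwise-complete samples.
# Errors if any pair shares fewer than min_shared samples.
pairwise_sd_matrix <- function(m, min_shared = 3L) {
  g <- nrow(m)
  out <- matrix(NA_real_, g, g, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      d <- m[i, ] - m[j, ]
      d <- d[!is.na(d)]
      if (length(d) < min_shared) {
        stop(sprintf("gene pair %s / %s shares only %d complete sample(s); need >= %d",
                     rownames(m)[i], rownames(m)[j], length(d), min_shared))
      }
      out[i, j] <- out[j, i] <- stats::sd(d)
    }
  }
  out
}

#' Comparative Delta Ct stability
#'
#' For every gene pair, the per-sample Cq difference is taken and its SD
#' across samples computed; a gene's stability value is the mean of these
#' SDs over all its partners. Constant gene-to-gene offsets contribute
#' nothing, so a gene tracking the others perfectly scores 0.
#'
#' @param x A `collapsed_cq_table` (or any `cq_table`; columns are treated as
#'   samples).
#' @return A `stability_result` with values in cycles.
#' @export
delta_ct_stability <- function(x) {
  m <- collapsed_matrix(x)
  if (nrow(m) < 2) stop("comparative Delta Ct needs at least 2 genes")
  sdm <- pairwise_sd_matrix(m)
  values <- rowMeans(sdm, na.rm = TRUE)
  new_stability_result("delta_ct", values, rank_stability_values(values),
                       diagnostics = list(pairwise_sd = sdm))
}

#' geNorm stability (M value and pairwise variation)
#'
#' Expression is converted to relative quantities `Q = 2^(min Cq - Cq)` per
#' gene; on the log2 scale the pairwise variation `V_jk` is the SD across
#' samples of `log2(Q_j / Q_k)` and a gene's `M` is the mean of its pairwise
#' variations. The gene with the highest `M` is excluded and `M` recomputed,
#' repeatedly, until two genes remain; those two cannot be resolved further
#' and share the top (tied) rank. A gene's reported value is its `M` at the
#' step it was excluded (the final two carry the final-step `M`).
#'
#' Diagnostics: `exclusion_order` (worst first), `M_steps`, and the pairwise
#' variation series `V[n]` = SD across samples of `log2(NF_n / NF_{n+1})`,
#' where `NF_n` is the per-sample geometric mean of the top-n genes'
#' relative quantities, for n = 2..(n_genes - 1).
#'
#' @param x A `collapsed_cq_table`.
#' @return A `stability_result`; values are `M` (dimensionless, log2-SD).
#' @export
genorm_stability <- function(x) {
  m <- collapsed_matrix(x)
  g <- nrow(m)
  if (g < 2) stop("geNorm needs at least 2 genes")
  genes <- rownames(m)
  sdm <- pairwise_sd_matrix(m)  # SD of Cq differences == SD of log2 Q ratios
  values <- stats::setNames(rep(NA_real_, g), genes)
  active <- genes
  exclusion <- character(0)
  m_steps <- list()
  while (length(active) > 2) {
    M <- rowMeans(sdm[active, active, drop = FALSE], na.rm = TRUE)
    m_steps[[length(m_steps) + 1L]] <- M
    worst <- names(M)[order(-M, names(M))][1]
    values[worst] <- M[worst]
    exclusion <- c(exclusion, worst)
    active <- setdiff(active, worst)
  }
  M_final <- rowMeans(sdm[active, active, drop = FALSE], na.rm = TRUE)
  if (length(active) == 2) {
    # with two genes the row mean is just the single pairwise SD
    M_final <- stats::setNames(rep(sdm[active[1], active[2]], 2), active)
  }
  m_steps[[length(m_steps) + 1L]] <- M_final
  values[active] <- M_final
  # rank by exclusion: final two tie at 1.5, then 3, 4, ... worst last
  ranks <- stats::setNames(rep(1.5, g), genes)
  if (length(exclusion)) {
    ranks[rev(exclusion)] <- 3:(2 + length(exclusion))
  }
  ranking_order <- c(sort(active), rev(exclusion))
  V <- genorm_v_series(m, ranking_order)
  new_stability_result("genorm", values, ranks,
                       diagnostics = list(exclusion_order = exclusion,
                                          M_steps = m_steps,
                                          V = V))
}

# Pairwise variation V_{n/n+1} between normalization factors of the top-n and
# top-(n+1) genes, on samples complete for the genes involved.
genorm_v_series <- function(m, ranking_order) {
  g <- length(ranking_order)
  if (g < 3) return(stats::setNames(numeric(0), character(0)))
  # log2 relative quantities: Q_gs = 2^(min_s Cq - Cq); constant per gene
  lq <- sweep(-m, 1, apply(-m, 1, max, na.rm = TRUE))  # = min Cq - Cq
  V <- numeric(g - 2)
  names(V) <- paste0("V", 2:(g - 1), "/", 3:g)
  for (n in 2:(g - 1)) {
    top_n <- ranking_order[1:n]
    top_n1 <- ranking_order[1:(n + 1)]
    nf_n <- colMeans(lq[top_n, , drop = FALSE])      # log2 geometric mean
    nf_n1 <- colMeans(lq[top_n1, , drop = FALSE])
    d <- nf_n - nf_n1
    V[n - 1] <- stats::sd(d[!is.na(d)])
  }
  V
}

#' BestKeeper stability (Cq dispersion and index correlation)
#'
#' Per gene, the descriptive stability is the mean absolute deviation of Cq
#' from the gene's arithmetic mean Cq (reported as `SD [+/- Cq]` in the
#' original tool) and `CV%` = SD / mean * 100. The BestKeeper index is the
#' per-sample geometric mean of all candidate genes' Cq; each gene's Pearson
#' correlation `r` with the index (with its two-sided p-value) is reported in
#' the diagnostics. Ranking uses `SD [+/- Cq]` by default; `CV%` or `1 - r`
#' can be selected instead.
#'
#' @param x A `collapsed_cq_table`.
#' @param rank_by One of `"sd"`, `"cv"`, `"r"`.
#' @return A `stability_result`; values in cycles (`sd`), percent (`cv`), or
#'   `1 - r` (dimensionless).
#' @export
bestkeeper_stability <- function(x, rank_by = c("sd", "cv", "r")) {
  rank_by <- match.arg(rank_by)
  m <- collapsed_matrix(x)
  if (nrow(m) < 2) stop("BestKeeper needs at least 2 genes")
  complete_n <- rowSums(!is.na(m))
  if (any(complete_n < 3)) {
    stop("gene(s) with < 3 usable samples: ",
         paste(rownames(m)[complete_n < 3], collapse = ", "))
  }
  gene_mean <- rowMeans(m, na.rm = TRUE)
  sd_cq <- rowMeans(abs(m - gene_mean), na.rm = TRUE)      # MAD about the mean
  cv <- sd_cq / gene_mean * 100
  index <- apply(m, 2, function(v) exp(mean(log(v[!is.na(v)]))))
  r <- p_r <- stats::setNames(rep(NA_real_, nrow(m)), rownames(m))
  for (i in seq_len(nrow(m))) {
    ok <- !is.na(m[i, ]) & !is.na(index)
    if (stats::sd(index[ok]) == 0 || stats::sd(m[i, ok]) == 0) {
      if (stats::sd(m[i, ok]) > 0) {
        warning(sprintf("BestKeeper index has zero variance; r undefined for %s",
                        rownames(m)[i]))
      }
      next
    }
    ct <- stats::cor.test(m[i, ok], index[ok])
    r[i] <- unname(ct$estimate)
    p_r[i] <- ct$p.value
  }
  values <- switch(rank_by, sd = sd_cq, cv = cv, r = 1 - r)
  names(values) <- rownames(m)
  new_stability_result("bestkeeper", values, rank_stability_values(values),
                       diagnostics = list(sd_cq = sd_cq, cv_pct = cv,
                                          r = r, p_r = p_r, index = index))
}

# Core NormFinder computation on a log-expression matrix (genes x samples).
# Returns per-gene stability plus per-group components.
normfinder_core <- function(y, groups) {
  k <- nrow(y)
  genes <- rownames(y)
  if (k < 3) stop("NormFinder needs at least 3 genes")
  if (anyNA(y)) {
    ok <- colSums(is.na(y)) == 0
    if (any(!ok)) warning(sprintf("NormFinder: dropping %d sample(s) with missing Cq", sum(!ok)))
    y <- y[, ok, drop = FALSE]
    groups <- groups[ok]
  }
  lv <- unique(groups)
  G <- length(lv)
  n_g <- table(factor(groups, levels = lv))
  if (any(n_g < 2)) {
    stop("NormFinder group(s) with < 2 samples: ",
         paste(lv[n_g < 2], collapse = ", "))
  }
  zbar <- matrix(NA_real_, k, G, dimnames = list(genes, lv))
  sig2 <- matrix(NA_real_, k, G, dimnames = list(genes, lv))
  for (g in seq_len(G)) {
    zg <- y[, groups == lv[g], drop = FALSE]
    zg <- sweep(zg, 2, colMeans(zg))           # within-sample centering
    zbar[, g] <- rowMeans(zg)
    s2 <- apply(zg, 1, stats::var)
    # correct for the correlation that centering across k genes induces
    sig2[, g] <- pmax((s2 - mean(s2) / (k - 1)) * k / (k - 2), 0)
  }
  if (G == 1) {
    values <- sqrt(sig2[, 1])
    return(list(values = values, d = zbar * 0, d_shrunk = zbar * 0,
                sig2 = sig2, gamma2 = 0))
  }
  d <- zbar - rowMeans(zbar)                   # intergroup deviations
  vard <- sweep(sig2, 2, as.numeric(n_g), "/")
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(vard))
  d_shrunk <- d * gamma2 / (gamma2 + vard)
  var_new <- vard + gamma2 * vard / (gamma2 + vard)
  values <- rowMeans(abs(d_shrunk) + sqrt(var_new))
  list(values = values, d = d, d_shrunk = d_shrunk, sig2 = sig2, gamma2 = gamma2)
}

#' NormFinder stability (model-based variance decomposition)
#'
#' Works on a log-scale expression proxy (`-Cq`; the sign does not affect any
#' variance). Each sample is centered across genes, removing per-sample
#' offsets; per group, a bias-corrected intragroup variance is estimated for
#' every gene, and each gene's intergroup deviation is shrunk toward zero by
#' an empirical-Bayes factor. The stability value averages, over groups, the
#' shrunken absolute intergroup deviation plus the sampling SD of the group
#' estimate. With no groups (`groups = NULL`) the estimator reduces to the
#' square root of the corrected intragroup variance.
#'
#' @param x A `collapsed_cq_table`.
#' @param groups Optional per-sample group labels (length = number of
#'   samples), or the name of an annotation column (`"genotype"`,
#'   `"region"`). `NULL` for the single-group form.
#' @return A `stability_result`; diagnostics carry the per-group intergroup
#'   deviations (which sum to 0 across genes within each group), their
#'   shrunken versions, the intragroup variance estimates, and the
#'   between-group variance `gamma2`.
#' @export
normfinder_stability <- function(x, groups = NULL) {
  m <- collapsed_matrix(x)
  if (is.character(groups) && length(groups) == 1 && groups %in% names(x$samples)) {
    groups <- as.character(x$samples[[groups]])
  }
  if (is.null(groups)) {
    groups <- rep("all", ncol(m))
  }
  if (length(groups) != ncol(m)) stop("groups must have one label per sample")
  core <- normfinder_core(-m, as.character(groups))
  values <- core$values
  names(values) <- rownames(m)
  new_stability_result("normfinder", values, rank_stability_values(values),
                       diagnostics = list(intergroup_dev = core$d,
                                          intergroup_dev_shrunk = core$d_shrunk,
                                          intragroup_var = core$sig2,
                                          gamma2 = core$gamma2))
}

#' Run all four stability estimators on one table
#'
#' Convenience wrapper returning the comparative Delta Ct, geNorm,
#' BestKeeper and NormFinder results as a named list, ready for
#' [comprehensive_rank()].
#'
#' @inheritParams normfinder_stability
#' @param bestkeeper_rank_by Passed to [bestkeeper_stability()].
#' @param normfinder_groups Passed to [normfinder_stability()] as `groups`.
#' @return Named list of four `stability_result`s.
#' @export
stability_suite <- function(x, normfinder_groups = NULL,
                            bestkeeper_rank_by = "sd") {
  list(
    delta_ct = delta_ct_stability(x),
    genorm = genorm_stability(x),
    bestkeeper = bestkeeper_stability(x, rank_by = bestkeeper_rank_by),
    normfinder = normfinder_stability(x, groups = normfinder_groups)
  )
}
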