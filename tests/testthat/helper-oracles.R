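# Independent, loop-based oracles for the four stability estimators.
# These transcribe each method's original formulation directly, without
# sharing code with the package implementations.

oracle_pair_sd <- function(m, i, j) {
  d <- numeric(0)
  for (s in seq_len(ncol(m))) {
    if (!is.na(m[i, s]) && !is.na(m[j, s])) d <- c(d, m[i, s] - m[j, s])
  }
  sd(d)
}

# Comparative Delta Ct: mean over partners of the SD of pairwise Cq
# differences across samples.
oracle_delta_ct <- function(m) {
  g <- nrow(m)
  out <- numeric(g)
  names(out) <- rownames(m)
  for (i in seq_len(g)) {
    sds <- numeric(0)
    for (j in seq_len(g)) {
      if (j != i) sds <- c(sds, oracle_pair_sd(m, i, j))
    }
    out[i] <- mean(sds)
  }
  out
}

# geNorm: M = mean pairwise variation; exclude the highest-M gene and
# recompute everything from scratch until two genes remain.
oracle_genorm <- function(m) {
  genes <- rownames(m)
  active <- genes
  values <- setNames(rep(NA_real_, length(genes)), genes)
  exclusion <- character(0)
  steps <- list()
  repeat {
    M <- setNames(numeric(length(active)), active)
    for (a in active) {
      sds <- numeric(0)
      for (b in active) {
        if (b != a) sds <- c(sds, oracle_pair_sd(m, match(a, genes), match(b, genes)))
      }
      M[a] <- mean(sds)
    }
    steps[[length(steps) + 1L]] <- M
    if (length(active) == 2) {
      values[active] <- M
      break
    }
    worst <- names(M)[order(-M, names(M))][1]
    values[worst] <- M[worst]
    exclusion <- c(exclusion, worst)
    active <- setdiff(active, worst)
  }
  ranks <- setNames(rep(1.5, length(genes)), genes)
  rr <- 3
  for (g in rev(exclusion)) {
    ranks[g] <- rr
    rr <- rr + 1
  }
  list(values = values, ranks = ranks, exclusion = exclusion, steps = steps,
       order = c(sort(active), rev(exclusion)))
}

# geNorm pairwise-variation series from explicit relative quantities.
oracle_genorm_v <- function(m, ranking_order) {
  q <- m
  for (i in seq_len(nrow(m))) q[i, ] <- 2^(min(m[i, ], na.rm = TRUE) - m[i, ])
  g <- length(ranking_order)
  V <- numeric(g - 2)
  for (n in 2:(g - 1)) {
    nf_n <- nf_n1 <- numeric(ncol(m))
    for (s in seq_len(ncol(m))) {
      nf_n[s] <- prod(q[ranking_order[1:n], s])^(1 / n)
      nf_n1[s] <- prod(q[ranking_order[1:(n + 1)], s])^(1 / (n + 1))
    }
    ratio <- log2(nf_n / nf_n1)
    V[n - 1] <- sd(ratio[!is.na(ratio)])
  }
  V
}

# BestKeeper: per-gene mean absolute deviation from the mean Cq ("SD"),
# CV%, the per-sample geometric-mean index, and Pearson r with a
# hand-coded t-based p-value.
oracle_bestkeeper <- function(m) {
  g <- nrow(m)
  n <- ncol(m)
  mu <- sd_cq <- cv <- numeric(g)
  for (i in seq_len(g)) {
    v <- m[i, !is.na(m[i, ])]
    mu[i] <- sum(v) / length(v)
    sd_cq[i] <- sum(abs(v - mu[i])) / length(v)
    cv[i] <- sd_cq[i] / mu[i] * 100
  }
  index <- numeric(n)
  for (s in seq_len(n)) {
    v <- m[!is.na(m[, s]), s]
    index[s] <- prod(v)^(1 / length(v))
  }
  r <- p <- rep(NA_real_, g)
  for (i in seq_len(g)) {
    ok <- !is.na(m[i, ])
    x <- m[i, ok]; y <- index[ok]
    if (sd(x) > 0 && sd(y) > 0) {
      r[i] <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      tt <- r[i] * sqrt((length(x) - 2) / (1 - r[i]^2))
      p[i] <- 2 * pt(-abs(tt), df = length(x) - 2)
    }
  }
  list(sd = setNames(sd_cq, rownames(m)), cv = setNames(cv, rownames(m)),
       index = index, r = setNames(r, rownames(m)), p = setNames(p, rownames(m)))
}

# NormFinder: within-sample centering, bias-corrected per-group variances,
# empirical-Bayes shrinkage of intergroup deviations; stability = group mean
# of |shrunken deviation| + sqrt(estimator variance). Single group:
# sqrt(corrected variance).
oracle_normfinder <- function(cq, groups = NULL) {
  y <- -cq
  k <- nrow(y)
  genes <- rownames(y)
  if (is.null(groups)) groups <- rep("all", ncol(y))
  lv <- unique(groups)
  G <- length(lv)
  zbar <- sig2 <- matrix(NA_real_, k, G, dimnames = list(genes, lv))
  n_g <- integer(G)
  for (gi in seq_len(G)) {
    cols <- which(groups == lv[gi])
    n <- length(cols)
    n_g[gi] <- n
    z <- matrix(NA_real_, k, n)
    for (jj in seq_along(cols)) {
      z[, jj] <- y[, cols[jj]] - mean(y[, cols[jj]])
    }
    s2 <- numeric(k)
    for (i in seq_len(k)) {
      zb <- mean(z[i, ])
      zbar[i, gi] <- zb
      s2[i] <- sum((z[i, ] - zb)^2) / (n - 1)
    }
    for (i in seq_len(k)) {
      sig2[i, gi] <- max((s2[i] - mean(s2) / (k - 1)) * k / (k - 2), 0)
    }
  }
  if (G == 1) {
    return(setNames(sqrt(sig2[, 1]), genes))
  }
  d <- zbar - rowMeans(zbar)
  vard <- sig2
  for (gi in seq_len(G)) vard[, gi] <- sig2[, gi] / n_g[gi]
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(vard))
  stab <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (gi in seq_len(G)) {
      ds <- d[i, gi] * gamma2 / (gamma2 + vard[i, gi])
      vn <- vard[i, gi] + gamma2 * vard[i, gi] / (gamma2 + vard[i, gi])
      acc <- acc + abs(ds) + sqrt(vn)
    }
    stab[i] <- acc / G
  }
  setNames(stab, genes)
}

# Hand-coded two-sided two-sample t-test (pooled and Welch) on raw vectors.
oracle_t_test <- function(a, b, var_equal = TRUE) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  2 * pt(-abs(tt), df)
}
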