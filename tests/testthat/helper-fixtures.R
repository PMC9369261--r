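# In-code fixtures: small Cq tables built programmatically.

# Wrap a genes x samples matrix as a collapsed table with minimal
# annotations (each column its own biological replicate).
make_collapsed <- function(m, region = "hippocampus", genotype = "WT",
                           regions = NULL, genotypes = NULL) {
  n <- ncol(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  samples <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    region = rep_len(region, n),
    genotype = rep_len(genotype, n),
    bio_rep = seq_len(n),
    tech_rep = 1L,
    stringsAsFactors = FALSE
  )
  # distinct bio_rep per (region, genotype) cell
  key <- paste(samples$region, samples$genotype)
  samples$bio_rep <- stats::ave(seq_len(n), key, FUN = seq_along)
  x <- cq_table(m, samples,
                design = list(regions = unique(samples$region),
                              genotypes = unique(samples$genotype)))
  x$tech_spread <- m * 0
  x$n_tech <- matrix(1L, nrow(m), n, dimnames = dimnames(m))
  class(x) <- c("collapsed_cq_table", class(x))
  x
}

# Random Cq table in the dimensions used by the oracle-equivalence checks.
random_cq_matrix <- function(seed, n_genes = NULL, n_samples = NULL) {
  set.seed(seed)
  if (is.null(n_genes)) n_genes <- sample(4:6, 1)
  if (is.null(n_samples)) n_samples <- sample(6:12, 1)
  m <- matrix(rnorm(n_genes * n_samples, mean = 25, sd = 2),
              n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  round(m, 4)
}

# Long-format text fixture written to a temp file.
write_long_fixture <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

long_rows <- function(gene, sample_id, cq, region = "hippocampus",
                      genotype = "WT", bio_rep = 1, tech_rep = 1) {
  data.frame(sample_id = sample_id, gene = gene, cq = cq, region = region,
             genotype = genotype, bio_rep = bio_rep, tech_rep = tech_rep,
             stringsAsFactors = FALSE)
}
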