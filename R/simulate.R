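#' Specify one simulated gene
#'
#' Defines a gene's Cq model for the generator:
#' `Cq = base_cq + region_effect + genotype_effect + eps_bio + eps_tech`,
#' with independent Gaussian noise on the Cq scale (log-normal on the linear
#' scale, the standard qPCR error model). `genotype_effect` is the Cq shift
#' applied to the second genotype of the design; since expression is
#' `2^-Cq`-like, the implied log2 fold change is `-genotype_effect` (a
#' negative shift means upregulation).
#'
#' @param symbol Gene symbol.
#' @param base_cq Baseline Cq in cycles, in (5, 40).
#' @param region_effects Named numeric vector of Cq offsets per region
#'   (regions not named get 0).
#' @param genotype_effect Scalar Cq offset for the second genotype, or a
#'   named numeric vector per region for region-specific effects.
#' @param bio_sd Between-biological-replicate SD, cycles.
#' @param tech_sd Technical-replicate SD, cycles.
#' @param dropout_p Probability that a technical replicate is a non-detect.
#' @return A `gene_spec` list.
#' @export
gene_spec <- function(symbol, base_cq = 25, region_effects = numeric(0),
                      genotype_effect = 0, bio_sd = 0.2, tech_sd = 0.1,
                      dropout_p = 0) {
  if (bio_sd < 0 || tech_sd < 0) stop(symbol, ": bio_sd and tech_sd must be >= 0")
  if (dropout_p < 0 || dropout_p >= 1) stop(symbol, ": dropout_p must be in [0, 1)")
  if (base_cq <= 5 || base_cq >= 40) stop(symbol, ": base_cq must be in (5, 40)")
  structure(
    list(symbol = symbol, base_cq = base_cq,
         region_effects = region_effects, genotype_effect = genotype_effect,
         bio_sd = bio_sd, tech_sd = tech_sd, dropout_p = dropout_p),
    class = "gene_spec"
  )
}

#' Configure the synthetic Cq generator
#'
#' Describes the factorial layout (regions x genotypes x biological x
#' technical replicates) and the gene models. Per-cell replicate overrides
#' reproduce unbalanced designs such as six biological replicates for the WT
#' hypothalamus with three everywhere else.
#'
#' @param genes List of [gene_spec()] objects with unique symbols.
#' @param regions,genotypes Factor levels (defaults: [brain_design()]).
#' @param n_bio Biological replicates per region x genotype cell.
#' @param n_tech Technical replicates per biological replicate.
#' @param n_bio_overrides Optional `data.frame(region, genotype, n_bio)` of
#'   per-cell replicate counts.
#' @param seed Default RNG seed for [simulate_cq()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(genes,
                             regions = brain_design()$regions,
                             genotypes = brain_design()$genotypes,
                             n_bio = 3, n_tech = 3,
                             n_bio_overrides = NULL, seed = 1L) {
  if (!length(genes) || !all(vapply(genes, inherits, logical(1), "gene_spec"))) {
    stop("genes must be a non-empty list of gene_spec objects")
  }
  syms <- vapply(genes, `[[`, character(1), "symbol")
  if (anyDuplicated(syms)) stop("duplicate gene symbols in config")
  names(genes) <- syms
  if (length(genotypes) != 2) stop("generator expects exactly 2 genotypes")
  if (n_bio < 1 || n_tech < 1) stop("n_bio and n_tech must be >= 1")
  for (g in genes) {
    bad <- setdiff(names(g$region_effects), regions)
    if (length(bad)) stop(g$symbol, ": unknown region(s) in region_effects: ",
                          paste(bad, collapse = ", "))
    ge <- g$genotype_effect
    if (!is.null(names(ge))) {
      bad <- setdiff(names(ge), regions)
      if (length(bad)) stop(g$symbol, ": unknown region(s) in genotype_effect: ",
                            paste(bad, collapse = ", "))
    } else if (length(ge) != 1) {
      stop(g$symbol, ": genotype_effect must be a scalar or region-named vector")
    }
  }
  if (!is.null(n_bio_overrides)) {
    stopifnot(all(c("region", "genotype", "n_bio") %in% names(n_bio_overrides)))
    bad <- !(n_bio_overrides$region %in% regions &
             n_bio_overrides$genotype %in% genotypes)
    if (any(bad)) stop("n_bio_overrides refers to cells outside the design")
  }
  structure(
    list(genes = genes, regions = regions, genotypes = genotypes,
         n_bio = n_bio, n_tech = n_tech, n_bio_overrides = n_bio_overrides,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

cell_n_bio <- function(config, region, genotype) {
  ov <- config$n_bio_overrides
  if (!is.null(ov)) {
    hit <- ov$region == region & ov$genotype == genotype
    if (any(hit)) return(ov$n_bio[which(hit)[1]])
  }
  config$n_bio
}

region_effect_of <- function(g, region) {
  if (region %in% names(g$region_effects)) unname(g$region_effects[[region]]) else 0
}

genotype_effect_of <- function(g, region) {
  ge <- g$genotype_effect
  if (is.null(names(ge))) unname(ge)
  else if (region %in% names(ge)) unname(ge[[region]]) else 0
}

#' Deterministic ground truth of a generator configuration
#'
#' Derived from the configuration alone, without sampling. The composite
#' instability score declared for the true stability order is
#' `sqrt(bio_sd^2 + var_pop(region effects over all design regions) +
#' mean(genotype effect^2 over regions))`, combining the three sources of
#' between-sample Cq variation a stability estimator sees. True fold changes
#' are `2^-genotype_effect` per (gene, region).
#'
#' @param config A [generator_config()].
#' @return A `simulation_truth` list: `instability` (named numeric),
#'   `true_stability_order` (most stable first, ties alphabetical), and
#'   `true_fold_changes` (genes x regions matrix).
#' @export
simulation_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  genes <- config$genes
  instability <- vapply(genes, function(g) {
    re <- vapply(config$regions, function(r) region_effect_of(g, r), numeric(1))
    ge <- vapply(config$regions, function(r) genotype_effect_of(g, r), numeric(1))
    sqrt(g$bio_sd^2 + mean((re - mean(re))^2) + mean(ge^2))
  }, numeric(1))
  fc <- matrix(NA_real_, length(genes), length(config$regions),
               dimnames = list(names(genes), config$regions))
  for (gi in seq_along(genes)) {
    fc[gi, ] <- 2^-vapply(config$regions, function(r)
      genotype_effect_of(genes[[gi]], r), numeric(1))
  }
  structure(
    list(instability = instability,
         true_stability_order = names(instability)[
           order(instability, names(instability))],
         true_fold_changes = fc),
    class = "simulation_truth"
  )
}

#' Generate a synthetic Cq table with known ground truth
#'
#' Draws `Cq(gene, sample) = base_cq + region effect + genotype effect *
#' [second genotype] + eps_bio + eps_tech` with independent Gaussian noise;
#' each biological replicate shares one `eps_bio` across its technical
#' replicates. Dropouts (non-detects) are applied independently per
#' technical replicate. Fully reproducible from the seed; each gene draws
#' from its own derived RNG stream, so edits to one gene's spec do not
#' perturb the others' values.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return List with `table` (a [cq_table()]) and `truth`
#'   (a [simulation_truth()]).
#' @export
simulate_cq <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  seed <- as.integer(seed)
  layout <- do.call(rbind, lapply(config$regions, function(r) {
    do.call(rbind, lapply(config$genotypes, function(gt) {
      nb <- cell_n_bio(config, r, gt)
      expand.grid(tech_rep = seq_len(config$n_tech), bio_rep = seq_len(nb),
                  genotype = gt, region = r,
                  stringsAsFactors = FALSE)[, c("region", "genotype", "bio_rep", "tech_rep")]
    }))
  }))
  layout$sample_id <- paste(gsub("[^[:alnum:]]+", "_", layout$region),
                            layout$genotype, layout$bio_rep, "t", layout$tech_rep,
                            sep = "_")
  bio_unit <- paste(layout$region, layout$genotype, layout$bio_rep, sep = "\r")
  units <- unique(bio_unit)
  n_s <- nrow(layout)
  second <- config$genotypes[2]
  cq <- matrix(NA_real_, length(config$genes), n_s,
               dimnames = list(names(config$genes), layout$sample_id))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  for (i in seq_along(config$genes)) {
    g <- config$genes[[i]]
    set.seed(as.integer((as.numeric(seed) + 7919 * i) %% 2147483647))
    eps_bio <- stats::setNames(stats::rnorm(length(units), 0, g$bio_sd), units)
    eps_tech <- stats::rnorm(n_s, 0, g$tech_sd)
    drop_u <- stats::runif(n_s)
    mu <- g$base_cq +
      vapply(layout$region, function(r) region_effect_of(g, r), numeric(1)) +
      ifelse(layout$genotype == second,
             vapply(layout$region, function(r) genotype_effect_of(g, r), numeric(1)),
             0)
    v <- mu + eps_bio[bio_unit] + eps_tech
    v[drop_u < g$dropout_p] <- NA_real_
    v[!is.na(v) & v < 0] <- 0
    cq[i, ] <- v
  }
  tab <- cq_table(cq, layout[, c("sample_id", "region", "genotype", "bio_rep", "tech_rep")],
                  design = list(regions = config$regions, genotypes = config$genotypes))
  list(table = tab, truth = simulation_truth(config))
}

#' Generator configuration mirroring the brain-region study design
#'
#' A ready-made [generator_config()] reproducing the structure of the
#' reference-gene study: 11 reference-gene candidates (the 8 that survive
#' screening plus 3 designed-unstable classics: Sdha, B2m, Actb), of which
#' three designed panel genes (Alg5, Hmbs, Gusb) have the smallest noise and
#' no genotype effect; plus target genes with region-specific genotype
#' effects in the directions reported for this mouse model (Igfbp7 up in
#' PWScr with the clearest shifts in hippocampus/hypothalamus/cerebellum,
#' Pcsk1 down in hypothalamus and pons, Pcsk2 up in olfactory
#' bulb/isocortex/hippocampus/medulla, Nhlh2 up in cerebellum/midbrain/
#' hippocampus, and three Nlgn3 isoform assays mildly up everywhere).
#' Layout: 9 regions x 2 genotypes x 3 biological replicates (6 for the WT
#' hypothalamus) x 3 technical replicates.
#'
#' Designed noise levels separate the tiers: panel genes bio_sd = 0.1
#' cycles, remaining screened candidates >= 0.6, designed-unstable
#' candidates >= 1.5 with strong region/genotype structure.
#'
#' @param seed Default seed stored in the config.
#' @return A `generator_config` with attributes `candidates`, `targets`,
#'   `designed_panel` and `designed_unstable`.
#' @export
study_config <- function(seed = 1L) {
  rg <- brain_design()$regions
  re <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  panel <- list(
    gene_spec("Alg5", base_cq = 22.0, bio_sd = 0.1, tech_sd = 0.1),
    gene_spec("Hmbs", base_cq = 26.0, bio_sd = 0.1, tech_sd = 0.1),
    gene_spec("Gusb", base_cq = 27.5, bio_sd = 0.1, tech_sd = 0.1)
  )
  mid <- list(
    gene_spec("Mogs", base_cq = 24.0, bio_sd = 0.6, tech_sd = 0.1,
              region_effects = re(isocortex = 0.2, cerebellum = -0.2)),
    gene_spec("Man2b2", base_cq = 25.5, bio_sd = 0.65, tech_sd = 0.1,
              region_effects = re(thalamus = 0.25, pons = -0.2)),
    gene_spec("Cyc1", base_cq = 21.0, bio_sd = 0.7, tech_sd = 0.1,
              region_effects = re(cerebellum = -0.3, medulla = 0.2),
              genotype_effect = 0.1),
    gene_spec("Snhg12", base_cq = 23.5, bio_sd = 0.9, tech_sd = 0.1,
              region_effects = re(hippocampus = 0.4, hypothalamus = -0.4),
              genotype_effect = 0.2),
    gene_spec("Tfrc", base_cq = 24.5, bio_sd = 0.9, tech_sd = 0.1,
              region_effects = re("olfactory bulb" = 0.5, midbrain = -0.4),
              genotype_effect = 0.25)
  )
  unstable <- list(
    gene_spec("Sdha", base_cq = 23.0, bio_sd = 1.6, tech_sd = 0.15,
              region_effects = re(cerebellum = 1.2, hypothalamus = -1.0,
                                  isocortex = 0.8),
              genotype_effect = 0.5),
    gene_spec("B2m", base_cq = 20.0, bio_sd = 1.8, tech_sd = 0.15,
              region_effects = re("olfactory bulb" = 1.5, medulla = -1.2,
                                  pons = 0.9),
              genotype_effect = -0.6),
    gene_spec("Actb", base_cq = 17.5, bio_sd = 2.0, tech_sd = 0.15,
              region_effects = re(hippocampus = 1.4, thalamus = -1.3,
                                  midbrain = 1.0),
              genotype_effect = 0.7)
  )
  targets <- list(
    gene_spec("Igfbp7", base_cq = 21.0, bio_sd = 0.25, tech_sd = 0.1,
              region_effects = re(hypothalamus = -0.5, cerebellum = -0.3,
                                  pons = 0.6),
              genotype_effect = re(hippocampus = -0.5, hypothalamus = -0.5,
                                   cerebellum = -0.5, "olfactory bulb" = -0.15,
                                   isocortex = -0.15, thalamus = -0.15,
                                   midbrain = -0.15, pons = -0.15,
                                   medulla = -0.15)),
    gene_spec("Pcsk1", base_cq = 26.0, bio_sd = 0.25, tech_sd = 0.1,
              region_effects = re(hypothalamus = -1.5, "olfactory bulb" = -1.2,
                                  isocortex = -1.0, hippocampus = 1.0),
              genotype_effect = re(hypothalamus = 1.0, pons = 0.45)),
    gene_spec("Pcsk2", base_cq = 24.0, bio_sd = 0.25, tech_sd = 0.1,
              region_effects = re(isocortex = -1.2, hippocampus = -0.6,
                                  thalamus = -0.5, "olfactory bulb" = 0.8,
                                  cerebellum = 0.8, pons = 0.8),
              genotype_effect = re("olfactory bulb" = -0.45, isocortex = -0.45,
                                   hippocampus = -0.4, medulla = -0.4)),
    gene_spec("Nhlh2", base_cq = 28.0, bio_sd = 0.3, tech_sd = 0.15,
              region_effects = re(cerebellum = -2.0, thalamus = -1.0,
                                  hypothalamus = -0.8, "olfactory bulb" = 3.0,
                                  isocortex = 5.0),
              genotype_effect = re(cerebellum = -1.0, midbrain = -1.0,
                                   hippocampus = -0.55)),
    gene_spec("Nlgn3_total", base_cq = 22.5, bio_sd = 0.2, tech_sd = 0.1,
              region_effects = re(hippocampus = -0.5, isocortex = -0.4,
                                  "olfactory bulb" = -0.35, hypothalamus = -0.3,
                                  cerebellum = 0.5, medulla = 0.4),
              genotype_effect = re("olfactory bulb" = -0.2, isocortex = -0.2,
                                   hippocampus = -0.2, thalamus = -0.2,
                                   hypothalamus = -0.2, midbrain = -0.2,
                                   cerebellum = -0.2, medulla = -0.2)),
    gene_spec("Nlgn3_iso1", base_cq = 25.0, bio_sd = 0.2, tech_sd = 0.1,
              region_effects = re(thalamus = -0.5, hippocampus = -0.45,
                                  isocortex = -0.4, "olfactory bulb" = -0.35,
                                  hypothalamus = 0.6),
              genotype_effect = -0.26),
    gene_spec("Nlgn3_iso2", base_cq = 24.0, bio_sd = 0.2, tech_sd = 0.1,
              region_effects = re(hippocampus = -0.5, isocortex = -0.45,
                                  "olfactory bulb" = -0.4),
              genotype_effect = -0.26)
  )
  genes <- c(panel, mid, unstable, targets)
  cfg <- generator_config(
    genes, regions = rg, genotypes = c("WT", "PWScr"),
    n_bio = 3, n_tech = 3,
    n_bio_overrides = data.frame(region = "hypothalamus", genotype = "WT",
                                 n_bio = 6, stringsAsFactors = FALSE),
    seed = seed
  )
  attr(cfg, "candidates") <- c("Alg5", "Hmbs", "Gusb", "Mogs", "Man2b2",
                               "Cyc1", "Snhg12", "Tfrc", "Sdha", "B2m", "Actb")
  attr(cfg, "targets") <- c("Igfbp7", "Pcsk1", "Pcsk2", "Nhlh2",
                            "Nlgn3_total", "Nlgn3_iso1", "Nlgn3_iso2")
  attr(cfg, "designed_panel") <- c("Alg5", "Gusb", "Hmbs")
  attr(cfg, "designed_unstable") <- c("Actb", "B2m", "Sdha")
  cfg
}
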