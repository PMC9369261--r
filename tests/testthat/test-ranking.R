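fake_result <- function(method, ranks) {
  values <- ranks / 10
  refstab:::new_stability_result(method, values, ranks)
}

fake_suite <- function(rank_matrix) {
  # rank_matrix: methods x genes, rownames the four methods
  lapply(rownames(rank_matrix), function(m) {
    fake_result(m, setNames(rank_matrix[m, ], colnames(rank_matrix)))
  })
}

methods4 <- c("delta_ct", "genorm", "bestkeeper", "normfinder")

test_that("geometric mean of the four ranks drives the final order", {
  rm <- matrix(c(1, 1, 1, 1,   # geomean 1
                 1, 2, 1, 4,   # geomean 8^(1/4)
                 3, 3, 3, 2),  # clearly worse
               nrow = 4, dimnames = list(methods4, c("a", "b", "c")))
  cr <- comprehensive_rank(fake_suite(rm))
  expect_equal(cr$geomean_rank[["a"]], 1)
  expect_equal(cr$geomean_rank[["b"]], 8^(1 / 4))
  expect_equal(cr$final_order, c("a", "b", "c"))
})

test_that("identical rank vectors tie and break alphabetically", {
  rm <- matrix(c(2, 1, 2, 1,
                 2, 1, 2, 1),
               nrow = 4, dimnames = list(methods4, c("zz", "aa")))
  cr <- comprehensive_rank(fake_suite(rm))
  expect_equal(unname(diff(cr$geomean_rank[c("aa", "zz")])), 0)
  expect_equal(cr$final_order, c("aa", "zz"))
})

test_that("comprehensive ranking is invariant to result order and strict on inputs", {
  rm <- matrix(sample(1:4, 16, replace = TRUE), nrow = 4,
               dimnames = list(methods4, letters[1:4]))
  suite <- fake_suite(rm)
  a <- comprehensive_rank(suite)
  b <- comprehensive_rank(rev(suite))
  expect_equal(a$geomean_rank, b$geomean_rank)

  bad <- suite
  bad[[2]] <- fake_result("genorm", setNames(1:4, c("a", "b", "c", "zzz")))
  expect_error(comprehensive_rank(bad), "zzz")
  expect_error(comprehensive_rank(suite[1:3]), "four")
  expect_error(comprehensive_rank(c(suite[1:3], suite[1])), "normfinder")
})

test_that("improving one method rank never worsens the geometric mean", {
  base <- c(delta_ct = 3, genorm = 2, bestkeeper = 4, normfinder = 2)
  gm <- function(v) exp(mean(log(v)))
  for (m in names(base)) {
    for (better in seq_len(base[[m]])) {
      v <- base
      v[m] <- better
      expect_lte(gm(v), gm(base))
    }
  }
})

test_that("condition sweep keys its output by condition level", {
  sim <- simulate_cq(generator_config(
    list(gene_spec("a", 20, bio_sd = 0.1), gene_spec("b", 24, bio_sd = 0.3),
         gene_spec("c", 27, bio_sd = 0.6), gene_spec("d", 29, bio_sd = 1.0)),
    regions = c("pons", "medulla", "midbrain"), n_bio = 4, n_tech = 1, seed = 9
  ))
  x <- collapse_technical_replicates(sim$table)
  sw <- condition_sweep(x, "within_genotype_across_regions", mode = "pooled")
  expect_named(sw, c("WT", "PWScr"))
  sw2 <- condition_sweep(x, "within_region_across_genotypes", mode = "pooled")
  expect_named(sw2, c("pons", "medulla", "midbrain"))
})

test_that("per-cell averaging of identical rankings equals the common ranking", {
  # noise-free construction: same gene-stability structure in every cell
  regions <- c("pons", "medulla")
  m <- NULL; ann <- NULL
  base <- c(0, 0.4, -0.4, 0.9, -0.9, 1.5)  # per-replicate deviations
  for (r in regions) for (g in c("WT", "PWScr")) {
    cols <- rbind(a = 20 + 0 * base, b = 24 + base, c = 28 + 2 * base)
    colnames(cols) <- paste(r, g, seq_along(base), sep = "_")
    m <- cbind(m, cols)
    ann <- rbind(ann, data.frame(sample_id = colnames(cols), region = r,
                                 genotype = g, bio_rep = seq_along(base),
                                 tech_rep = 1L))
  }
  x <- cq_table(m, ann)
  x$tech_spread <- m * 0
  x$n_tech <- matrix(1L, nrow(m), ncol(m))
  class(x) <- c("collapsed_cq_table", class(x))
  pooled <- condition_sweep(x, "within_genotype_across_regions", mode = "pooled")
  avg <- condition_sweep(x, "within_genotype_across_regions", mode = "per_cell_averaged")
  for (g in c("WT", "PWScr")) {
    expect_equal(avg[[g]]$score, pooled[[g]]$geomean_rank, tolerance = 1e-12)
    expect_equal(avg[[g]]$final_order, pooled[[g]]$final_order)
  }
})

test_that("a gene most stable everywhere wins both sweep modes", {
  cfg <- generator_config(
    list(gene_spec("winner", 22, bio_sd = 0.05),
         gene_spec("mid1", 24, bio_sd = 0.7),
         gene_spec("mid2", 26, bio_sd = 0.8),
         gene_spec("noisy", 28, bio_sd = 1.4)),
    regions = c("pons", "medulla", "thalamus"), n_bio = 4, n_tech = 1, seed = 21
  )
  x <- collapse_technical_replicates(simulate_cq(cfg)$table)
  for (mode in c("pooled", "per_cell_averaged")) {
    sw <- condition_sweep(x, "within_genotype_across_regions", mode = mode)
    for (cond in names(sw)) {
      expect_equal(sw[[cond]]$final_order[1], "winner", info = paste(mode, cond))
    }
  }
})

test_that("panel compilation weights the two axis scores arithmetically", {
  mk <- function(scores) {
    structure(list(score = scores,
                   per_method_ranks = matrix(1, 4, length(scores),
                                             dimnames = list(methods4, names(scores))),
                   final_order = names(sort(scores)), per_cell = list()),
              class = "averaged_ranking")
  }
  region_axis <- list(WT = mk(c(a = 2, b = 1, c = 3)),
                      PWScr = mk(c(a = 2, b = 3, c = 1)))
  genotype_axis <- list(pons = mk(c(a = 4, b = 2, c = 3)))
  p <- compile_panel(region_axis, genotype_axis, weights = c(0.5, 0.5), k = 2)
  expect_equal(p$combined_rank[["a"]], 0.5 * 2 + 0.5 * 4)
  expect_equal(p$combined_rank[["b"]], 0.5 * 2 + 0.5 * 2)
  expect_equal(p$panel, c("b", "c"))

  # degenerate weighting: region axis alone decides (here all tied at 2)
  p2 <- compile_panel(region_axis, genotype_axis, weights = c(1, 0), k = 1)
  expect_equal(unname(p2$combined_rank), c(2, 2, 2))
  expect_equal(p2$panel, "a")
  p3 <- compile_panel(region_axis, genotype_axis, weights = c(0, 1), k = 1)
  expect_equal(p3$panel, "b")

  expect_error(compile_panel(region_axis, genotype_axis, weights = c(0.7, 0.6)),
               "summing to 1")
  bad_axis <- list(pons = mk(c(a = 1, zzz = 2, c = 3)))
  expect_error(compile_panel(region_axis, bad_axis), "zzz")
})

test_that("equal axis scores fall back to the deterministic alphabetical order", {
  mk <- function(scores) structure(list(score = scores), class = "averaged_ranking")
  eq <- list(x = mk(c(b = 2, a = 2, c = 2)))
  p <- compile_panel(eq, eq, k = 3)
  expect_equal(p$panel, c("a", "b", "c"))
})

test_that("screening truncates the final order", {
  rm <- matrix(rep(c(2, 1, 3), each = 4), nrow = 4,
               dimnames = list(methods4, c("a", "b", "c")))
  cr <- comprehensive_rank(fake_suite(rm))
  expect_equal(screen_candidates(cr, 3), cr$final_order)
  expect_equal(screen_candidates(cr, 2), c("b", "a"))
  expect_equal(screen_candidates(cr, 0), character(0))
  expect_error(screen_candidates(cr, 4), "exceeds")
})
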