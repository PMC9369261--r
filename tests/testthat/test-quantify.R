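panel3 <- c("p1", "p2", "p3")

quant_table <- function(target_cq, panel_cq = list(c(20), c(21), c(19)),
                        region = "pons", genotype = "WT") {
  n <- length(target_cq)
  m <- rbind(
    t = target_cq,
    p1 = rep_len(panel_cq[[1]], n),
    p2 = rep_len(panel_cq[[2]], n),
    p3 = rep_len(panel_cq[[3]], n)
  )
  rownames(m) <- c("t", panel3)
  make_collapsed(m, region = region, genotype = genotype)
}

test_that("relative expression is 2^-(Cq_target - panel mean)", {
  x <- quant_table(25)
  res <- relative_expression(x, "t", panel3)
  expect_equal(res$mean, 2^-5)  # 25 - mean(20, 21, 19) = 5
  expect_equal(res$n, 1L)
  expect_true(is.na(res$sd))

  # target equal to the panel mean gives exactly 1
  res1 <- relative_expression(quant_table(20), "t", panel3)
  expect_equal(res1$mean, 1)
})

test_that("reducing the target Cq by one cycle doubles expression", {
  x1 <- quant_table(c(25, 24.5, 26))
  x2 <- quant_table(c(24, 23.5, 25))
  r1 <- relative_expression(x1, "t", panel3)
  r2 <- relative_expression(x2, "t", panel3)
  expect_equal(r2$rel[[1]], 2 * r1$rel[[1]], tolerance = 1e-12)
})

test_that("a constant shift of all genes in a replicate cancels", {
  m <- rbind(t = c(25, 26), p1 = c(20, 21), p2 = c(21, 22), p3 = c(19, 20))
  x <- make_collapsed(m)
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 3.7
  y <- make_collapsed(shifted)
  expect_equal(relative_expression(x, "t", panel3)$rel[[1]][1],
               relative_expression(y, "t", panel3)$rel[[1]][1], tolerance = 1e-12)
  # replicate 1 unshifted in both tables; shifted replicate unchanged too
  expect_equal(relative_expression(x, "t", panel3)$rel[[1]],
               relative_expression(y, "t", panel3)$rel[[1]], tolerance = 1e-12)
})

test_that("input contracts: target not in panel, replicate dropping", {
  x <- quant_table(c(25, 26))
  expect_error(relative_expression(x, "p1", panel3), "panel")
  expect_error(relative_expression(x, "absent", panel3), "absent")

  m <- rbind(t = c(25, NA, 26), p1 = 20, p2 = 21, p3 = 19)
  rownames(m) <- c("t", panel3)
  y <- make_collapsed(m)
  expect_warning(res <- relative_expression(y, "t", panel3), "dropping 1")
  expect_equal(res$n, 2L)

  m2 <- rbind(t = c(NA, NA), p1 = 20, p2 = 21, p3 = 19)
  rownames(m2) <- c("t", panel3)
  expect_error(suppressWarnings(relative_expression(make_collapsed(m2), "t", panel3)),
               "no usable replicate")
})

test_that("Monte-Carlo: dCq ~ N(3, 0.1^2) at n = 100 recovers 2^-3", {
  cfg <- generator_config(
    list(gene_spec("ref", 20, bio_sd = 0, tech_sd = 0),
         gene_spec("ref2", 22, bio_sd = 0, tech_sd = 0),
         gene_spec("ref3", 24, bio_sd = 0, tech_sd = 0),
         gene_spec("tgt", 25, bio_sd = 0.1, tech_sd = 0)),
    regions = "pons", n_bio = 100, n_tech = 1, seed = 77
  )
  x <- collapse_technical_replicates(simulate_cq(cfg)$table)
  res <- relative_expression(subset_condition(x, genotype = "WT"), "tgt",
                             c("ref", "ref2", "ref3"))
  # lognormal mean correction is exp((0.1 ln2)^2 / 2) ~ 1.0024: negligible
  se <- res$sd[1] / sqrt(res$n[1])
  expect_lt(abs(res$mean[1] - 2^-3), 3 * se + 2^-3 * 0.003)
})

test_that("group comparison matches a hand-coded t-test and is symmetric", {
  x <- quant_table(c(25, 25.3, 24.8), genotype = "WT")
  y <- quant_table(c(24.2, 24.0, 24.4), genotype = "PWScr")
  a <- relative_expression(x, "t", panel3)
  b <- relative_expression(y, "t", panel3)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$p_value, oracle_t_test(a$rel[[1]], b$rel[[1]], var_equal = TRUE),
               tolerance = 1e-10)
  cmpw <- compare_groups(a, b, var_equal = FALSE)
  expect_equal(cmpw$p_value, oracle_t_test(a$rel[[1]], b$rel[[1]], var_equal = FALSE),
               tolerance = 1e-10)

  rev_cmp <- compare_groups(b, a)
  expect_equal(rev_cmp$p_value, cmp$p_value, tolerance = 1e-12)
  expect_equal(rev_cmp$fold_change, 1 / cmp$fold_change, tolerance = 1e-12)
})

test_that("Student and Welch agree for equal n and equal sample variance", {
  x <- quant_table(c(25, 25.5, 24.7, 25.2), genotype = "WT")
  a <- relative_expression(x, "t", panel3)
  va <- a$rel[[1]]
  # shifted copy: identical sample variance and equal n, where Welch's df
  # reduces exactly to Student's
  b <- a
  b$rel <- I(list(va + 0.01))
  b$mean <- mean(b$rel[[1]])
  b$genotype <- "PWScr"
  s <- compare_groups(a, b, var_equal = TRUE)
  w <- compare_groups(a, b, var_equal = FALSE)
  expect_equal(s$p_value, w$p_value, tolerance = 1e-12)
})

test_that("identical groups give fold change 1 and p = 1", {
  m <- rbind(t = c(25, 25, 25), p1 = 20, p2 = 21, p3 = 19)
  rownames(m) <- c("t", panel3)
  a <- suppressWarnings(relative_expression(make_collapsed(m, genotype = "WT"),
                                            "t", panel3))
  b <- suppressWarnings(relative_expression(make_collapsed(m, genotype = "PWScr"),
                                            "t", panel3))
  w <- capture_warnings(cmp <- compare_groups(a, b))
  expect_equal(cmp$fold_change, 1)
  expect_equal(cmp$p_value, 1)
  expect_match(w, "constant", all = FALSE)
})

test_that("significance labels follow the star convention", {
  expect_equal(refstab:::significance_label(0.03), "*")
  expect_equal(refstab:::significance_label(0.005), "**")
  expect_equal(refstab:::significance_label(0.0005), "***")
  expect_equal(refstab:::significance_label(0.2), "ns")
  expect_equal(refstab:::significance_label(0.05), "*")   # thresholds inclusive
  expect_equal(refstab:::significance_label(0.01), "**")
  expect_equal(refstab:::significance_label(0.001), "***")
})

test_that("labels stay consistent with p-values across a sweep", {
  set.seed(31)
  for (i in 1:10) {
    x <- quant_table(25 + rnorm(4, 0, 0.3), genotype = "WT")
    y <- quant_table(25 + rnorm(4, -i / 10, 0.3), genotype = "PWScr")
    a <- relative_expression(x, "t", panel3)
    b <- relative_expression(y, "t", panel3)
    cmp <- suppressWarnings(compare_groups(a, b))  # occasional normality flags
    expected <- if (cmp$p_value <= 0.001) "***" else if (cmp$p_value <= 0.01) "**"
                else if (cmp$p_value <= 0.05) "*" else "ns"
    expect_equal(cmp$label, expected)
    expect_gt(cmp$fold_change, 0)
  }
})

test_that("isoform profiling batches assays and checks their presence", {
  cfg <- generator_config(
    list(gene_spec("ref", 20, bio_sd = 0.05, tech_sd = 0),
         gene_spec("ref2", 22, bio_sd = 0.05, tech_sd = 0),
         gene_spec("ref3", 24, bio_sd = 0.05, tech_sd = 0),
         gene_spec("total", 23, bio_sd = 0.1, tech_sd = 0, genotype_effect = -0.2),
         gene_spec("iso1", 25, bio_sd = 0.1, tech_sd = 0, genotype_effect = -0.26),
         gene_spec("iso2", 26, bio_sd = 0.1, tech_sd = 0, genotype_effect = -0.26)),
    regions = "pons", n_bio = 60, n_tech = 1, seed = 13
  )
  x <- collapse_technical_replicates(simulate_cq(cfg)$table)
  prof <- isoform_profile(x, c("total", "iso1", "iso2"), c("ref", "ref2", "ref3"))
  expect_equal(sort(unique(prof$gene)), c("iso1", "iso2", "total"))
  expect_equal(nrow(prof), 3 * 2)  # three assays x two genotypes

  cmp <- do.call(rbind, lapply(c("total", "iso1"), function(g) {
    compare_by_region(prof[prof$gene == g, ])
  }))
  # designed: iso1 shift (0.26 cycles) exceeds total's (0.2) -> fold change
  # further from 1
  expect_gt(abs(cmp$fold_change[cmp$gene == "iso1"] - 1),
            abs(cmp$fold_change[cmp$gene == "total"] - 1))

  expect_error(isoform_profile(x, c("total", "ghost"), c("ref", "ref2", "ref3")),
               "ghost")
})

test_that("mismatched gene or region comparisons are refused", {
  a <- relative_expression(quant_table(c(25, 25.2)), "t", panel3)
  b <- relative_expression(quant_table(c(24, 24.2), region = "medulla",
                                       genotype = "PWScr"), "t", panel3)
  expect_error(compare_groups(a, b), "mismatched")
})
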