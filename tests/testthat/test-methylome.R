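# brute-force per-cytosine filter oracle
oracle_cytosine_filter <- function(meth, groups, min_cov, max_cov, min_samples) {
  m <- merge(as.data.frame(meth), as.data.frame(groups), by = "sample_id")
  keys <- unique(m[c("chrom", "pos", "strand")])
  keep <- logical(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- m[m$chrom == keys$chrom[i] & m$pos == keys$pos[i] &
               m$strand == keys$strand[i], ]
    ok <- TRUE
    for (g in unique(groups$group)) {
      n_ok <- sum(sub$group == g & sub$total >= min_cov & sub$total <= max_cov)
      if (n_ok < min_samples) ok <- FALSE
    }
    keep[i] <- ok
  }
  keys[keep, ]
}

test_that("cytosine filtering keeps exactly the rule-satisfying sites", {
  sim <- simulate_methylomes(methylome_sim_config(
    n_cytosines = 150L, group_sizes = c(anc = 4L, sel = 4L),
    coverage_mu = 12, coverage_size = 2, coverage_range = c(0L, 150L)),
    seed = 11)
  flt <- filter_cytosines(sim$methylation, sim$groups,
                          min_cov = 5, max_cov = 100, min_samples = 2)
  got <- dplyr::distinct(flt, chrom, pos, strand) |> dplyr::arrange(pos)
  expected <- oracle_cytosine_filter(sim$methylation, sim$groups, 5, 100, 2) |>
    dplyr::arrange(pos)
  expect_equal(tibble::as_tibble(got), tibble::as_tibble(expected),
               ignore_attr = TRUE)
  # a cytosine below min coverage everywhere is gone
  low <- dplyr::mutate(sim$methylation,
                       total = ifelse(pos == pos[1], 4L, total),
                       meth = pmin(meth, total))
  flt2 <- filter_cytosines(low, sim$groups, min_cov = 5, max_cov = 100,
                           min_samples = 2)
  expect_false(sim$methylation$pos[1] %in% flt2$pos)
})

test_that("identical group counts give p = 1 and no DMC", {
  meth <- tidyr::expand_grid(pos = c(10L, 20L),
                             sample_id = c("a1", "a2", "b1", "b2")) |>
    dplyr::mutate(chrom = "chr1", strand = "+", context = "CG",
                  meth = 5L, total = 10L)
  groups <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                           group = c("g1", "g1", "g2", "g2"))
  res <- test_dmc(meth, groups, compare = c("g1", "g2"))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
  expect_equal(res$pct_g1, res$pct_g2)
})

test_that("planted methylation shifts are recovered at FDR < 0.05", {
  plan <- tibble::tibble(cytosine = 1:50, group = "sel", shift = 0.5)
  cfg <- methylome_sim_config(
    n_cytosines = 2000L, group_sizes = c(anc = 5L, sel = 5L),
    baseline_beta = list(CG = c(2, 8), CHG = c(2, 8), CHH = c(2, 8)),
    coverage_mu = 30, coverage_size = 10, dmc_plan = plan)
  sim <- suppressWarnings(simulate_methylomes(cfg, seed = 19))
  flt <- filter_cytosines(sim$methylation, sim$groups)
  res <- test_dmc(flt, sim$groups, compare = c("anc", "sel"))
  hits <- dplyr::semi_join(dplyr::filter(res, significant),
                           sim$truth, by = c("chrom", "pos", "strand"))
  planted_tested <- dplyr::semi_join(res, sim$truth,
                                     by = c("chrom", "pos", "strand"))
  expect_gte(nrow(hits) / nrow(planted_tested), 0.8)
})

test_that("the BH conversion controls the false-discovery proportion", {
  cfg <- methylome_sim_config(n_cytosines = 10000L,
                              group_sizes = c(a = 5L, b = 5L),
                              coverage_mu = 30, coverage_size = 10)
  sim <- simulate_methylomes(cfg, seed = 23)
  res <- test_dmc(sim$methylation, sim$groups, compare = c("a", "b"))
  # null data: expected share of FDR-significant cytosines stays near zero
  expect_lte(mean(res$significant), 0.005)
  expect_true(all(res$fdr >= res$p_value))
})

test_that("epigenetic distances are mean absolute percent differences", {
  meth <- tibble::tibble(
    chrom = "chr1", strand = "+", context = "CG",
    pos = rep(c(1L, 2L, 3L), 2),
    sample_id = rep(c("a", "b"), each = 3),
    meth = c(1L, 2L, 3L, 2L, 4L, 3L),
    total = 10L
  )
  # (|10-20| + |20-40| + |30-30|) / 3 = 10
  expect_equal(epigenetic_distance(meth)$distance, 10)
  flipped <- dplyr::mutate(meth, meth = c(0L, 0L, 0L, 10L, 10L, 10L))
  expect_equal(epigenetic_distance(flipped)$distance, 100)
  same <- dplyr::mutate(meth, meth = rep(c(1L, 2L, 3L), 2))
  expect_equal(epigenetic_distance(same)$distance, 0)
})

test_that("centroid distances reproduce exact Euclidean geometry", {
  # points on a line: group a at 0 and 2 (centroid 1, both distances 1),
  # group b at 9, 11, 16 (centroid 12, distances 3, 1, 4)
  pts <- c(a1 = 0, a2 = 2, b1 = 9, b2 = 11, b3 = 16)
  m <- abs(outer(pts, pts, "-"))
  groups <- tibble::tibble(sample_id = names(pts),
                           group = c("a", "a", "b", "b", "b"))
  dt <- dispersion_test(m, groups, n_perm = 99, seed = 1, min_group_size = 2)
  expect_equal(dt$centroid_distances$distance, c(1, 1, 3, 1, 4))
})

test_that("identical point clouds are exchangeable under permutation", {
  pts <- c(a1 = 0, a2 = 2, a3 = 7, b1 = 100, b2 = 102, b3 = 107)
  m <- abs(outer(pts, pts, "-"))
  groups <- tibble::tibble(sample_id = names(pts),
                           group = rep(c("a", "b"), each = 3))
  dt <- dispersion_test(m, groups, n_perm = 99, seed = 3, min_group_size = 3)
  # the two clouds have identical spreads, so the observed F is minimal
  expect_gte(dt$p_value, 0.9)
})

test_that("dispersion test excludes small groups and flags degeneracy", {
  pts <- seq(0, 14, by = 2)
  names(pts) <- sprintf("s%d", seq_along(pts))
  m <- abs(outer(pts, pts, "-"))
  groups <- tibble::tibble(sample_id = names(pts),
                           group = c(rep("a", 4), rep("b", 3), "c"))
  dt <- dispersion_test(m, groups, n_perm = 49, seed = 2, min_group_size = 3)
  expect_setequal(dt$excluded, "s8")
  z <- matrix(0, 8, 8, dimnames = list(names(pts), names(pts)))
  dz <- dispersion_test(z, groups, n_perm = 49, min_group_size = 3)
  expect_true(dz$degenerate)
  expect_true(is.na(dz$p_value))
})

test_that("a variance-inflated group is detected by the dispersion test", {
  detect <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    set.seed(300 + r)
    base <- matrix(rnorm(8 * 20, sd = 1), nrow = 8)
    infl <- matrix(rnorm(8 * 20, sd = 2), nrow = 8)
    x <- rbind(base, infl)
    rownames(x) <- sprintf("s%02d", 1:16)
    m <- as.matrix(dist(x))
    groups <- tibble::tibble(sample_id = rownames(x),
                             group = rep(c("a", "b"), each = 8))
    dt <- dispersion_test(m, groups, n_perm = 199, seed = r)
    detect <- detect + (dt$p_value < 0.05)
  }
  expect_gte(detect / n_rep, 0.7)
})

test_that("DMC annotation windows and context shares are exact", {
  ann <- tibble::tibble(chrom = "chr1",
                        start = c(10000L, 30000L),
                        end = c(12000L, 32000L),
                        strand = "+",
                        feature = c("gene", "TE"),
                        feature_id = c("G1", "T1"))
  dmcs <- tibble::tibble(
    chrom = "chr1",
    pos = c(11000L,          # inside the gene
            8500L,           # 1500 bp upstream of the gene
            20000L,          # far from everything
            29500L),         # 500 bp from the TE only
    context = c("CG", "CG", "CHG", "CHH"))
  res <- annotate_dmcs(dmcs, ann, window = 2000)
  expect_identical(res$per_dmc$near_gene, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(res$per_dmc$near_gene_or_te, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(res$per_dmc$dist_gene, c(0, 1500, 8000, 17500))
  expect_equal(res$summary$frac_near_gene, 0.5)
  expect_equal(res$summary$frac_near_gene_or_te, 0.75)
  expect_equal(res$summary$frac_cg, 0.5)
  expect_warning(annotate_dmcs(dplyr::mutate(dmcs, chrom = "chrX"), ann),
                 "absent")
})

test_that("annotation fractions match a brute-force interval oracle", {
  ann <- simulate_annotation(n_genes = 40L, n_tes = 15L, seed = 8)
  sim <- simulate_methylomes(methylome_sim_config(
    n_cytosines = 500L, group_sizes = c(a = 2L, b = 2L)), seed = 9)
  dmcs <- dplyr::distinct(sim$methylation, chrom, pos, .keep_all = TRUE)[1:200, ]
  res <- annotate_dmcs(dmcs[c("chrom", "pos", "context")], ann, window = 2000)
  brute <- vapply(dmcs$pos, function(p) {
    genes <- ann[ann$feature == "gene", ]
    any(pmax(0, genes$start - p, p - genes$end) <= 2000)
  }, logical(1))
  expect_identical(res$per_dmc$near_gene, brute)
  expect_equal(res$summary$frac_near_gene, mean(brute))
})

test_that("cytosine contexts classify by their downstream two bases", {
  expect_identical(classify_triplet(c("CGA", "CAG", "CTT", "CCG", "CCC")),
                   c("CG", "CHG", "CHH", "CHG", "CHH"))
  expect_true(is.na(classify_triplet("CNG")))
  expect_true(is.na(classify_triplet("ACG")))
  # plus strand read directly; minus strand via reverse complement
  seq <- "ACGAT"
  expect_identical(classify_context(seq, pos = 2, strand = "+"), "CG")
  # position 3 on the minus strand reads CGT -> CG... the reverse
  # complement of positions 1..3 (ACG) is CGT
  expect_identical(classify_context("ACG", pos = 3, strand = "-"), "CG")
  expect_identical(classify_context("TAG", pos = 3, strand = "-"), "CHH")
  expect_true(is.na(classify_context("AC", pos = 2, strand = "+")))
})
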