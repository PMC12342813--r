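# brute-force re-implementation of the two variant filters, applied
# variant by variant on the raw table
oracle_filter <- function(genotypes, meta, min_cov, max_cov, min_cell, maf_min) {
  g <- merge(as.data.frame(genotypes), as.data.frame(meta), by = "sample_id")
  keep <- character(0)
  for (v in unique(g$variant_id)) {
    gv <- g[g$variant_id == v, ]
    ok_cells <- TRUE
    for (cell in split(gv, paste(gv$accession, gv$treatment))) {
      n_ok <- sum(!is.na(cell$coverage) & cell$coverage >= min_cov &
                    cell$coverage <= max_cov)
      if (n_ok < min_cell) ok_cells <- FALSE
    }
    if (!ok_cells) next
    d <- gv$dosage[!is.na(gv$dosage)]
    af <- sum(d) / (2 * length(d))
    if (min(af, 1 - af) >= maf_min) keep <- c(keep, v)
  }
  keep
}

test_that("variant filtering applies the coverage-then-MAF rules in order", {
  sim <- simulate_genotypes(genotype_sim_config(n_variants = 60L), seed = 31)
  g <- sim$genotypes
  # push one variant below min coverage everywhere, another to MAF 0
  g$coverage[g$variant_id == g$variant_id[1]] <- 9
  flt <- filter_variants(g, sim$meta, min_cov = 10, max_cov = 1000,
                         min_samples_per_cell = 4, maf_min = 0.05)
  expect_false(g$variant_id[1] %in% flt$variant_id)
  mono <- g |>
    dplyr::group_by(variant_id) |>
    dplyr::summarise(af = sum(dosage) / (2 * dplyr::n())) |>
    dplyr::filter(pmin(af, 1 - af) < 0.05)
  expect_false(any(mono$variant_id %in% flt$variant_id))
})

test_that("survivor set equals the brute-force filter oracle", {
  set.seed(77)
  meta <- tidyr::expand_grid(accession = c("X", "Y"),
                             treatment = c("t1", "t2"),
                             i = 1:6) |>
    dplyr::mutate(sample_id = sprintf("s%02d", dplyr::row_number()),
                  lineage = paste(accession, treatment, i %% 2))
  g <- tidyr::expand_grid(variant_id = sprintf("v%03d", 1:80),
                          sample_id = meta$sample_id) |>
    dplyr::mutate(dosage = sample(c(0L, 1L, 2L, NA), dplyr::n(),
                                  replace = TRUE,
                                  prob = c(0.45, 0.1, 0.4, 0.05)),
                  coverage = sample(0:40, dplyr::n(), replace = TRUE))
  expected <- sort(oracle_filter(g, meta, 8, 35, 4, 0.1))
  got <- tryCatch(
    sort(unique(filter_variants(g, meta, min_cov = 8, max_cov = 35,
                                min_samples_per_cell = 4,
                                maf_min = 0.1)$variant_id)),
    error = function(e) character(0))
  expect_identical(got, expected)
})

test_that("variant filtering is idempotent", {
  sim <- simulate_genotypes(genotype_sim_config(n_variants = 80L), seed = 9)
  once <- filter_variants(sim$genotypes, sim$meta, min_cov = 10,
                          max_cov = 40, min_samples_per_cell = 2,
                          maf_min = 0.05)
  twice <- filter_variants(once, sim$meta, min_cov = 10, max_cov = 40,
                           min_samples_per_cell = 2, maf_min = 0.05)
  expect_identical(once, twice)
})

test_that("allele distances follow the fraction-of-differing-alleles rule", {
  g <- tibble::tibble(
    variant_id = rep(sprintf("v%d", 1:4), times = 3),
    sample_id = rep(c("a", "b", "c"), each = 4),
    dosage = c(0, 1, 2, NA,
               0, 2, 2, 1,
               2, 2, 0, 1)
  )
  pairs <- allele_distance(g, min_overlap = 3)
  d <- function(x, y) pairs$distance[pairs$sample_a == x & pairs$sample_b == y]
  # (|0-0| + |1-2| + |2-2|) / (2 * 3) jointly typed sites
  expect_equal(d("a", "b"), (0 + 0.5 + 0) / 3)
  expect_equal(d("a", "c"), (1 + 0.5 + 1) / 3)
  # identical and maximally different profiles
  g2 <- tibble::tibble(variant_id = rep(sprintf("v%d", 1:3), 2),
                       sample_id = rep(c("a", "b"), each = 3),
                       dosage = c(0, 0, 2, 0, 0, 2))
  expect_equal(allele_distance(g2, min_overlap = 1)$distance, 0)
  g3 <- tibble::tibble(variant_id = rep(sprintf("v%d", 1:3), 2),
                       sample_id = rep(c("a", "b"), each = 3),
                       dosage = c(0, 0, 2, 2, 2, 0))
  expect_equal(allele_distance(g3, min_overlap = 1)$distance, 1)
  # pairs below the overlap floor are flagged unreliable
  expect_false(all(allele_distance(g, min_overlap = 4)$reliable))
})

test_that("allele distance is a pseudometric on complete data", {
  sim <- simulate_genotypes(genotype_sim_config(n_variants = 200L), seed = 2)
  m <- dist_matrix(allele_distance(sim$genotypes, min_overlap = 1))
  ids <- rownames(m)[1:min(12, nrow(m))]
  m <- m[ids, ids]
  expect_true(all(diag(m) == 0))
  expect_identical(m, t(m))
  for (i in seq_along(ids)) for (j in seq_along(ids)) for (k in seq_along(ids)) {
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
  }
})

test_that("pair classification respects lineage precedence", {
  meta <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         accession = c("X", "X", "X", "Y"),
                         treatment = "t",
                         lineage = c("L1", "L1", "L2", "L3"))
  pairs <- tibble::tibble(sample_a = c("a", "a", "a"),
                          sample_b = c("b", "c", "d"),
                          distance = c(0, 0.01, 0.4),
                          n_sites = 100, reliable = TRUE)
  cls <- classify_pairs(pairs, meta)
  expect_identical(as.character(cls$class),
                   c("within_line", "within_accession", "between_accession"))
  expect_error(classify_pairs(dplyr::mutate(pairs, sample_b = "zz"), meta),
               "absent")
  smry <- pair_class_summary(cls)
  expect_identical(nrow(smry), 3L)
})

test_that("the mix-up threshold is the within-line mean plus three SD", {
  expect_equal(mixup_threshold(c(0.001, 0.002, 0.003)), 0.002 + 3 * 0.001)
  expect_equal(mixup_threshold(c(0.004, 0.004, 0.004)), 0.004)
  expect_error(mixup_threshold(0.001), "at least two")
})

test_that("samples are assigned to the nearest reference accession", {
  sim <- simulate_genotypes(genotype_sim_config(n_variants = 500L,
                                                within_error = 0.002),
                            seed = 15)
  asn <- assign_accessions(sim$genotypes, sim$panel)
  truth <- sim$meta$accession
  expect_identical(asn$assigned_accession[match(sim$meta$sample_id,
                                                asn$sample_id)], truth)
  expect_true(all(asn$best_distance < 0.01))
  expect_true(all(asn$margin > 0.2))
  # single-reference panel: everything maps there
  panel1 <- dplyr::filter(sim$panel, accession == "Abd-0")
  asn1 <- assign_accessions(sim$genotypes, panel1)
  expect_true(all(asn1$assigned_accession == "Abd-0"))
  expect_error(assign_accessions(sim$genotypes,
                                 dplyr::mutate(panel1,
                                               variant_id = paste0("zz",
                                                                   variant_id))),
               "shared")
})

test_that("clean data yield an empty confounding report", {
  sim <- simulate_genotypes(genotype_sim_config(n_variants = 400L), seed = 6)
  rep <- confounding_report(sim$meta,
                            assign_accessions(sim$genotypes, sim$panel))
  expect_false(any(rep$flagged))
  expect_false(attr(rep, "confounded"))
  expect_identical(attr(rep, "n_reassigned"), 0L)
})

test_that("planted mislabels are recovered cell-exactly with the fraction", {
  plan <- tibble::tibble(accession = c("Abd-0", "TRE-1"),
                         treatment = c("high_Cd", "drought"),
                         true_accession = c("Ang-0", "Ang-0"))
  cfg <- genotype_sim_config(n_variants = 1000L, divergence = 0.4,
                             within_error = 0.002, mislabel_plan = plan)
  sim <- simulate_genotypes(cfg, seed = 30)
  asn <- assign_accessions(sim$genotypes, sim$panel)
  rep <- confounding_report(sim$meta, asn)
  flagged <- dplyr::filter(tibble::as_tibble(rep), flagged)
  expect_identical(nrow(flagged), 2L)
  expect_equal(
    dplyr::arrange(flagged[c("accession", "treatment")], accession),
    dplyr::arrange(plan[c("accession", "treatment")], accession),
    ignore_attr = TRUE)
  # every swapped sample reassigned to its true source accession
  expect_identical(unique(flagged$modal_assignment), "Ang-0")
  n_cell <- 4L  # 2 lineages x 2 plants per cell
  expect_identical(attr(rep, "n_reassigned"), 2L * n_cell)
  expect_equal(attr(rep, "frac_reassigned"),
               (2 * n_cell) / nrow(sim$meta))
})
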