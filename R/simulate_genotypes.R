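#' Genotype simulation configuration
#'
#' Settings for simulating near-identical genotypes within accessions and
#' lineages, with configurable between-accession divergence and an optional
#' mislabel plan that reproduces treatment-by-accession confounding: all
#' samples of a mislabelled (accession, treatment) cell are generated from a
#' different accession's genotype while keeping the original label.
#'
#' Accessions are modelled as fully inbred (homozygous, dosage 0 or 2) with
#' independent per-variant alleles whose frequency is chosen so the expected
#' pairwise allele-sharing distance between accessions equals `divergence`.
#' Individual plants deviate from their accession by rare independent
#' homozygous flips, so the expected within-lineage distance equals
#' `within_error`.
#'
#' @param accessions Accession names.
#' @param treatments Treatment labels.
#' @param n_variants Number of biallelic variants (>= 10).
#' @param divergence Expected between-accession allele-difference fraction
#'   (0 < divergence <= 0.5).
#' @param within_error Expected within-accession/lineage difference fraction
#'   (`0 <= within_error << divergence`).
#' @param lineages_per_cell Single-seed-descent lineages per
#'   accession-by-treatment cell.
#' @param samples_per_lineage Plants per lineage (generations along the
#'   descent).
#' @param coverage_range Integer bounds of the per-cell uniform coverage draw.
#' @param mislabel_plan `NULL` or a data frame with columns `accession`,
#'   `treatment`, `true_accession`.
#' @return A list of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(accessions = c("Abd-0", "TRE-1", "Ang-0"),
                                treatments = c("control", "high_Cd", "drought"),
                                n_variants = 2000L,
                                divergence = 0.4,
                                within_error = 0.002,
                                lineages_per_cell = 2L,
                                samples_per_lineage = 2L,
                                coverage_range = c(5L, 60L),
                                mislabel_plan = NULL) {
  stopifnot(length(accessions) >= 2L, n_variants >= 10L,
            divergence > 0, divergence <= 0.5,
            within_error >= 0, within_error < divergence)
  if (!is.null(mislabel_plan)) {
    mislabel_plan <- tibble::as_tibble(mislabel_plan)
    stopifnot(all(c("accession", "treatment", "true_accession") %in%
                    names(mislabel_plan)))
    bad <- setdiff(c(mislabel_plan$accession, mislabel_plan$true_accession),
                   accessions)
    if (length(bad)) {
      stop("Mislabel plan refers to unknown accession(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(accessions = accessions, treatments = treatments,
                 n_variants = as.integer(n_variants), divergence = divergence,
                 within_error = within_error,
                 lineages_per_cell = as.integer(lineages_per_cell),
                 samples_per_lineage = as.integer(samples_per_lineage),
                 coverage_range = as.integer(coverage_range),
                 mislabel_plan = mislabel_plan),
            class = "genotype_sim_config")
}

#' Simulate genotypes with injectable accession mix-ups
#'
#' Generates a long genotype table (samples by biallelic variants, dosage
#' 0/1/2 with per-cell coverage), sample metadata (accession label as
#' assigned by the experimenters, treatment, generation, lineage), and an
#' error-free reference panel of the accession genotypes. When the config
#' carries a mislabel plan, the affected cells' samples are drawn from the
#' `true_accession` genotype while keeping the original accession label; the
#' returned `truth` table records the planted swaps.
#'
#' @param config A [genotype_sim_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list with tibbles `genotypes` (`variant_id`, `sample_id`,
#'   `dosage`, `coverage`), `meta` (`sample_id`, `accession`, `treatment`,
#'   `generation`, `lineage`), `panel` (`accession`, `variant_id`, `dosage`)
#'   and `truth` (the mislabel plan, possibly empty).
#' @examples
#' sim <- simulate_genotypes(genotype_sim_config(n_variants = 200), seed = 1)
#' dplyr::count(sim$meta, accession, treatment)
#' @export
simulate_genotypes <- function(config = genotype_sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nv <- config$n_variants
  variant_ids <- sprintf("chr1:%d", sort(sample.int(nv * 100L, nv)))
  # allele frequency giving expected between-accession distance `divergence`
  q <- (1 - sqrt(1 - 2 * config$divergence)) / 2
  panel_mat <- vapply(config$accessions,
                      function(a) 2L * stats::rbinom(nv, 1L, q),
                      integer(nv))
  colnames(panel_mat) <- config$accessions

  plan <- config$mislabel_plan
  true_source <- function(acc, treat) {
    if (!is.null(plan)) {
      hit <- plan$accession == acc & plan$treatment == treat
      if (any(hit)) return(plan$true_accession[which(hit)[1]])
    }
    acc
  }

  meta <- tidyr::expand_grid(accession = config$accessions,
                             treatment = config$treatments,
                             lineage_i = seq_len(config$lineages_per_cell),
                             generation = seq_len(config$samples_per_lineage)) |>
    dplyr::mutate(
      lineage = paste(.data$accession, .data$treatment, .data$lineage_i,
                      sep = "_"),
      sample_id = sprintf("S%03d", dplyr::row_number())
    ) |>
    dplyr::select("sample_id", "accession", "treatment", "generation",
                  "lineage")

  flip_p <- config$within_error / 2
  cov_lo <- config$coverage_range[1]
  cov_hi <- config$coverage_range[2]
  geno <- purrr::pmap_dfr(meta, function(sample_id, accession, treatment,
                                         generation, lineage) {
    src <- true_source(accession, treatment)
    d <- panel_mat[, src]
    if (flip_p > 0) {
      flip <- stats::runif(nv) < flip_p
      d <- ifelse(flip, 2L - d, d)
    }
    tibble::tibble(variant_id = variant_ids, sample_id = sample_id,
                   dosage = as.integer(d),
                   coverage = sample(cov_lo:cov_hi, nv, replace = TRUE))
  })

  panel <- tibble::tibble(
    accession = rep(config$accessions, each = nv),
    variant_id = rep(variant_ids, times = length(config$accessions)),
    dosage = as.integer(panel_mat)
  )
  truth <- if (is.null(plan)) {
    tibble::tibble(accession = character(), treatment = character(),
                   true_accession = character())
  } else plan
  list(genotypes = geno, meta = meta, panel = panel, truth = truth)
}
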