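#' Methylome simulation configuration
#'
#' Settings for simulating per-cytosine bisulfite counts for several
#' treatment groups, with planted differentially methylated cytosines
#' (DMCs). Contexts are drawn multinomially with genome-like proportions
#' (about 13% CG, 15% CHG, 72% CHH in the *Arabidopsis* genome); baseline
#' methylation levels are Beta-distributed per context (CG highest, CHH
#' lowest, as in plant methylomes); coverage is negative-binomial, truncated
#' to configurable bounds so the 5-100 coverage filter is exercisable.
#'
#' @param n_cytosines Number of cytosines (>= 100).
#' @param context_proportions Named fractions for CG, CHG, CHH; must sum to 1.
#' @param group_sizes Named integer vector of samples per group (defaults to
#'   the 7/12/15 ancestral/BB/LE layout).
#' @param baseline_beta Named list of `c(shape1, shape2)` per context for the
#'   per-cytosine baseline methylation probability.
#' @param coverage_mu,coverage_size Negative-binomial coverage parameters.
#' @param coverage_range Truncation bounds for coverage.
#' @param dmc_plan `NULL` or a data frame with columns `cytosine` (index),
#'   `group`, `shift` (added to the methylation probability for that group,
#'   clipped to `[0, 1]` with a warning).
#' @return A list of class `methylome_sim_config`.
#' @export
methylome_sim_config <- function(n_cytosines = 1000L,
                                 context_proportions = c(CG = 0.13, CHG = 0.15,
                                                         CHH = 0.72),
                                 group_sizes = c(ancestral = 7L, BB = 12L,
                                                 LE = 15L),
                                 baseline_beta = list(CG = c(0.4, 1.2),
                                                      CHG = c(0.3, 2.7),
                                                      CHH = c(0.25, 7)),
                                 coverage_mu = 30, coverage_size = 5,
                                 coverage_range = c(0L, 150L),
                                 dmc_plan = NULL) {
  stopifnot(n_cytosines >= 100L, length(group_sizes) >= 2L,
            abs(sum(context_proportions) - 1) < 1e-8,
            all(context_proportions >= 0))
  if (!is.null(dmc_plan)) {
    dmc_plan <- tibble::as_tibble(dmc_plan)
    stopifnot(all(c("cytosine", "group", "shift") %in% names(dmc_plan)))
    bad <- setdiff(dmc_plan$group, names(group_sizes))
    if (length(bad)) {
      stop("DMC plan refers to unknown group(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    stopifnot(all(dmc_plan$cytosine >= 1),
              all(dmc_plan$cytosine <= n_cytosines))
  }
  structure(list(n_cytosines = as.integer(n_cytosines),
                 context_proportions = context_proportions,
                 group_sizes = group_sizes, baseline_beta = baseline_beta,
                 coverage_mu = coverage_mu, coverage_size = coverage_size,
                 coverage_range = as.integer(coverage_range),
                 dmc_plan = dmc_plan),
            class = "methylome_sim_config")
}

#' Simulate a three-context methylome with planted DMCs
#'
#' Draws per-cytosine, per-sample (methylated | total) counts: coverage is
#' truncated negative-binomial, the methylated count is binomial with the
#' cytosine's baseline probability, shifted for the groups named in the DMC
#' plan. Returns the long methylation table, the sample-to-group map and the
#' truth table of planted DMCs (empty when no plan was given).
#'
#' @param config A [methylome_sim_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list with tibbles `methylation` (`chrom`, `pos`, `strand`,
#'   `context`, `sample_id`, `meth`, `total`), `groups` (`sample_id`,
#'   `group`) and `truth` (`chrom`, `pos`, `strand`, `group`, `shift`).
#' @examples
#' sim <- simulate_methylomes(methylome_sim_config(n_cytosines = 200), seed = 1)
#' dplyr::count(sim$methylation, context)
#' @export
simulate_methylomes <- function(config = methylome_sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- config$n_cytosines
  pos <- sort(sample.int(nc * 50L, nc))
  strand <- sample(c("+", "-"), nc, replace = TRUE)
  ctx_levels <- names(config$context_proportions)
  context <- sample(ctx_levels, nc, replace = TRUE,
                    prob = config$context_proportions)
  p0 <- numeric(nc)
  for (cx in ctx_levels) {
    sel <- context == cx
    b <- config$baseline_beta[[cx]]
    p0[sel] <- stats::rbeta(sum(sel), b[1], b[2])
  }
  groups <- tibble::tibble(
    sample_id = sprintf("%s_%02d",
                        rep(names(config$group_sizes), config$group_sizes),
                        unlist(lapply(config$group_sizes, seq_len))),
    group = rep(names(config$group_sizes), config$group_sizes)
  )
  # per-group probability matrix with planted shifts
  plan <- config$dmc_plan
  clipped <- FALSE
  p_group <- sapply(names(config$group_sizes), function(g) p0)
  if (!is.null(plan) && nrow(plan) > 0) {
    for (k in seq_len(nrow(plan))) {
      i <- plan$cytosine[k]
      g <- plan$group[k]
      p_new <- p_group[i, g] + plan$shift[k]
      if (p_new < 0 || p_new > 1) clipped <- TRUE
      p_group[i, g] <- min(1, max(0, p_new))
    }
    if (clipped) {
      warning("DMC shift(s) pushed methylation probability outside [0, 1]; ",
              "clipped.", call. = FALSE)
    }
  }
  lo <- config$coverage_range[1]
  hi <- config$coverage_range[2]
  meth <- purrr::pmap_dfr(groups, function(sample_id, group) {
    cov <- stats::rnbinom(nc, mu = config$coverage_mu,
                          size = config$coverage_size)
    cov <- pmin(pmax(cov, lo), hi)
    tibble::tibble(chrom = "chr1", pos = pos, strand = strand,
                   context = context, sample_id = sample_id,
                   meth = stats::rbinom(nc, cov, p_group[, group]),
                   total = cov)
  })
  truth <- if (is.null(plan) || nrow(plan) == 0) {
    tibble::tibble(chrom = character(), pos = integer(), strand = character(),
                   group = character(), shift = numeric())
  } else {
    tibble::tibble(chrom = "chr1", pos = pos[plan$cytosine],
                   strand = strand[plan$cytosine], group = plan$group,
                   shift = plan$shift)
  }
  list(methylation = meth, groups = groups, truth = truth)
}

#' Simulate a gene/TE annotation
#'
#' Lays out non-overlapping gene and transposable-element intervals along a
#' chromosome, for exercising DMC proximity summaries.
#'
#' @param n_genes,n_tes Feature counts.
#' @param chrom_length Chromosome length in bp.
#' @param feature_length Mean feature length in bp.
#' @param chrom Chromosome name.
#' @param seed Integer seed, or `NULL`.
#' @return An annotation tibble (`chrom`, `start`, `end`, `strand`,
#'   `feature`, `feature_id`).
#' @export
simulate_annotation <- function(n_genes = 50L, n_tes = 20L,
                                chrom_length = 5e5, feature_length = 2000,
                                chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_genes + n_tes
  starts <- sort(sample.int(chrom_length - 2L * feature_length, n))
  len <- pmax(200L, stats::rpois(n, feature_length))
  ends <- pmin(starts + len - 1L, chrom_length)
  # push apart overlapping neighbours deterministically
  for (i in seq_len(n - 1L)) {
    if (starts[i + 1L] <= ends[i]) starts[i + 1L] <- ends[i] + 1L
    if (ends[i + 1L] < starts[i + 1L]) ends[i + 1L] <- starts[i + 1L] + 199L
  }
  feature <- sample(c(rep("gene", n_genes), rep("TE", n_tes)))
  tibble::tibble(chrom = chrom, start = starts, end = ends,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 feature = feature,
                 feature_id = sprintf("%s%03d", ifelse(feature == "gene",
                                                       "AT1G", "TE"),
                                      seq_len(n)))
}
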