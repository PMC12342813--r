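#' Filter cytosines on per-group coverage
#'
#' Keeps cytosines whose total coverage lies between `min_cov` and `max_cov`
#' in at least `min_samples` samples of *every* group. The default
#' (`min_samples = 2`) is the differential-testing filter; the stricter
#' distance-analysis variant uses `min_samples = 5` per treatment.
#'
#' @param methylation Long methylation tibble (`chrom`, `pos`, `strand`,
#'   `context`, `sample_id`, `meth`, `total`).
#' @param groups Sample-to-group map (`sample_id`, `group`).
#' @param min_cov,max_cov Coverage bounds (defaults 5 and 100).
#' @param min_samples Minimum qualifying samples per group (default 2).
#' @return The filtered long methylation tibble.
#' @export
filter_cytosines <- function(methylation, groups, min_cov = 5, max_cov = 100,
                             min_samples = 2) {
  m <- dplyr::left_join(tibble::as_tibble(methylation), groups,
                        by = "sample_id")
  if (anyNA(m$group)) {
    stop("Sample(s) absent from group map: ",
         paste(unique(m$sample_id[is.na(m$group)]), collapse = ", "),
         call. = FALSE)
  }
  n_groups <- dplyr::n_distinct(groups$group)
  keep <- m |>
    dplyr::filter(.data$total >= min_cov, .data$total <= max_cov) |>
    dplyr::count(.data$chrom, .data$pos, .data$strand, .data$group) |>
    dplyr::filter(.data$n >= min_samples) |>
    dplyr::count(.data$chrom, .data$pos, .data$strand, name = "n_groups_ok") |>
    dplyr::filter(.data$n_groups_ok == n_groups)
  out <- dplyr::semi_join(tibble::as_tibble(methylation), keep,
                          by = c("chrom", "pos", "strand"))
  if (nrow(out) == 0L) {
    stop("No cytosine survives the coverage filter.", call. = FALSE)
  }
  out
}

#' Per-cytosine differential methylation test
#'
#' A two-group comparison per cytosine on the pooled counts: a chi-square
#' test of equal methylation proportions (no continuity correction), with an
#' overdispersion-robust option that deflates the statistic by the
#' per-cytosine quasi-likelihood dispersion estimated from the between-sample
#' Pearson residuals. P-values are converted to FDRs by Benjamini-Hochberg
#' step-up over all tested cytosines (pooled across contexts). This is a
#' deliberately simple stand-in for shrinkage-based bisulfite testers; it is
#' not a reimplementation of them.
#'
#' Cytosines with zero total coverage in either group cannot be tested; they
#' are skipped and counted in the `skipped` attribute.
#'
#' @param methylation Long methylation tibble, typically pre-filtered with
#'   [filter_cytosines()].
#' @param groups Sample-to-group map.
#' @param compare Character vector of the two group labels to compare.
#' @param method `"pooled"` or `"overdispersed"`.
#' @param fdr_threshold Significance threshold on the FDR (default 0.05).
#' @return A tibble with one row per tested cytosine: `chrom`, `pos`,
#'   `strand`, `context`, per-group mean methylation percent
#'   (`pct_<group>`), `statistic`, `p_value`, `fdr`, `significant`.
#'   Attribute `skipped` holds the untestable cytosine count.
#' @export
test_dmc <- function(methylation, groups, compare,
                     method = c("pooled", "overdispersed"),
                     fdr_threshold = 0.05) {
  method <- match.arg(method)
  if (length(compare) != 2L) {
    stop("`compare` must name exactly two groups.", call. = FALSE)
  }
  g <- dplyr::inner_join(tibble::as_tibble(methylation),
                         dplyr::filter(groups, .data$group %in% compare),
                         by = "sample_id")
  if (dplyr::n_distinct(g$group) < 2L) {
    stop("Both groups must have samples in the methylation table.",
         call. = FALSE)
  }
  agg <- g |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand, .data$context,
                    .data$group) |>
    dplyr::summarise(meth = sum(.data$meth), total = sum(.data$total),
                     pct = 100 * mean(ifelse(.data$total > 0,
                                             .data$meth / .data$total, NA)),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("meth", "total", "pct"))
  m1 <- agg[[paste0("meth_", compare[1])]]
  t1 <- agg[[paste0("total_", compare[1])]]
  m2 <- agg[[paste0("meth_", compare[2])]]
  t2 <- agg[[paste0("total_", compare[2])]]
  testable <- !is.na(t1) & !is.na(t2) & t1 > 0 & t2 > 0
  n_skipped <- sum(!testable)
  agg <- agg[testable, ]
  m1 <- m1[testable]; t1 <- t1[testable]
  m2 <- m2[testable]; t2 <- t2[testable]
  p_pool <- (m1 + m2) / (t1 + t2)
  num <- (m1 / t1 - m2 / t2)^2
  den <- p_pool * (1 - p_pool) * (1 / t1 + 1 / t2)
  stat <- ifelse(den > 0, num / den, 0)
  if (method == "overdispersed") {
    phi <- .dmc_dispersion(g, compare)
    key <- paste(agg$chrom, agg$pos, agg$strand)
    stat <- stat / pmax(1, phi[key])
  }
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  res <- tibble::tibble(
    chrom = agg$chrom, pos = agg$pos, strand = agg$strand,
    context = agg$context,
    stats::setNames(tibble::tibble(100 * m1 / t1, 100 * m2 / t2),
                    paste0("pct_", compare)),
    statistic = stat, p_value = p,
    fdr = stats::p.adjust(p, method = "BH")
  )
  res$significant <- res$fdr < fdr_threshold
  attr(res, "skipped") <- n_skipped
  res
}

# per-cytosine quasi-likelihood dispersion: sum over samples of squared
# Pearson residuals against the group-pooled proportion, divided by the
# residual degrees of freedom (n_samples - 2 groups)
.dmc_dispersion <- function(g, compare) {
  d <- g |>
    dplyr::filter(.data$total > 0) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand, .data$group) |>
    dplyr::mutate(p_hat = sum(.data$meth) / sum(.data$total)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      pearson2 = ifelse(.data$p_hat > 0 & .data$p_hat < 1,
                        (.data$meth - .data$total * .data$p_hat)^2 /
                          (.data$total * .data$p_hat * (1 - .data$p_hat)),
                        0)) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
    dplyr::summarise(phi = sum(.data$pearson2) / max(1, dplyr::n() - 2),
                     .groups = "drop")
  stats::setNames(d$phi, paste(d$chrom, d$pos, d$strand))
}

#' Pairwise epigenetic distances
#'
#' The epigenetic distance between two samples is the average absolute
#' difference in percent methylation across all cytosines jointly covered in
#' both samples. (A signed average would cancel opposing differences, so the
#' absolute difference is used.) Values are on the 0-100 percent scale.
#'
#' @param methylation Long methylation tibble; for the distance analysis the
#'   stricter filter (`min_samples = 5` per treatment, coverage 5-100) is the
#'   convention, applied beforehand with [filter_cytosines()].
#' @param min_overlap Minimum jointly covered cytosines for a reliable pair.
#' @return A pair tibble (`sample_a`, `sample_b`, `distance`, `n_sites`,
#'   `reliable`).
#' @export
epigenetic_distance <- function(methylation, min_overlap = 1) {
  m <- tibble::as_tibble(methylation) |>
    dplyr::mutate(key = paste(.data$chrom, .data$pos, .data$strand),
                  pct = ifelse(.data$total > 0,
                               100 * .data$meth / .data$total, NA_real_)) |>
    dplyr::select("key", "sample_id", "pct") |>
    tidyr::pivot_wider(names_from = "key", values_from = "pct")
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m$sample_id
  if (nrow(mat) < 2L) stop("Need at least two samples.", call. = FALSE)
  .pairwise_mean_absdiff(mat, scale = 1, min_overlap = min_overlap)
}

#' Permutation test of multivariate dispersion
#'
#' Compares the spread of groups in the space implied by a distance matrix:
#' samples are embedded by principal-coordinates decomposition (negative
#' eigenvalues retained as imaginary axes), each sample's distance to its
#' group centroid is computed, and group differences in these centroid
#' distances are tested by an F statistic whose null distribution is obtained
#' by permuting group labels. Groups with fewer than `min_group_size` samples
#' are excluded. Implemented via [vegan::betadisper()] and
#' [vegan::permutest()].
#'
#' @param distances Pair tibble ([epigenetic_distance()]) or a symmetric
#'   distance matrix.
#' @param groups Sample-to-group map (`sample_id`, `group`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations, or `NULL`.
#' @param min_group_size Minimum samples per group (default 4).
#' @return An object of class `dispersion_test`: list with
#'   `centroid_distances` (tibble `sample_id`, `group`, `distance`),
#'   `statistic`, `p_value` (overall), `pairwise_p` (tibble), `n_perm`,
#'   `excluded` (dropped samples), `degenerate` flag.
#' @export
dispersion_test <- function(distances, groups, n_perm = 999, seed = NULL,
                            min_group_size = 4) {
  m <- if (is.matrix(distances)) distances else dist_matrix(distances)
  if (anyNA(m)) {
    stop("Distance matrix contains missing values; increase overlap or ",
         "filter samples.", call. = FALSE)
  }
  grp <- stats::setNames(groups$group, groups$sample_id)[rownames(m)]
  if (anyNA(grp)) {
    stop("Sample(s) absent from group map: ",
         paste(rownames(m)[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  sizes <- table(grp)
  keep_groups <- names(sizes)[sizes >= min_group_size]
  excluded <- rownames(m)[!grp %in% keep_groups]
  keep <- grp %in% keep_groups
  m <- m[keep, keep, drop = FALSE]
  grp <- factor(grp[keep])
  if (nlevels(grp) < 2L) {
    stop("Need at least two groups with >= ", min_group_size, " samples.",
         call. = FALSE)
  }
  if (all(m == 0)) {
    return(structure(list(
      centroid_distances = tibble::tibble(sample_id = rownames(m),
                                          group = as.character(grp),
                                          distance = 0),
      statistic = NA_real_, p_value = NA_real_,
      pairwise_p = NULL, n_perm = n_perm, excluded = excluded,
      degenerate = TRUE), class = "dispersion_test"))
  }
  bd <- vegan::betadisper(stats::as.dist(m), grp, type = "centroid")
  if (!is.null(seed)) set.seed(seed)
  pt <- vegan::permutest(bd, permutations = n_perm, pairwise = TRUE)
  pw <- pt$pairwise$permuted
  pairwise_p <- if (!is.null(pw)) {
    tibble::tibble(pair = names(pw), p_value = unname(pw))
  } else NULL
  structure(list(
    centroid_distances = tibble::tibble(sample_id = rownames(m),
                                        group = as.character(grp),
                                        distance = unname(bd$distances)),
    statistic = pt$tab$F[1],
    p_value = pt$tab$`Pr(>F)`[1],
    pairwise_p = pairwise_p,
    n_perm = n_perm, excluded = excluded, degenerate = FALSE),
    class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  if (x$degenerate) {
    cat("Dispersion test: degenerate (all distances zero); p undefined\n")
    return(invisible(x))
  }
  cat(sprintf("Dispersion test (permutation, %d perms): F = %.3f, p = %.4g\n",
              x$n_perm, x$statistic, x$p_value))
  if (!is.null(x$pairwise_p)) {
    cat("Pairwise p-values:\n")
    print(as.data.frame(x$pairwise_p), row.names = FALSE)
  }
  invisible(x)
}

#' @rdname tidy.strata_anova
#' @export
tidy.dispersion_test <- function(x, ...) x$centroid_distances

#' @rdname glance.strata_anova
#' @export
glance.dispersion_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_perm = x$n_perm, degenerate = x$degenerate)
}

#' Plot group dispersions
#'
#' Boxplots of distances to the group centroid, the visual companion of
#' [dispersion_test()].
#'
#' @param object A `dispersion_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dispersion_test <- function(object, ...) {
  ggplot2::ggplot(object$centroid_distances,
                  ggplot2::aes(x = .data$group, y = .data$distance)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Distance to group centroid") +
    ggplot2::theme_minimal()
}

#' Annotate DMCs by proximity to genes and transposable elements
#'
#' For each differentially methylated cytosine, computes the distance to the
#' nearest gene (0 if inside, otherwise base pairs to the nearest boundary)
#' and flags whether it lies within `window` bp of a gene, and of a gene or
#' TE. The summary reports the two fractions and the context shares of the
#' DMC set. DMCs on chromosomes absent from the annotation are counted as
#' unannotated with a warning.
#'
#' @param dmcs Tibble with `chrom`, `pos`, `context` (e.g. the significant
#'   rows of [test_dmc()]).
#' @param annotation Annotation tibble ([read_annotation()] or
#'   [simulate_annotation()]).
#' @param window Proximity window in bp (default 2000).
#' @return A list with `per_dmc` (input plus `dist_gene`, `dist_gene_or_te`,
#'   `near_gene`, `near_gene_or_te`) and `summary` (tibble with
#'   `frac_near_gene`, `frac_near_gene_or_te`, `n_dmcs`, `n_unannotated` and
#'   per-context shares).
#' @export
annotate_dmcs <- function(dmcs, annotation, window = 2000) {
  dmcs <- tibble::as_tibble(dmcs)
  if (nrow(dmcs) == 0L) stop("Empty DMC set.", call. = FALSE)
  unknown <- setdiff(unique(dmcs$chrom), unique(annotation$chrom))
  if (length(unknown)) {
    warning("DMC(s) on chromosome(s) absent from the annotation: ",
            paste(unknown, collapse = ", "), "; counted as unannotated.",
            call. = FALSE)
  }
  dist_to <- function(ann) {
    if (nrow(ann) == 0L) return(rep(NA_real_, nrow(dmcs)))
    gr_ann <- GenomicRanges::GRanges(ann$chrom,
                                     IRanges::IRanges(ann$start, ann$end))
    gr_dmc <- GenomicRanges::GRanges(dmcs$chrom,
                                     IRanges::IRanges(dmcs$pos, dmcs$pos))
    # chromosomes absent from the annotation are handled explicitly above;
    # silence the seqlevel-mismatch warning that search would re-raise
    hits <- suppressWarnings(GenomicRanges::distanceToNearest(gr_dmc, gr_ann))
    out <- rep(NA_real_, nrow(dmcs))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    # 0 inside a feature, else gap to the nearest boundary in bp
    out[qi] <- pmax(0, ann$start[si] - dmcs$pos[qi],
                    dmcs$pos[qi] - ann$end[si])
    out
  }
  d_gene <- dist_to(dplyr::filter(annotation, .data$feature == "gene"))
  d_any <- dist_to(annotation)
  per_dmc <- dplyr::mutate(dmcs,
                           dist_gene = d_gene,
                           dist_gene_or_te = d_any,
                           near_gene = !is.na(d_gene) & d_gene <= window,
                           near_gene_or_te = !is.na(d_any) & d_any <= window)
  ctx <- prop.table(table(factor(dmcs$context,
                                 levels = c("CG", "CHG", "CHH"))))
  summary <- tibble::tibble(
    n_dmcs = nrow(dmcs),
    n_unannotated = sum(is.na(d_any)),
    frac_near_gene = mean(per_dmc$near_gene),
    frac_near_gene_or_te = mean(per_dmc$near_gene_or_te),
    frac_cg = unname(ctx["CG"]),
    frac_chg = unname(ctx["CHG"]),
    frac_chh = unname(ctx["CHH"])
  )
  list(per_dmc = per_dmc, summary = summary)
}

#' Classify the sequence context of a cytosine
#'
#' A cytosine's context is read from the two bases following it on its own
#' strand: `CG` when followed by G; `CHG` when followed by H then G; `CHH`
#' otherwise (H is A, T or C). Reverse-strand cytosines are classified on the
#' reverse complement. Triplets containing an ambiguous base (N) yield `NA`.
#'
#' @param sequence Chromosome sequence as a single character string
#'   (plus strand).
#' @param pos 1-based position(s) of the cytosine on the plus strand.
#' @param strand `"+"` or `"-"` per position.
#' @return Character vector of `"CG"`, `"CHG"`, `"CHH"` or `NA`.
#' @examples
#' classify_context("ACGAT", pos = 2, strand = "+") # "CG"
#' @export
classify_context <- function(sequence, pos, strand = "+") {
  strand <- rep_len(strand, length(pos))
  n <- nchar(sequence)
  triplet <- character(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (strand[i] == "+") {
      if (p + 2 > n) { triplet[i] <- NA_character_; next }
      triplet[i] <- substr(sequence, p, p + 2)
    } else {
      if (p - 2 < 1) { triplet[i] <- NA_character_; next }
      rev3 <- paste(rev(strsplit(substr(sequence, p - 2, p), "")[[1]]),
                    collapse = "")
      triplet[i] <- chartr("ACGTacgt", "TGCATGCA", rev3)
    }
  }
  classify_triplet(triplet)
}

#' @rdname classify_context
#' @param triplet Character vector of three-base strings starting with the
#'   cytosine, already on the cytosine's strand.
#' @export
classify_triplet <- function(triplet) {
  triplet <- toupper(triplet)
  b1 <- substr(triplet, 1, 1)
  b2 <- substr(triplet, 2, 2)
  b3 <- substr(triplet, 3, 3)
  h <- c("A", "T", "C")
  out <- rep(NA_character_, length(triplet))
  valid <- b1 == "C" & b2 %in% c("A", "C", "G", "T") & b3 %in% c("A", "C", "G", "T")
  out[valid & b2 == "G"] <- "CG"
  out[valid & b2 %in% h & b3 == "G"] <- "CHG"
  out[valid & b2 %in% h & b3 %in% h] <- "CHH"
  out
}
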