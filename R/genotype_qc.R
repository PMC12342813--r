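#' Filter variants on per-cell coverage and minor allele frequency
#'
#' Applies the two variant filters in their fixed order: (1) keep variants
#' whose coverage lies between `min_cov` and `max_cov` in at least
#' `min_samples_per_cell` samples of *every* accession-by-treatment cell
#' present in the metadata; (2) among the survivors, remove variants whose
#' minor allele frequency over all samples (computed from the non-missing
#' dosages) is below `maf_min`. The operation is idempotent.
#'
#' @param genotypes Long genotype tibble (`variant_id`, `sample_id`,
#'   `dosage`, `coverage`).
#' @param meta Sample metadata with `sample_id`, `accession`, `treatment`.
#' @param min_cov,max_cov Coverage bounds (defaults 10 and 1000).
#' @param min_samples_per_cell Minimum qualifying samples per cell (4).
#' @param maf_min Minor-allele-frequency cutoff (0.05).
#' @return The filtered long genotype tibble.
#' @export
filter_variants <- function(genotypes, meta, min_cov = 10, max_cov = 1000,
                            min_samples_per_cell = 4, maf_min = 0.05) {
  if (!"coverage" %in% names(genotypes)) {
    stop("Coverage column required for variant filtering.", call. = FALSE)
  }
  g <- dplyr::left_join(tibble::as_tibble(genotypes),
                        dplyr::select(meta, "sample_id", "accession",
                                      "treatment"),
                        by = "sample_id")
  if (anyNA(g$accession)) {
    stop("Sample(s) absent from metadata: ",
         paste(unique(g$sample_id[is.na(g$accession)]), collapse = ", "),
         call. = FALSE)
  }
  n_cells <- nrow(dplyr::distinct(g, .data$accession, .data$treatment))
  cov_ok <- g |>
    dplyr::filter(!is.na(.data$coverage), .data$coverage >= min_cov,
                  .data$coverage <= max_cov) |>
    dplyr::count(.data$variant_id, .data$accession, .data$treatment) |>
    dplyr::filter(.data$n >= min_samples_per_cell) |>
    dplyr::count(.data$variant_id, name = "n_cells_ok") |>
    dplyr::filter(.data$n_cells_ok == n_cells)
  out <- dplyr::filter(tibble::as_tibble(genotypes),
                       .data$variant_id %in% cov_ok$variant_id)
  maf <- out |>
    dplyr::filter(!is.na(.data$dosage)) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(af = sum(.data$dosage) / (2 * dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(maf = pmin(.data$af, 1 - .data$af)) |>
    dplyr::filter(.data$maf >= maf_min)
  out <- dplyr::filter(out, .data$variant_id %in% maf$variant_id)
  if (nrow(out) == 0L) {
    stop("No variant survives the coverage/MAF filters.", call. = FALSE)
  }
  out
}

# long genotype tibble -> samples x variants dosage matrix
.dosage_matrix <- function(genotypes) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(genotypes), "variant_id", "sample_id",
                  "dosage"),
    names_from = "variant_id", values_from = "dosage")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

# pairwise mean absolute difference of rows of `m`, scaled by `scale`,
# excluding pairwise-incomplete columns
.pairwise_mean_absdiff <- function(m, scale = 1, min_overlap = 1) {
  ids <- rownames(m)
  ns <- nrow(m)
  pairs <- which(upper.tri(matrix(TRUE, ns, ns)), arr.ind = TRUE)
  d <- numeric(nrow(pairs))
  n_sites <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    n_sites[k] <- sum(ok)
    d[k] <- if (n_sites[k] > 0) mean(abs(m[i, ok] - m[j, ok]) / scale) else
      NA_real_
  }
  tibble::tibble(sample_a = ids[pairs[, 1]], sample_b = ids[pairs[, 2]],
                 distance = d, n_sites = n_sites,
                 reliable = n_sites >= min_overlap)
}

#' Pairwise allele-sharing distances
#'
#' The genetic distance between two plants is the fraction of alleles that
#' differ between them: the mean over jointly typed variants of
#' `|dosage_a - dosage_b| / 2`. Missing genotypes are excluded pairwise; a
#' pair with fewer than `min_overlap` jointly typed variants is flagged
#' unreliable (`reliable = FALSE`, distance still reported when at least one
#' site overlaps).
#'
#' @param genotypes Long genotype tibble.
#' @param min_overlap Minimum jointly typed variants for a reliable pair
#'   (default 100; RNA-seq-derived genotypes are sparse).
#' @return A tibble of unordered sample pairs: `sample_a`, `sample_b`,
#'   `distance` in `[0, 1]`, `n_sites`, `reliable`.
#' @export
allele_distance <- function(genotypes, min_overlap = 100) {
  m <- .dosage_matrix(genotypes)
  if (nrow(m) < 2L) stop("Need at least two samples.", call. = FALSE)
  .pairwise_mean_absdiff(m, scale = 2, min_overlap = min_overlap)
}

#' Convert a pair table to a symmetric distance matrix
#'
#' @param pairs Pair tibble from [allele_distance()] or
#'   [epigenetic_distance()].
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
dist_matrix <- function(pairs) {
  ids <- sort(unique(c(pairs$sample_a, pairs$sample_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(pairs$sample_a, ids)
  j <- match(pairs$sample_b, ids)
  m[cbind(i, j)] <- pairs$distance
  m[cbind(j, i)] <- pairs$distance
  m
}

#' Classify sample pairs by pedigree relation
#'
#' Assigns each unordered pair exactly one class: `within_line` (same
#' single-seed-descent lineage; takes precedence), `within_accession` (same
#' accession label, different lineage) or `between_accession`.
#'
#' @param pairs Pair tibble from [allele_distance()].
#' @param meta Sample metadata with `sample_id`, `accession` and `lineage`.
#' @return The pair tibble with a `class` column (ordered factor).
#' @export
classify_pairs <- function(pairs, meta) {
  ids <- unique(c(pairs$sample_a, pairs$sample_b))
  absent <- setdiff(ids, meta$sample_id)
  if (length(absent)) {
    stop("Sample(s) absent from metadata: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ma <- meta[match(pairs$sample_a, meta$sample_id), ]
  mb <- meta[match(pairs$sample_b, meta$sample_id), ]
  cls <- dplyr::case_when(
    ma$lineage == mb$lineage ~ "within_line",
    ma$accession == mb$accession ~ "within_accession",
    TRUE ~ "between_accession"
  )
  dplyr::mutate(pairs, class = factor(cls, levels = c("within_line",
                                                      "within_accession",
                                                      "between_accession")))
}

#' Per-class distance summaries
#'
#' @param pairs Classified pair tibble from [classify_pairs()].
#' @return A tibble with per-class `n`, `mean`, `sd`, `max`.
#' @export
pair_class_summary <- function(pairs) {
  pairs |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$distance),
                     sd = stats::sd(.data$distance),
                     max = max(.data$distance), .groups = "drop")
}

#' Mix-up flag line from within-line distances
#'
#' The threshold above which a pairwise distance is incompatible with plants
#' being single-seed descendants: the mean of the within-line distances plus
#' three sample standard deviations (n-1 denominator).
#'
#' @param x Numeric vector of within-line distances, or a classified pair
#'   tibble from [classify_pairs()] (the `within_line` rows are used).
#' @return The threshold value.
#' @examples
#' mixup_threshold(c(0.001, 0.002, 0.003)) # 0.002 + 3 * 0.001 = 0.005
#' @export
mixup_threshold <- function(x) {
  if (is.data.frame(x)) {
    if (!"class" %in% names(x)) {
      stop("Pair table must carry a `class` column; see classify_pairs().",
           call. = FALSE)
    }
    x <- x$distance[x$class == "within_line"]
  }
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    stop("Need at least two within-line distances.", call. = FALSE)
  }
  mean(x) + 3 * stats::sd(x)
}

#' Assign samples to their nearest reference accession
#'
#' Computes the allele-sharing distance from every sample to every reference
#' accession over the variants shared between the experimental data and the
#' panel, and assigns each sample to the closest reference (deterministic
#' lexicographic tie-break). The margin is the runner-up distance minus the
#' best distance.
#'
#' @param genotypes Long genotype tibble of the experimental samples.
#' @param panel Reference panel: long tibble with `accession`, `variant_id`,
#'   `dosage`.
#' @param min_overlap Minimum shared variants per sample-reference pair.
#' @return A tibble with `sample_id`, `assigned_accession`, `best_distance`,
#'   `runner_up`, `runner_up_distance`, `margin`, `n_shared`.
#' @export
assign_accessions <- function(genotypes, panel, min_overlap = 1) {
  m <- .dosage_matrix(genotypes)
  pw <- tidyr::pivot_wider(tibble::as_tibble(panel),
                           names_from = "variant_id",
                           values_from = "dosage")
  pm <- as.matrix(pw[, -1, drop = FALSE])
  rownames(pm) <- pw$accession
  shared <- intersect(colnames(m), colnames(pm))
  if (length(shared) == 0L) {
    stop("No variants shared between samples and reference panel.",
         call. = FALSE)
  }
  m <- m[, shared, drop = FALSE]
  pm <- pm[order(rownames(pm)), shared, drop = FALSE]
  purrr::map_dfr(rownames(m), function(s) {
    d <- vapply(rownames(pm), function(a) {
      ok <- !is.na(m[s, ]) & !is.na(pm[a, ])
      if (sum(ok) < min_overlap) return(NA_real_)
      mean(abs(m[s, ok] - pm[a, ok]) / 2)
    }, numeric(1))
    if (all(is.na(d))) {
      stop("Sample ", s, ": no reference with sufficient variant overlap.",
           call. = FALSE)
    }
    best <- which.min(d)
    runner <- if (length(d) > 1L) {
      d2 <- d; d2[best] <- NA_real_
      which.min(d2)
    } else NA_integer_
    tibble::tibble(
      sample_id = s,
      assigned_accession = names(d)[best],
      best_distance = unname(d[best]),
      runner_up = if (is.na(runner)) NA_character_ else names(d)[runner],
      runner_up_distance = if (is.na(runner)) NA_real_ else unname(d[runner]),
      margin = if (is.na(runner)) NA_real_ else unname(d[runner] - d[best]),
      n_shared = length(shared)
    )
  })
}

#' Treatment-by-accession confounding report
#'
#' Cross-tabulates each accession-label-by-treatment cell against the
#' genotype-based accession assignments. A cell is flagged when the modal
#' assigned accession of its samples differs from the label; the experiment
#' is reported confounded when any cell is flagged (a coherent remap of a
#' whole treatment cell to a different accession is exactly the signature of
#' a mix-up confounded with treatment). An empty flag list means the labels
#' are clean.
#'
#' @param meta Sample metadata (`sample_id`, `accession`, `treatment`).
#' @param assignments Output of [assign_accessions()].
#' @return An object of class `confounding_report`: a tibble of cells with
#'   `accession`, `treatment`, `n_samples`, `n_mismatched`,
#'   `modal_assignment`, `flagged`; attributes `confounded`, `n_reassigned`,
#'   `frac_reassigned`.
#' @export
confounding_report <- function(meta, assignments) {
  x <- dplyr::left_join(tibble::as_tibble(meta),
                        dplyr::select(assignments, "sample_id",
                                      "assigned_accession"),
                        by = "sample_id")
  if (anyNA(x$assigned_accession)) {
    stop("Assignments missing for sample(s): ",
         paste(x$sample_id[is.na(x$assigned_accession)], collapse = ", "),
         call. = FALSE)
  }
  cells <- x |>
    dplyr::group_by(.data$accession, .data$treatment) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_mismatched = sum(.data$assigned_accession != .data$accession),
      modal_assignment = names(sort(table(.data$assigned_accession),
                                    decreasing = TRUE))[1],
      .groups = "drop") |>
    dplyr::mutate(flagged = .data$modal_assignment != .data$accession)
  structure(cells,
            class = c("confounding_report", class(cells)),
            confounded = any(cells$flagged),
            n_reassigned = sum(x$assigned_accession != x$accession),
            frac_reassigned = mean(x$assigned_accession != x$accession))
}

#' @export
print.confounding_report <- function(x, ...) {
  n_flag <- sum(x$flagged)
  cat(sprintf("Confounding report: %d flagged cell(s); %d/%d samples reassigned (%.1f%%)\n",
              n_flag, attr(x, "n_reassigned"),
              sum(x$n_samples), 100 * attr(x, "frac_reassigned")))
  if (n_flag > 0) {
    print(tibble::as_tibble(x[x$flagged, ]), ...)
  }
  invisible(x)
}

#' Plot pairwise distances by pedigree class
#'
#' Boxplots of within-line, within-accession and between-accession distances
#' with the mix-up flag line (within-line mean + 3 SD) drawn in red.
#'
#' @param pairs Classified pair tibble from [classify_pairs()].
#' @param threshold Flag line; by default computed with [mixup_threshold()].
#' @return A ggplot object.
#' @export
plot_pair_classes <- function(pairs, threshold = mixup_threshold(pairs)) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$class, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = threshold, colour = "red") +
    ggplot2::labs(x = NULL, y = "Allele-sharing distance") +
    ggplot2::theme_minimal()
}
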