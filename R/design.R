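#' Orthogonal contrast coding for the selection experiment
#'
#' Builds the fixed, integer-valued contrast vectors used throughout the
#' analysis: three orthogonal one-degree-of-freedom contrasts over the
#' selection treatments and one contrast over the experimental blocks.
#'
#' * `AN` compares ancestral plants with all plants from the selection
#'   experiment, `(3, -1, -1, -1)` over `(ancestral, control, BB, LE)`.
#' * `CO` compares the control treatment with the two aphid treatments,
#'   `(0, 2, -1, -1)`.
#' * `SE` compares the two aphid treatments with each other,
#'   `(0, 0, 1, -1)`.
#' * `EX` compares blocks 1-3 with blocks 4-5, `(2, 2, 2, -3, -3)`.
#'
#' Each vector sums to zero over its levels and the treatment contrasts are
#' mutually orthogonal. F tests are invariant to rescaling a contrast, so the
#' integer Helmert-style coefficients are a convention, not a choice that
#' affects results.
#'
#' @param st_levels Ordered selection-treatment levels; must be exactly
#'   `c("ancestral", "control", "BB", "LE")`.
#' @param bl_levels Block levels; must be five levels (1..5).
#' @return An object of class `contrast_scheme`: a list with elements
#'   `AN`, `CO`, `SE` (named numeric vectors over `st_levels`) and `EX`
#'   (named numeric vector over `bl_levels`).
#' @examples
#' cs <- encode_contrasts()
#' cs$AN
#' sum(cs$AN * cs$CO) # orthogonal
#' @export
encode_contrasts <- function(st_levels = c("ancestral", "control", "BB", "LE"),
                             bl_levels = 1:5) {
  st_levels <- trimws(as.character(st_levels))
  bl_levels <- trimws(as.character(bl_levels))
  expected_st <- c("ancestral", "control", "BB", "LE")
  if (!identical(st_levels, expected_st)) {
    stop("`st_levels` must be exactly c(\"ancestral\", \"control\", \"BB\", \"LE\") ",
         "in that order; got: ", paste(st_levels, collapse = ", "),
         call. = FALSE)
  }
  if (length(bl_levels) != 5L || anyDuplicated(bl_levels)) {
    stop("`bl_levels` must be five distinct block levels.", call. = FALSE)
  }
  scheme <- list(
    AN = stats::setNames(c(3, -1, -1, -1), st_levels),
    CO = stats::setNames(c(0, 2, -1, -1), st_levels),
    SE = stats::setNames(c(0, 0, 1, -1), st_levels),
    EX = stats::setNames(c(2, 2, 2, -3, -3), bl_levels)
  )
  structure(scheme, class = "contrast_scheme",
            st_levels = st_levels, bl_levels = bl_levels)
}

#' @export
print.contrast_scheme <- function(x, ...) {
  cat("Contrast scheme (zero-sum, mutually orthogonal):\n")
  for (nm in c("AN", "CO", "SE", "EX")) {
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s=%+d", names(x[[nm]]), as.integer(x[[nm]])),
                      collapse = " ")))
  }
  invisible(x)
}

#' Attach numeric contrast covariates to a phenotype table
#'
#' Adds columns `EX`, `AN`, `CO`, `SE` to a design/phenotype tibble by mapping
#' each plant's block and selection treatment through a [encode_contrasts()]
#' scheme. These numeric covariates are what the sequential ANOVA enters as
#' one-degree-of-freedom terms.
#'
#' @param data A data frame with columns `block` and `treatment`.
#' @param scheme A `contrast_scheme`, by default [encode_contrasts()].
#' @return `data` as a tibble with four numeric columns appended.
#' @export
attach_contrasts <- function(data, scheme = encode_contrasts()) {
  block <- trimws(as.character(data$block))
  treatment <- trimws(as.character(data$treatment))
  bad_bl <- setdiff(unique(block), names(scheme$EX))
  if (length(bad_bl)) {
    stop("Unknown block level(s): ", paste(bad_bl, collapse = ", "),
         call. = FALSE)
  }
  bad_st <- setdiff(unique(treatment), names(scheme$AN))
  if (length(bad_st)) {
    stop("Unknown treatment level(s): ", paste(bad_st, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(data),
                EX = unname(scheme$EX[block]),
                AN = unname(scheme$AN[treatment]),
                CO = unname(scheme$CO[treatment]),
                SE = unname(scheme$SE[treatment]))
}

#' Build the experiment's design template
#'
#' Enumerates the plant-level design of the common-environment experiment:
#' five randomized blocks, trays of 24 plants, three accessions, six replicate
#' populations per selection treatment plus a per-accession ancestral
#' pseudo-population, and maternal lines nested in population-by-accession
#' cells. The realized experiment planted offspring of every mother in every
#' block and filled the remaining tray positions by cycling through the
#' mothers, which the template reproduces deterministically.
#'
#' Ancestral plants did not stem from replicate populations; they carry a
#' single shared pseudo-population label (`"A"`), giving population identity
#' 18 + 1 levels. This keeps population identity defined for ancestral plants
#' while leaving the contrast-by-accession interactions estimable (a
#' per-accession ancestral label would be absorbed by the population and
#' accession main effects, aliasing `AN:ET` completely).
#'
#' @param accessions Accession names (default the three focal accessions).
#' @param n_mothers Total number of realized maternal lines. The planned
#'   design has `5 mothers x 6 populations x 3 treatments x n_accessions`
#'   selection mothers plus `ancestral_mothers` per accession; when
#'   `n_mothers` is smaller, mothers are pruned deterministically
#'   (highest within-cell index first, spread across cells) to emulate the
#'   realized shortfall (261 of 360 planned).
#' @param n_blocks Number of blocks (5).
#' @param plants_per_tray Plants per tray (24).
#' @param n_populations Replicate populations per selection treatment (6).
#' @param mothers_per_cell Planned mothers per population-by-accession cell (5).
#' @param ancestral_mothers Planned ancestral mothers per accession (30).
#' @return A tibble with one row per plant: `plant_id`, `block`, `tray`,
#'   `accession`, `population`, `mother`, `treatment`.
#' @examples
#' tpl <- design_template()
#' nrow(tpl)                      # 1800 plants
#' dplyr::n_distinct(tpl$mother)  # 261 maternal lines
#' @export
design_template <- function(accessions = c("Ma-0", "Wei-0", "Wil-3"),
                            n_mothers = 261L,
                            n_blocks = 5L,
                            plants_per_tray = 24L,
                            n_populations = 6L,
                            mothers_per_cell = 5L,
                            ancestral_mothers = 30L) {
  stopifnot(length(accessions) >= 1L, n_blocks >= 1L, plants_per_tray >= 1L)
  treatments <- c("control", "BB", "LE")
  pop_labels <- unlist(lapply(treatments, function(tr) {
    paste0(switch(tr, control = "C", BB = "BB", LE = "LE"), seq_len(n_populations))
  }))
  pop_treat <- stats::setNames(rep(treatments, each = n_populations), pop_labels)

  sel <- tidyr::expand_grid(population = pop_labels,
                            accession = accessions,
                            idx = seq_len(mothers_per_cell)) |>
    dplyr::mutate(treatment = unname(pop_treat[.data$population]))
  anc <- tidyr::expand_grid(accession = accessions,
                            idx = seq_len(ancestral_mothers)) |>
    dplyr::mutate(population = "A", treatment = "ancestral")
  mothers <- dplyr::bind_rows(sel, anc)

  n_planned <- nrow(mothers)
  if (n_mothers > n_planned) n_mothers <- n_planned
  if (n_mothers < n_planned) {
    # prune deterministically by largest-remainder apportionment: each
    # population-by-accession cell keeps a share of its planned mothers
    # proportional to the realized/planned ratio, never emptying a cell
    cells <- mothers |>
      dplyr::count(.data$population, .data$accession, name = "planned")
    target <- cells$planned * n_mothers / n_planned
    base <- pmax(1L, floor(target))
    remainder <- n_mothers - sum(base)
    if (remainder > 0L) {
      # largest fractional part first; ties rotated over cells so no
      # treatment is systematically favoured
      frac_ord <- order(-(target - floor(target)),
                        ((seq_along(target) - 1L) * 37L) %% length(target))
      base[frac_ord[seq_len(remainder)]] <- base[frac_ord[seq_len(remainder)]] + 1L
    } else if (remainder < 0L) {
      ord <- order(base, decreasing = TRUE)
      i <- 1L
      while (remainder < 0L) {
        k <- ord[(i - 1L) %% length(ord) + 1L]
        if (base[k] > 1L) {
          base[k] <- base[k] - 1L
          remainder <- remainder + 1L
        }
        i <- i + 1L
      }
    }
    cells$keep <- base
    mothers <- mothers |>
      dplyr::left_join(dplyr::select(cells, "population", "accession", "keep"),
                       by = c("population", "accession")) |>
      dplyr::filter(.data$idx <= .data$keep) |>
      dplyr::select(-"keep")
  }
  mothers <- mothers |>
    dplyr::arrange(.data$treatment, .data$population, .data$accession, .data$idx) |>
    dplyr::mutate(mother = sprintf("M%03d", dplyr::row_number())) |>
    dplyr::select("mother", "accession", "population", "treatment")

  nm <- nrow(mothers)
  # block size: one plant per mother plus proportional fill (1800/261 ~ 6.9
  # plants per mother over five blocks in the realized experiment)
  extra_per_block <- round(nm * 99 / 261)
  block_size <- nm + extra_per_block
  # round down to a whole number of trays
  block_size <- plants_per_tray * max(1L, block_size %/% plants_per_tray)
  extra_per_block <- block_size - nm
  if (extra_per_block < 0L) {
    stop("Design template infeasible: fewer tray positions than mothers.",
         call. = FALSE)
  }

  rows <- vector("list", n_blocks)
  trays_per_block <- block_size %/% plants_per_tray
  for (b in seq_len(n_blocks)) {
    fill <- if (extra_per_block > 0L) {
      ((b - 1L) * extra_per_block + seq_len(extra_per_block) - 1L) %% nm + 1L
    } else integer(0)
    midx <- c(seq_len(nm), fill)
    # deterministic interleave so consecutive mothers spread over trays
    pos <- ((seq_along(midx) - 1L) * 151L) %% block_size
    ord <- order(pos)
    midx <- midx[ord]
    tray <- (b - 1L) * trays_per_block + (seq_len(block_size) - 1L) %/% plants_per_tray + 1L
    rows[[b]] <- tibble::tibble(block = as.character(b),
                                tray = as.character(tray),
                                mother = mothers$mother[midx])
  }
  plants <- dplyr::bind_rows(rows) |>
    dplyr::left_join(mothers, by = "mother") |>
    dplyr::mutate(plant_id = sprintf("P%04d", dplyr::row_number())) |>
    dplyr::select("plant_id", "block", "tray", "accession", "population",
                  "mother", "treatment")
  plants
}

#' Validate design-factor consistency
#'
#' Checks the nesting invariants of the experimental design: every mother maps
#' to exactly one accession, one population and one treatment, and every
#' population maps to exactly one treatment.
#'
#' @param data A data frame with columns `mother`, `accession`, `population`,
#'   `treatment`.
#' @return Invisibly `TRUE`; aborts with a labeled error on violation.
#' @export
check_design <- function(data) {
  m <- dplyr::distinct(dplyr::as_tibble(data),
                       .data$mother, .data$accession, .data$population,
                       .data$treatment)
  dup <- m$mother[duplicated(m$mother)]
  if (length(dup)) {
    stop("Design inconsistency: mother(s) mapped to more than one ",
         "accession/population/treatment: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  p <- dplyr::distinct(dplyr::as_tibble(data), .data$population, .data$treatment)
  dup <- p$population[duplicated(p$population)]
  if (length(dup)) {
    stop("Design inconsistency: population(s) mapped to more than one ",
         "treatment: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
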