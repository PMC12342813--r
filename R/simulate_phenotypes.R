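#' Variance components of the phenotype generator
#'
#' Standard deviations of the independent normal random effects drawn at each
#' level of the design, plus the grand mean and the fixed offset between
#' blocks 1-3 and 4-5 (the agar-plate change). With `scale = "log"` the
#' components are log-scale standard deviations and effects combine
#' multiplicatively, producing a log-normal trait (the trichome-density
#' regime); with `scale = "identity"` effects are additive on the trait
#' scale. Normal random effects and residuals mirror the assumptions of the
#' ANOVA that analyses the data.
#'
#' @param grand_mean Trait-scale grand mean (> 0).
#' @param sd_block,sd_tray,sd_accession,sd_population,sd_mother,sd_residual
#'   Standard deviations (>= 0) of the per-level effects; on the log scale
#'   when `scale = "log"`.
#' @param ex_shift Fixed deficit applied to blocks 4-5 relative to blocks 1-3.
#' @param scale `"identity"` or `"log"`.
#' @return A list of class `variance_components`.
#' @export
variance_components <- function(grand_mean, sd_block = 0, sd_tray = 0,
                                sd_accession = 0, sd_population = 0,
                                sd_mother = 0, sd_residual = 0,
                                ex_shift = 0, scale = c("identity", "log")) {
  scale <- match.arg(scale)
  sds <- c(sd_block, sd_tray, sd_accession, sd_population, sd_mother,
           sd_residual)
  stopifnot(grand_mean > 0, all(sds >= 0))
  structure(list(grand_mean = grand_mean, sd_block = sd_block,
                 sd_tray = sd_tray, sd_accession = sd_accession,
                 sd_population = sd_population, sd_mother = sd_mother,
                 sd_residual = sd_residual, ex_shift = ex_shift,
                 scale = scale),
            class = "variance_components")
}

#' Preset trait variance profiles
#'
#' Default variance components per trait, calibrated so that the expected
#' percent sums of squares roughly match the magnitudes observed in the real
#' experiment (blocks dominant for most traits; accession dominant for time
#' to bolting) at field-realistic grand means and coefficients of variation.
#' The trichome-density profile is log-normal (trichome counts are heavily
#' right-skewed), uses only the two trichome-bearing accessions and the
#' correspondingly reduced number of maternal lines, and is analysed on the
#' log scale. All values are overridable by constructing
#' [variance_components()] directly.
#'
#' @param trait One of `"bolting"`, `"blade_area"`, `"rosette_diameter"`,
#'   `"rosette_leaves"`, `"trichome_density"`.
#' @return A list with elements `vc` ([variance_components()]), `accessions`,
#'   `n_mothers`, `transformation` (the analysis transformation) and `trait`.
#' @examples
#' trait_profile("bolting")$vc$grand_mean
#' @export
trait_profile <- function(trait = c("bolting", "blade_area",
                                    "rosette_diameter", "rosette_leaves",
                                    "trichome_density")) {
  trait <- match.arg(trait)
  three <- c("Ma-0", "Wei-0", "Wil-3")
  two <- c("Ma-0", "Wei-0")
  p <- switch(trait,
    bolting = list(
      vc = variance_components(grand_mean = 30, sd_block = 1.2, sd_tray = 0.7,
                               sd_accession = 2.4, sd_population = 1.5,
                               sd_mother = 1.4, sd_residual = 3.6,
                               ex_shift = 0.7),
      accessions = three, n_mothers = 261L, transformation = "identity"),
    blade_area = list(
      vc = variance_components(grand_mean = 300, sd_block = 20, sd_tray = 13,
                               sd_accession = 26, sd_population = 14,
                               sd_mother = 22, sd_residual = 54,
                               ex_shift = 120),
      accessions = three, n_mothers = 261L, transformation = "identity"),
    rosette_diameter = list(
      vc = variance_components(grand_mean = 80, sd_block = 2.9, sd_tray = 3.2,
                               sd_accession = 2.2, sd_population = 1.6,
                               sd_mother = 4.1, sd_residual = 9.8,
                               ex_shift = 19),
      accessions = three, n_mothers = 261L, transformation = "identity"),
    rosette_leaves = list(
      vc = variance_components(grand_mean = 30, sd_block = 0.4, sd_tray = 0.6,
                               sd_accession = 1.7, sd_population = 1.3,
                               sd_mother = 1.2, sd_residual = 2.9,
                               ex_shift = 4.7),
      accessions = three, n_mothers = 261L, transformation = "identity"),
    trichome_density = list(
      vc = variance_components(grand_mean = 2.5, sd_block = 0.073,
                               sd_tray = 0.054, sd_accession = 0.14,
                               sd_population = 0.085, sd_mother = 0.11,
                               sd_residual = 0.24, ex_shift = 0.39,
                               scale = "log"),
      accessions = two, n_mothers = 174L, transformation = "log")
  )
  c(p, list(trait = trait))
}

#' Treatment-effect scenario for the power study
#'
#' The five simulated settings of treatment effects, expressed as a fraction
#' of the grand mean:
#' * `"i"`: differences between all four groups with cumulative steps of
#'   `effect_size` between each, ordered ancestral < control < BB < LE (so
#'   the largest difference is three steps);
#' * `"ii"`: only the ancestral group differs;
#' * `"iii"`: only the control group differs;
#' * `"iv"`: both aphid treatments (BB and LE) differ;
#' * `"v"`: only one aphid treatment (LE) differs.
#'
#' @param scenario_id One of `"i"` .. `"v"`.
#' @param effect_size Effect size as a fraction of the grand mean (>= 0).
#' @return A list of class `power_scenario`.
#' @export
power_scenario <- function(scenario_id = c("i", "ii", "iii", "iv", "v"),
                           effect_size = 0.1) {
  scenario_id <- match.arg(scenario_id)
  stopifnot(effect_size >= 0)
  structure(list(scenario_id = scenario_id, effect_size = effect_size),
            class = "power_scenario")
}

# treatment offset *in units of effect steps* per scenario
.scenario_steps <- function(scenario_id) {
  switch(scenario_id,
    i = c(ancestral = 0, control = 1, BB = 2, LE = 3),
    ii = c(ancestral = 1, control = 0, BB = 0, LE = 0),
    iii = c(ancestral = 0, control = 1, BB = 0, LE = 0),
    iv = c(ancestral = 0, control = 0, BB = 1, LE = 1),
    v = c(ancestral = 0, control = 0, BB = 0, LE = 1),
    stop("Unknown scenario: ", scenario_id, call. = FALSE)
  )
}

# Precompute integer index vectors for a template so repeated draws are cheap.
.pheno_indices <- function(template, scheme = encode_contrasts()) {
  stopifnot(nrow(template) > 0)
  f <- function(v) as.integer(factor(v))
  list(
    n = nrow(template),
    block = f(template$block),
    n_block = dplyr::n_distinct(template$block),
    tray = f(template$tray),
    n_tray = dplyr::n_distinct(template$tray),
    accession = f(template$accession),
    n_accession = dplyr::n_distinct(template$accession),
    population = f(template$population),
    n_population = dplyr::n_distinct(template$population),
    mother = f(template$mother),
    n_mother = dplyr::n_distinct(template$mother),
    ex_low = unname(scheme$EX[trimws(as.character(template$block))] < 0),
    treatment = trimws(as.character(template$treatment))
  )
}

# Draw one trait vector with the current RNG state.
.pheno_draw <- function(idx, vc, steps, effect_size) {
  eff <- vc$grand_mean * effect_size * unname(steps[idx$treatment])
  lin <- stats::rnorm(idx$n_block, 0, vc$sd_block)[idx$block] +
    stats::rnorm(idx$n_tray, 0, vc$sd_tray)[idx$tray] +
    stats::rnorm(idx$n_accession, 0, vc$sd_accession)[idx$accession] +
    stats::rnorm(idx$n_population, 0, vc$sd_population)[idx$population] +
    stats::rnorm(idx$n_mother, 0, vc$sd_mother)[idx$mother] +
    stats::rnorm(idx$n, 0, vc$sd_residual) -
    ifelse(idx$ex_low, vc$ex_shift, 0)
  if (vc$scale == "identity") {
    vc$grand_mean + eff + lin
  } else {
    # multiplicative effects: a fractional effect f scales the group by (1+f)
    mult <- (1 + effect_size)^unname(steps[idx$treatment])
    vc$grand_mean * mult * exp(lin)
  }
}

#' Simulate phenotypes over a design template
#'
#' Draws one trait per plant as grand mean + fixed block-contrast offset +
#' independent normal random effects for block, tray, accession, population
#' and mother + residual noise + scenario-specific treatment offsets
#' (additive fractions of the grand mean on the identity scale,
#' multiplicative factors on the log scale). Reproducible under a fixed seed.
#'
#' @param template Design template tibble, see [design_template()].
#' @param profile A [trait_profile()] result or a [variance_components()]
#'   object.
#' @param scenario A [power_scenario()] or `NULL` for no treatment effect.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param trait_name Name of the generated trait column.
#' @param scheme Contrast scheme (for the block-contrast sign).
#' @return The template with a trait column appended.
#' @examples
#' tpl <- design_template()
#' ph <- simulate_phenotypes(tpl, trait_profile("bolting"),
#'                           power_scenario("v", 0.1), seed = 42)
#' @export
simulate_phenotypes <- function(template, profile, scenario = NULL,
                                seed = NULL, trait_name = "trait",
                                scheme = encode_contrasts()) {
  if (is.null(template) || nrow(template) == 0L) {
    stop("Empty design template.", call. = FALSE)
  }
  vc <- if (inherits(profile, "variance_components")) profile else profile$vc
  if (!is.null(seed)) set.seed(seed)
  idx <- .pheno_indices(template, scheme)
  if (is.null(scenario)) scenario <- power_scenario("i", 0)
  steps <- .scenario_steps(scenario$scenario_id)
  out <- tibble::as_tibble(template)
  out[[trait_name]] <- .pheno_draw(idx, vc, steps, scenario$effect_size)
  out
}
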