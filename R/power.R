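#' Detection rule per simulation scenario
#'
#' Maps each treatment-effect scenario to the planned contrast that is meant
#' to detect it: scenario `"ii"` is detected by `AN` (ancestral vs rest),
#' `"iii"` and `"iv"` by `CO` (control vs treated), `"v"` by `SE` (the two
#' aphid treatments against each other), and `"i"` (all groups differ) by any
#' of the three.
#'
#' @param scenario_id Scenario id, `"i"` .. `"v"`.
#' @param anova A `strata_anova` fit, its table tibble, or a named vector of
#'   p-values containing `AN`, `CO`, `SE`.
#' @param alpha Significance level.
#' @return Logical: was the scenario's effect detected? The rule label is
#'   attached as attribute `"rule"`.
#' @export
detection_rule <- function(scenario_id, anova, alpha = 0.05) {
  p <- if (inherits(anova, "strata_anova")) {
    stats::setNames(anova$table$p_value, anova$table$term)
  } else if (is.data.frame(anova)) {
    stats::setNames(anova$p_value, anova$term)
  } else {
    anova
  }
  need <- c("AN", "CO", "SE")
  bad <- need[!(need %in% names(p)) | is.na(p[need])]
  if (length(bad)) {
    stop("ANOVA table lacks p-values for contrast(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rule <- switch(scenario_id,
                 i = "any of AN/CO/SE",
                 ii = "AN", iii = "CO", iv = "CO", v = "SE",
                 stop("Unknown scenario: ", scenario_id, call. = FALSE))
  detected <- switch(scenario_id,
                     i = any(p[need] < alpha),
                     ii = unname(p["AN"] < alpha),
                     iii = unname(p["CO"] < alpha),
                     iv = unname(p["CO"] < alpha),
                     v = unname(p["SE"] < alpha))
  structure(detected, rule = rule)
}

#' Monte-Carlo power study over the experiment's design
#'
#' For each combination of scenario and effect size, simulates replicate
#' phenotype datasets over the design template, analyses each with the
#' multi-stratum sequential ANOVA (model `m1` by default, contrasts tested
#' against their error strata), applies the scenario-matched detection rule
#' at level `alpha`, and reports the fraction of significant replicates with
#' its Monte-Carlo standard error `sqrt(p (1 - p) / n)`.
#'
#' The design template and its model matrix are fixed across replicates (the
#' experiment's layout is a constant of the study, not a random quantity), so
#' the QR decomposition is computed once and each replicate costs one
#' projection. Replicate seeds are derived deterministically from the master
#' seed, making the whole table reproducible.
#'
#' @param profile A [trait_profile()] result (or a list with elements `vc`,
#'   `accessions`, `n_mothers`, `transformation`).
#' @param scenarios Character vector of scenario ids among `"i"` .. `"v"`.
#' @param effect_sizes Numeric vector of effect sizes (fractions of the grand
#'   mean).
#' @param n_reps Replicates per scenario-by-effect cell.
#' @param alpha Significance level.
#' @param model Model id, `"m1"` or `"m2"`.
#' @param seed Master seed.
#' @param template Optional design template; by default built from the
#'   profile's accessions and mother count.
#' @return A tibble of class `power_result`: `scenario`, `effect_size`,
#'   `trait`, `rule`, `n_reps`, `detected`, `power`, `mc_se`.
#' @examples
#' \donttest{
#' pr <- run_power(trait_profile("bolting"), scenarios = "v",
#'                 effect_sizes = 0.1, n_reps = 20, seed = 1)
#' pr
#' }
#' @export
run_power <- function(profile = trait_profile("bolting"),
                      scenarios = c("i", "ii", "iii", "iv", "v"),
                      effect_sizes = 0.1, n_reps = 1000L, alpha = 0.05,
                      model = "m1", seed = NULL, template = NULL) {
  stopifnot(n_reps >= 1L, all(effect_sizes >= 0))
  bad <- setdiff(scenarios, c("i", "ii", "iii", "iv", "v"))
  if (length(bad)) stop("Unknown scenario(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(template)) {
    template <- design_template(accessions = profile$accessions,
                                n_mothers = profile$n_mothers)
  }
  if (nrow(template) == 0L) stop("Empty design template.", call. = FALSE)
  vc <- profile$vc
  transformation <- profile$transformation %||% "identity"
  scheme <- encode_contrasts()
  engine <- .anova_engine(template, model, scheme)
  li_k <- match("LI", engine$labels)
  if (is.na(li_k) || engine$df[li_k] == 0) {
    stop("Design template leaves no degrees of freedom for the LI stratum; ",
         "contrast tests are undefined.", call. = FALSE)
  }
  contrast_k <- match(c("AN", "CO", "SE"), engine$labels)
  if (anyNA(contrast_k)) {
    stop("Design template does not support the treatment contrasts.",
         call. = FALSE)
  }
  idx <- .pheno_indices(template, scheme)

  cells <- tidyr::expand_grid(scenario = scenarios, effect_size = effect_sizes)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, nrow(cells) * n_reps),
                      nrow = nrow(cells))

  df_li <- engine$df[li_k]
  res <- purrr::pmap_dfr(
    list(cells$scenario, cells$effect_size, seq_len(nrow(cells))),
    function(sc, f, ci) {
      steps <- .scenario_steps(sc)
      detected <- 0L
      rule <- NULL
      for (r in seq_len(n_reps)) {
        set.seed(rep_seeds[ci, r])
        y <- .pheno_draw(idx, vc, steps, f)
        y <- apply_transformation(y, transformation)
        parts <- .anova_ss(engine, y)
        ms_li <- parts$ss[li_k] / df_li
        fstat <- parts$ss[contrast_k] / ms_li
        p <- stats::pf(fstat, 1, df_li, lower.tail = FALSE)
        names(p) <- c("AN", "CO", "SE")
        d <- detection_rule(sc, p, alpha)
        rule <- attr(d, "rule")
        detected <- detected + as.integer(d)
      }
      pw <- detected / n_reps
      tibble::tibble(scenario = sc, effect_size = f,
                     trait = profile$trait %||% NA_character_,
                     rule = rule, n_reps = n_reps, detected = detected,
                     power = pw, mc_se = sqrt(pw * (1 - pw) / n_reps))
    })
  class(res) <- c("power_result", class(res))
  res
}

#' Plot power curves
#'
#' Power against effect size, one line per scenario, with +/- 2 Monte-Carlo
#' standard-error ribbons and the conventional 0.80 reference line.
#'
#' @param object A `power_result` tibble from [run_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 100 * .data$effect_size, y = .data$power,
                               colour = .data$scenario,
                               group = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$power - 2 * .data$mc_se),
                                      ymax = pmin(1, .data$power + 2 * .data$mc_se),
                                      fill = .data$scenario),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2) +
    ggplot2::labs(x = "Effect size (% of grand mean)",
                  y = "Estimated power") +
    ggplot2::theme_minimal()
}
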