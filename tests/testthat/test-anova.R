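test_that("one-factor toy matches the closed-form one-way decomposition", {
  # two accessions x 4 plants, means 0 and 1, no noise: between-group SS = 2,
  # residual SS = 0, everything else constant and dropped
  d <- tibble::tibble(
    plant_id = sprintf("P%d", 1:8),
    block = "1", tray = "1", population = "C1",
    mother = rep(c("M1", "M2"), each = 4),
    treatment = "control",
    accession = rep(c("Ma-0", "Wei-0"), each = 4),
    y = rep(c(0, 1), each = 4)
  )
  fit <- fit_sequential(d, "y", anova_config("m1"))
  tab <- tidy(fit)
  expect_equal(tab$ss[tab$term == "ET"], 2)
  expect_equal(tab$ss[tab$term == "Residuals"], 0, tolerance = 1e-12)
})

test_that("sequential SS equal the brute-force projection oracle", {
  for (model in c("m1", "m2")) {
    d <- mini_design()        # 50 observations, full factor structure
    set.seed(42)
    d$y <- 10 + rnorm(nrow(d))
    fit <- fit_sequential(d, "y", anova_config(model))
    tab <- tidy(fit)
    oracle <- oracle_sequential_ss(d, d$y, model)
    for (term in names(oracle$ss)) {
      expect_equal(tab$ss[tab$term == term], unname(oracle$ss[term]),
                   tolerance = 1e-8, label = paste(model, term))
    }
    expect_equal(tab$ss[tab$term == "Residuals"], oracle$resid_ss,
                 tolerance = 1e-8)
  }
})

test_that("sequential SS agree with anova(lm) on the full design", {
  tpl <- design_template(accessions = c("Ma-0", "Wei-0"), n_mothers = 40L)
  ph <- simulate_phenotypes(tpl, trait_profile("bolting"),
                            power_scenario("i", 0.1), seed = 9)
  fit <- fit_sequential(ph, "trait", anova_config("m1"))
  tab <- tidy(fit)
  d <- attach_contrasts(ph)
  for (v in c("block", "tray", "population", "accession", "mother")) {
    d[[v]] <- factor(d[[v]])
  }
  # keep.order preserves the entry order the sequential decomposition uses
  fo <- stats::terms(trait ~ EX + block + tray + AN + CO + SE + population +
                       accession + AN:accession + CO:accession +
                       SE:accession + population:accession + mother,
                     keep.order = TRUE)
  oa <- stats::anova(stats::lm(fo, data = d))
  lm_names <- c(EX = "EX", block = "BL", tray = "TR", AN = "AN", CO = "CO",
                SE = "SE", population = "LI", accession = "ET",
                `AN:accession` = "AN:ET", `CO:accession` = "CO:ET",
                `SE:accession` = "SE:ET", `population:accession` = "LI:ET",
                mother = "MO", Residuals = "Residuals")
  for (rn in rownames(oa)) {
    expect_equal(tab$ss[tab$term == lm_names[[rn]]], oa[rn, "Sum Sq"],
                 tolerance = 1e-8, label = rn)
    expect_equal(tab$df[tab$term == lm_names[[rn]]], oa[rn, "Df"],
                 label = paste(rn, "df"))
  }
})

test_that("term SS are order-invariant on an orthogonal balanced design", {
  # balanced treatments within each accession, no population/mother nesting
  # conflicts: the contrast columns are orthogonal to the accession columns
  d <- tidyr::expand_grid(
    treatment = c("ancestral", "control", "BB", "LE"),
    accession = c("Ma-0", "Wei-0"),
    rep = 1:3
  ) |>
    dplyr::mutate(plant_id = sprintf("P%d", dplyr::row_number()),
                  block = "1", tray = "1",
                  population = "C1", mother = "M1")
  set.seed(1)
  d$y <- rnorm(nrow(d))
  # m1 and m2 share the leading EX..ET terms; with only AN/CO/SE/ET active,
  # orthogonality makes each term's SS independent of what else is fitted
  fit <- fit_sequential(d, "y", anova_config("m1"))
  tab <- tidy(fit)
  for (term in c("AN", "CO", "SE")) {
    x <- attach_contrasts(d)[[term]]
    ss_alone <- sum(x * d$y)^2 / sum(x^2)
    expect_equal(tab$ss[tab$term == term], ss_alone, tolerance = 1e-10)
  }
})

test_that("error strata follow the design's testing rules", {
  tpl <- design_template(accessions = c("Ma-0", "Wei-0"), n_mothers = 40L)
  ph <- simulate_phenotypes(tpl, trait_profile("bolting"), seed = 2)
  for (model in c("m1", "m2")) {
    tab <- tidy(fit_sequential(ph, "trait", anova_config(model)))
    strata <- stats::setNames(tab$stratum, tab$term)
    expect_identical(unname(strata[c("AN", "CO", "SE")]), rep("LI", 3))
    expect_identical(unname(strata["ET"]), "MO")
    if (model == "m1") {
      expect_identical(unname(strata[c("AN:ET", "CO:ET", "SE:ET")]),
                       rep("LI:ET", 3))
    } else {
      expect_identical(unname(strata[c("EX:AN", "EX:CO", "EX:SE", "EX:ET")]),
                       rep("LI:ET", 4))
    }
    expect_identical(unname(strata[c("BL", "TR", "LI", "MO")]),
                     rep("Residuals", 4))
    # contrasts carry one degree of freedom each
    expect_identical(tab$df[tab$term %in% c("AN", "CO", "SE")], rep(1L, 3))
    # p-values for tested terms are defined and F ratios reconstructible
    li <- tab[tab$term == "LI", ]
    an <- tab[tab$term == "AN", ]
    expect_equal(an$statistic, (an$ss / an$df) / (li$ss / li$df))
    expect_equal(an$p_value,
                 stats::pf(an$statistic, an$df, li$df, lower.tail = FALSE))
  }
})

test_that("SS bookkeeping conserves the total and %SS sums to 100", {
  tpl <- design_template(accessions = c("Ma-0", "Wei-0"), n_mothers = 40L)
  ph <- simulate_phenotypes(tpl, trait_profile("rosette_leaves"), seed = 3)
  fit <- fit_sequential(ph, "trait", anova_config("m1"))
  tab <- tidy(fit)
  y <- ph$trait
  expect_equal(sum(tab$ss), sum((y - mean(y))^2), tolerance = 1e-8)
  expect_equal(sum(tab$pct_ss), 100, tolerance = 1e-8)
  expect_equal(percent_ss(tab)$pct_ss, tab$pct_ss)
  zero <- dplyr::mutate(tab, ss = 0)
  expect_error(percent_ss(zero), "zero")
})

test_that("percent_ss is plain arithmetic on the SS column", {
  tab <- tibble::tibble(term = c("a", "b", "Residuals"), ss = c(1, 3, 0))
  out <- percent_ss(tab)
  expect_equal(out$pct_ss, c(25, 75, 0))
  only_resid <- tibble::tibble(term = "Residuals", ss = 5)
  expect_equal(percent_ss(only_resid)$pct_ss, 100)
})

test_that("a zero-df error stratum is flagged, not silently NA", {
  # single population: LI never enters, so the contrasts have no stratum df
  d <- tidyr::expand_grid(
    treatment = c("ancestral", "control", "BB", "LE"),
    rep = 1:4
  ) |>
    dplyr::mutate(plant_id = sprintf("P%d", dplyr::row_number()),
                  block = "1", tray = "1", accession = "Ma-0",
                  population = dplyr::case_when(
                    treatment == "ancestral" ~ "A",
                    treatment == "control" ~ "C1",
                    treatment == "BB" ~ "BB1",
                    TRUE ~ "LE1"),
                  mother = paste0("M", treatment))
  set.seed(4)
  d$y <- rnorm(nrow(d))
  tab <- tidy(fit_sequential(d, "y", anova_config("m1")))
  an <- tab[tab$term == "AN", ]
  expect_false(an$p_defined)
  expect_true(is.na(an$p_value))
})

test_that("transformation choice tracks the residual distribution", {
  d <- mini_design(n_rep = 24L)   # 1200 plants: W differences resolve clearly
  picks_norm <- picks_log <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    mu <- 20 + 10 * (d$accession == "Wei-0")
    d$norm_trait <- mu + rnorm(nrow(d), sd = 5)
    d$skew_trait <- exp(mu / 10 + rnorm(nrow(d)))
    picks_norm <- picks_norm +
      (choose_transformation(d, "norm_trait")$transformation == "identity")
    picks_log <- picks_log +
      (choose_transformation(d, "skew_trait")$transformation == "log")
  }
  expect_gte(picks_norm / n_rep, 0.9)
  expect_gte(picks_log / n_rep, 0.9)
})

test_that("transformations enforce their domains", {
  expect_error(apply_transformation(c(-1, 2), "sqrt"), "non-negative")
  expect_error(apply_transformation(c(0, 2), "log"), "positive")
  expect_equal(apply_transformation(c(0, 2), "log", shift_zeros = TRUE),
               log(c(2, 4)))
  d <- mini_design()
  d$y <- 1
  expect_error(choose_transformation(d, "y"), "constant")
})

test_that("tidy/glance expose the fit; autoplot returns a ggplot", {
  tpl <- design_template(accessions = c("Ma-0", "Wei-0"), n_mothers = 40L)
  ph <- simulate_phenotypes(tpl, trait_profile("bolting"), seed = 6)
  fit <- fit_sequential(ph, "trait")
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_identical(g$n, nrow(ph))
  expect_identical(g$model, "m1")
  expect_s3_class(autoplot(fit), "ggplot")
})
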