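# Small design with the full factor structure (all four treatments, two
# accessions, blocks 1..5) at toy size, for closed-form and brute-force
# oracle checks.
mini_design <- function(n_rep = 1L) {
  base <- tidyr::expand_grid(
    block = as.character(1:5),
    cell = tibble::tibble(
      population = c("A", "C1", "C2", "BB1", "LE1"),
      treatment = c("ancestral", "control", "control", "BB", "LE")
    ),
    accession = c("Ma-0", "Wei-0"),
    rep = seq_len(n_rep)
  ) |>
    tidyr::unnest(cell) |>
    dplyr::mutate(
      tray = block,
      mother = paste0("M_", population, "_", accession),
      plant_id = sprintf("P%03d", dplyr::row_number())
    )
  base[c("plant_id", "block", "tray", "accession", "population", "mother",
         "treatment")]
}

# Independent sequential-SS oracle: per term, the drop in residual sum of
# squares when the term's columns are appended to the cumulative design,
# each step fitted with lm.fit on the raw column blocks.
oracle_sequential_ss <- function(data, y, model = "m1") {
  data <- episelect::attach_contrasts(data)
  fac <- function(v) droplevels(factor(data[[v]]))
  blocks <- list()
  add <- function(label, m) {
    if (!is.null(m) && ncol(m) > 0) blocks[[label]] <<- m
  }
  num <- function(v) {
    x <- as.numeric(data[[v]])
    if (stats::var(x) == 0) NULL else matrix(x, ncol = 1)
  }
  indi <- function(f) if (nlevels(f) < 2) NULL else stats::model.matrix(~ 0 + f)
  num_by_fac <- function(v, fv) {
    x <- as.numeric(data[[v]]); f <- fac(fv)
    if (stats::var(x) == 0 || nlevels(f) < 2) NULL else
      stats::model.matrix(~ 0 + f) * x
  }
  add("EX", num("EX")); add("BL", indi(fac("block")))
  add("TR", indi(fac("tray")))
  add("AN", num("AN")); add("CO", num("CO")); add("SE", num("SE"))
  add("LI", indi(fac("population"))); add("ET", indi(fac("accession")))
  if (model == "m1") {
    add("AN:ET", num_by_fac("AN", "accession"))
    add("CO:ET", num_by_fac("CO", "accession"))
    add("SE:ET", num_by_fac("SE", "accession"))
  } else {
    ex <- as.numeric(data$EX)
    for (v in c("AN", "CO", "SE")) {
      x <- ex * as.numeric(data[[v]])
      if (stats::var(x) > 0) blocks[[paste0("EX:", v)]] <- matrix(x, ncol = 1)
    }
    add("EX:LI", num_by_fac("EX", "population"))
    add("EX:ET", num_by_fac("EX", "accession"))
  }
  f1 <- fac("population"); f2 <- fac("accession")
  if (nlevels(f1) >= 2 && nlevels(f2) >= 2) {
    f <- droplevels(interaction(f1, f2, drop = TRUE))
    blocks[["LI:ET"]] <- stats::model.matrix(~ 0 + f)
  }
  add("MO", indi(fac("mother")))

  n <- length(y)
  rss <- sum((y - mean(y))^2)
  X <- matrix(1, n, 1)
  out <- numeric(0)
  for (label in names(blocks)) {
    X <- cbind(X, blocks[[label]])
    fit <- stats::lm.fit(X, y)
    new_rss <- sum(fit$residuals^2)
    out[label] <- rss - new_rss
    rss <- new_rss
  }
  list(ss = out, resid_ss = rss)
}
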