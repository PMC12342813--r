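#' ANOVA configuration
#'
#' Bundles the options of the sequential multi-stratum ANOVA.
#'
#' @param model `"m1"` or `"m2"`. Both enter, in this order: the block
#'   contrast `EX`, blocks `BL`, trays `TR`, the treatment contrasts
#'   `AN`/`CO`/`SE`, populations `LI`, accessions `ET`; `m1` then adds the
#'   contrast-by-accession interactions and `LI:ET`, `m2` instead adds the
#'   contrast-by-`EX` interactions, `EX:LI`, `EX:ET` and `LI:ET`; both end
#'   with maternal lines `MO`.
#' @param alpha Significance level for downstream detection rules.
#' @param transformation `"identity"`, `"log"`, `"sqrt"` or `"auto"`
#'   (Shapiro-Wilk-guided choice, see [choose_transformation()]).
#' @param rout_q ROUT false-discovery budget for outlier flagging.
#' @return A list of class `anova_config`.
#' @export
anova_config <- function(model = c("m1", "m2"), alpha = 0.05,
                         transformation = c("identity", "log", "sqrt", "auto"),
                         rout_q = 0.01) {
  model <- match.arg(model)
  transformation <- match.arg(transformation)
  stopifnot(alpha > 0, alpha < 1, rout_q >= 0, rout_q < 1)
  structure(list(model = model, alpha = alpha,
                 transformation = transformation, rout_q = rout_q),
            class = "anova_config")
}

# Ordered term specifications for each model. Each term is
# list(label, kind, vars) with kind in {"numeric", "factor",
# "numeric_by_factor", "factor_by_factor"}.
.anova_terms <- function(model) {
  base <- list(
    list(label = "EX", kind = "numeric", vars = "EX"),
    list(label = "BL", kind = "factor", vars = "block"),
    list(label = "TR", kind = "factor", vars = "tray"),
    list(label = "AN", kind = "numeric", vars = "AN"),
    list(label = "CO", kind = "numeric", vars = "CO"),
    list(label = "SE", kind = "numeric", vars = "SE"),
    list(label = "LI", kind = "factor", vars = "population"),
    list(label = "ET", kind = "factor", vars = "accession")
  )
  if (model == "m1") {
    extra <- list(
      list(label = "AN:ET", kind = "numeric_by_factor", vars = c("AN", "accession")),
      list(label = "CO:ET", kind = "numeric_by_factor", vars = c("CO", "accession")),
      list(label = "SE:ET", kind = "numeric_by_factor", vars = c("SE", "accession")),
      list(label = "LI:ET", kind = "factor_by_factor", vars = c("population", "accession"))
    )
  } else {
    extra <- list(
      list(label = "EX:AN", kind = "numeric", vars = c("EX", "AN")),
      list(label = "EX:CO", kind = "numeric", vars = c("EX", "CO")),
      list(label = "EX:SE", kind = "numeric", vars = c("EX", "SE")),
      list(label = "EX:LI", kind = "numeric_by_factor", vars = c("EX", "population")),
      list(label = "EX:ET", kind = "numeric_by_factor", vars = c("EX", "accession")),
      list(label = "LI:ET", kind = "factor_by_factor", vars = c("population", "accession"))
    )
  }
  c(base, extra, list(list(label = "MO", kind = "factor", vars = "mother")))
}

# Denominator stratum per term. Terms the design treats as nuisance are
# tested against the residual stratum.
.strata_map <- function(model) {
  map <- c(AN = "LI", CO = "LI", SE = "LI", ET = "MO")
  if (model == "m1") {
    map <- c(map, `AN:ET` = "LI:ET", `CO:ET` = "LI:ET", `SE:ET` = "LI:ET")
  } else {
    map <- c(map, `EX:AN` = "LI:ET", `EX:CO` = "LI:ET", `EX:SE` = "LI:ET",
             `EX:ET` = "LI:ET")
  }
  map
}

.term_matrix <- function(term, data) {
  kind <- term$kind
  if (kind == "numeric") {
    cols <- lapply(term$vars, function(v) as.numeric(data[[v]]))
    m <- if (length(cols) == 1L) matrix(cols[[1]], ncol = 1) else
      matrix(Reduce(`*`, cols), ncol = 1)
    if (stats::var(m[, 1]) == 0) return(NULL)
    return(m)
  }
  if (kind == "factor") {
    f <- droplevels(factor(data[[term$vars]]))
    if (nlevels(f) < 2L) return(NULL)
    m <- stats::model.matrix(~ 0 + f)
    return(m)
  }
  if (kind == "numeric_by_factor") {
    x <- as.numeric(data[[term$vars[1]]])
    f <- droplevels(factor(data[[term$vars[2]]]))
    if (stats::var(x) == 0) return(NULL)
    if (nlevels(f) < 2L) return(NULL)
    return(stats::model.matrix(~ 0 + f) * x)
  }
  # factor_by_factor
  f1 <- droplevels(factor(data[[term$vars[1]]]))
  f2 <- droplevels(factor(data[[term$vars[2]]]))
  if (nlevels(f1) < 2L || nlevels(f2) < 2L) return(NULL)
  f <- droplevels(interaction(f1, f2, drop = TRUE))
  stats::model.matrix(~ 0 + f)
}

# Build the fixed part of the analysis once: model matrix in formula order,
# pivoted QR decomposition, per-term degrees of freedom and the error-strata
# assignment. The response never enters here, so the same engine serves
# every replicate of a power simulation.
.anova_engine <- function(data, model = c("m1", "m2"),
                          scheme = encode_contrasts()) {
  model <- match.arg(model)
  if (!all(c("EX", "AN", "CO", "SE") %in% names(data))) {
    data <- attach_contrasts(data, scheme)
  }
  terms <- .anova_terms(model)
  mats <- list(matrix(1, nrow = nrow(data), ncol = 1))
  assign <- 0L
  labels <- character(0)
  kept <- 0L
  for (tm in terms) {
    m <- .term_matrix(tm, data)
    if (is.null(m)) next
    kept <- kept + 1L
    labels <- c(labels, tm$label)
    mats <- c(mats, list(m))
    assign <- c(assign, rep(kept, ncol(m)))
  }
  X <- do.call(cbind, mats)
  qr_x <- qr(X)
  rank <- qr_x$rank
  pivot <- qr_x$pivot
  assign_piv <- assign[pivot]
  df <- tabulate(assign_piv[seq_len(rank)], nbins = kept)
  # intercept consumes one of the leading effects
  list(model = model, labels = labels, qr = qr_x, n = nrow(data),
       rank = rank, assign_pivoted = assign_piv, df = df,
       resid_df = nrow(data) - rank, strata = .strata_map(model))
}

# Sequential (Type I) sums of squares for a response, via the engine's QR:
# squared orthogonalized effects grouped by the term each pivoted column
# belongs to. Equals the reduction in residual SS when each term is added
# after all preceding terms.
.anova_ss <- function(engine, y) {
  qty <- qr.qty(engine$qr, y)
  eff2 <- qty[seq_len(engine$rank)]^2
  grp <- engine$assign_pivoted[seq_len(engine$rank)]
  ss <- vapply(seq_along(engine$labels),
               function(k) sum(eff2[grp == k]), numeric(1))
  resid_ss <- sum(qty[-seq_len(engine$rank)]^2)
  list(ss = ss, resid_ss = resid_ss)
}

.anova_table <- function(engine, y) {
  parts <- .anova_ss(engine, y)
  labels <- engine$labels
  df <- engine$df
  ss <- parts$ss
  ms <- ifelse(df > 0, ss / df, NA_real_)
  total_ss <- sum(ss) + parts$resid_ss
  denom_label <- unname(engine$strata[labels])
  denom_label[is.na(denom_label)] <- "Residuals"
  get_den <- function(lab) {
    if (lab == "Residuals") {
      c(ms = parts$resid_ss / engine$resid_df, df = engine$resid_df)
    } else {
      k <- match(lab, labels)
      if (is.na(k) || df[k] == 0) c(ms = NA_real_, df = 0) else
        c(ms = ms[k], df = df[k])
    }
  }
  stat <- p <- rep(NA_real_, length(labels))
  p_defined <- rep(FALSE, length(labels))
  for (i in seq_along(labels)) {
    den <- get_den(denom_label[i])
    if (df[i] > 0 && !is.na(den["ms"]) && den["df"] > 0 && den["ms"] > 0) {
      stat[i] <- ms[i] / den[["ms"]]
      p[i] <- stats::pf(stat[i], df[i], den[["df"]], lower.tail = FALSE)
      p_defined[i] <- TRUE
    }
  }
  all_ss <- c(ss, parts$resid_ss)
  tab <- tibble::tibble(
    term = c(labels, "Residuals"),
    df = c(df, engine$resid_df),
    ss = all_ss,
    pct_ss = 100 * all_ss / total_ss,
    stratum = c(denom_label, NA_character_),
    statistic = c(stat, NA_real_),
    p_value = c(p, NA_real_),
    p_defined = c(p_defined, NA)
  )
  attr(tab, "total_ss") <- total_ss
  tab
}

#' Fit the multi-stratum sequential ANOVA
#'
#' Fits the fixed-effects linear model of the selection experiment with
#' sequential (Type I) sums of squares and computes F tests against the
#' design's error strata: the treatment contrasts `AN`, `CO`, `SE` are tested
#' against population identity (`LI`); interactions of the contrasts with
#' accession or with the block contrast are tested against `LI:ET`; accession
#' (`ET`) is tested against maternal lines (`MO`); all remaining (nuisance)
#' terms are tested against the residual stratum. Aliased columns are dropped
#' in entry order with degrees of freedom adjusted, which is how the nested,
#' unbalanced design distributes information (e.g. `LI` retains the
#' population variation left after the three treatment contrasts).
#'
#' Rows with a missing trait value are dropped for that trait only. An error
#' stratum with zero realized degrees of freedom yields `p_defined = FALSE`
#' for the terms tested against it, never a silent `NA`.
#'
#' @param data Phenotype tibble (see [read_phenotypes()] or
#'   [simulate_phenotypes()]).
#' @param trait Name of the trait column to analyse.
#' @param config An [anova_config()].
#' @param scheme Contrast scheme, by default [encode_contrasts()].
#' @return An object of class `strata_anova` with the ANOVA table (a tibble
#'   with columns `term`, `df`, `ss`, `pct_ss`, `stratum`, `statistic`,
#'   `p_value`, `p_defined`), accessible via [tidy()][generics::tidy].
#' @examples
#' tpl <- design_template()
#' pheno <- simulate_phenotypes(tpl, trait_profile("bolting"), seed = 1)
#' fit <- fit_sequential(pheno, "trait", anova_config("m1"))
#' tidy(fit)
#' @export
fit_sequential <- function(data, trait, config = anova_config(),
                           scheme = encode_contrasts()) {
  if (!trait %in% names(data)) {
    stop("Trait column `", trait, "` not found.", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  if (nrow(data) < 3L) stop("Too few non-missing trait values.", call. = FALSE)
  transformation <- config$transformation
  if (transformation == "auto") {
    transformation <- choose_transformation(data, trait,
                                            model = config$model,
                                            scheme = scheme)$transformation
  }
  y <- apply_transformation(data[[trait]], transformation)
  engine <- .anova_engine(data, config$model, scheme)
  tab <- .anova_table(engine, y)
  structure(list(
    table = tab,
    model = config$model,
    trait = trait,
    transformation = transformation,
    alpha = config$alpha,
    n = engine$n,
    total_ss = attr(tab, "total_ss"),
    df_residual = engine$resid_df,
    residuals = qr.resid(engine$qr, y),
    fitted = qr.fitted(engine$qr, y)
  ), class = "strata_anova")
}

#' Percent sums of squares
#'
#' Recomputes the `%SS` column of an ANOVA table as `100 * SS / total SS`
#' (residual row included, so the column sums to 100).
#'
#' @param table An ANOVA table tibble with columns `term` and `ss`, or a
#'   `strata_anova` object.
#' @return The table with `pct_ss` (re)computed.
#' @export
percent_ss <- function(table) {
  if (inherits(table, "strata_anova")) table <- table$table
  total <- sum(table$ss)
  if (!isTRUE(total > 0)) {
    stop("Total sum of squares is zero; %SS undefined.", call. = FALSE)
  }
  dplyr::mutate(table, pct_ss = 100 * .data$ss / total)
}

#' Apply a trait transformation
#'
#' @param y Numeric vector.
#' @param transformation `"identity"`, `"log"` (natural log, requires strictly
#'   positive values) or `"sqrt"` (requires non-negative values).
#' @param shift_zeros If `TRUE`, `log` shifts the data by the smallest
#'   positive observed value before taking logs; off by default.
#' @return Transformed numeric vector.
#' @export
apply_transformation <- function(y, transformation, shift_zeros = FALSE) {
  switch(transformation,
    identity = y,
    sqrt = {
      if (any(y < 0, na.rm = TRUE)) {
        stop("sqrt transformation requires non-negative values.", call. = FALSE)
      }
      sqrt(y)
    },
    log = {
      if (any(y <= 0, na.rm = TRUE)) {
        if (!shift_zeros || any(y < 0, na.rm = TRUE)) {
          stop("log transformation requires strictly positive values.",
               call. = FALSE)
        }
        y <- y + min(y[y > 0], na.rm = TRUE)
      }
      log(y)
    },
    stop("Unknown transformation: ", transformation, call. = FALSE)
  )
}

#' Shapiro-Wilk-guided transformation choice
#'
#' Fits the model under each admissible candidate transformation (identity
#' always; square root when the trait is non-negative; natural log when it is
#' strictly positive), computes the Shapiro-Wilk W statistic on the model
#' residuals and returns the transformation with the largest W. Identity wins
#' ties. For more than 5000 residuals an evenly spaced subsample of 5000 is
#' used, as the test is undefined beyond that size.
#'
#' @inheritParams fit_sequential
#' @param model Model id passed to the engine.
#' @return A list with `transformation` (the winner) and `diagnostics`
#'   (a tibble of candidate, W and Shapiro-Wilk p-value).
#' @export
choose_transformation <- function(data, trait, model = "m1",
                                  scheme = encode_contrasts()) {
  data <- tibble::as_tibble(data)
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  y0 <- data[[trait]]
  if (length(y0) < 3L) stop("Need at least 3 non-missing values.", call. = FALSE)
  if (stats::var(y0) == 0) stop("Trait is constant; nothing to choose.",
                                call. = FALSE)
  candidates <- "identity"
  if (all(y0 >= 0)) candidates <- c(candidates, "sqrt")
  if (all(y0 > 0)) candidates <- c(candidates, "log")
  engine <- .anova_engine(data, model, scheme)
  diag <- purrr::map_dfr(candidates, function(tr) {
    y <- apply_transformation(y0, tr)
    r <- qr.resid(engine$qr, y)
    if (length(r) > 5000L) {
      r <- r[round(seq(1L, length(r), length.out = 5000L))]
    }
    sw <- stats::shapiro.test(r)
    tibble::tibble(transformation = tr,
                   shapiro_w = unname(sw$statistic),
                   shapiro_p = sw$p.value)
  })
  best <- diag$transformation[which.max(diag$shapiro_w)]
  list(transformation = best, diagnostics = diag)
}

#' @export
print.strata_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Multi-stratum sequential ANOVA (model %s), trait `%s` (%s), n = %d\n",
              x$model, x$trait, x$transformation, x$n))
  print(as.data.frame(x$table), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a multi-stratum ANOVA fit
#'
#' @param x A `strata_anova` object.
#' @param ... Unused.
#' @return The ANOVA table as a tibble.
#' @export
tidy.strata_anova <- function(x, ...) x$table

#' One-row model summary
#'
#' @param x A `strata_anova` object.
#' @param ... Unused.
#' @return A one-row tibble with model id, trait, transformation, n, total
#'   SS and residual degrees of freedom.
#' @export
glance.strata_anova <- function(x, ...) {
  tibble::tibble(model = x$model, trait = x$trait,
                 transformation = x$transformation, n = x$n,
                 total_ss = x$total_ss, df_residual = x$df_residual)
}

#' Plot percent sums of squares
#'
#' Bar chart of the share of total variation attributed to each model term,
#' with tested terms coloured by significance at the configured alpha.
#'
#' @param object A `strata_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strata_anova <- function(object, ...) {
  tab <- dplyr::mutate(object$table,
                       term = factor(.data$term, levels = rev(.data$term)),
                       significant = !is.na(.data$p_value) &
                         .data$p_value < object$alpha)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pct_ss, y = .data$term,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of total sum of squares", y = NULL,
                  fill = sprintf("p < %.2g", object$alpha),
                  title = sprintf("Variance decomposition: %s (model %s)",
                                  object$trait, object$model)) +
    ggplot2::theme_minimal()
}
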