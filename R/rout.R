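#' ROUT outlier flagging for grouped measurements
#'
#' Adapts the ROUT procedure (robust fit followed by outlier detection at a
#' chosen false-discovery budget Q) to grouped univariate data: within each
#' group the robust centre is the median, the robust scale (RSDR) is the
#' 68.27th percentile of the absolute residuals times `n / (n - 1)`, and each
#' point receives a t-type statistic `|residual| / RSDR`. Points are then
#' examined from the most extreme inwards; the i-th most extreme point is
#' flagged when its two-sided t probability (on `n - 1` degrees of freedom)
#' falls below `Q * (n - i + 1) / n`, and examination stops at the first
#' point that is not flagged. ROUT was defined for nonlinear regression; the
#' group robust centre plays the role of the fit here, which is the natural
#' degenerate case (an intercept-only model per group).
#'
#' @param data A data frame with the value column and grouping columns, or a
#'   numeric vector (then `grouping` must be a vector or omitted for a single
#'   group).
#' @param values Name of the value column when `data` is a data frame.
#' @param grouping Character vector of grouping column names (typically
#'   accession and selection treatment), or a vector of group labels when
#'   `data` is numeric.
#' @param q False-discovery budget Q in `[0, 1)`; `Q = 0` flags nothing.
#' @return A tibble with the input rows plus `outlier` (logical; `NA` for
#'   groups with fewer than 3 values, which are skipped with a warning).
#'   The input is never mutated.
#' @examples
#' rout_outliers(c(1, 1.1, 0.9, 1.05, 10), q = 0.01)
#' @export
rout_outliers <- function(data, values = "value", grouping = NULL, q = 0.01) {
  stopifnot(q >= 0, q < 1)
  if (is.numeric(data)) {
    x <- data
    g <- if (is.null(grouping)) rep("all", length(x)) else as.character(grouping)
    df <- tibble::tibble(value = x, .group = g)
    values <- "value"
  } else {
    df <- tibble::as_tibble(data)
    if (!values %in% names(df)) {
      stop("Value column `", values, "` not found.", call. = FALSE)
    }
    if (is.null(grouping)) {
      df$.group <- "all"
    } else {
      df$.group <- do.call(paste, c(df[grouping], sep = " / "))
    }
  }
  flag_group <- function(x) {
    out <- rep(FALSE, length(x))
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 3L) return(rep(NA, length(x)))
    if (q == 0) return(out)
    resid <- x[ok] - stats::median(x[ok])
    rsdr <- unname(stats::quantile(abs(resid), 0.6827, type = 7)) * n / (n - 1)
    if (rsdr == 0 && all(resid == 0)) return(out)
    # degenerate scale with nonzero residuals: those points are infinitely
    # many robust SDs out
    t_stat <- if (rsdr == 0) ifelse(resid == 0, 0, Inf) else abs(resid) / rsdr
    p <- 2 * stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
    ord <- order(t_stat, decreasing = TRUE)
    fl <- rep(FALSE, n)
    for (i in seq_len(n)) {
      alpha_i <- q * (n - i + 1) / n
      if (p[ord[i]] < alpha_i) fl[ord[i]] <- TRUE else break
    }
    out[ok] <- fl
    out
  }
  groups <- unique(df$.group)
  res <- rep(NA, nrow(df))
  skipped <- character(0)
  for (g in groups) {
    idx <- df$.group == g
    fl <- flag_group(df[[values]][idx])
    if (all(is.na(fl))) skipped <- c(skipped, g)
    res[idx] <- fl
  }
  if (length(skipped)) {
    warning("Group(s) with fewer than 3 values skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  df$outlier <- res
  df$.group <- NULL
  df
}
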