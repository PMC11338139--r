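#' Pearson correlation with an exact-t significance test
#'
#' Thin wrapper around [stats::cor.test()] returning the coefficient, the
#' two-sided p-value from the exact t distribution
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df), the sample size
#' and the degrees of freedom, in the same record shape as
#' [partial_corr()].
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return A list of class `corr_result`: `r`, `p`, `n`, `df`,
#'   `n_controls = 0`.
#' @export
pearson_corr <- function(x, y) {
  check_corr_inputs(x, y, m = 0)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  corr_result(r = unname(ct$estimate), p = ct$p.value,
              n = length(x), n_controls = 0L)
}

#' Partial correlation with covariate control
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' set of control variables from both. Computed by the residual-regression
#' route: `x` and `y` are each regressed on the controls (with intercept)
#' by least squares, and the Pearson coefficient of the two residual
#' vectors is taken. Significance uses `t = r * sqrt(df / (1 - r^2))` on
#' `df = n - 2 - m` degrees of freedom, two-sided, where `m` is the number
#' of controls. With `controls = NULL` this reduces exactly to the plain
#' Pearson coefficient.
#'
#' The residual route is numerically robust for the small per-window
#' sample sizes this package works with; the equivalent inverse
#' correlation-matrix formula is used only as an independent cross-check
#' in the test suite.
#'
#' @param x,y Numeric vectors of equal length `n`, neither constant.
#' @param controls A numeric matrix or data frame with `m` columns of
#'   covariates (or `NULL` for none). Requires `n >= m + 3` and full
#'   column rank.
#' @return A list of class `corr_result`: `r`, `p`, `n`, `df`,
#'   `n_controls`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' pearson_corr(x, y)$r        # inflated by the shared cause z
#' partial_corr(x, y, cbind(z))$r  # near 0 once z is controlled
#' @export
partial_corr <- function(x, y, controls = NULL) {
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    storage.mode(controls) <- "double"
  }
  m <- if (is.null(controls)) 0L else ncol(controls)
  check_corr_inputs(x, y, m = m, controls = controls)
  n <- length(x)
  if (m == 0L) {
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    qrc <- qr(cbind(1, controls))
    if (qrc$rank < m + 1) {
      stop("control matrix is rank deficient (collinear controls)", call. = FALSE)
    }
    rx <- qr.resid(qrc, x)
    ry <- qr.resid(qrc, y)
  }
  # a residual vector that is numerically zero means the variable is fully
  # explained by the controls: nothing is left to correlate, so r = 0
  if (stats::sd(rx) <= 1e-12 * stats::sd(x) ||
      stats::sd(ry) <= 1e-12 * stats::sd(y)) {
    warning("a variable is (numerically) perfectly explained by the controls; ",
            "reporting r = 0", call. = FALSE)
    return(corr_result(r = 0, p = 1, n = n, n_controls = m))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - m
  p <- corr_pvalue(r, df)
  corr_result(r = r, p = p, n = n, n_controls = m)
}

# two-sided p for a correlation r on df degrees of freedom (exact t)
corr_pvalue <- function(r, df) {
  r <- min(1, max(-1, r))
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
}

corr_result <- function(r, p, n, n_controls) {
  structure(list(r = r, p = p, n = as.integer(n),
                 df = as.integer(n - 2 - n_controls),
                 n_controls = as.integer(n_controls)),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  kind <- if (x$n_controls == 0) "Pearson" else
    sprintf("partial (m = %d)", x$n_controls)
  cat(sprintf("%s correlation: r = %.4f, p = %.4g (n = %d, df = %d)\n",
              kind, x$r, x$p, x$n, x$df))
  invisible(x)
}

check_corr_inputs <- function(x, y, m, controls = NULL) {
  stopifnot(is.numeric(x), is.numeric(y))
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < m + 3) {
    stop("need at least ", m + 3, " samples for ", m,
         " control(s); got ", n, call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || (!is.null(controls) && anyNA(controls))) {
    stop("missing values in correlation inputs", call. = FALSE)
  }
  if (!is.null(controls) && nrow(controls) != n) {
    stop("controls must have one row per sample", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input vector: correlation undefined", call. = FALSE)
  }
  invisible(TRUE)
}

#' Four-level significance stratification
#'
#' Classifies a p-value into the four display strata used throughout the
#' package: `NS` (p >= 0.05, black), `L1` (0.01 <= p < 0.05, blue), `L2`
#' (0.001 <= p < 0.01, green), `L3` (p < 0.001, red). Each boundary value
#' belongs to the *less* significant stratum, extending the conventional
#' p = 0.05 -> not significant rule to the inner boundaries.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Factor with levels `NS`, `L1`, `L2`, `L3`.
#' @examples
#' classify_significance(c(0.5, 0.05, 0.03, 0.01, 0.001, 1e-4))
#' @export
classify_significance <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  lev <- ifelse(is.na(p), NA_character_,
         ifelse(p >= 0.05, "NS",
         ifelse(p >= 0.01, "L1",
         ifelse(p >= 0.001, "L2", "L3"))))
  factor(lev, levels = c("NS", "L1", "L2", "L3"))
}

#' Display colors of the significance strata
#'
#' @return Named character vector mapping stratum to plot color:
#'   NS = black, L1 = blue, L2 = green, L3 = red.
#' @export
significance_colors <- function() {
  c(NS = "black", L1 = "blue", L2 = "green", L3 = "red")
}

#' Warn on highly collinear control variables
#'
#' Partial correlation is unreliable when controls are nearly collinear.
#' This screen computes all pairwise Pearson coefficients among the
#' controls and returns (and emits) a warning for each pair whose |r|
#' exceeds the threshold. It never errors: the analysis proceeds, flagged.
#'
#' @param controls Numeric matrix or data frame of control columns.
#' @param threshold Absolute pairwise correlation above which to warn
#'   (default 0.9).
#' @param warn Emit `warning()`s (default) or just return the messages.
#' @return Character vector of warning messages (invisibly), one per
#'   offending pair; empty when all pairs are below the threshold.
#' @export
check_collinearity <- function(controls, threshold = 0.9, warn = TRUE) {
  controls <- as.matrix(controls)
  m <- ncol(controls)
  msgs <- character(0)
  if (m >= 2) {
    cn <- colnames(controls)
    if (is.null(cn)) cn <- paste0("control", seq_len(m))
    cm <- suppressWarnings(stats::cor(controls))
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        if (is.finite(cm[i, j]) && abs(cm[i, j]) > threshold) {
          msgs <- c(msgs, sprintf(
            "controls '%s' and '%s' are highly correlated (r = %.3f); partial correlation may be unstable",
            cn[i], cn[j], cm[i, j]))
        }
      }
    }
  }
  if (warn) for (msg in msgs) warning(msg, call. = FALSE)
  invisible(msgs)
}
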