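#' Run the sliding-window correlation sweep
#'
#' Slides value-range windows of width `w` (step `l`) along the driver
#' variable and computes, inside each window, the correlation between
#' driver and response: plain Pearson when `controls` is empty, partial
#' correlation controlling the named covariates otherwise. The sequence of
#' windowed coefficients is the order parameter read downstream by
#' [detect_transition()].
#'
#' Windows with fewer than `min_samples` members (default: number of
#' controls + 3) or with a constant column are reported with their
#' descriptive statistics but an undefined (`NA`) coefficient; they are
#' never silently dropped, since sparse high-intensity windows are exactly
#' where small-sample artifacts arise.
#'
#' @param table Data frame of observations with no missing values in the
#'   analysis columns (see [load_table()]).
#' @param driver,response Names of the driver and response columns.
#' @param controls Character vector of control column names (may be
#'   empty).
#' @param spec A [window_spec()].
#' @param norm_params Optional `norm_params` from [normalize_minmax()],
#'   carried through so thresholds can be reported in original units.
#' @return A `sweep_result`: list with `driver`, `response`, `controls`,
#'   `spec`, `norm_params`, and `windows`, a tibble with one row per
#'   window (`window_id`, `nominal_lower`, `nominal_upper`, `sample_min`,
#'   `sample_max`, `sample_mean`, `n`, `r`, `p`, `level`).
#' @examples
#' d <- generate_coupled(piecewise_model(n = 500, seed = 1))
#' run_sweep(d$table, "driver", "response", spec = window_spec(40, 5))
#' @export
run_sweep <- function(table, driver, response, controls = character(),
                      spec, norm_params = NULL) {
  stopifnot(inherits(spec, "window_spec"))
  table <- tibble::as_tibble(table)
  cols <- c(driver, response, controls)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (driver == response) stop("driver and response must differ", call. = FALSE)
  if (any(controls %in% c(driver, response))) {
    stop("controls must exclude the driver and response columns", call. = FALSE)
  }
  for (col in cols) {
    if (!is.numeric(table[[col]])) stop("column '", col, "' is not numeric", call. = FALSE)
    if (anyNA(table[[col]])) stop("column '", col, "' has missing values", call. = FALSE)
  }
  m <- length(controls)
  min_samples <- if (is.null(spec$min_samples)) m + 3L else
    max(spec$min_samples, m + 3L)

  ord <- sort_key(table, driver)
  table <- table[ord, , drop = FALSE]
  win <- generate_windows(spec, driver_max = max(table[[driver]]))
  n_win <- nrow(win)

  res <- tibble::tibble(
    window_id = win$window_id,
    nominal_lower = win$nominal_lower,
    nominal_upper = win$nominal_upper,
    sample_min = NA_real_, sample_max = NA_real_, sample_mean = NA_real_,
    n = 0L, r = NA_real_, p = NA_real_
  )
  ctrl_mat <- if (m > 0) as.matrix(table[controls]) else NULL
  for (i in seq_len(n_win)) {
    idx <- assign_samples(table, driver, win$nominal_lower[i],
                          win$nominal_upper[i], terminal = (i == n_win))
    res$n[i] <- length(idx)
    if (length(idx) >= 1) {
      dv <- table[[driver]][idx]
      res$sample_min[i] <- min(dv)
      res$sample_max[i] <- max(dv)
      res$sample_mean[i] <- mean(dv)
    }
    if (length(idx) >= min_samples) {
      x <- table[[driver]][idx]
      y <- table[[response]][idx]
      z <- if (m > 0) ctrl_mat[idx, , drop = FALSE] else NULL
      ok <- stats::sd(x) > 0 && stats::sd(y) > 0 &&
        (m == 0 || qr(cbind(1, z))$rank == m + 1)
      if (ok) {
        cr <- partial_corr(x, y, z)
        res$r[i] <- cr$r
        res$p[i] <- cr$p
      }
    }
  }
  res$level <- classify_significance(res$p)
  structure(list(driver = driver, response = response, controls = controls,
                 spec = spec, norm_params = norm_params, windows = res),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  kind <- if (length(x$controls) == 0) "Pearson" else
    sprintf("partial (controls: %s)", paste(x$controls, collapse = ", "))
  cat(sprintf("sliding-window %s correlation sweep\n", kind))
  cat(sprintf("  driver: %s   response: %s\n", x$driver, x$response))
  cat(sprintf("  w = %g, l = %g; %d windows (%d with defined coefficient)\n",
              x$spec$w, x$spec$l, nrow(x$windows), sum(!is.na(x$windows$r))))
  print(x$windows, n = 10)
  invisible(x)
}

#' Detect the coupling regime transition and intensity threshold
#'
#' Scans windows with a defined coefficient in ascending driver order.
#' Once a run of significantly positive windows (`r > 0`, `p < alpha`) of
#' length at least `min_run` has been seen, the first subsequent window
#' whose p-value reaches `alpha` is the transition window: the point where
#' the driver stops reliably driving the response. The reported threshold
#' is that window's *minimum member sample value* (not its nominal lower
#' bound), i.e. the lowest driver value already inside the decoupled
#' regime. If a later window is significantly negative (`r < 0`,
#' `p < 0.001`) the pattern is upgraded from `"pos_ns"` to
#' `"pos_ns_neg"`: input levels beyond the threshold actively depress the
#' response.
#'
#' Patterns: `"pos_ns"`, `"pos_ns_neg"`, `"none"` (no significant positive
#' run exists), `"pos_sustained"` (a positive run that never loses
#' significance; no transition to report).
#'
#' @param sweep A `sweep_result` from [run_sweep()].
#' @param alpha Significance level separating coupled from decoupled
#'   windows (default 0.05).
#' @param min_run Minimum length of the significant-positive run required
#'   before a loss of significance counts as a transition (default 1).
#' @return A `transition_report`: `transition_window_id` (or `NA`),
#'   `transition_range` (`c(sample_min, sample_max)` of that window),
#'   `threshold_normalized`, `threshold_original` (via the sweep's
#'   normalization parameters, when present), and `pattern`.
#' @export
detect_transition <- function(sweep, alpha = 0.05, min_run = 1) {
  stopifnot(inherits(sweep, "sweep_result"), alpha > 0, alpha < 1,
            min_run >= 1)
  w <- sweep$windows[!is.na(sweep$windows$r), , drop = FALSE]
  if (nrow(w) == 0) stop("no windows with a defined coefficient", call. = FALSE)

  run_len <- 0L
  trans_i <- NA_integer_
  for (i in seq_len(nrow(w))) {
    if (w$r[i] > 0 && w$p[i] < alpha) {
      run_len <- run_len + 1L
    } else if (run_len >= min_run && w$p[i] >= alpha) {
      trans_i <- i
      break
    } else {
      run_len <- 0L
    }
  }

  if (is.na(trans_i)) {
    pattern <- if (run_len >= min_run) "pos_sustained" else "none"
    rep <- list(transition_window_id = NA_integer_,
                transition_range = c(NA_real_, NA_real_),
                threshold_normalized = NA_real_,
                threshold_original = NA_real_,
                pattern = pattern, alpha = alpha,
                driver = sweep$driver, response = sweep$response,
                controls = sweep$controls)
    return(structure(rep, class = "transition_report"))
  }

  later <- w[seq(trans_i, nrow(w)), , drop = FALSE]
  pattern <- if (any(later$r < 0 & later$p < 0.001)) "pos_ns_neg" else "pos_ns"
  thr <- w$sample_min[trans_i]
  thr_orig <- if (!is.null(sweep$norm_params) &&
                  sweep$driver %in% sweep$norm_params$column) {
    denormalize(thr, sweep$norm_params, sweep$driver)
  } else NA_real_
  structure(list(
    transition_window_id = w$window_id[trans_i],
    transition_range = c(w$sample_min[trans_i], w$sample_max[trans_i]),
    threshold_normalized = thr,
    threshold_original = thr_orig,
    pattern = pattern, alpha = alpha,
    driver = sweep$driver, response = sweep$response,
    controls = sweep$controls
  ), class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("transition report: %s ~ %s", x$response, x$driver))
  if (length(x$controls) > 0)
    cat(sprintf(" | %s", paste(x$controls, collapse = ", ")))
  cat("\n")
  cat(sprintf("  pattern: %s (alpha = %g)\n", x$pattern, x$alpha))
  if (is.na(x$transition_window_id)) {
    cat("  no transition window detected\n")
  } else {
    cat(sprintf("  transition window #%d, sample range [%.3f, %.3f]\n",
                x$transition_window_id,
                x$transition_range[1], x$transition_range[2]))
    cat(sprintf("  threshold (normalized driver units): %.3f\n",
                x$threshold_normalized))
    if (!is.na(x$threshold_original)) {
      cat(sprintf("  threshold (original driver units): %.6g\n",
                  x$threshold_original))
    }
  }
  invisible(x)
}
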