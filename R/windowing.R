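#' Sliding-window specification
#'
#' Defines the value-range windows slid over the driver variable: width
#' `w` and step `l`, both in driver units (0-100 when the driver is
#' normalized). Windows are intervals over the driver's *values*, not over
#' time or sample index; window `k` spans
#' `[origin + k*l, origin + k*l + w]`.
#'
#' @param w Window size in driver units; must be positive.
#' @param l Step width in driver units; must be positive. `l < w` gives
#'   overlapping windows (consecutive windows share `w - l` of range);
#'   `l = w` tiles the axis.
#' @param min_samples Minimum number of member samples for a window to
#'   yield a coefficient. Default `NULL` means "number of controls + 3",
#'   resolved at sweep time: the smallest n for which the partial
#'   correlation t-test has at least one degree of freedom.
#' @param origin Lower bound of the first window; 0 by default, matching
#'   a driver normalized to start at 0.
#' @return A `window_spec` object.
#' @examples
#' window_spec(w = 40, l = 5)
#' @export
window_spec <- function(w, l, min_samples = NULL, origin = 0) {
  stopifnot(is.numeric(w), length(w) == 1, is.finite(w), w > 0,
            is.numeric(l), length(l) == 1, is.finite(l), l > 0,
            is.numeric(origin), length(origin) == 1, is.finite(origin))
  if (!is.null(min_samples)) {
    stopifnot(is.numeric(min_samples), length(min_samples) == 1,
              min_samples >= 3)
    min_samples <- as.integer(min_samples)
  }
  structure(list(w = w, l = l, min_samples = min_samples, origin = origin),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("sliding-window spec: w = %g, l = %g, origin = %g, min_samples = %s\n",
              x$w, x$l, x$origin,
              if (is.null(x$min_samples)) "n_controls + 3" else x$min_samples))
  invisible(x)
}

#' Order rows by ascending driver value
#'
#' Stable ascending permutation of row indices by the driver column (ties
#' keep original row order). Sorting is the first step of the sweep; with
#' value-range windows it is a presentation convenience, since membership
#' depends only on each sample's value.
#'
#' @param table Data frame of observations.
#' @param driver Name of the driver column.
#' @return Integer permutation of `seq_len(nrow(table))`.
#' @export
sort_key <- function(table, driver) {
  stopifnot(driver %in% names(table))
  order(table[[driver]])  # order() is a stable sort
}

#' Generate the sequence of value-range windows
#'
#' Window `k` (k = 0, 1, ...) spans `[origin + k*l, origin + k*l + w]`.
#' Generation stops with the first window whose upper bound reaches or
#' exceeds `driver_max`; that terminal window is included, so the
#' highest-value samples always participate in at least one window.
#'
#' @param spec A [window_spec()].
#' @param driver_max Maximum observed driver value; must exceed
#'   `spec$origin`.
#' @return A tibble with one row per window: `window_id` (1-based),
#'   `nominal_lower`, `nominal_upper`.
#' @examples
#' generate_windows(window_spec(40, 5), driver_max = 100)  # 13 windows
#' @export
generate_windows <- function(spec, driver_max) {
  stopifnot(inherits(spec, "window_spec"),
            is.numeric(driver_max), length(driver_max) == 1,
            is.finite(driver_max))
  if (driver_max <= spec$origin) {
    stop("driver maximum (", driver_max, ") must exceed the window origin (",
         spec$origin, ")", call. = FALSE)
  }
  # number of steps until the upper bound first reaches driver_max
  if (spec$origin + spec$w >= driver_max) {
    k_last <- 0L
  } else {
    k_last <- as.integer(ceiling((driver_max - spec$w - spec$origin) / spec$l))
    # guard against ceiling() landing one short under floating point
    while (spec$origin + k_last * spec$l + spec$w < driver_max) k_last <- k_last + 1L
  }
  k <- 0:k_last
  lower <- spec$origin + k * spec$l
  tibble::tibble(window_id = k + 1L,
                 nominal_lower = lower,
                 nominal_upper = lower + spec$w)
}

#' Assign samples to a value-range window
#'
#' Membership is half-open, `lower <= x < upper`, so a sample on a shared
#' bound belongs to exactly one of two adjacent tiling windows. The
#' terminal window is closed on the right (`terminal = TRUE`) so the
#' maximum driver value is never orphaned.
#'
#' @param table Data frame of observations.
#' @param driver Name of the driver column.
#' @param lower,upper Window bounds.
#' @param terminal Whether this is the last generated window (closed upper
#'   bound).
#' @return Integer vector of member row indices.
#' @export
assign_samples <- function(table, driver, lower, upper, terminal = FALSE) {
  stopifnot(driver %in% names(table), is.finite(lower), is.finite(upper))
  x <- table[[driver]]
  inside <- x >= lower & (if (terminal) x <= upper else x < upper)
  which(inside)
}
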