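#' Load a delimited observation table
#'
#' Reads a comma-delimited text file with a header row into a tibble and
#' validates that the columns needed for an analysis are present, numeric,
#' and complete. Rows with a missing value in any required column are
#' dropped (listwise deletion) and the number dropped is reported as a
#' warning, so silently shrinking sample sizes cannot go unnoticed.
#'
#' @param path Path to a CSV file (header row required, UTF-8, decimal
#'   point notation).
#' @param required_columns Character vector of column names that the
#'   downstream analysis will use (driver, response, controls). These must
#'   exist and be numeric; rows incomplete in any of them are removed.
#' @return A tibble with at least the required columns and no missing
#'   values in them.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("prov,fert,yield", "a,1,2", "b,2,4", "c,3,6"), f)
#' load_table(f, c("fert", "yield"))
#' @export
load_table <- function(path, required_columns = character()) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required_columns, names(tab))
  if (length(missing_cols) > 0) {
    stop("required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in required_columns) {
    if (!is.numeric(tab[[col]])) {
      # read_csv types a column character when any cell is non-numeric
      suppressWarnings(num <- as.numeric(tab[[col]]))
      bad <- !is.na(tab[[col]]) & is.na(num)
      if (any(bad)) {
        stop("column '", col, "' contains non-numeric value(s), e.g. '",
             tab[[col]][which(bad)[1]], "'", call. = FALSE)
      }
      tab[[col]] <- num
    }
  }
  if (length(required_columns) > 0) {
    complete <- stats::complete.cases(tab[required_columns])
    n_drop <- sum(!complete)
    if (n_drop > 0) {
      warning(n_drop, " row(s) dropped with missing values in required columns",
              call. = FALSE)
      tab <- tab[complete, , drop = FALSE]
    }
  }
  if (nrow(tab) < 1) stop("no complete rows remain after validation", call. = FALSE)
  tab
}

#' Min-max normalize columns to the 0-100 scale
#'
#' Rescales each named column by the affine map
#' \eqn{x \mapsto 100 (x - \min x) / (\max x - \min x)}, the unique affine
#' transform placing observed values exactly on \[0, 100\]. The observed
#' per-column extremes are recorded so that thresholds estimated on the
#' normalized scale can be mapped back to original units with
#' [denormalize()].
#'
#' @param table A data frame of observations.
#' @param columns Character vector of columns to normalize; each must be
#'   numeric with `max > min`.
#' @return A list with elements `table` (the rescaled tibble) and `params`
#'   (a `norm_params` object recording per-column min and max).
#' @examples
#' nz <- normalize_minmax(tibble::tibble(x = c(2, 4, 6)), "x")
#' nz$table$x  # 0 50 100
#' @seealso [denormalize()]
#' @export
normalize_minmax <- function(table, columns) {
  table <- tibble::as_tibble(table)
  stopifnot(all(columns %in% names(table)))
  mins <- maxs <- numeric(length(columns))
  for (i in seq_along(columns)) {
    x <- table[[columns[i]]]
    if (!is.numeric(x)) stop("column '", columns[i], "' is not numeric", call. = FALSE)
    if (anyNA(x)) stop("column '", columns[i], "' contains missing values", call. = FALSE)
    mins[i] <- min(x)
    maxs[i] <- max(x)
    if (maxs[i] <= mins[i]) {
      stop("column '", columns[i], "' is constant; cannot min-max normalize",
           call. = FALSE)
    }
    table[[columns[i]]] <- 100 * (x - mins[i]) / (maxs[i] - mins[i])
  }
  params <- structure(
    list(column = columns, min = mins, max = maxs,
         target_lo = 0, target_hi = 100),
    class = "norm_params"
  )
  list(table = table, params = params)
}

#' @export
print.norm_params <- function(x, ...) {
  cat("min-max normalization to [0, 100]\n")
  for (i in seq_along(x$column)) {
    cat(sprintf("  %s: observed [%g, %g]\n", x$column[i], x$min[i], x$max[i]))
  }
  invisible(x)
}

#' Map a normalized value back to original units
#'
#' Exact inverse of [normalize_minmax()]:
#' \eqn{v \mapsto \min + v/100 (\max - \min)} using the recorded per-column
#' extremes. Used to report thresholds found on the 0-100 scale in the
#' driver's native units (e.g. sej/ha input intensity).
#'
#' @param value Numeric value(s) on the 0-100 scale.
#' @param params A `norm_params` object from [normalize_minmax()].
#' @param column Name of the column whose recorded extremes apply.
#' @return Value(s) in the column's original units.
#' @examples
#' nz <- normalize_minmax(tibble::tibble(x = c(2, 4, 6)), "x")
#' denormalize(50, nz$params, "x")  # 4
#' @export
denormalize <- function(value, params, column) {
  stopifnot(inherits(params, "norm_params"))
  i <- match(column, params$column)
  if (is.na(i)) stop("no normalization parameters recorded for column '",
                     column, "'", call. = FALSE)
  params$min[i] + value / 100 * (params$max[i] - params$min[i])
}

#' Flag outliers by the IQR fence rule
#'
#' Optional pre-filter: marks values beyond `k` interquartile ranges from
#' the quartiles (Tukey fences with a wide default multiplier). Correlation
#' inside narrow windows is sensitive to extreme values, so screening
#' before the sweep is advisable for noisy observational data; no method
#' is forced and this filter is off unless called explicitly.
#'
#' @param x Numeric vector.
#' @param k Fence multiplier (default 3, a conservative "far out" fence).
#' @return Logical vector, `TRUE` where `x` lies outside
#'   `[Q1 - k*IQR, Q3 + k*IQR]`.
#' @export
flag_outliers <- function(x, k = 3) {
  stopifnot(is.numeric(x), k > 0)
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}
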