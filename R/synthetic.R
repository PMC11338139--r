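#' Piecewise-coupled driver/response model
#'
#' Specifies a synthetic system whose response is a continuous
#' piecewise-linear function of a driver uniform on \[0, 100\], plus
#' optional confounders and additive Gaussian noise. The default shape
#' (slope +1 up to driver 40, flat to 60, slope -1 above) reproduces the
#' canonical intensification story: input helps, then stops helping, then
#' hurts — a ground-truth regime structure the sweep should recover.
#'
#' @param n Sample count.
#' @param breakpoints Ascending driver values strictly inside (0, 100)
#'   splitting the axis into segments.
#' @param slopes Response slope per segment; length
#'   `length(breakpoints) + 1`.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   response. The default `NULL` resolves at generation time to 10% of
#'   the noiseless response range, a moderate signal-to-noise typical of
#'   provincial panel aggregates.
#' @param confounders Optional data frame / list with one row (element
#'   set) per confounder and numeric fields `driver_loading`,
#'   `response_loading`, `sd`: each confounder is
#'   `C = driver_loading * driver/100 + Normal(0, sd)`, and
#'   `response_loading * C` is added to the response. Nonzero loadings on
#'   both sides create classical confounding that partial correlation on
#'   the confounder should remove.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `piecewise_model` object.
#' @export
piecewise_model <- function(n = 1000, breakpoints = c(40, 60),
                            slopes = c(1, 0, -1), noise_sd = NULL,
                            confounders = NULL, seed = 1L) {
  stopifnot(n >= 1,
            length(slopes) == length(breakpoints) + 1,
            !is.unsorted(breakpoints, strictly = TRUE))
  if (length(breakpoints) > 0) {
    stopifnot(all(breakpoints > 0), all(breakpoints < 100))
  }
  if (!is.null(noise_sd)) stopifnot(is.numeric(noise_sd), noise_sd >= 0)
  if (!is.null(confounders)) {
    confounders <- as.data.frame(confounders)
    stopifnot(all(c("driver_loading", "response_loading", "sd") %in%
                    names(confounders)),
              all(confounders$sd >= 0))
  }
  structure(list(n = as.integer(n), breakpoints = breakpoints,
                 slopes = slopes, noise_sd = noise_sd,
                 confounders = confounders, seed = as.integer(seed)),
            class = "piecewise_model")
}

# continuous piecewise-linear response: segments joined at the breakpoints
piecewise_response <- function(driver, breakpoints, slopes) {
  knots <- c(0, breakpoints, 100)
  # cumulative value at each knot
  knot_val <- cumsum(c(0, slopes * diff(knots)))
  seg <- findInterval(driver, knots, rightmost.closed = TRUE)
  knot_val[seg] + slopes[seg] * (driver - knots[seg])
}

#' Generate a synthetic coupled dataset
#'
#' Draws `n` driver values uniform on \[0, 100\], builds the continuous
#' piecewise-linear response, adds confounder contributions and Gaussian
#' noise, and returns both the observation table and the ground truth the
#' generator used — so recovery of breakpoints and patterns can be tested
#' against known values. The global RNG state is left untouched.
#'
#' @param model A [piecewise_model()].
#' @return List with `table` (tibble: `driver`, `response`, and
#'   `conf1..confm` when confounders are present) and `truth`
#'   (breakpoints, slopes, resolved noise_sd, seed, response range).
#' @examples
#' d <- generate_coupled(piecewise_model(n = 200, seed = 42))
#' head(d$table)
#' d$truth$breakpoints
#' @export
generate_coupled <- function(model) {
  stopifnot(inherits(model, "piecewise_model"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(model$seed)

  driver <- stats::runif(model$n, 0, 100)
  signal <- piecewise_response(driver, model$breakpoints, model$slopes)
  sig_range <- diff(range(piecewise_response(seq(0, 100, by = 0.1),
                                             model$breakpoints, model$slopes)))
  noise_sd <- if (is.null(model$noise_sd)) 0.1 * sig_range else model$noise_sd

  tab <- tibble::tibble(driver = driver, response = signal)
  m <- if (is.null(model$confounders)) 0L else nrow(model$confounders)
  if (m > 0) {
    for (j in seq_len(m)) {
      cj <- model$confounders$driver_loading[j] * driver / 100 +
        stats::rnorm(model$n, 0, model$confounders$sd[j])
      tab[[paste0("conf", j)]] <- cj
      tab$response <- tab$response + model$confounders$response_loading[j] * cj
    }
  }
  tab$response <- tab$response + stats::rnorm(model$n, 0, noise_sd)

  list(table = tab,
       truth = list(breakpoints = model$breakpoints, slopes = model$slopes,
                    noise_sd = noise_sd, seed = model$seed,
                    response_range = sig_range,
                    n_confounders = m))
}

#' Write a generated table as a CSV fixture
#'
#' Emits the same comma-delimited, headered dialect that [load_table()]
#' consumes, at full double precision so a write/load round trip is
#' lossless well below 1e-12.
#'
#' @param table Data frame to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}
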