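# Independent oracles the test suite checks the implementation against.
# Everything here deliberately avoids the package's own code paths.

# partial correlation from the inverse of the full correlation matrix:
# r_xy.Z = -Omega_xy / sqrt(Omega_xx * Omega_yy)
oracle_partial_r <- function(x, y, controls = NULL) {
  dat <- cbind(x, y, controls)
  omega <- solve(stats::cor(dat))
  -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2])
}

# two-sided p for a correlation on df degrees of freedom, written out
oracle_corr_p <- function(r, df) {
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
}

# enumerate window bounds by literal iteration of the stepping rule
oracle_windows <- function(w, l, origin, driver_max) {
  lower <- origin
  out <- NULL
  repeat {
    upper <- lower + w
    out <- rbind(out, c(lower, upper))
    if (upper >= driver_max) break
    lower <- lower + l
  }
  out
}

# linear-scan membership filter
oracle_members <- function(x, lower, upper, terminal) {
  keep <- logical(length(x))
  for (i in seq_along(x)) {
    keep[i] <- x[i] >= lower && (if (terminal) x[i] <= upper else x[i] < upper)
  }
  which(keep)
}

# write a table to a throwaway CSV and return the path
tmp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
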