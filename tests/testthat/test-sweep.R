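# build a sweep_result by hand for detector tests
fake_sweep <- function(r, p, sample_min = NULL, norm_params = NULL) {
  k <- length(r)
  if (is.null(sample_min)) sample_min <- seq(0, by = 5, length.out = k)
  win <- tibble::tibble(
    window_id = seq_len(k),
    nominal_lower = sample_min, nominal_upper = sample_min + 40,
    sample_min = sample_min, sample_max = sample_min + 38,
    sample_mean = sample_min + 20, n = 30L, r = r, p = p,
    level = classify_significance(p)
  )
  structure(list(driver = "input", response = "output",
                 controls = character(0), spec = window_spec(40, 5),
                 norm_params = norm_params, windows = win),
            class = "sweep_result")
}

test_that("a sweep over one window reduces to the plain coefficient", {
  tab <- tibble::tibble(d = c(10, 20, 30), y = c(1, 3, 2))
  s <- run_sweep(tab, "d", "y", spec = window_spec(50, 5))
  expect_equal(nrow(s$windows), 1)
  expect_equal(s$windows$n, 3L)
  expect_equal(s$windows$r, pearson_corr(tab$d, tab$y)$r)
  expect_equal(s$windows$p, pearson_corr(tab$d, tab$y)$p)
})

test_that("sweep emits one result per generated window with coherent descriptives", {
  d <- generate_coupled(piecewise_model(n = 2000, seed = 31))
  nz <- normalize_minmax(d$table, "driver")
  s <- run_sweep(nz$table, "driver", "response", spec = window_spec(40, 5),
                 norm_params = nz$params)
  expect_equal(nrow(s$windows), 13)
  expect_equal(s$windows$nominal_lower, seq(0, 60, by = 5))
  w <- s$windows
  occupied <- w$n >= 1
  expect_true(all(w$nominal_lower[occupied] <= w$sample_min[occupied]))
  expect_true(all(w$sample_min[occupied] <= w$sample_mean[occupied]))
  expect_true(all(w$sample_mean[occupied] <= w$sample_max[occupied]))
  expect_true(all(w$sample_max[occupied] <= w$nominal_upper[occupied]))
  expect_identical(is.na(w$r), w$n < 3L)
})

test_that("every windowed coefficient equals an independent recomputation", {
  d <- generate_coupled(piecewise_model(
    n = 1500, seed = 32,
    confounders = data.frame(driver_loading = c(20, -10),
                             response_loading = c(0.5, 0.3),
                             sd = c(5, 5))))
  tab <- d$table
  s <- run_sweep(tab, "driver", "response", controls = c("conf1", "conf2"),
                 spec = window_spec(20, 4))
  win <- s$windows
  dmax <- max(tab$driver)
  for (i in seq_len(nrow(win))) {
    idx <- oracle_members(tab$driver, win$nominal_lower[i],
                          win$nominal_upper[i], i == nrow(win))
    expect_equal(win$n[i], length(idx))
    if (!is.na(win$r[i])) {
      r_ref <- oracle_partial_r(tab$driver[idx], tab$response[idx],
                                as.matrix(tab[idx, c("conf1", "conf2")]))
      expect_lt(abs(win$r[i] - r_ref), 1e-10)
      expect_lt(abs(win$p[i] - oracle_corr_p(r_ref, length(idx) - 4)), 1e-9)
    }
  }
})

test_that("sweeps are deterministic and validate their inputs", {
  d <- generate_coupled(piecewise_model(n = 300, seed = 33))
  s1 <- run_sweep(d$table, "driver", "response", spec = window_spec(30, 10))
  s2 <- run_sweep(d$table, "driver", "response", spec = window_spec(30, 10))
  expect_identical(s1$windows, s2$windows)

  expect_error(run_sweep(d$table, "driver", "driver", spec = window_spec(30, 10)),
               "must differ")
  expect_error(run_sweep(d$table, "driver", "response", controls = "driver",
                         spec = window_spec(30, 10)), "exclude")
  expect_error(run_sweep(d$table, "nope", "response", spec = window_spec(30, 10)),
               "not in table")
})

test_that("under-filled windows carry descriptives but no coefficient", {
  tab <- tibble::tibble(d = c(1, 2, 3, 4, 5, 50), y = c(2, 4, 5, 9, 11, 3))
  s <- run_sweep(tab, "d", "y", spec = window_spec(10, 10))
  w <- s$windows
  expect_equal(nrow(w), 5)
  expect_false(is.na(w$r[1]))
  # middle windows are empty; terminal window holds a single sample
  expect_true(all(w$n[2:4] == 0))
  expect_true(all(is.na(w$r[2:5])))
  expect_equal(w$sample_min[5], 50)
  expect_equal(w$n[5], 1L)
})

test_that("transition scan finds the first loss of significance after a positive run", {
  rep1 <- detect_transition(fake_sweep(r = c(0.8, 0.7, 0.2, -0.6),
                                       p = c(0.001, 0.002, 0.2, 1e-4)))
  expect_equal(rep1$transition_window_id, 3L)
  expect_equal(rep1$pattern, "pos_ns_neg")
  expect_equal(rep1$threshold_normalized, 10)           # sample_min of window 3
  expect_equal(rep1$transition_range, c(10, 48))

  # without a later strong negative window the pattern stays pos_ns
  rep2 <- detect_transition(fake_sweep(r = c(0.8, 0.1), p = c(0.001, 0.5)))
  expect_equal(rep2$pattern, "pos_ns")
  expect_equal(rep2$transition_window_id, 2L)

  # sustained significant positive coupling: no transition to report
  rep3 <- detect_transition(fake_sweep(r = c(0.8, 0.9, 0.85),
                                       p = c(1e-4, 1e-5, 1e-4)))
  expect_true(is.na(rep3$transition_window_id))
  expect_equal(rep3$pattern, "pos_sustained")

  # no significant positive run at all
  rep4 <- detect_transition(fake_sweep(r = c(0.1, -0.2), p = c(0.4, 0.6)))
  expect_equal(rep4$pattern, "none")

  # undefined windows are skipped, not treated as transitions
  rep5 <- detect_transition(fake_sweep(r = c(0.8, NA, 0.7, 0.1),
                                       p = c(0.001, NA, 0.002, 0.3)))
  expect_equal(rep5$transition_window_id, 4L)
})

test_that("a minimum run length can be required before a transition counts", {
  s <- fake_sweep(r = c(0.8, 0.1, 0.7, 0.75, 0.1),
                  p = c(0.01, 0.5, 0.01, 0.01, 0.5))
  # run of 1 then NS at window 2 counts by default
  expect_equal(detect_transition(s)$transition_window_id, 2L)
  # requiring a run of 2 pushes the transition to window 5
  expect_equal(detect_transition(s, min_run = 2)$transition_window_id, 5L)
})

test_that("thresholds are reported in original units when normalization is on record", {
  nz <- normalize_minmax(tibble::tibble(input = c(0, 2.5e15)), "input")
  s <- fake_sweep(r = c(0.9, 0.1), p = c(0.001, 0.4),
                  sample_min = c(0, 35.288), norm_params = nz$params)
  s$driver <- "input"
  rep <- detect_transition(s)
  expect_equal(rep$threshold_normalized, 35.288)
  expect_equal(rep$threshold_original, 35.288 / 100 * 2.5e15)
})
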