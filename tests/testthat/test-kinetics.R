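test_that("min-max normalization behaves on ramps and rejects constants", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_error(normalize_minmax(c(5, 5)), "constant")
  expect_error(normalize_minmax(5), "2 frames")
  x <- normalize_minmax(c(1, 3, 9, 4))
  expect_equal(normalize_minmax(x), x)   # idempotent
})

test_that("onset detection reads a sustained step and ignores flat noise", {
  tt <- seq(0, 20, by = 0.5)
  series <- ifelse(tt >= 5, 10, 0)
  expect_equal(detect_onset(series, tt, background_sd = 1), 5.0)
  set.seed(4)
  flat <- rnorm(length(tt), 0, 1)
  expect_true(is.na(detect_onset(flat, tt, background_sd = 1)))
  # single-frame excursions do not trigger
  spike <- rep(0, length(tt)); spike[10] <- 100
  expect_true(is.na(detect_onset(spike, tt, background_sd = 1)))
})

test_that("simulated Rev onsets are recovered within one frame on average", {
  cfg <- scenario_config("rev", "gradual", penetrance = 1,
                         rev_onset_mean = 8, rev_onset_sd = 2)
  opt <- fix_optics()
  errs <- vapply(1:15, function(i) {
    cell <- fix_cell(cfg, seed = 300 + i, channels = "mCherry",
                     t_end_h = 20, optics = opt)
    masks <- retroflux:::static_masks(list(history = cell$history,
                                           movie = cell$movie), opt)
    meas <- measure_movie(cell$movie, channels = "mCherry", masks = masks)
    tr <- cell_trace(meas)
    tr$rev_onset - cell$history$drawn$rev_onset
  }, 0)
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("peak alignment centres every trace and preserves shape", {
  tr <- list(c(0, 0.2, 1, 0.5), c(1, 0.3, 0.2))
  al <- align_to_peak(tr)
  expect_equal(al$matrix[1, al$offsets == 0], 1)
  expect_equal(al$matrix[2, al$offsets == 0], 1)
  expect_equal(al$matrix[1, al$offsets == -2], 0)

  same <- replicate(5, c(0, 0.5, 1, 0.4), simplify = FALSE)
  alm <- align_to_peak(same)$matrix
  expect_true(all(apply(alm, 2, function(col) var(col) == 0)))
  expect_error(align_to_peak(list()), "empty")

  # ties break to the earliest maximum
  al2 <- align_to_peak(list(c(0, 1, 1, 0)))
  expect_equal(al2$offsets[which(al2$matrix[1, ] == 1)[1]], 0)
})

test_that("transition duration recovers linear ramps and steps", {
  tt <- seq(0, 12, by = 0.1)
  ramp <- pmin(tt / 9, 1)
  expect_equal(transition_duration(ramp, tt), 9.0, tolerance = 1e-9)
  step <- ifelse(tt >= 5, 1, 0)
  expect_lte(transition_duration(step, tt), 0.1 / 0.8 + 1e-9)
  low <- pmin(tt / 9, 0.8)
  expect_true(is.na(transition_duration(low, tt)))
})

test_that("interpolated crossings agree with a brute-force dense search", {
  brute <- function(x, tt, lvl) {
    dense_t <- seq(min(tt), max(tt), length.out = 200001)
    dense_x <- approx(tt, x, xout = dense_t)$y
    up <- which(dense_x[-1] >= lvl & dense_x[-length(dense_x)] < lvl)
    c(first = dense_t[up[1] + 1], last = dense_t[up[length(up)] + 1])
  }
  set.seed(5)
  for (i in 1:20) {
    tt <- seq(0, 20, by = 0.5)
    x <- cumsum(runif(length(tt)))
    x <- (x - min(x)) / (max(x) - min(x))
    est <- transition_duration(x, tt)
    b <- brute(x, tt, 0.1)
    b9 <- brute(x, tt, 0.9)
    expect_equal(est, (b9["last"] - b["first"]) / 0.8,
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("duration is invariant to time shifts and monotone intensity rescaling", {
  tt <- seq(0, 20, by = 0.5)
  raw <- pmin(pmax(tt - 3, 0) / 9, 1) * 4 + 0.2
  d1 <- transition_duration(normalize_minmax(raw), tt)
  d2 <- transition_duration(normalize_minmax(raw), tt + 7)
  expect_equal(d1, d2)
  d3 <- transition_duration(normalize_minmax(raw * 13 + 5), tt)
  expect_equal(d1, d3, tolerance = 1e-9)
})

test_that("export classification separates burst, gradual and retained traces", {
  tt <- seq(0, 20, by = 0.5)
  gradual <- pmin(pmax(tt - 2, 0) / 9, 1) * 3
  expect_identical(classify_export(gradual, tt)$class, "gradual")
  burst <- ifelse(tt >= 10.25, 3, 0.05)
  expect_identical(classify_export(burst, tt)$class, "burst")
  flat <- rep(0.4, length(tt))
  expect_identical(classify_export(flat, tt)$class, "none")
})

test_that("VLP onset needs three sustained punctae", {
  tt <- seq(0, 36, by = 0.5)
  counts <- ifelse(tt >= 16, 3L, 0L)
  expect_equal(vlp_onset(counts, tt), 16)
  expect_true(is.na(vlp_onset(rep(2L, length(tt)), tt)))
  blip <- rep(0L, length(tt)); blip[20] <- 5L
  expect_true(is.na(vlp_onset(blip, tt)))
})

test_that("aligned burst traces rise sharply just before the peak", {
  cfg <- scenario_config("b", "burst", penetrance = 1, burst_penetrance = 1)
  opt <- fix_optics()
  traces <- list()
  for (i in 1:8) {
    cell <- fix_cell(cfg, seed = 400 + i, channels = "YFP", t_end_h = 30,
                     optics = opt)
    masks <- retroflux:::static_masks(list(history = cell$history,
                                           movie = cell$movie), opt)
    meas <- measure_movie(cell$movie, channels = "YFP", masks = masks)
    cn <- meas$cytoplasmic_mfi / pmax(meas$nuclear_mfi, 1e-6)
    # round so plateau frames tie and alignment lands on the first
    # attainment of the maximum (the documented tie rule)
    traces[[i]] <- round(normalize_minmax(cn), 1)
  }
  al <- align_to_peak(traces)
  pre <- al$matrix[, al$offsets == -2]   # one hour before the peak
  expect_lt(mean(pre, na.rm = TRUE), 0.5)
})
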