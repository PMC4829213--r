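test_that("distribution classification follows the C:N boundaries", {
  expect_identical(classify_distribution(100, 300), "cytoplasmic")
  expect_identical(classify_distribution(100, 100), "equal")
  expect_identical(classify_distribution(300, 100), "nuclear")
  expect_identical(classify_distribution(0, 10), "cytoplasmic")  # limit case
  # scale invariance
  expect_identical(classify_distribution(1, 1.6),
                   classify_distribution(1000, 1600))
})

test_that("the centrosome is located within 2 px of the rendered marker", {
  cell <- fix_cell("4xCTE", seed = 31, channels = c("YFP", "DNA", "PCNT"),
                   frames = 49, sample_times_h = seq(0, 24, 0.5),
                   t_end_h = 24)
  nuc <- segment_nucleus(frame_of(cell$movie, 1, "DNA"))
  cm <- segment_cell(frame_of(cell$movie, 1, "YFP"), nuc)
  masks <- compartment_masks(nuc, cm)
  sig_px <- cell$optics$psf_sigma / cell$optics$pixel_size
  cs <- locate_centrosome(frame_of(cell$movie, 1, "PCNT"), masks$cytoplasm,
                          sig_px)
  truth <- cell$movie$ground_truth$centrosome_px
  expect_true(cs$found)
  expect_lt(sqrt((cs$x_px - truth["x"])^2 + (cs$y_px - truth["y"])^2), 2)
})

test_that("a featureless marker frame yields a not-found flag", {
  set.seed(6)
  flat <- matrix(rpois(128^2, 100), 128, 128)
  mask <- matrix(TRUE, 128, 128)
  cs <- locate_centrosome(flat, mask, 1.23)
  expect_false(cs$found)
})

test_that("equal maxima break ties to the earliest position in row-major order", {
  img <- matrix(0, 64, 64)
  img[20, 30] <- 1000
  img[40, 10] <- 1000
  mask <- matrix(TRUE, 64, 64)
  cs <- locate_centrosome(img, mask, 1.23)
  expect_true(cs$found)
  expect_equal(cs$y_px, 19)   # row 20 comes before row 40
  expect_equal(cs$x_px, 29)
})

test_that("MTOC fold is ~1 for uniform cytoplasm and large for a pure cluster", {
  nuc <- matrix(FALSE, 200, 200)
  yy <- matrix(seq_len(200), 200, 200); xx <- t(yy)
  nuc[(yy - 100)^2 + (xx - 100)^2 < 20^2] <- TRUE
  cellm <- (yy - 100)^2 + (xx - 100)^2 < 75^2
  masks <- compartment_masks(nuc, cellm)
  cs <- list(x_px = 100, y_px = 75)   # just outside the nucleus
  uni <- matrix(0, 200, 200); uni[masks$cytoplasm] <- 120
  me <- mtoc_enrichment(uni, cs, masks, 0, 0.325)
  expect_lt(abs(me$fold - 1), 0.05)
  expect_false(me$targeted)

  conc <- matrix(0, 200, 200)
  d_cs <- sqrt((yy - 76)^2 + (xx - 100)^2) * 0.325
  conc[masks$cytoplasm & d_cs <= 2] <- 5000
  me2 <- mtoc_enrichment(conc, cs, masks, 0, 0.325)
  expect_gt(me2$fold, 3)
  expect_true(me2$targeted)

  # invariance to a background shift after subtraction
  me3 <- mtoc_enrichment(conc + 50, cs, masks, 50, 0.325)
  expect_equal(me2$fold, me3$fold, tolerance = 1e-9)
})

test_that("population summaries report fractions and replicate dispersion", {
  one <- population_summary(c("cyt", "cyt", "cyt", "nuc"), rep(1, 4))
  expect_equal(unname(one$mean["cyt"]), 0.75)
  expect_true(is.na(one$sd["cyt"]))

  same <- population_summary(rep(c("a", "b"), 30),
                             rep(1:3, each = 20))
  expect_equal(unname(same$sd["a"]), 0)

  calls <- c(rep("t", 7), rep("f", 3), rep("t", 8), rep("f", 2),
             rep("t", 75), rep("f", 25))
  reps <- c(rep(1, 10), rep(2, 10), rep(3, 100))
  ps <- population_summary(calls, reps)
  expect_equal(unname(ps$mean["t"]), mean(c(0.7, 0.8, 0.75)))
  expect_equal(unname(ps$sd["t"]), sd(c(0.7, 0.8, 0.75)))
  expect_error(population_summary(character(), integer()), "no phenotype")
})

test_that("realized phenotype fractions sit inside the exact binomial band", {
  # ground-truth penetrance draws at n = 300 across 10 seeds
  cfg <- scenario_config("p", "cte_mtoc", penetrance = 0.177,
                         rev_onset_mean = NA_real_)
  ci <- qbinom(c(0.005, 0.995), 300, cfg$penetrance)
  for (s in 1:10) {
    set.seed(s)
    draws <- rbinom(1, 300, cfg$penetrance)  # the generator's class draw law
    expect_gte(draws, ci[1])
    expect_lte(draws, ci[2])
  }
  # and the simulator's own class draw matches that law over a pooled sample
  classes <- vapply(1:60, function(i) {
    g <- make_cell_geometry(cfg, i)
    h <- simulate_trafficking(g, cfg, i + 1000, sample_times_h = c(0, 24))
    h$drawn$class
  }, "")
  p_hat <- mean(classes == "mtoc")
  expect_gt(p_hat, qbinom(0.005, 60, 0.177) / 60 - 1e-9)
  expect_lt(p_hat, qbinom(0.995, 60, 0.177) / 60 + 1e-9)
})
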