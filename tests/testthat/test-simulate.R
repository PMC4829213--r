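reg <- scenario_registry()

sim_one <- function(scenario, seed, ...) {
  cfg <- if (is.character(scenario)) reg[[scenario]] else scenario
  g <- make_cell_geometry(cfg, seed)
  simulate_trafficking(g, cfg, seed + 1, ...)
}

test_that("without an export element no particle ever leaves the nucleus", {
  h <- sim_one("dEE", 3, t_end_h = 24)
  expect_true(all(h$counts$cytoplasmic == 0))
  expect_true(all(h$counts$mt_bound == 0))
  expect_true(all(h$counts$mtoc == 0))
  expect_true(all(h$frames$compartment == "nuclear"))
})

test_that("particle counts are conserved exactly at every frame", {
  for (sc in c("RRE_Rev", "4xCTE", "MPMV", "dEE")) {
    for (seed in c(5, 6)) {
      h <- sim_one(sc, seed, t_end_h = 24)
      tot <- h$counts$nuclear + h$counts$cytoplasmic + h$counts$mt_bound +
        h$counts$mtoc + h$counts$degraded
      expect_identical(tot, h$counts$born)
    }
  }
})

test_that("burst cells build past the threshold then evacuate >90% of the peak", {
  cfg <- scenario_config("b", "burst", penetrance = 1, burst_penetrance = 1)
  found <- FALSE
  for (seed in 11:14) {
    # sample finely enough to resolve the armed threshold plateau and the
    # sub-hour evacuation
    h <- sim_one(cfg, seed, t_end_h = 30,
                 sample_times_h = seq(0, 30, by = 0.1))
    if (h$drawn$class != "burst") next
    found <- TRUE
    nuc <- h$counts$nuclear
    pk <- max(nuc)
    expect_gte(pk, cfg$burst_threshold)
    # nuclear count falls below 10% of its peak within the burst duration
    # (plus the arming delay) of the threshold crossing
    after <- h$counts$t_h >= h$drawn$burst_time + 0.25 +
      cfg$burst_duration + 0.1
    expect_true(all(nuc[after] < 0.1 * pk))
    # the threshold is crossed before the peak frame
    expect_lte(min(which(nuc >= cfg$burst_threshold)), which.max(nuc))
  }
  expect_true(found)
})

test_that("nocodazole abolishes MTOC occupancy and arrests transcripts at the envelope", {
  cfg_on <- scenario_config("cte", "cte_mtoc", penetrance = 1)
  cfg_noc <- scenario_config("cte_noc", "cte_mtoc", penetrance = 1,
                             nocodazole = TRUE)
  h_on <- sim_one(cfg_on, 21, t_end_h = 24)
  h_noc <- sim_one(cfg_noc, 21, t_end_h = 24)
  expect_gt(h_on$counts$mtoc[nrow(h_on$counts)], 0)
  expect_true(all(h_noc$counts$mtoc == 0))
  expect_true(all(h_noc$counts$mt_bound == 0))
  # arrested particles sit within 2 um of the nuclear envelope
  last <- h_noc$frames[h_noc$frames$frame == max(h_noc$frames$frame) &
                         h_noc$frames$compartment == "cytoplasmic", ]
  g <- h_noc$geometry
  dn <- sqrt((last$x_um - g$nucleus$center[1])^2 +
               (last$y_um - g$nucleus$center[2])^2)
  er <- vapply(atan2(last$y_um - g$nucleus$center[2],
                     last$x_um - g$nucleus$center[1]),
               function(a) retroflux:::ellipse_radius_at(g$nucleus, a), 0)
  expect_true(mean(dn - er <= 2.1) > 0.95)
})

test_that("recorded compartment sequences use only the legal transition edges", {
  h <- sim_one("4xCTE", 31, t_end_h = 24)
  legal <- list(nuclear = c("nuclear", "cytoplasmic"),
                cytoplasmic = c("cytoplasmic", "mt_bound"),
                mt_bound = c("mt_bound", "mtoc"),
                mtoc = c("mtoc", "cytoplasmic"))
  fr <- h$frames[order(h$frames$particle_id, h$frames$frame), ]
  prev <- head(fr, -1); nxt <- tail(fr, -1)
  same <- prev$particle_id == nxt$particle_id
  ok <- mapply(function(a, b) b %in% legal[[a]],
               prev$compartment[same], nxt$compartment[same])
  expect_true(all(ok))
})

test_that("the same seed reproduces the history bit for bit", {
  h1 <- sim_one("RRE_Rev", 41, t_end_h = 12)
  h2 <- sim_one("RRE_Rev", 41, t_end_h = 12)
  expect_identical(h1$frames, h2$frames)
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$pool, h2$pool)
})

test_that("zero penetrance reduces every program to the no-phenotype control", {
  for (mode in c("burst", "gradual")) {
    cfg <- scenario_config("p0", mode, penetrance = 0, burst_penetrance = 0)
    for (seed in 51:56) {
      h <- sim_one(cfg, seed, t_end_h = 18)
      expect_identical(h$drawn$class, "none")
      expect_true(all(h$counts$cytoplasmic == 0))
    }
  }
})

test_that("cytoplasmic MSD grows linearly with slope 4*D_cyt", {
  # fast-mode ground truth of freely diffusing exported transcripts
  cfg <- scenario_config("diff", "gradual", penetrance = 1, D_cyt = 0.5,
                         ms2_saturation = 30)
  xs <- list(); ys <- list()
  for (seed in 61:64) {
    g <- make_cell_geometry(cfg, seed)
    h <- simulate_trafficking(g, cfg, seed + 1, mode = "fast",
                              fast_start_h = 24, fast_span_s = 14,
                              fast_interval_s = 0.7)
    fr <- h$frames[h$frames$compartment == "cytoplasmic", ]
    wide_x <- tapply(fr$x_um, list(fr$particle_id, fr$frame), identity)
    wide_y <- tapply(fr$y_um, list(fr$particle_id, fr$frame), identity)
    keep <- rowSums(!is.na(wide_x)) == ncol(wide_x)
    xs[[length(xs) + 1]] <- wide_x[keep, , drop = FALSE]
    ys[[length(ys) + 1]] <- wide_y[keep, , drop = FALSE]
  }
  X <- do.call(rbind, xs); Y <- do.call(rbind, ys)
  expect_gte(nrow(X), 200)
  lags <- 1:5
  msd <- vapply(lags, function(L) {
    dx <- X[, (1 + L):ncol(X)] - X[, 1:(ncol(X) - L)]
    dy <- Y[, (1 + L):ncol(Y)] - Y[, 1:(ncol(Y) - L)]
    mean(dx^2 + dy^2)
  }, 0)
  slope <- coef(lm(msd ~ I(lags * 0.7)))[2]
  expect_lt(abs(slope - 4 * cfg$D_cyt) / (4 * cfg$D_cyt), 0.10)
})

test_that("microtubule-bound particles advance along the track at the motor speed", {
  cfg <- scenario_config("cte", "cte_mtoc", penetrance = 1)
  g <- make_cell_geometry(cfg, 71)
  h <- simulate_trafficking(g, cfg, 72, mode = "fast", fast_start_h = 24,
                            fast_span_s = 10.5, fast_interval_s = 0.35)
  fr <- h$frames[order(h$frames$particle_id, h$frames$frame), ]
  prev <- head(fr, -1); nxt <- tail(fr, -1)
  ok <- prev$particle_id == nxt$particle_id &
    prev$compartment == "mt_bound" & nxt$compartment == "mt_bound" &
    !is.na(prev$mt_dir) & !is.na(nxt$mt_dir) & prev$mt_dir == nxt$mt_dir
  d <- sqrt((nxt$x_um[ok] - prev$x_um[ok])^2 +
              (nxt$y_um[ok] - prev$y_um[ok])^2)
  expect_gte(length(d), 50)
  expect_lt(abs(mean(d) - cfg$mt_speed * 0.35) / (cfg$mt_speed * 0.35), 0.05)
})

test_that("reporters: no substrate means no Gag; linear accumulation otherwise", {
  h <- sim_one("dEE", 81, t_end_h = 12)
  cfg <- reg$dEE
  h <- simulate_reporters(h, cfg, 82)
  expect_true(all(h$reporters$gag_cytoplasm == 0))
  expect_true(all(h$reporters$gag_membrane_punctae == 0))

  # constant 10 cytoplasmic particles at k_translate = 2 for 3 h -> 60 units
  fake <- h
  fake$counts$cytoplasmic <- 10L
  fake$counts$mt_bound <- 0L
  fake$counts$mtoc <- 0L
  cfg2 <- scenario_config("k", "none", k_translate = 2)
  fake <- simulate_reporters(fake, cfg2, 83)
  row3h <- which(abs(fake$reporters$t_h - 3) < 1e-9)
  expect_equal(fake$reporters$gag_cytoplasm[row3h], 60)
})

test_that("VLP onsets never precede the minimum and sites never decrease", {
  cfg <- scenario_config("v", "cte_mtoc", penetrance = 1,
                         rev_onset_mean = NA_real_,
                         vlp_onset_mean = 16.7, vlp_onset_sd = 8.06,
                         vlp_onset_min = 5)
  for (seed in 91:100) {
    h <- sim_one(cfg, seed, t_end_h = 36)
    h <- simulate_reporters(h, cfg, seed + 200)
    if (!is.na(h$drawn$vlp_onset)) expect_gte(h$drawn$vlp_onset, 5)
    x <- h$reporters$gag_membrane_punctae
    expect_true(all(diff(x) >= 0))
    if (any(x > 0))
      expect_gte(min(h$reporters$t_h[x > 0]), h$drawn$vlp_onset)
  }
})

test_that("the free MS2 pool ledger is non-negative and balances", {
  h <- sim_one("RRE_Rev", 111, t_end_h = 24)
  p <- h$pool
  expect_true(all(p$free >= -1e-9))
  expect_true(all(p$B_n >= -1e-9))
  expect_true(all(abs(p$free + p$B_n + p$U - reg$RRE_Rev$ms2_pool) < 1e-6))
  expect_true(all(diff(p$U) >= -1e-9))  # coats never return once exported
})
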