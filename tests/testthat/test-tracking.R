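test_that("two stationary distant spots give two full-length tracks", {
  frames <- replicate(20, data.frame(x_um = c(5, 15), y_um = c(5, 5)),
                      simplify = FALSE)
  tr <- link_tracks(frames, max_disp_um = 1.5, dt_s = 0.7)
  expect_length(tr, 2)
  expect_true(all(vapply(tr, nrow, 0L) == 20))
})

test_that("a single-frame disappearance is bridged by gap closing", {
  frames <- replicate(10, data.frame(x_um = 5, y_um = 5), simplify = FALSE)
  empty <- data.frame(x_um = numeric(), y_um = numeric())
  frames[[5]] <- empty
  tr <- link_tracks(frames, max_disp_um = 1.5, max_gap_frames = 1, dt_s = 0.7)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 9)
  # a two-frame gap exceeds the default and starts a new track
  frames[[6]] <- empty
  tr2 <- link_tracks(frames, max_disp_um = 1.5, max_gap_frames = 1, dt_s = 0.7)
  expect_length(tr2, 2)
})

test_that("greedy linking matches brute-force optimal assignment almost always", {
  # brute force: enumerate every injective partial assignment within the
  # gating radius; the optimum maximizes the number of links and, among
  # those, minimizes the total linked distance
  brute_optimal <- function(a, b, max_d) {
    na <- nrow(a); nb <- nrow(b)
    d <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
    best <- list(links = -1L, cost = Inf)
    rec <- function(i, used_b, links, cost) {
      if (i > na) {
        if (links > best$links ||
            (links == best$links && cost < best$cost))
          best <<- list(links = links, cost = cost)
        return(invisible())
      }
      rec(i + 1L, used_b, links, cost)       # leave spot i unlinked
      for (j in seq_len(nb)) {
        if (!used_b[j] && d[i, j] <= max_d) {
          used_b[j] <- TRUE
          rec(i + 1L, used_b, links + 1L, cost + d[i, j])
          used_b[j] <- FALSE
        }
      }
    }
    rec(1L, rep(FALSE, nb), 0L, 0)
    best
  }
  greedy_result <- function(a, b, max_d) {
    tr <- link_tracks(list(a, b), max_disp_um = max_d, dt_s = 1)
    linked <- vapply(tr, nrow, 0L) == 2
    cost <- sum(vapply(tr[linked], function(t)
      sqrt(diff(t$x_um)^2 + diff(t$y_um)^2), 0))
    list(links = sum(linked), cost = cost)
  }
  # spot density and gating radius follow the fast-mode regime the linker
  # operates in (~1 spot per 35 um^2, 1.5 um gate); successive frames are
  # displaced positions of the same emitters plus appearances/losses
  set.seed(7)
  agree <- 0
  n_trials <- 300
  for (i in seq_len(n_trials)) {
    n1 <- sample(2:4, 1)
    a <- data.frame(x_um = runif(n1, 0, 12), y_um = runif(n1, 0, 12))
    keep <- runif(n1) < 0.85
    b <- data.frame(x_um = a$x_um[keep] + rnorm(sum(keep), 0, 0.5),
                    y_um = a$y_um[keep] + rnorm(sum(keep), 0, 0.5))
    if (runif(1) < 0.3)
      b <- rbind(b, data.frame(x_um = runif(1, 0, 12),
                               y_um = runif(1, 0, 12)))
    if (nrow(b) == 0) next
    g <- greedy_result(a, b, 1.5)
    o <- brute_optimal(a, b, 1.5)
    if (g$links == o$links && abs(g$cost - o$cost) < 1e-9) agree <- agree + 1
  }
  expect_gte(agree / n_trials, 0.95)
})

test_that("track speed averages per-step displacements above the noise floor", {
  n <- 10
  tr <- data.frame(frame = 1:n, t_s = (0:(n - 1)) * 0.7,
                   x_um = (0:(n - 1)) * 0.42, y_um = 0)
  sp <- track_speed(tr)
  expect_equal(sp$speed_um_s, 0.6)
  expect_false(sp$stationary)

  still <- data.frame(frame = 1:n, t_s = (0:(n - 1)) * 0.7,
                      x_um = rep(1, n), y_um = rep(2, n))
  sps <- track_speed(still)
  expect_equal(sps$speed_um_s, 0)
  expect_true(sps$stationary)
  expect_error(track_speed(tr[1:3, ]), "5 points")
})

test_that("speed is invariant to track reversal and rigid rotation", {
  tr <- ballistic_track(30, seed = 8)
  s0 <- track_speed(tr)$speed_um_s
  rev <- tr; rev$x_um <- rev(tr$x_um); rev$y_um <- rev(tr$y_um)
  expect_equal(track_speed(rev)$speed_um_s, s0)
  th <- 1.1
  rot <- tr
  rot$x_um <- tr$x_um * cos(th) - tr$y_um * sin(th)
  rot$y_um <- tr$x_um * sin(th) + tr$y_um * cos(th)
  expect_equal(track_speed(rot)$speed_um_s, s0, tolerance = 1e-9)
})

test_that("MSD exponents separate ballistic, Brownian and confined motion", {
  b <- classify_motion(ballistic_track(60, noise = 0.02, seed = 9))
  expect_identical(b$class, "directed")
  expect_gt(b$alpha, 1.7)

  rw <- classify_motion(brownian_track(1000, seed = 10))
  expect_identical(rw$class, "diffusive")
  expect_lt(abs(rw$alpha - 1), 0.2)

  set.seed(11)
  pin <- data.frame(frame = 1:60, t_s = (0:59) * 0.7,
                    x_um = rnorm(60, 0, 0.03), y_um = rnorm(60, 0, 0.03))
  expect_identical(classify_motion(pin)$class, "confined")

  frozen <- data.frame(frame = 1:20, t_s = (0:19) * 0.7,
                       x_um = rep(0, 20), y_um = rep(0, 20))
  expect_identical(classify_motion(frozen)$class, "confined")
})

test_that("MT transport yields more directed tracks than free diffusion", {
  tr_cte <- cohort_tracking(scenario_registry()[["4xCTE"]], n_cells = 2,
                            seed = 3, min_tracks = 5, max_cells = 4)
  cfg_diff <- scenario_config("diff", "gradual", penetrance = 1)
  tr_diff <- cohort_tracking(cfg_diff, n_cells = 2, seed = 3,
                             min_tracks = 0, max_cells = 2)
  frac <- function(tr) {
    cl <- tr$summary$class
    if (!length(cl)) return(0)
    mean(cl == "directed", na.rm = TRUE)
  }
  expect_gt(frac(tr_cte), frac(tr_diff))
})
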