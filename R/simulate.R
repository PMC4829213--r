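# Agent-based simulator of single-cell gRNA trafficking.
#
# Two integration regimes share one generative model:
#  * long mode (frames minutes to hours apart): compartment dynamics advance
#    once per recorded frame through the legal transition graph
#    nuclear -> cytoplasmic <-> mt_bound -> mtoc -> cytoplasmic, and free
#    diffusion is sampled from its exact between-frame equilibrium (uniform
#    within the compartment), because 4*D*dt far exceeds the squared cell
#    size at these cadences;
#  * fast mode (sub-second frames): positions are integrated at
#    dt = min(10 s, frame_interval/2) with explicit diffusion, microtubule
#    run-and-reverse transport, MTOC capture/dwell and release.
#
# MS2-YFP pool bookkeeping (equilibrium-redistribution model): the nuclear
# pool binds nuclear transcripts up to their coat capacity, redistributing
# as transcription proceeds; coats travel with a transcript on export and
# never return. Under the Rev program a burst transfers the entire
# remaining pool (bound and free) to the cytoplasm at once, where most of
# it is free (diffuse); CTE transcripts carry only their bound coats, which
# stay transcript-associated in the cytoplasm.

LONG_MODE_GAP_S <- 60          # frame gaps above this use equilibrium sampling
ATTACH_PROB_LONG <- 0.9        # cyt -> mt_bound per recorded long-mode frame
REV_RISE_TAU_H <- 3            # Rev-mCherry saturating rise time constant
REV_LAG_H <- 0.25              # lag from Rev detection to export competence
POST_BURST_RESIDENCE_H <- 0.1  # nuclear dwell of transcripts born post-burst
BURST_ARM_H <- 0.25            # delay from threshold crossing to evacuation
                               # (export-complex assembly); the nuclear count
                               # sits at the threshold during this window
VLP_SITE_RATE <- 4             # additional assembly sites per hour past onset
VLP_INIT_SITES <- 3L           # sites nucleating together at onset
CYT_BOUND_FRAC_REV <- 0.08     # cytoplasmic YFP displayed as spots, Rev program
CYT_BOUND_FRAC_CTE <- 1.0      # ... CTE program (coats stay transcript-bound)

cyt_bound_frac <- function(config) {
  if (config$export_mode == "cte_mtoc") CYT_BOUND_FRAC_CTE
  else CYT_BOUND_FRAC_REV
}


#' Simulate single-cell mRNA trafficking under a scenario
#'
#' Runs the agent-based transport model for one cell and returns the
#' ground-truth particle history: per-frame particle positions,
#' compartments and displayed YFP units, per-frame compartment counts, and
#' the MS2 pool ledger. Reporter traces are filled in by
#' [simulate_reporters()].
#'
#' The cell's hallmark phenotype is drawn from the scenario penetrance:
#' under the Rev/CRM1 program a penetrant cell redistributes its
#' transcripts to the cytoplasm either gradually — export is scheduled so
#' the measured cytoplasmic-to-nuclear YFP ratio rises linearly over a
#' per-cell window drawn from the scenario's transition distribution, then
#' plateaus — or as a threshold-triggered burst that transfers the entire
#' nuclear MS2-YFP content (transcript-bound and free) to the cytoplasm
#' within \code{burst_duration} once \code{burst_threshold} transcripts
#' have accumulated. Under the CTE/NXF1 program transcripts are exported
#' constitutively and, in penetrant cells, engage microtubules and cluster
#' at the MTOC; with nocodazole they arrest in a 2 um band at the nuclear
#' envelope.
#'
#' @param geometry a [make_cell_geometry()] result.
#' @param config a [scenario_config()].
#' @param rng_seed integer seed; identical seeds give identical histories.
#' @param sample_times_h frame times in hours. Defaults to
#'   \code{seq(0, t_end_h, by = 0.5)} in long mode and
#'   \code{fast_start_h + seq(0, fast_span_s, by = fast_interval_s)/3600}
#'   in fast mode.
#' @param mode \code{"long"} or \code{"fast"}.
#' @param t_end_h end of the long-mode observation, hours.
#' @param fast_start_h time at which a fast acquisition begins, hours.
#' @param fast_span_s,fast_interval_s span and cadence of the fast
#'   acquisition, seconds.
#' @param optics the [optics_config()] the movie will be rendered with;
#'   the gradual-export controller targets the measured-space C:N ratio,
#'   which depends on the renderer's calibration.
#' @return object of class \code{particle_history}: list with \code{frames}
#'   (frame, t_h, particle_id, x_um, y_um, compartment, yfp_units, mt_dir),
#'   \code{counts} (per-frame compartment counts and cumulative born),
#'   \code{pool} (per-frame MS2 ledger: exported units U, bound nuclear
#'   B_n, free nuclear, cytoplasmic diffuse units), \code{drawn} (per-cell
#'   ground truth), and config/geometry/seed provenance.
#' @export
simulate_trafficking <- function(geometry, config, rng_seed,
                                 sample_times_h = NULL,
                                 mode = c("long", "fast"),
                                 t_end_h = 36,
                                 fast_start_h = 24,
                                 fast_span_s = 49,
                                 fast_interval_s = 0.7,
                                 optics = optics_config()) {
  mode <- match.arg(mode)
  validate_scenario_config(config)
  if (config$export_mode == "cte_mtoc" && !config$nocodazole &&
      (is.null(geometry$mt_tracks) || length(geometry$mt_tracks) == 0))
    stop("configuration error in field 'mt_tracks': cte_mtoc export ",
         "requires a geometry with microtubule tracks", call. = FALSE)
  set.seed(as.integer(rng_seed))

  if (is.null(sample_times_h)) {
    sample_times_h <- if (mode == "long") {
      seq(0, t_end_h, by = 0.5)
    } else {
      fast_start_h + seq(0, fast_span_s, by = fast_interval_s) / 3600
    }
  }
  sample_times_h <- sort(sample_times_h)
  horizon <- max(sample_times_h)

  ## ---- per-cell phenotype draw ------------------------------------------
  u <- stats::runif(1)
  class <- switch(config$export_mode,
    none = "none",
    gradual = if (u < config$penetrance) "gradual" else "none",
    burst = if (u < config$burst_penetrance) "burst"
            else if (u < config$penetrance) "gradual" else "none",
    cte_mtoc = if (u < config$penetrance) "mtoc" else "cte_diffuse"
  )

  rev_onset <- if (!is.na(config$rev_onset_mean)) {
    rtruncnorm(1, config$rev_onset_mean, config$rev_onset_sd, lower = 0.5)
  } else NA_real_

  ## ---- transcription ----------------------------------------------------
  span <- max(0, horizon - config$tx_onset)
  n_born <- stats::rpois(1, config$k_tx * span)
  birth <- sort(stats::runif(n_born, config$tx_onset, horizon))

  ## ---- export schedule + pool ledger ------------------------------------
  book_times <- if (mode == "long") sample_times_h else
    unique(sort(c(seq(0, sample_times_h[1], by = 0.5), sample_times_h)))
  sched <- schedule_exports(geometry, config, class, book_times, birth,
                            rev_onset, optics)
  drawn <- c(list(class = sched$realized_class, rev_onset = rev_onset),
             sched$drawn)

  ## ---- frame-by-frame state ---------------------------------------------
  history <- if (mode == "long") {
    frames_long_mode(geometry, config, sched$realized_class, sample_times_h,
                     birth, sched)
  } else {
    frames_fast_mode(geometry, config, sched$realized_class, sample_times_h,
                     birth, sched, fast_interval_s)
  }

  out <- list(frames = history$frames, counts = history$counts,
              pool = sched$pool[match(round(sample_times_h, 9),
                                      round(sched$pool$t_h, 9)), ],
              reporters = NULL, sample_times_h = sample_times_h,
              drawn = drawn, n_born_total = n_born,
              config = config, geometry = geometry,
              seed = as.integer(rng_seed), mode = mode)
  class(out) <- "particle_history"
  out
}

#' @export
print.particle_history <- function(x, ...) {
  cat(sprintf("<particle_history> %s cell (%s), %d frames, %d transcripts\n",
              x$config$name, x$drawn$class, length(x$sample_times_h),
              x$n_born_total))
  invisible(x)
}

# measured-space YFP signal model shared by the renderer and the gradual
# controller. The renderer conserves photons within each compartment
# (punctae borrow their photons from the surrounding haze), so the
# expected per-pixel signal depends only on the exported unit total U:
#   nuc_px = (pool - U)/n_nuc_px + af ; cyt_px = U/n_cyt_px + af
yfp_signal_model <- function(U, pool, n_nuc_px, n_cyt_px, af) {
  nuc_px <- (pool - U) / n_nuc_px + af
  cyt_px <- U / n_cyt_px + af
  list(nuc_px = nuc_px, cyt_px = cyt_px, ratio = cyt_px / nuc_px)
}

# Sequential export scheduler and MS2 pool ledger over bookkeeping frames.
# Burst/CTE export times are drawn up front; gradual export is chosen per
# frame by a controller that drives the measured-space C:N ratio linearly
# to the drawn plateau over the drawn window.
schedule_exports <- function(geometry, config, class, times_h, birth,
                             rev_onset, optics) {
  n <- length(birth)
  pool <- config$ms2_pool
  cap <- pool / config$ms2_saturation
  phi <- cyt_bound_frac(config)
  ps2 <- optics$pixel_size^2
  n_nuc_px <- pi * geometry$nucleus$a * geometry$nucleus$b / ps2
  n_cyt_px <- (polygon_area(geometry$cell_boundary) -
                 pi * geometry$nucleus$a * geometry$nucleus$b) / ps2
  af <- optics$autofluor_level

  export_t <- rep(Inf, n)
  frozen <- rep(0, n)
  drawn <- list(transition_window = NA_real_, transition_start = NA_real_,
                burst_time = NA_real_, cn_plateau = NA_real_)
  realized <- class

  if (class == "burst") {
    thr <- config$burst_threshold
    if (n >= thr) {
      tb <- max(birth[thr], (rev_onset %||% 0) + REV_LAG_H, na.rm = TRUE)
      ev <- tb + BURST_ARM_H
      pre <- birth <= ev
      export_t[pre] <- ev + stats::runif(sum(pre), 0, config$burst_duration)
      export_t[!pre] <- pmax(birth[!pre], ev) +
        stats::rexp(sum(!pre), 1 / POST_BURST_RESIDENCE_H)
      drawn$burst_time <- tb
    } else {
      realized <- "none"
    }
  } else if (class == "gradual") {
    drawn$transition_window <-
      rtruncnorm(1, config$transition_duration_mean,
                 config$transition_duration_sd, lower = 0.25)
    drawn$transition_start <-
      if (!is.na(rev_onset)) rev_onset + REV_LAG_H else config$tx_onset + 1
    drawn$cn_plateau <- rtruncnorm(1, config$cn_plateau_mean,
                                   config$cn_plateau_sd, lower = 2.6)
  } else if (class %in% c("mtoc", "cte_diffuse")) {
    if (config$k_exp_max > 0)
      export_t <- birth + stats::rexp(n, config$k_exp_max)
  }

  # frame-sequential ledger
  nT <- length(times_h)
  U <- 0
  exported <- rep(FALSE, n)
  led <- data.frame(t_h = times_h, U = 0, B_n = 0, free = 0, share = 0,
                    diffuse = 0)
  burst_done <- FALSE
  for (k in seq_len(nT)) {
    t <- times_h[k]
    is_nuc <- birth <= t & !exported
    n_nuc <- sum(is_nuc)
    B_n <- min(pool - U, cap * n_nuc)
    share <- if (n_nuc > 0) B_n / n_nuc else 0

    m <- 0L
    if (realized == "gradual") {
      t0 <- drawn$transition_start; W <- drawn$transition_window
      if (t >= t0 && share > 0) {
        target <- drawn$cn_plateau * min(1, (t - t0) / W)
        f <- function(Ux) yfp_signal_model(Ux, pool, n_nuc_px, n_cyt_px,
                                           af)$ratio - target
        U_star <- if (f(0) >= 0) 0 else if (f(pool) <= 0) pool else
          stats::uniroot(f, c(0, pool), tol = 1)$root
        m <- max(0L, min(n_nuc, as.integer(round((U_star - U) / share))))
      }
      if (m > 0) {
        idx <- which(is_nuc)[seq_len(m)]   # FIFO by birth
        export_t[idx] <- t
        frozen[idx] <- share
        exported[idx] <- TRUE
        U <- U + m * share
      }
    } else {
      due <- which(is_nuc & export_t <= t)
      if (length(due)) {
        frozen[due] <- share
        exported[due] <- TRUE
        U <- U + length(due) * share
      }
      if (realized == "burst" && !burst_done && !is.na(drawn$burst_time) &&
          t >= drawn$burst_time + BURST_ARM_H + config$burst_duration) {
        # the burst carries the whole remaining pool, free included
        U <- pool
        burst_done <- TRUE
      }
    }
    is_nuc <- birth <= t & !exported
    n_nuc <- sum(is_nuc)
    B_n <- min(pool - U, cap * n_nuc)
    led$U[k] <- U
    led$B_n[k] <- B_n
    led$free[k] <- pool - U - B_n
    led$share[k] <- if (n_nuc > 0) B_n / n_nuc else 0
    led$diffuse[k] <- U - phi * sum(frozen[exported])
  }

  list(export_t = export_t, frozen = frozen, pool = led,
       realized_class = realized, drawn = drawn, phi = phi)
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## ---- long mode -----------------------------------------------------------

frames_long_mode <- function(geometry, config, class, times_h, birth, sched) {
  n <- length(birth)
  nT <- length(times_h)
  export_t <- sched$export_t
  use_chain <- class == "mtoc" && !config$nocodazole
  ring <- class == "mtoc" && config$nocodazole
  # Markov chain over {1 cyt, 2 mt_bound, 3 mtoc} per recorded frame;
  # stationary MTOC occupancy equals config$mtoc_occupancy.
  om <- config$mtoc_occupancy
  a <- ATTACH_PROB_LONG
  cc <- if (om > 0) min(1, (1 - om) / (om * (1 + 1 / a))) else 1
  pi_stat <- c(cyt = om * cc / a, mt = om * cc, mtoc = om)
  pi_stat <- pi_stat / sum(pi_stat)

  state <- integer(n)            # 0 unborn/nuclear, 1 cyt, 2 mt, 3 mtoc
  frames <- vector("list", nT)
  counts <- matrix(0L, nT, 5,
                   dimnames = list(NULL, c("nuclear", "cytoplasmic",
                                           "mt_bound", "mtoc", "degraded")))
  born_cum <- integer(nT)
  ray_angles <- vapply(geometry$mt_tracks, function(tr)
    atan2(tr[2, 2] - tr[1, 2], tr[2, 1] - tr[1, 1]), 0)
  ray_len <- vapply(geometry$mt_tracks, function(tr)
    sqrt(sum((tr[2, ] - tr[1, ])^2)), 0)
  pool_row <- match(round(times_h, 9), round(sched$pool$t_h, 9))

  for (k in seq_len(nT)) {
    t <- times_h[k]
    alive <- birth <= t
    exported <- alive & export_t <= t
    if (use_chain) {
      # newly exported particles enter at the stationary law (they may have
      # cycled many times since export); existing ones advance one legal step
      newly <- exported & state == 0L
      if (any(newly))
        state[newly] <- sample.int(3, sum(newly), replace = TRUE,
                                   prob = pi_stat)
      adv <- exported & !newly
      if (any(adv)) {
        s <- state[adv]
        r <- stats::runif(length(s))
        s_new <- s
        s_new[s == 1 & r < a] <- 2L
        s_new[s == 2] <- 3L
        s_new[s == 3 & r < cc] <- 1L
        state[adv] <- s_new
      }
    } else {
      state[exported] <- 1L
    }

    ids <- which(alive)
    comp <- character(length(ids))
    xy <- matrix(NA_real_, length(ids), 2)
    mt_dir <- rep(NA_real_, length(ids))
    st <- ifelse(exported[ids], state[ids], 0L)
    share_k <- sched$pool$share[pool_row[k]]
    units <- ifelse(st == 0L, share_k, sched$phi * sched$frozen[ids])

    nuc_i <- st == 0L
    if (any(nuc_i)) {
      comp[nuc_i] <- "nuclear"
      xy[nuc_i, ] <- sample_in_nucleus(geometry, sum(nuc_i))
    }
    cyt_i <- st == 1L
    if (any(cyt_i)) {
      comp[cyt_i] <- "cytoplasmic"
      xy[cyt_i, ] <- if (ring) sample_envelope_ring(geometry, sum(cyt_i))
                     else sample_in_cytoplasm(geometry, sum(cyt_i))
    }
    mt_i <- st == 2L
    if (any(mt_i)) {
      comp[mt_i] <- "mt_bound"
      ri <- sample.int(length(ray_angles), sum(mt_i), replace = TRUE)
      dd <- stats::runif(sum(mt_i), config$mtoc_capture_radius,
                         pmax(config$mtoc_capture_radius + 0.5,
                              0.85 * ray_len[ri]))
      xy[mt_i, ] <- position_on_ray(geometry, ray_angles[ri], dd)
      mt_dir[mt_i] <- ifelse(stats::runif(sum(mt_i)) < 0.7, -1, 1)
    }
    mtoc_i <- st == 3L
    if (any(mtoc_i)) {
      comp[mtoc_i] <- "mtoc"
      xy[mtoc_i, ] <- sample_at_mtoc(geometry, sum(mtoc_i))
    }

    frames[[k]] <- data.frame(frame = rep(k, length(ids)),
                              t_h = rep(t, length(ids)), particle_id = ids,
                              x_um = xy[, 1], y_um = xy[, 2],
                              compartment = comp, yfp_units = units,
                              mt_dir = mt_dir)
    counts[k, ] <- c(sum(nuc_i), sum(cyt_i), sum(mt_i), sum(mtoc_i), 0L)
    born_cum[k] <- sum(alive)
  }
  finish_frames(frames, counts, born_cum, times_h)
}

## ---- fast mode -----------------------------------------------------------

frames_fast_mode <- function(geometry, config, class, times_h, birth, sched,
                             frame_interval_s) {
  dt_s <- min(10, frame_interval_s / 2)
  dt_h <- dt_s / 3600
  t0 <- times_h[1]
  nT <- length(times_h)
  n <- length(birth)
  export_t <- sched$export_t
  use_mt <- class == "mtoc" && !config$nocodazole
  ring <- class == "mtoc" && config$nocodazole
  om <- config$mtoc_occupancy

  ray_angles <- vapply(geometry$mt_tracks, function(tr)
    atan2(tr[2, 2] - tr[1, 2], tr[2, 1] - tr[1, 1]), 0)
  ray_len <- vapply(geometry$mt_tracks, function(tr)
    sqrt(sum((tr[2, ] - tr[1, ])^2)), 0)

  ## initial state at t0 from the long-run law
  state <- integer(n)                       # 0 nuclear, 1 cyt, 2 mt, 3 mtoc
  pos <- matrix(NA_real_, n, 2)
  ray <- rep(NA_integer_, n)
  rdist <- rep(NA_real_, n)
  rdir <- rep(NA_real_, n)
  dwell_left <- rep(NA_real_, n)

  alive0 <- birth <= t0
  exported0 <- alive0 & export_t <= t0
  state[exported0] <- 1L
  if (use_mt && any(exported0)) {
    p_mt <- min(0.15, om / 5)
    state[exported0] <- sample(1:3, sum(exported0), replace = TRUE,
                               prob = c(max(0, 1 - om - p_mt), p_mt, om))
  }
  nuc0 <- alive0 & state == 0L
  if (any(nuc0)) pos[nuc0, ] <- sample_in_nucleus(geometry, sum(nuc0))
  cyt0 <- state == 1L
  if (any(cyt0)) {
    pos[cyt0, ] <- if (ring) sample_envelope_ring(geometry, sum(cyt0))
                   else sample_in_cytoplasm(geometry, sum(cyt0))
  }
  mt0 <- which(state == 2L)
  if (length(mt0)) {
    ray[mt0] <- sample.int(length(ray_angles), length(mt0), replace = TRUE)
    rdist[mt0] <- stats::runif(length(mt0), config$mtoc_capture_radius + 1,
                               pmax(config$mtoc_capture_radius + 2,
                                    0.8 * ray_len[ray[mt0]]))
    rdir[mt0] <- ifelse(stats::runif(length(mt0)) < 0.7, -1, 1)
    pos[mt0, ] <- position_on_ray(geometry, ray_angles[ray[mt0]], rdist[mt0])
  }
  mtoc0 <- which(state == 3L)
  if (length(mtoc0)) {
    pos[mtoc0, ] <- sample_at_mtoc(geometry, length(mtoc0))
    dwell_left[mtoc0] <- stats::rexp(length(mtoc0), 1 / config$mtoc_dwell_mean)
  }

  step_sd_cyt <- sqrt(2 * config$D_cyt * dt_s)
  step_sd_nuc <- sqrt(2 * config$D_nuc * dt_s)
  p_runend <- 1 - exp(-config$mt_speed * dt_s / config$mt_run_length)

  frames <- vector("list", nT)
  counts <- matrix(0L, nT, 5,
                   dimnames = list(NULL, c("nuclear", "cytoplasmic",
                                           "mt_bound", "mtoc", "degraded")))
  born_cum <- integer(nT)
  # pool ledger row at (or just before) each fast frame
  pool_row <- findInterval(round(times_h, 9), round(sched$pool$t_h, 9))

  record <- function(k, t) {
    ids <- which(birth <= t)
    st <- state[ids]
    comp <- c("nuclear", "cytoplasmic", "mt_bound", "mtoc")[st + 1L]
    share_k <- sched$pool$share[max(1L, pool_row[k])]
    units <- ifelse(st == 0L, share_k, sched$phi * sched$frozen[ids])
    frames[[k]] <<- data.frame(frame = rep(k, length(ids)),
                               t_h = rep(t, length(ids)), particle_id = ids,
                               x_um = pos[ids, 1], y_um = pos[ids, 2],
                               compartment = comp, yfp_units = units,
                               mt_dir = rdir[ids])
    counts[k, ] <<- c(sum(st == 0L), sum(st == 1L), sum(st == 2L),
                      sum(st == 3L), 0L)
    born_cum[k] <<- length(ids)
  }
  record(1L, t0)

  t_now <- t0
  for (k in 2:nT) {
    while (t_now < times_h[k] - 1e-12) {
      step_h <- min(dt_h, times_h[k] - t_now)
      sc <- step_h / dt_h   # fractional last step within a frame gap
      t_now <- t_now + step_h

      # births and exports crossing this step
      newly_exported <- which(state == 0L & birth <= t_now &
                                export_t <= t_now)
      if (length(newly_exported)) {
        state[newly_exported] <- 1L
        # exit at the nuclear envelope nearest the current position
        for (i in newly_exported) {
          ang <- atan2(pos[i, 2] - geometry$nucleus$center[2],
                       pos[i, 1] - geometry$nucleus$center[1])
          er <- ellipse_radius_at(geometry$nucleus, ang) + 0.3
          pos[i, ] <- geometry$nucleus$center + er * c(cos(ang), sin(ang))
        }
      }
      born_nuc <- which(birth <= t_now & state == 0L & is.na(pos[, 1]))
      if (length(born_nuc))
        pos[born_nuc, ] <- sample_in_nucleus(geometry, length(born_nuc))

      # nuclear diffusion
      nuc_i <- which(state == 0L & birth <= t_now)
      if (length(nuc_i))
        pos[nuc_i, ] <- reflect_step(pos[nuc_i, , drop = FALSE],
                                     step_sd_nuc * sqrt(sc), geometry,
                                     region = "nucleus")
      # cytoplasmic diffusion (+ possible MT attachment)
      cyt_i <- which(state == 1L)
      if (length(cyt_i)) {
        if (ring) {
          pos[cyt_i, ] <- sample_envelope_ring(geometry, length(cyt_i))
        } else {
          pos[cyt_i, ] <- reflect_step(pos[cyt_i, , drop = FALSE],
                                       step_sd_cyt * sqrt(sc), geometry,
                                       region = "cytoplasm")
          if (use_mt) {
            att <- cyt_i[stats::runif(length(cyt_i)) <
                           config$mt_attach_prob * sc]
            if (length(att)) {
              dx <- pos[att, 1] - geometry$centrosome[1]
              dy <- pos[att, 2] - geometry$centrosome[2]
              pang <- atan2(dy, dx)
              ray[att] <- vapply(pang, function(a)
                which.min(abs(((ray_angles - a + pi) %% (2 * pi)) - pi)), 1L)
              rdist[att] <- pmin(sqrt(dx^2 + dy^2), ray_len[ray[att]] - 0.1)
              rdir[att] <- -1          # dynein-loaded: first run is minus-end
              state[att] <- 2L
              pos[att, ] <- position_on_ray(geometry, ray_angles[ray[att]],
                                            rdist[att])
            }
          }
        }
      }
      # microtubule transport: run, possibly reverse at a run end, capture
      mt_i <- which(state == 2L)
      if (length(mt_i)) {
        rdist[mt_i] <- rdist[mt_i] + rdir[mt_i] * config$mt_speed * dt_s * sc
        ends <- stats::runif(length(mt_i)) < p_runend * sc
        if (any(ends)) {
          rev_i <- mt_i[ends][stats::runif(sum(ends)) < 0.3]
          rdir[rev_i] <- -rdir[rev_i]
        }
        cap <- mt_i[rdist[mt_i] <= config$mtoc_capture_radius]
        if (length(cap)) {
          state[cap] <- 3L
          pos[cap, ] <- sample_at_mtoc(geometry, length(cap), sigma = 0.4)
          dwell_left[cap] <- stats::rexp(length(cap),
                                         1 / config$mtoc_dwell_mean)
        }
        run_i <- setdiff(mt_i, cap)
        off <- run_i[rdist[run_i] >= ray_len[ray[run_i]]]
        if (length(off)) {           # reached the plus end: unbind
          state[off] <- 1L
          pos[off, ] <- position_on_ray(geometry, ray_angles[ray[off]],
                                        ray_len[ray[off]] - 0.1)
        }
        keep <- setdiff(run_i, off)
        if (length(keep))
          pos[keep, ] <- position_on_ray(geometry, ray_angles[ray[keep]],
                                         rdist[keep])
      }
      # MTOC dwell and release
      mtoc_i <- which(state == 3L)
      if (length(mtoc_i)) {
        dwell_left[mtoc_i] <- dwell_left[mtoc_i] - dt_s * sc
        rel <- mtoc_i[dwell_left[mtoc_i] <= 0]
        if (length(rel)) state[rel] <- 1L
      }
    }
    record(k, times_h[k])
  }
  finish_frames(frames, counts, born_cum, times_h)
}

# one diffusion step with rejection of moves leaving the region
reflect_step <- function(p, sd, geometry, region = c("cytoplasm", "nucleus")) {
  region <- match.arg(region)
  if (sd == 0 || nrow(p) == 0) return(p)
  inside <- function(x, y) {
    if (region == "nucleus") in_nucleus(geometry, x, y)
    else in_cell(geometry, x, y) & !in_nucleus(geometry, x, y)
  }
  cand <- p + matrix(stats::rnorm(2 * nrow(p), 0, sd), ncol = 2)
  bad <- !inside(cand[, 1], cand[, 2])
  tries <- 0
  while (any(bad) && tries < 5) {
    m <- sum(bad)
    cand[bad, ] <- p[bad, , drop = FALSE] +
      matrix(stats::rnorm(2 * m, 0, sd), ncol = 2)
    bad <- !inside(cand[, 1], cand[, 2])
    tries <- tries + 1
  }
  cand[bad, ] <- p[bad, , drop = FALSE]
  cand
}

finish_frames <- function(frames, counts, born_cum, times_h) {
  fr <- do.call(rbind, frames)
  cdf <- data.frame(frame = seq_along(times_h), t_h = times_h, counts,
                    born = born_cum)
  list(frames = fr, counts = cdf)
}

#' Fill in reporter traces for a simulated cell
#'
#' Computes the per-frame reporter ground truth on top of a particle
#' history: the Rev-mCherry level (zero before the per-cell onset, then a
#' saturating rise), cytoplasmic Gag (accumulating at \code{k_translate}
#' units per cytoplasmic transcript per hour), the membrane VLP punctae
#' count (zero before the per-cell VLP onset drawn from the scenario's
#' measured-space onset distribution, then non-decreasing; several assembly
#' sites nucleate together at onset), and the free nuclear MS2-YFP pool.
#'
#' @param history a [simulate_trafficking()] result.
#' @param config the scenario used to generate it.
#' @param rng_seed integer seed for the reporter draws.
#' @return the history with \code{reporters} (data frame: t_h, rev_level,
#'   gag_cytoplasm, gag_membrane_punctae, free_ms2_nuclear) and
#'   \code{vlp_sites} (per-site appearance times and positions) filled in.
#' @export
simulate_reporters <- function(history, config, rng_seed) {
  stopifnot(inherits(history, "particle_history"))
  set.seed(as.integer(rng_seed))
  tt <- history$counts$t_h
  n_cyt <- history$counts$cytoplasmic + history$counts$mt_bound +
    history$counts$mtoc

  rev_onset <- history$drawn$rev_onset
  rev_level <- if (is.na(rev_onset)) rep(0, length(tt)) else {
    ifelse(tt < rev_onset, 0, 1 - exp(-(tt - rev_onset) / REV_RISE_TAU_H))
  }

  # cumulative trapezoid of k_translate * n_cyt over time
  gag <- c(0, cumsum(diff(tt) * config$k_translate *
                       (utils::head(n_cyt, -1) + utils::tail(n_cyt, -1)) / 2))

  exports_any <- any(n_cyt > 0)
  vlp_onset <- NA_real_
  n_sites <- integer(length(tt))
  vlp_sites <- NULL
  if (!is.na(config$vlp_onset_mean) && exports_any) {
    base <- truncnorm_match(config$vlp_onset_mean, config$vlp_onset_sd,
                            lower = config$vlp_onset_min)
    vlp_onset <- rtruncnorm(1, base$mean, base$sd,
                            lower = config$vlp_onset_min)
    if (vlp_onset <= max(tt)) {
      n_sites <- ifelse(tt < vlp_onset, 0L,
                        VLP_INIT_SITES +
                          floor(VLP_SITE_RATE * (tt - vlp_onset)))
      n_max <- max(n_sites)
      ang <- stats::runif(n_max, 0, 2 * pi)
      rr <- cell_radius_at(history$geometry, ang) - 0.5
      appear <- vlp_onset +
        c(rep(0, min(VLP_INIT_SITES, n_max)),
          if (n_max > VLP_INIT_SITES)
            (seq_len(n_max - VLP_INIT_SITES)) / VLP_SITE_RATE)
      vlp_sites <- data.frame(
        site = seq_len(n_max),
        appear_t_h = appear[seq_len(n_max)],
        x_um = history$geometry$center[1] + rr * cos(ang),
        y_um = history$geometry$center[2] + rr * sin(ang))
    }
  }

  history$reporters <- data.frame(
    t_h = tt, rev_level = rev_level, gag_cytoplasm = gag,
    gag_membrane_punctae = n_sites,
    free_ms2_nuclear = history$pool$free)
  history$vlp_sites <- vlp_sites
  history$drawn$vlp_onset <- vlp_onset
  history
}
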