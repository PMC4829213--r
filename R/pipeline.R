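# Orchestration: run whole simulated experiments (cohorts of cells through
# simulate -> render -> measure -> analyze -> score, or the fast-mode
# tracking chain) and produce a deterministic report.

#' Configuration for a simulated experiment
#'
#' @param scenario name of a [scenario_registry()] preset, or a
#'   [scenario_config()] object.
#' @param n_cells cells per replicate.
#' @param n_replicates independent replicate batches.
#' @param seed master seed; every downstream draw derives from it.
#' @param mode \code{"long"} (30-min cadence kinetic imaging) or
#'   \code{"fast"} (700-ms cadence particle tracking).
#' @param t_end_h end of long-mode observation, hours.
#' @param analyses subset of \code{"endpoint"}, \code{"kinetics"},
#'   \code{"vlp"}, \code{"enrichment"}, \code{"tracking"}; defaults by mode.
#' @param optics an [optics_config()] or NULL for mode defaults.
#' @param out_dir optional directory for the JSON report and CSV tables.
#' @return validated \code{run_config} list.
#' @export
run_config <- function(scenario, n_cells = 30, n_replicates = 1, seed = 1,
                       mode = c("long", "fast"), t_end_h = 36,
                       analyses = NULL, optics = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(scenario)) {
    reg <- scenario_registry()
    if (!scenario %in% names(reg))
      stop("configuration error in field 'scenario': unknown scenario '",
           scenario, "'", call. = FALSE)
    scenario <- reg[[scenario]]
  }
  validate_scenario_config(scenario)
  if (n_cells < 1)
    stop("configuration error in field 'n_cells': need at least one cell",
         call. = FALSE)
  analyses <- analyses %||% if (mode == "fast") "tracking" else
    c("endpoint", "kinetics")
  structure(list(scenario = scenario, n_cells = as.integer(n_cells),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), mode = mode, t_end_h = t_end_h,
                 analyses = analyses,
                 optics = optics %||% optics_config(mode = mode),
                 out_dir = out_dir),
            class = "run_config")
}

# simulate + report one cell (long mode); renders only the channels and
# frames each analysis needs
simulate_cell_movie <- function(config, cell_seed, optics, channels,
                                frames = NULL, mode = "long",
                                t_end_h = 36, ...) {
  seeds <- derive_seeds(cell_seed, 4)
  geom <- make_cell_geometry(config, seeds[1],
                             field_um = optics$img_size * optics$pixel_size,
                             pixel_size = optics$pixel_size)
  hist <- simulate_trafficking(geom, config, seeds[2], mode = mode,
                               t_end_h = t_end_h, optics = optics, ...)
  hist <- simulate_reporters(hist, config, seeds[3])
  movie <- render_movie(hist, optics, seeds[4], frames = frames,
                        channels = channels)
  list(history = hist, movie = movie)
}

# per-cell regions of interest: segment the nucleus on a single rendered
# DNA frame and the cell on the first frame of the measured channel, as
# regions are drawn once for a stationary adherent cell
static_masks <- function(cm, optics, seed_extra = 91L) {
  dna_mv <- render_movie(cm$history, optics,
                         cm$movie$seed + seed_extra, frames = 1L,
                         channels = "DNA")
  nuc <- tryCatch(segment_nucleus(movie_frame(dna_mv, 1, "DNA")),
                  error = function(e) cm$movie$ground_truth$nucleus_mask)
  cell <- segment_cell(movie_frame(cm$movie, 1, cm$movie$channels[1]), nuc)
  compartment_masks(nuc, cell)
}

#' Run a full simulated experiment
#'
#' Executes the pipeline stages selected in the configuration for every
#' cell of every replicate and aggregates a report: subcellular
#' distribution fractions (with across-replicate SD), MTOC-targeting
#' fractions, export-class fractions with the mean gradual transition
#' duration, VLP onset statistics, punctae enrichment, and fast-mode speed
#' and motion-class summaries. The same configuration and seed always
#' produce an identical report.
#'
#' @param cfg a [run_config()].
#' @return report list (JSON-serializable); written to
#'   \code{cfg$out_dir/report.json} when an output directory is set.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  sc <- cfg$scenario
  report <- list(scenario = sc$name, seed = cfg$seed,
                 n_cells = cfg$n_cells, n_replicates = cfg$n_replicates,
                 mode = cfg$mode, t_end_h = cfg$t_end_h,
                 package_version =
                   as.character(utils::packageVersion("retroflux")))

  if (cfg$mode == "fast" || "tracking" %in% cfg$analyses) {
    tr <- cohort_tracking(sc, n_cells = cfg$n_cells, seed = cfg$seed,
                          optics = if (cfg$optics$mode == "fast") cfg$optics
                                   else optics_config(mode = "fast"))
    report$tracking <- tr[c("n_tracks", "n_directed", "mean_speed_directed",
                            "class_fractions")]
  }
  if ("endpoint" %in% cfg$analyses && cfg$mode == "long") {
    ep <- cohort_endpoint(sc, cfg$n_cells, cfg$n_replicates, cfg$seed,
                          cfg$t_end_h, cfg$optics)
    report$distribution <- ep$distribution
    report$mtoc <- ep$mtoc
  }
  if ("kinetics" %in% cfg$analyses && cfg$mode == "long") {
    ki <- cohort_kinetics(sc, cfg$n_cells, cfg$seed, cfg$t_end_h,
                          cfg$optics)
    report$kinetics <- ki$summary
  }
  if ("vlp" %in% cfg$analyses && cfg$mode == "long") {
    vl <- cohort_vlp(sc, cfg$n_cells, cfg$seed, cfg$t_end_h, cfg$optics)
    report$vlp <- vl$summary
  }
  if ("enrichment" %in% cfg$analyses && cfg$mode == "long") {
    en <- cohort_enrichment(sc, cfg$n_cells, cfg$seed, cfg$optics)
    report$enrichment <- en$summary
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Endpoint phenotype scoring for a simulated cohort
#'
#' Simulates \code{n_cells * n_replicates} cells, renders the final frame,
#' measures it, and scores the subcellular distribution
#' ([classify_distribution()]) and — for CTE scenarios — MTOC targeting
#' ([locate_centrosome()] + [mtoc_enrichment()]).
#'
#' @param config scenario; \code{n_cells}, \code{n_replicates} cohort
#'   shape; \code{seed} master seed; \code{t_end_h} endpoint; optics as in
#'   [optics_config()].
#' @return list with per-cell \code{calls} data frame and
#'   \code{distribution} / \code{mtoc} population summaries.
#' @export
cohort_endpoint <- function(config, n_cells, n_replicates = 1, seed = 1,
                            t_end_h = 36, optics = optics_config()) {
  total <- n_cells * n_replicates
  seeds <- derive_seeds(seed, total)
  score_mtoc <- config$export_mode == "cte_mtoc"
  channels <- c("YFP", "DNA", if (score_mtoc) "PCNT")
  sig_px <- optics$psf_sigma / optics$pixel_size
  sample_times <- seq(0, t_end_h, by = 0.5)
  rows <- vector("list", total)
  for (i in seq_len(total)) {
    cm <- simulate_cell_movie(config, seeds[i], optics, channels,
                              frames = length(sample_times),
                              t_end_h = t_end_h,
                              sample_times_h = sample_times)
    mv <- cm$movie
    meas <- measure_movie(mv, channels = "YFP")
    cls <- classify_distribution(meas$nuclear_mfi[1],
                                 meas$cytoplasmic_mfi[1])
    fold <- NA_real_; targeted <- NA
    if (score_mtoc) {
      dna <- movie_frame(mv, 1, "DNA")
      nuc <- tryCatch(segment_nucleus(dna),
                      error = function(e) mv$ground_truth$nucleus_mask)
      cell <- segment_cell(movie_frame(mv, 1, "YFP"), nuc)
      masks <- compartment_masks(nuc, cell)
      yfp <- movie_frame(mv, 1, "YFP")
      bg <- estimate_background(yfp, masks)
      # search the cell minus the nuclear interior: a juxtanuclear
      # centrosome often projects onto the segmented nucleus edge
      search_mask <- masks$cell &
        !EBImage::erode(masks$nucleus, EBImage::makeBrush(17L, "disc"))
      cs <- locate_centrosome(movie_frame(mv, 1, "PCNT"), search_mask,
                              sig_px)
      me <- mtoc_enrichment(yfp, cs, masks, bg, optics$pixel_size)
      fold <- me$fold; targeted <- me$targeted
    }
    rows[[i]] <- data.frame(cell = i,
                            replicate = ((i - 1) %/% n_cells) + 1L,
                            class = cls, mtoc_fold = fold,
                            mtoc_targeted = targeted,
                            true_class = cm$history$drawn$class)
  }
  calls <- do.call(rbind, rows)
  distribution <- population_summary(calls$class, calls$replicate)
  mtoc <- if (score_mtoc) {
    population_summary(ifelse(!is.na(calls$mtoc_targeted) &
                                calls$mtoc_targeted,
                              "targeted", "untargeted"),
                       calls$replicate)
  } else NULL
  list(calls = calls, distribution = distribution, mtoc = mtoc)
}

#' C:N kinetics for a simulated cohort
#'
#' Simulates cells, renders YFP + DNA over the whole observation, measures
#' the C:N ratio trace of every cell, and derives export classes and
#' gradual transition durations.
#'
#' @inheritParams cohort_endpoint
#' @return list with per-cell \code{traces}, \code{cells} (class/duration
#'   table including ground truth) and a \code{summary}.
#' @export
cohort_kinetics <- function(config, n_cells, seed = 1, t_end_h = 36,
                            optics = optics_config()) {
  seeds <- derive_seeds(seed, n_cells)
  rows <- vector("list", n_cells)
  traces <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cm <- simulate_cell_movie(config, seeds[i], optics, "YFP",
                              t_end_h = t_end_h)
    meas <- measure_movie(cm$movie, channels = "YFP",
                          masks = static_masks(cm, optics))
    tr <- cell_trace(meas)
    traces[[i]] <- tr
    rows[[i]] <- data.frame(
      cell = i, export_class = tr$export_class,
      transition_duration_h = tr$transition_duration %||% NA_real_,
      true_class = cm$history$drawn$class,
      true_window_h = cm$history$drawn$transition_window)
  }
  cells <- do.call(rbind, rows)
  grad <- cells$export_class == "gradual" &
    is.finite(cells$transition_duration_h)
  summary <- list(
    class_fractions = as.list(table(cells$export_class) / nrow(cells)),
    burst_fraction = mean(cells$export_class == "burst"),
    transition_duration_mean_h =
      if (any(grad)) mean(cells$transition_duration_h[grad]) else NA_real_,
    n_gradual = sum(grad))
  list(traces = traces, cells = cells, summary = summary)
}

#' VLP onset timing for a simulated cohort
#'
#' Simulates cells, renders CFP + DNA, counts membrane punctae in a 3-px
#' boundary band each frame, and applies [vlp_onset()] per cell.
#'
#' @inheritParams cohort_endpoint
#' @return list with per-cell table and a summary (mean measured onset over
#'   cells with an onset, earliest onset, ground-truth mean).
#' @export
cohort_vlp <- function(config, n_cells, seed = 1, t_end_h = 36,
                       optics = optics_config()) {
  seeds <- derive_seeds(seed, n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cm <- simulate_cell_movie(config, seeds[i], optics, "CFP",
                              t_end_h = t_end_h)
    meas <- measure_movie(cm$movie, channels = "CFP", membrane = TRUE,
                          masks = static_masks(cm, optics))
    onset <- vlp_onset(meas$n_membrane_punctae, meas$t_h)
    rows[[i]] <- data.frame(cell = i, vlp_onset_h = onset,
                            true_onset_h =
                              cm$history$drawn$vlp_onset %||% NA_real_)
  }
  cells <- do.call(rbind, rows)
  det <- is.finite(cells$vlp_onset_h)
  list(cells = cells,
       summary = list(
         vlp_onset_mean_h = if (any(det)) mean(cells$vlp_onset_h[det])
                            else NA_real_,
         vlp_onset_min_h = if (any(det)) min(cells$vlp_onset_h[det])
                           else NA_real_,
         n_detected = sum(det),
         true_mean_h = mean(cells$true_onset_h[is.finite(cells$true_onset_h)])))
}

#' Nuclear punctae enrichment for a simulated cohort
#'
#' For each cell, renders early frames (transcripts still sparse), picks
#' the first frame with at least \code{min_spots} detected nuclear punctae
#' — the first frame where punctae are countable, matching how punctae are
#' quantified in practice — and records the fold-enrichment of every spot.
#'
#' @inheritParams cohort_endpoint
#' @param min_spots minimum punctae for a frame to be scored.
#' @return list with per-spot folds and a summary (grand mean, sd, n).
#' @export
cohort_enrichment <- function(config, n_cells, seed = 1,
                              optics = optics_config(), min_spots = 3) {
  seeds <- derive_seeds(seed, n_cells)
  sig_px <- optics$psf_sigma / optics$pixel_size
  sample_times <- seq(0, config$tx_onset + 4, by = 0.5)
  early <- which(sample_times > config$tx_onset)
  folds <- list()
  for (i in seq_len(n_cells)) {
    cm <- simulate_cell_movie(config, seeds[i], optics, c("YFP", "DNA"),
                              frames = early,
                              sample_times_h = sample_times,
                              t_end_h = max(sample_times))
    mv <- cm$movie
    for (fi in seq_along(early)) {
      dna <- movie_frame(mv, fi, "DNA")
      nuc <- tryCatch(segment_nucleus(dna),
                      error = function(e) mv$ground_truth$nucleus_mask)
      cell <- segment_cell(movie_frame(mv, fi, "YFP"), nuc)
      masks <- compartment_masks(nuc, cell)
      yfp <- movie_frame(mv, fi, "YFP")
      bg <- estimate_background(yfp, masks)
      sp <- detect_punctae(yfp, masks$nucleus, sig_px, background = bg)
      if (nrow(sp) >= min_spots) {
        en <- punctae_enrichment(sp, yfp, masks$nucleus, bg, sig_px)
        folds[[length(folds) + 1L]] <-
          data.frame(cell = i, frame = early[fi], n_spots = en$n,
                     fold = en$mean)
        break
      }
    }
  }
  per_frame <- do.call(rbind, folds)
  list(cells = per_frame,
       summary = list(
         enrichment_mean = stats::weighted.mean(per_frame$fold,
                                                per_frame$n_spots),
         n_spots = sum(per_frame$n_spots),
         n_cells_scored = nrow(per_frame)))
}

#' Fast-mode tracking for a simulated cohort
#'
#' Simulates fast acquisitions (700 ms cadence), tracks cytoplasmic YFP
#' spots, and summarizes directed-transport speed and motion classes.
#' Cells are added until \code{min_tracks} tracks of at least 5 points are
#' collected (up to \code{max_cells}).
#'
#' @inheritParams cohort_endpoint
#' @param min_tracks target number of usable tracks.
#' @param max_cells cap on simulated cells.
#' @param min_points_speed minimum track length entering the directed-speed
#'   pool. Short tracks give unstable MSD exponents, and free transcripts
#'   rarely stay linkable this long (large diffusive steps break links), so
#'   the long directed tracks isolate microtubule-bound transport.
#' @return list with the pooled track \code{summary} data frame,
#'   \code{n_tracks}, \code{n_directed}, \code{mean_speed_directed} and
#'   \code{class_fractions}.
#' @export
cohort_tracking <- function(config, n_cells = 10, seed = 1,
                            optics = optics_config(mode = "fast"),
                            min_tracks = 50, max_cells = 30,
                            min_points_speed = 25) {
  seeds <- derive_seeds(seed, max_cells)
  summaries <- list()
  n_pool <- 0   # directed tracks long enough for the speed pool
  i <- 0
  while (i < max_cells && (i < n_cells || n_pool < min_tracks)) {
    i <- i + 1
    cm <- simulate_cell_movie(config, seeds[i], optics, "YFP",
                              mode = "fast")
    tm <- track_movie(cm$movie)
    if (nrow(tm$summary)) {
      tm$summary$cell <- i
      summaries[[length(summaries) + 1L]] <- tm$summary
      n_pool <- n_pool + sum(!is.na(tm$summary$class) &
                               tm$summary$class == "directed" &
                               tm$summary$n_points >= min_points_speed)
    }
  }
  summ <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(mean_speed_um_s = numeric(), class = character())
  directed <- !is.na(summ$class) & summ$class == "directed" &
    !summ$stationary & summ$n_points >= min_points_speed
  classed <- summ$class[!is.na(summ$class)]
  list(summary = summ, n_tracks = nrow(summ),
       n_directed = sum(directed),
       mean_speed_directed = if (any(directed))
         mean(summ$mean_speed_um_s[directed]) else NA_real_,
       class_fractions = if (length(classed))
         as.list(table(classed) / length(classed)) else list(),
       n_cells_used = i)
}
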