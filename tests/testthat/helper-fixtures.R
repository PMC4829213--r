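# Shared fixtures: small simulated cells and rendered movies built in code.

fix_optics <- function(...) optics_config(...)

# one simulated cell with reporters, rendered on selected channels/frames
fix_cell <- function(scenario = "RRE_noRev", seed = 101, channels = c("YFP", "DNA"),
                     frames = NULL, t_end_h = 12, optics = fix_optics(),
                     sample_times_h = NULL, mode = "long", ...) {
  cfg <- if (is.character(scenario)) scenario_registry()[[scenario]]
         else scenario
  seeds <- retroflux:::derive_seeds(seed, 4)
  geom <- make_cell_geometry(cfg, seeds[1],
                             field_um = optics$img_size * optics$pixel_size,
                             pixel_size = optics$pixel_size)
  hist <- simulate_trafficking(geom, cfg, seeds[2], mode = mode,
                               t_end_h = t_end_h, optics = optics,
                               sample_times_h = sample_times_h, ...)
  hist <- simulate_reporters(hist, cfg, seeds[3])
  movie <- render_movie(hist, optics, seeds[4], frames = frames,
                        channels = channels)
  list(config = cfg, geometry = geom, history = hist, movie = movie,
       optics = optics)
}

frame_of <- function(movie, frame, channel) {
  retroflux:::movie_frame(movie, frame, channel)
}

# intersection-over-union of two logical masks
iou <- function(a, b) sum(a & b) / sum(a | b)

# synthetic track builders
ballistic_track <- function(n, v = 0.6, dt = 0.7, angle = 0.3, noise = 0.03,
                            seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) * dt
  data.frame(frame = seq_len(n), t_s = t,
             x_um = v * t * cos(angle) + rnorm(n, 0, noise),
             y_um = v * t * sin(angle) + rnorm(n, 0, noise))
}

brownian_track <- function(n, D = 0.3, dt = 0.7, seed = 1) {
  set.seed(seed)
  sd <- sqrt(2 * D * dt)
  data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) * dt,
             x_um = cumsum(c(0, rnorm(n - 1, 0, sd))),
             y_um = cumsum(c(0, rnorm(n - 1, 0, sd))))
}
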