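# Synthetic fluorescence microscopy rendering: ground-truth histories are
# turned into multichannel 16-bit time-lapse stacks with a Gaussian PSF,
# Poisson shot noise and Gaussian read noise.

DNA_FILL_PHOTONS <- 250      # Hoechst-like nucleus fill, photons/px
PCNT_PEAK_PHOTONS <- 800     # pericentrin-like centrosome spot peak
VLP_PEAK_PHOTONS <- 500      # membrane assembly-site spot peak
REV_TOTAL_PHOTONS <- 2e5     # whole-cell mCherry photons at full Rev level
CFP_GAIN <- 400              # photons per Gag unit (spread over cytoplasm)
MTOC_GAG_FRACTION <- 0.2     # share of Gag at the MTOC in the CTE program
MTOC_GAG_SIGMA_UM <- 1.5
MAX_VIS_PUNCTAE <- 8         # discrete nuclear punctae rendered (sparse regime)

#' Optics and acquisition configuration
#'
#' Describes the virtual microscope: sampling, PSF width, photon conversion,
#' camera noise and the acquisition cadence. Defaults emulate a 20x
#' wide-field acquisition (0.325 um pixels) of one adherent cell in a
#' 256x256 field.
#'
#' @param pixel_size um per pixel.
#' @param psf_sigma isotropic 2-D Gaussian PSF sigma, um.
#' @param photon_scale photons per fluorescence signal unit.
#' @param read_noise_sd camera read noise, counts.
#' @param background_level background, counts (Poisson-distributed).
#' @param autofluor_level flat cell-body autofluorescence, photons/px,
#'   added to the YFP/CFP/mCherry channels.
#' @param bit_depth camera bit depth (16).
#' @param frame_interval acquisition interval: minutes in long mode,
#'   seconds in fast mode.
#' @param mode \code{"long"} or \code{"fast"}.
#' @param channels ordered channel names to render.
#' @param img_size image side, pixels.
#' @param noiseless logical; TRUE renders expected photon counts without
#'   shot or read noise (used by calibration oracles and tests).
#' @return an \code{optics_config} list.
#' @export
optics_config <- function(pixel_size = 0.325, psf_sigma = 0.4,
                          photon_scale = 1, read_noise_sd = 3,
                          background_level = 100, autofluor_level = 80,
                          bit_depth = 16,
                          frame_interval = if (mode == "long") 30 else 0.7,
                          mode = c("long", "fast"),
                          channels = c("YFP", "CFP", "mCherry", "DNA", "PCNT"),
                          img_size = 256, noiseless = FALSE) {
  mode <- match.arg(mode)
  if (psf_sigma <= 0) stop("configuration error in field 'psf_sigma': must be > 0")
  if (pixel_size <= 0) stop("configuration error in field 'pixel_size': must be > 0")
  if (frame_interval <= 0)
    stop("configuration error in field 'frame_interval': must be > 0")
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 background_level = background_level,
                 autofluor_level = autofluor_level,
                 bit_depth = bit_depth, frame_interval = frame_interval,
                 mode = mode, channels = channels, img_size = img_size,
                 noiseless = noiseless),
            class = "optics_config")
}

#' Disk-mean gain of a rendered point source
#'
#' Brute-force calibration oracle for spot amplitudes: renders one
#' unit-peak Gaussian spot on the pixel grid and returns the mean intensity
#' within the measurement disk of radius \code{2 * psf_sigma} pixels. The
#' punctae-enrichment parameter is defined in measured space, so rendered
#' amplitudes are scaled by this factor rather than by a closed-form
#' approximation.
#'
#' @param optics an [optics_config()].
#' @return scalar disk-mean response to a unit-peak spot.
#' @export
spot_disk_gain <- function(optics) {
  s <- optics$psf_sigma / optics$pixel_size
  r <- 2 * s
  half <- as.integer(ceiling(r)) + 2L
  g <- expand.grid(dr = -half:half, dc = -half:half)
  keep <- g$dr^2 + g$dc^2 <= r^2
  # average over subpixel emitter positions: the measurement disk is
  # centred on the detected (integer-rounded) maximum while the emitter
  # sits anywhere within the central pixel
  offs <- seq(-0.4, 0.4, by = 0.2)
  mean(vapply(offs, function(ox) {
    mean(vapply(offs, function(oy) {
      val <- exp(-((g$dr - oy)^2 + (g$dc - ox)^2) / (2 * s^2))
      mean(val[keep])
    }, 0))
  }, 0))
}

# rasterize geometry into pixel masks on the optics grid
geometry_masks <- function(geometry, optics) {
  n <- optics$img_size
  ps <- optics$pixel_size
  ctr <- (seq_len(n) - 0.5) * ps
  xx <- matrix(ctr, n, n, byrow = TRUE)   # x = column
  yy <- matrix(ctr, n, n)                 # y = row
  nuc <- matrix(in_nucleus(geometry, as.vector(xx), as.vector(yy)), n, n)
  cell <- matrix(in_cell(geometry, as.vector(xx), as.vector(yy)), n, n)
  cell <- cell | nuc
  list(nucleus = nuc, cell = cell, cytoplasm = cell & !nuc)
}

um_to_px <- function(u, pixel_size) u / pixel_size - 0.5   # 0-based centers

# additively paint Gaussian spots (0-based subpixel centers) onto an image
add_spots <- function(img, x_px, y_px, peak, sigma_px) {
  if (length(x_px) == 0) return(img)
  half <- as.integer(ceiling(4 * sigma_px))
  n_r <- nrow(img); n_c <- ncol(img)
  for (i in seq_along(x_px)) {
    c0 <- as.integer(round(x_px[i])); r0 <- as.integer(round(y_px[i]))
    rs <- max(1L, r0 + 1L - half):min(n_r, r0 + 1L + half)
    cs <- max(1L, c0 + 1L - half):min(n_c, c0 + 1L + half)
    if (!length(rs) || !length(cs)) next
    dr <- (rs - 1L) - y_px[i]
    dc <- (cs - 1L) - x_px[i]
    patch <- outer(dr^2, dc^2, "+")
    img[rs, cs] <- img[rs, cs] + peak[i] * exp(-patch / (2 * sigma_px^2))
  }
  img
}

#' Render a simulated cell into a multichannel movie
#'
#' Converts a particle history (with reporters filled in) into a 16-bit
#' multichannel stack. Channel composition: \strong{YFP} = free nuclear
#' MS2-YFP pool spread over the nucleus plus one PSF-shaped spot per
#' coat-carrying transcript (amplitude calibrated so a single punctum over
#' a full nucleoplasm pool measures at the scenario's fold-enrichment);
#' \strong{CFP} = cytoplasmic Gag spread over the cytoplasm, membrane
#' assembly-site spots, and an MTOC accumulation term in the CTE program;
#' \strong{mCherry} = Rev level over the whole cell weighted 60/40
#' nucleus/cytoplasm; \strong{DNA} = nucleus fill; \strong{PCNT} = a
#' pericentrin-like centrosome marker spot. Expected photons are then
#' Poisson-sampled on top of the background and Gaussian read noise is
#' added (unless \code{optics$noiseless}).
#'
#' @param history a [simulate_trafficking()] result with reporters filled
#'   by [simulate_reporters()].
#' @param optics an [optics_config()].
#' @param rng_seed integer seed; same seed gives a bit-identical stack.
#' @param frames integer indices of history frames to render (default all).
#' @param channels channels to render (default \code{optics$channels}).
#' @param geometry the cell geometry (defaults to the one in the history).
#' @return object of class \code{movie}: list with \code{data} (integer
#'   array T x C x H x W), \code{channels}, \code{times_h}, \code{optics},
#'   \code{scenario}, \code{seed} and \code{ground_truth} (nucleus and cell
#'   masks, centrosome pixel, per-frame spot list).
#' @export
render_movie <- function(history, optics, rng_seed, frames = NULL,
                         channels = NULL, geometry = history$geometry) {
  stopifnot(inherits(history, "particle_history"))
  if (is.null(history$reporters))
    stop("history has no reporter traces; run simulate_reporters() first")
  set.seed(as.integer(rng_seed))
  channels <- channels %||% optics$channels
  frames <- frames %||% seq_along(history$sample_times_h)
  n <- optics$img_size
  ps <- optics$pixel_size
  sig_px <- optics$psf_sigma / ps
  masks <- geometry_masks(geometry, optics)
  n_nuc_px <- sum(masks$nucleus)
  n_cyt_px <- sum(masks$cytoplasm)
  cfg <- history$config

  # Nuclear punctae are calibrated in measured space: each rendered punctum
  # sits at the scenario's fold-enrichment over the *current* nucleoplasm
  # haze, and its photons are borrowed from the haze so the nuclear photon
  # total equals the nuclear pool exactly. At most MAX_VIS_PUNCTAE discrete
  # punctae are drawn (the sparse, countable regime); beyond that the
  # crowded 2-D projection merges into the haze.
  gain <- spot_disk_gain(optics)
  k_q <- (cfg$punctae_enrichment - 1) * 2 * pi * sig_px^2 / gain
  spot_peak_per_unit <- 1 / (2 * pi * sig_px^2)

  cs_px <- c(x = um_to_px(geometry$centrosome[1], ps),
             y = um_to_px(geometry$centrosome[2], ps))

  dat <- array(0L, dim = c(length(frames), length(channels), n, n))
  spot_records <- vector("list", length(frames))
  rep_tr <- history$reporters
  n_sat <- 0

  for (fi in seq_along(frames)) {
    k <- frames[fi]
    fr <- history$frames[history$frames$frame == k, , drop = FALSE]
    t_h <- history$sample_times_h[k]
    rrow <- which.min(abs(rep_tr$t_h - t_h))
    spots_f <- list()

    for (ci in seq_along(channels)) {
      ch <- channels[ci]
      img <- matrix(0, n, n)
      if (ch == "YFP") {
        nuc_units <- cfg$ms2_pool - history$pool$U[k]
        fr_nuc <- fr[fr$compartment == "nuclear", , drop = FALSE]
        n_vis <- min(nrow(fr_nuc), MAX_VIS_PUNCTAE)
        haze_px <- nuc_units / (n_nuc_px + n_vis * k_q)
        img[masks$nucleus] <- haze_px * optics$photon_scale
        if (n_vis > 0 && haze_px > 0) {
          vis <- fr_nuc[order(fr_nuc$particle_id)[seq_len(n_vis)], ,
                        drop = FALSE]
          xs <- um_to_px(vis$x_um, ps); ys <- um_to_px(vis$y_um, ps)
          pk <- rep((cfg$punctae_enrichment - 1) * haze_px / gain, n_vis) *
            optics$photon_scale
          img <- add_spots(img, xs, ys, pk, sig_px)
          spots_f[[length(spots_f) + 1L]] <- data.frame(
            frame = k, channel = "YFP", x_px = xs, y_px = ys, peak = pk,
            particle_id = vis$particle_id, compartment = vis$compartment)
        }
        img[masks$cytoplasm] <- history$pool$diffuse[k] *
          optics$photon_scale / n_cyt_px
        cyt <- fr[fr$compartment != "nuclear" & fr$yfp_units > 0, ,
                  drop = FALSE]
        if (nrow(cyt)) {
          xs <- um_to_px(cyt$x_um, ps); ys <- um_to_px(cyt$y_um, ps)
          pk <- spot_peak_per_unit * optics$photon_scale * cyt$yfp_units
          img <- add_spots(img, xs, ys, pk, sig_px)
          spots_f[[length(spots_f) + 1L]] <- data.frame(
            frame = k, channel = "YFP", x_px = xs, y_px = ys, peak = pk,
            particle_id = cyt$particle_id, compartment = cyt$compartment)
        }
        img[masks$cell] <- img[masks$cell] + optics$autofluor_level
      } else if (ch == "CFP") {
        gag <- rep_tr$gag_cytoplasm[rrow] * optics$photon_scale
        mtoc_term <- cfg$export_mode == "cte_mtoc" && !cfg$nocodazole
        spread <- if (mtoc_term) gag * (1 - MTOC_GAG_FRACTION) else gag
        img[masks$cytoplasm] <- spread * CFP_GAIN / n_cyt_px
        if (mtoc_term && gag > 0) {
          blob_sig <- MTOC_GAG_SIGMA_UM / ps
          blob_int <- gag * MTOC_GAG_FRACTION * CFP_GAIN
          img <- add_spots(img, cs_px["x"], cs_px["y"],
                           blob_int / (2 * pi * blob_sig^2), blob_sig)
        }
        if (!is.null(history$vlp_sites)) {
          vs <- history$vlp_sites[history$vlp_sites$appear_t_h <= t_h, ,
                                  drop = FALSE]
          if (nrow(vs)) {
            xs <- um_to_px(vs$x_um, ps); ys <- um_to_px(vs$y_um, ps)
            img <- add_spots(img, xs, ys,
                             rep(VLP_PEAK_PHOTONS * optics$photon_scale,
                                 nrow(vs)), sig_px)
            spots_f[[length(spots_f) + 1L]] <- data.frame(
              frame = k, channel = "CFP", x_px = xs, y_px = ys,
              peak = VLP_PEAK_PHOTONS, particle_id = NA_integer_,
              compartment = "membrane")
          }
        }
        img[masks$cell] <- img[masks$cell] + optics$autofluor_level
      } else if (ch == "mCherry") {
        lev <- rep_tr$rev_level[rrow] * REV_TOTAL_PHOTONS *
          optics$photon_scale
        img[masks$nucleus] <- 0.6 * lev / n_nuc_px
        img[masks$cytoplasm] <- 0.4 * lev / n_cyt_px
        img[masks$cell] <- img[masks$cell] + optics$autofluor_level
      } else if (ch == "DNA") {
        img[masks$nucleus] <- DNA_FILL_PHOTONS * optics$photon_scale
      } else if (ch == "PCNT") {
        img <- add_spots(img, cs_px["x"], cs_px["y"],
                         PCNT_PEAK_PHOTONS * optics$photon_scale, sig_px)
      }

      lambda <- img + optics$background_level
      counts <- if (optics$noiseless) lambda else {
        stats::rpois(length(lambda), lambda) +
          round(stats::rnorm(length(lambda), 0, optics$read_noise_sd))
      }
      maxc <- 2^optics$bit_depth - 1
      counts <- pmin(pmax(counts, 0), maxc)
      n_sat <- n_sat + sum(counts == maxc)
      dat[fi, ci, , ] <- as.integer(matrix(counts, n, n))
    }
    spot_records[[fi]] <- if (length(spots_f)) do.call(rbind, spots_f)
                          else NULL
  }
  if (n_sat > 0.01 * length(dat))
    warning(sprintf("saturation: %.1f%% of pixels at max count",
                    100 * n_sat / length(dat)))

  spot_df <- do.call(rbind, spot_records)
  mv <- list(data = dat, channels = channels,
             times_h = history$sample_times_h[frames],
             frame_index = frames, optics = optics,
             scenario = cfg$name, seed = as.integer(rng_seed),
             ground_truth = list(
               nucleus_mask = masks$nucleus, cell_mask = masks$cell,
               centrosome_px = cs_px,
               spots = spot_df))
  class(mv) <- "movie"
  mv
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie> %s: %d frames x %d channels (%s), %dx%d px\n",
              x$scenario, d[1], d[2], paste(x$channels, collapse = "/"),
              d[3], d[4]))
  invisible(x)
}

# convenience accessor: one frame of one channel as a matrix
movie_frame <- function(movie, frame, channel) {
  ci <- match(channel, movie$channels)
  if (is.na(ci)) stop("channel not rendered: ", channel)
  matrix(movie$data[frame, ci, , ], dim(movie$data)[3], dim(movie$data)[4])
}
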