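# Per-frame segmentation and intensity measurement. Segmentation replaces
# the hand-drawn regions of interest used in manual analysis with fixed,
# documented operators: Otsu for the DNA-stained nucleus, triangle
# threshold for the whole cell on a summed-channel image, an annulus median
# for background.

#' Segment the nucleus from a DNA-stain frame
#'
#' Gaussian smoothing (sigma 2 px), Otsu threshold, hole filling, then the
#' largest connected component.
#'
#' @param dna_frame numeric matrix (counts).
#' @param sigma smoothing sigma, px.
#' @param min_area minimum nucleus area, px.
#' @return logical mask matrix.
#' @export
segment_nucleus <- function(dna_frame, sigma = 2, min_area = 200) {
  mx <- max(dna_frame)
  if (mx <= 0) stop("no nucleus found", call. = FALSE)
  f <- EBImage::gblur(dna_frame / mx, sigma = sigma)
  thr <- EBImage::otsu(EBImage::Image(f), range = c(0, 1))
  mask <- f > thr
  if (!any(mask)) stop("no nucleus found", call. = FALSE)
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < min_area)
    stop("no nucleus found", call. = FALSE)
  lab == which.max(sizes)
}

#' Segment the whole cell from a summed-channel frame
#'
#' Triangle threshold on the smoothed summed-channel image, morphological
#' closing, then the connected component containing the nucleus (union with
#' the nucleus mask, which always lies inside the cell).
#'
#' @param channel_sum_frame numeric matrix, sum of the fluorescent channels.
#' @param nucleus_mask logical mask from [segment_nucleus()].
#' @param sigma smoothing sigma, px.
#' @return logical mask matrix containing the nucleus.
#' @export
segment_cell <- function(channel_sum_frame, nucleus_mask, sigma = 2) {
  f <- EBImage::gblur(channel_sum_frame, sigma = sigma)
  thr <- triangle_threshold(as.vector(f))
  mask <- f > thr
  mask <- EBImage::closing(mask, EBImage::makeBrush(5, "disc"))
  mask <- EBImage::fillHull(mask)
  # the triangle threshold catches the far tail of the blurred edge;
  # erode by the smoothing radius so the mask tracks the true boundary
  mask <- EBImage::erode(mask, EBImage::makeBrush(2 * ceiling(sigma) + 1,
                                                  "disc"))
  mask <- mask | nucleus_mask
  lab <- EBImage::bwlabel(mask)
  labs_in_nuc <- lab[nucleus_mask & lab > 0]
  if (!length(labs_in_nuc)) return(nucleus_mask)
  main <- as.integer(names(which.max(table(labs_in_nuc))))
  (lab == main) | nucleus_mask
}

#' Compartment masks for one cell
#'
#' Bundles the nucleus, cell, derived cytoplasm (cell minus nucleus) and a
#' background annulus (ring of \code{annulus_width} px outside the cell,
#' clipped to the image).
#'
#' @param nucleus,cell logical masks (nucleus must be inside cell).
#' @param annulus_width ring width, px.
#' @return object of class \code{compartment_masks}.
#' @export
compartment_masks <- function(nucleus, cell, annulus_width = 10) {
  if (any(nucleus & !cell))
    stop("mask invariant violated: nucleus not contained in cell")
  grown <- EBImage::dilate(cell,
                           EBImage::makeBrush(2L * annulus_width + 1L, "disc"))
  structure(list(nucleus = nucleus, cell = cell,
                 cytoplasm = cell & !nucleus,
                 background_annulus = grown & !cell),
            class = "compartment_masks")
}

#' Estimate background from the annulus
#'
#' Median intensity over the background annulus adjacent to the cell.
#'
#' @param frame numeric matrix.
#' @param masks a [compartment_masks()].
#' @return scalar background, counts.
#' @export
estimate_background <- function(frame, masks) {
  px <- frame[masks$background_annulus]
  if (length(px) == 0) stop("background annulus is empty", call. = FALSE)
  if (length(px) < 50)
    warning("background annulus clipped to ", length(px),
            " px; using available pixels")
  stats::median(px)
}

#' Background-subtracted compartmental mean fluorescence intensity
#'
#' Mean of \code{max(counts - background, 0)} over the nucleus and the
#' cytoplasm. An empty compartment yields \code{NA} for that value.
#'
#' @param frame numeric matrix.
#' @param masks a [compartment_masks()].
#' @param background scalar counts from [estimate_background()].
#' @return list with \code{nuclear_mfi} and \code{cytoplasmic_mfi}.
#' @export
compartment_mfi <- function(frame, masks, background) {
  one <- function(m) {
    if (!any(m)) return(NA_real_)
    mean(pmax(frame[m] - background, 0))
  }
  list(nuclear_mfi = one(masks$nucleus),
       cytoplasmic_mfi = one(masks$cytoplasm))
}

#' Detect diffraction-limited punctae in a masked region
#'
#' Laplacian-of-Gaussian detection at the PSF scale: local maxima of the
#' LoG response inside the mask exceeding \code{k} times the median
#' absolute deviation of the in-mask response, refined to subpixel
#' precision by an intensity centroid within \code{r_spot = 2 * psf_sigma}
#' px. Spots closer than the PSF scale merge into a single detection.
#'
#' @param frame numeric matrix (counts).
#' @param mask logical matrix restricting the search.
#' @param psf_sigma_px PSF sigma in pixels.
#' @param k detection threshold in MADs of the in-mask LoG response.
#' @param background scalar counts subtracted when reporting spot MFI.
#' @return data frame with 0-based subpixel \code{x_px} (column),
#'   \code{y_px} (row), \code{mfi} (background-subtracted disk mean) and
#'   \code{response}; zero rows when nothing is found.
#' @export
detect_punctae <- function(frame, mask, psf_sigma_px, k = 5, background = 0) {
  kern <- -log_kernel(psf_sigma_px)       # positive response at bright spots
  resp <- EBImage::filter2(frame, kern)
  # search only the mask core: the region boundary itself produces LoG
  # maxima, and a spot this close to the edge has no measurable disk
  margin <- 2L * as.integer(ceiling(psf_sigma_px)) + 1L
  core <- EBImage::erode(mask, EBImage::makeBrush(2L * margin + 1L, "disc"))
  if (!any(core)) core <- mask
  thr <- k * stats::mad(resp[core])
  pk <- local_maxima(resp, core)
  if (nrow(pk)) pk <- pk[resp[pk] > thr, , drop = FALSE]
  empty <- data.frame(x_px = numeric(), y_px = numeric(),
                      mfi = numeric(), response = numeric())
  if (!nrow(pk)) return(empty)
  r_spot <- 2 * psf_sigma_px
  offs <- disk_offsets(r_spot)
  out <- lapply(seq_len(nrow(pk)), function(i) {
    r0 <- pk[i, 1]; c0 <- pk[i, 2]
    idx <- clip_idx(cbind(offs[, 1] + r0, offs[, 2] + c0),
                    nrow(frame), ncol(frame))
    v <- frame[idx]
    w <- pmax(v - min(v), 0)
    if (sum(w) == 0) w <- rep(1, length(v))
    data.frame(x_px = sum(w * (idx[, 2] - 1)) / sum(w),
               y_px = sum(w * (idx[, 1] - 1)) / sum(w),
               mfi = max(mean(v) - background, 0),
               response = resp[r0, c0])
  })
  do.call(rbind, out)
}

#' Fold-enrichment of punctae over the surrounding nucleoplasm
#'
#' For each spot, the background-subtracted MFI within its measurement disk
#' divided by the background-subtracted nucleoplasm MFI, where the
#' nucleoplasm is the nucleus minus all spot disks (to avoid
#' self-contamination).
#'
#' @param spots data frame from [detect_punctae()].
#' @param frame numeric matrix the spots were detected in.
#' @param nucleus_mask logical nucleus mask.
#' @param background scalar counts.
#' @param psf_sigma_px PSF sigma in pixels (sets the disk radius).
#' @return list with \code{mean}, \code{sd} and \code{n}; all \code{NA}
#'   when no spots are supplied (undefined measurement).
#' @export
punctae_enrichment <- function(spots, frame, nucleus_mask, background,
                               psf_sigma_px) {
  if (is.null(spots) || nrow(spots) == 0)
    return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  r_spot <- 2 * psf_sigma_px
  offs <- disk_offsets(r_spot)
  spot_mask <- matrix(FALSE, nrow(frame), ncol(frame))
  for (i in seq_len(nrow(spots))) {
    idx <- clip_idx(cbind(offs[, 1] + round(spots$y_px[i]) + 1L,
                          offs[, 2] + round(spots$x_px[i]) + 1L),
                    nrow(frame), ncol(frame))
    spot_mask[idx] <- TRUE
  }
  nucleo <- nucleus_mask & !spot_mask
  if (!any(nucleo)) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  nucleo_mfi <- mean(pmax(frame[nucleo] - background, 0))
  if (nucleo_mfi <= 0) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  folds <- vapply(seq_len(nrow(spots)), function(i) {
    idx <- clip_idx(cbind(offs[, 1] + round(spots$y_px[i]) + 1L,
                          offs[, 2] + round(spots$x_px[i]) + 1L),
                    nrow(frame), ncol(frame))
    max(mean(frame[idx]) - background, 0) / nucleo_mfi
  }, 0)
  list(mean = mean(folds), sd = stats::sd(folds), n = length(folds))
}

#' Measure a movie frame by frame
#'
#' Runs the full per-frame measurement chain: nucleus segmentation (DNA
#' channel), cell segmentation (summed channels), annulus background,
#' compartmental MFIs for every requested channel, optional nuclear
#' punctae detection and enrichment (YFP), and optional membrane punctae
#' counting (CFP spots within a boundary band of the cell mask).
#'
#' @param movie a [render_movie()] or [read_movie()] result.
#' @param channels channels to measure (default all rendered).
#' @param punctae logical; detect nuclear YFP punctae and their enrichment.
#' @param membrane logical; count CFP membrane punctae.
#' @param boundary_band_px width of the membrane band, px.
#' @param masks an optional [compartment_masks()] used for every frame.
#'   Adherent cells are stationary over these time scales, so regions of
#'   interest are usually drawn once per cell; when \code{NULL}, the
#'   nucleus and cell are re-segmented on every frame.
#' @return data frame with one row per frame and channel: \code{frame},
#'   \code{t_h}, \code{channel}, \code{nuclear_mfi}, \code{cytoplasmic_mfi},
#'   \code{background}, \code{n_punctae}, \code{enrichment_mean},
#'   \code{enrichment_sd}, \code{n_membrane_punctae}.
#' @export
measure_movie <- function(movie, channels = movie$channels, punctae = FALSE,
                          membrane = FALSE, boundary_band_px = 3,
                          masks = NULL) {
  stopifnot(inherits(movie, "movie"))
  sig_px <- movie$optics$psf_sigma / movie$optics$pixel_size
  nT <- dim(movie$data)[1]
  rows <- vector("list", nT * length(channels))
  ri <- 1L
  band_of <- function(cell) {
    cell & !EBImage::erode(cell,
                           EBImage::makeBrush(2L * boundary_band_px + 1L,
                                              "disc"))
  }
  if (!is.null(masks)) band <- band_of(masks$cell)
  for (fi in seq_len(nT)) {
    if (is.null(masks)) {
      dna <- if ("DNA" %in% movie$channels) movie_frame(movie, fi, "DNA")
             else NULL
      nuc <- tryCatch(segment_nucleus(dna), error = function(e) NULL)
      if (is.null(nuc)) nuc <- movie$ground_truth$nucleus_mask
      fluo <- setdiff(movie$channels, "DNA")
      sum_img <- Reduce(`+`, lapply(fluo, function(ch)
        movie_frame(movie, fi, ch)))
      cell <- segment_cell(sum_img, nuc)
      fr_masks <- compartment_masks(nuc, cell)
      band <- band_of(cell)
    } else {
      fr_masks <- masks
    }
    for (ch in channels) {
      img <- movie_frame(movie, fi, ch)
      bg <- estimate_background(img, fr_masks)
      mfi <- compartment_mfi(img, fr_masks, bg)
      n_p <- NA_integer_; en_m <- NA_real_; en_s <- NA_real_
      n_mb <- NA_integer_
      if (punctae && ch == "YFP") {
        sp <- detect_punctae(img, fr_masks$nucleus, sig_px, background = bg)
        n_p <- nrow(sp)
        en <- punctae_enrichment(sp, img, fr_masks$nucleus, bg, sig_px)
        en_m <- en$mean; en_s <- en$sd
      }
      if (membrane && ch == "CFP") {
        sp <- detect_punctae(img, band, sig_px, background = bg)
        n_mb <- nrow(sp)
      }
      rows[[ri]] <- data.frame(
        frame = fi, t_h = movie$times_h[fi], channel = ch,
        nuclear_mfi = mfi$nuclear_mfi,
        cytoplasmic_mfi = mfi$cytoplasmic_mfi, background = bg,
        n_punctae = n_p, enrichment_mean = en_m, enrichment_sd = en_s,
        n_membrane_punctae = n_mb)
      ri <- ri + 1L
    }
  }
  do.call(rbind, rows)
}
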