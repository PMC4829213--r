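# Movie persistence: multi-page 16-bit TIFF (TCYX page order) plus a JSON
# sidecar with acquisition metadata and ground-truth file names. Round
# trips are pixel-exact.

#' Write a movie to disk
#'
#' Writes the stack as one multi-page 16-bit TIFF in TCYX page order
#' (frame-major, channel-minor), a JSON sidecar with all metadata, the
#' ground-truth nucleus and cell masks as single-page TIFFs, and the
#' ground-truth spot list as CSV.
#'
#' @param movie a [render_movie()] result.
#' @param path directory to create/fill.
#' @return \code{path}, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(movie$data)
  pages <- vector("list", d[1] * d[2])
  idx <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      pages[[idx]] <- matrix(movie$data[t, c, , ], d[3], d[4]) / 65535
      idx <- idx + 1L
    }
  }
  tiff::writeTIFF(pages, file.path(path, "movie.tif"), bits.per.sample = 16)
  tiff::writeTIFF(matrix(as.numeric(movie$ground_truth$nucleus_mask),
                         d[3], d[4]),
                  file.path(path, "nucleus_mask.tif"), bits.per.sample = 8)
  tiff::writeTIFF(matrix(as.numeric(movie$ground_truth$cell_mask),
                         d[3], d[4]),
                  file.path(path, "cell_mask.tif"), bits.per.sample = 8)
  spots <- movie$ground_truth$spots
  if (is.null(spots))
    spots <- data.frame(frame = integer(), channel = character(),
                        x_px = numeric(), y_px = numeric(),
                        peak = numeric(), particle_id = integer(),
                        compartment = character())
  utils::write.csv(spots, file.path(path, "spots.csv"), row.names = FALSE)

  meta <- list(
    format = "retroflux-movie-1", dims = d,
    page_order = "TCYX", channels = movie$channels,
    times_h = movie$times_h, frame_index = movie$frame_index,
    scenario = movie$scenario, seed = movie$seed,
    optics = unclass(movie$optics),
    centrosome_px = as.list(movie$ground_truth$centrosome_px),
    files = list(stack = "movie.tif", nucleus_mask = "nucleus_mask.tif",
                 cell_mask = "cell_mask.tif", spots = "spots.csv"))
  jsonlite::write_json(meta, file.path(path, "movie.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie from disk
#'
#' Inverse of [write_movie()]; the pixel data round-trips exactly.
#'
#' @param path directory written by [write_movie()].
#' @return a \code{movie} object.
#' @export
read_movie <- function(path) {
  sidecar <- file.path(path, "movie.json")
  if (!file.exists(sidecar))
    stop("format error: expected sidecar file ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  stack_file <- file.path(path, meta$files$stack)
  if (!file.exists(stack_file))
    stop("format error: expected stack file ", stack_file, call. = FALSE)
  pages <- tiff::readTIFF(stack_file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- meta$dims
  if (length(pages) != d[1] * d[2])
    stop("validation error: stack has ", length(pages),
         " pages but metadata declares ", d[1], " frames x ", d[2],
         " channels", call. = FALSE)
  dat <- array(0L, dim = d)
  idx <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      dat[t, c, , ] <- as.integer(round(pages[[idx]] * 65535))
      idx <- idx + 1L
    }
  }
  nm <- tiff::readTIFF(file.path(path, meta$files$nucleus_mask)) > 0.5
  cm <- tiff::readTIFF(file.path(path, meta$files$cell_mask)) > 0.5
  spots <- utils::read.csv(file.path(path, meta$files$spots))
  if (nrow(spots) == 0) spots <- NULL
  opt <- meta$optics
  optics <- optics_config(pixel_size = opt$pixel_size,
                          psf_sigma = opt$psf_sigma,
                          photon_scale = opt$photon_scale,
                          read_noise_sd = opt$read_noise_sd,
                          background_level = opt$background_level,
                          autofluor_level = opt$autofluor_level,
                          bit_depth = opt$bit_depth,
                          frame_interval = opt$frame_interval,
                          mode = opt$mode, channels = opt$channels,
                          img_size = opt$img_size,
                          noiseless = isTRUE(opt$noiseless))
  mv <- list(data = dat, channels = meta$channels, times_h = meta$times_h,
             frame_index = meta$frame_index, optics = optics,
             scenario = meta$scenario, seed = meta$seed,
             ground_truth = list(
               nucleus_mask = nm, cell_mask = cm,
               centrosome_px = unlist(meta$centrosome_px),
               spots = spots))
  class(mv) <- "movie"
  mv
}
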