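#' Generate a HeLa-like single-cell geometry
#'
#' Builds the static geometry for one adherent cell: a star-convex cell
#' boundary with smooth low-frequency shape variation, an elliptical nucleus
#' strictly inside the cell, a juxtanuclear centrosome (within 3 um of the
#' nuclear envelope), microtubule tracks radiating from the centrosome to
#' the cell boundary, and a handful of nuclear transcription sites.
#' Coordinates are micrometres with origin at the top-left corner of the
#' imaged field, x increasing along columns and y along rows.
#'
#' @param config a [scenario_config()]; only validated, the geometry itself
#'   is scenario-independent.
#' @param rng_seed integer seed; the same seed yields an identical geometry.
#' @param field_um side length of the square imaged field, um.
#' @param pixel_size um per pixel (stored for downstream mask rasterisation).
#' @param n_mt_tracks number of microtubule tracks.
#' @return object of class \code{cell_geometry} with elements
#'   \code{cell_boundary} (closed polygon, um), \code{radius_theta}/
#'   \code{radius_r} (the star-convex radius function sampled on a grid),
#'   \code{center}, \code{nucleus} (center, semi-axes \code{a, b}, angle),
#'   \code{centrosome}, \code{mt_tracks} (list of 2-column matrices, each
#'   starting at the centrosome), \code{transcription_sites},
#'   \code{pixel_size}, \code{field_um}.
#' @export
make_cell_geometry <- function(config, rng_seed, field_um = 83.2,
                               pixel_size = 0.325, n_mt_tracks = 24) {
  validate_scenario_config(config)
  if (!is.numeric(rng_seed) || length(rng_seed) != 1 || is.na(rng_seed))
    stop("configuration error in field 'rng_seed': must be a single integer",
         call. = FALSE)
  set.seed(as.integer(rng_seed))

  center <- field_um / 2 + stats::runif(2, -2, 2)

  # star-convex boundary: base radius with three low-order harmonics
  base_r <- stats::runif(1, 16, 19)
  amp <- stats::runif(3, 0.01, 0.06)
  phase <- stats::runif(3, 0, 2 * pi)
  theta <- seq(0, 2 * pi, length.out = 361)
  rr <- base_r * (1 + amp[1] * cos(theta - phase[1]) +
                    amp[2] * cos(2 * theta - phase[2]) +
                    amp[3] * cos(3 * theta - phase[3]))
  boundary <- cbind(x = center[1] + rr * cos(theta),
                    y = center[2] + rr * sin(theta))

  nuc_center <- center + stats::runif(2, -1.5, 1.5)
  nuc <- list(center = nuc_center,
              a = stats::runif(1, 6, 7.5),
              b = stats::runif(1, 4.5, 6),
              angle = stats::runif(1, 0, pi))

  # centrosome: juxtanuclear, 0.8-2.2 um beyond the nuclear envelope
  cang <- stats::runif(1, 0, 2 * pi)
  edge_r <- ellipse_radius_at(nuc, cang)
  cdist <- stats::runif(1, 0.8, 2.2)
  centrosome <- nuc_center + (edge_r + cdist) * c(cos(cang), sin(cang))

  geom <- list(center = center, radius_theta = theta, radius_r = rr,
               cell_boundary = boundary, nucleus = nuc,
               centrosome = centrosome, pixel_size = pixel_size,
               field_um = field_um)
  class(geom) <- "cell_geometry"

  # microtubule tracks: rays from the centrosome to the cell boundary
  angles <- seq(0, 2 * pi, length.out = n_mt_tracks + 1)[-1] +
    stats::runif(n_mt_tracks, -0.05, 0.05)
  geom$mt_tracks <- lapply(angles, function(a) {
    len <- ray_length_in_cell(geom, centrosome, a)
    rbind(centrosome,
          centrosome + len * c(cos(a), sin(a)))
  })

  ts <- sample_in_nucleus(geom, 4, shrink = 0.6)
  geom$transcription_sites <- ts
  geom
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("<cell_geometry>\n")
  cat(sprintf("  field: %.1f um (%.3f um/px)\n", x$field_um, x$pixel_size))
  cat(sprintf("  nucleus: %.1f x %.1f um semi-axes\n", x$nucleus$a, x$nucleus$b))
  cat(sprintf("  centrosome: (%.1f, %.1f) um; %d MT tracks\n",
              x$centrosome[1], x$centrosome[2], length(x$mt_tracks)))
  invisible(x)
}

# radius of a rotated ellipse along direction ang from its center
ellipse_radius_at <- function(nuc, ang) {
  ca <- cos(ang - nuc$angle)
  sa <- sin(ang - nuc$angle)
  1 / sqrt((ca / nuc$a)^2 + (sa / nuc$b)^2)
}

# implicit ellipse value (<1 inside) for points (x, y)
ellipse_implicit <- function(nuc, x, y) {
  dx <- x - nuc$center[1]
  dy <- y - nuc$center[2]
  u <- dx * cos(nuc$angle) + dy * sin(nuc$angle)
  v <- -dx * sin(nuc$angle) + dy * cos(nuc$angle)
  (u / nuc$a)^2 + (v / nuc$b)^2
}

in_nucleus <- function(geom, x, y) ellipse_implicit(geom$nucleus, x, y) <= 1

cell_radius_at <- function(geom, ang) {
  ang <- ang %% (2 * pi)
  stats::approx(geom$radius_theta, geom$radius_r, xout = ang,
                rule = 2)$y
}

in_cell <- function(geom, x, y) {
  dx <- x - geom$center[1]
  dy <- y - geom$center[2]
  r <- sqrt(dx^2 + dy^2)
  r <= cell_radius_at(geom, atan2(dy, dx))
}

# distance from a point along direction ang to the cell boundary
ray_length_in_cell <- function(geom, from, ang, step = 0.25) {
  lo <- 0
  hi <- 2.5 * max(geom$radius_r)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    p <- from + mid * c(cos(ang), sin(ang))
    if (in_cell(geom, p[1], p[2])) lo <- mid else hi <- mid
  }
  lo
}

# uniform samples inside the nucleus (optionally shrunk toward the center)
sample_in_nucleus <- function(geom, n, shrink = 1) {
  nuc <- geom$nucleus
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(16, 2 * (n - nrow(out)))
    u <- stats::runif(m, -1, 1)
    v <- stats::runif(m, -1, 1)
    keep <- u^2 + v^2 <= 1
    u <- u[keep] * nuc$a * shrink
    v <- v[keep] * nuc$b * shrink
    x <- nuc$center[1] + u * cos(nuc$angle) - v * sin(nuc$angle)
    y <- nuc$center[2] + u * sin(nuc$angle) + v * cos(nuc$angle)
    out <- rbind(out, cbind(x, y))
  }
  out[seq_len(n), , drop = FALSE]
}

# uniform samples in the cytoplasm (inside cell, outside nucleus)
sample_in_cytoplasm <- function(geom, n) {
  out <- matrix(NA_real_, 0, 2)
  rmax <- max(geom$radius_r)
  while (nrow(out) < n) {
    m <- max(32, 3 * (n - nrow(out)))
    x <- geom$center[1] + stats::runif(m, -rmax, rmax)
    y <- geom$center[2] + stats::runif(m, -rmax, rmax)
    keep <- in_cell(geom, x, y) & !in_nucleus(geom, x, y)
    out <- rbind(out, cbind(x, y)[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# samples in a band of given width just outside the nuclear envelope
sample_envelope_ring <- function(geom, n, width = 2) {
  ang <- stats::runif(n, 0, 2 * pi)
  off <- stats::runif(n, 0.15, width)
  er <- vapply(ang, function(a) ellipse_radius_at(geom$nucleus, a), 0)
  x <- geom$nucleus$center[1] + (er + off) * cos(ang)
  y <- geom$nucleus$center[2] + (er + off) * sin(ang)
  # clip any point that left the cell back onto a shorter radius
  bad <- !in_cell(geom, x, y)
  if (any(bad)) {
    p <- sample_in_cytoplasm(geom, sum(bad))
    x[bad] <- p[, 1]; y[bad] <- p[, 2]
  }
  cbind(x = x, y = y)
}

# samples clustered at the MTOC (gaussian around the centrosome, kept
# inside the cytoplasm)
sample_at_mtoc <- function(geom, n, sigma = 0.8) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(16, 2 * (n - nrow(out)))
    x <- stats::rnorm(m, geom$centrosome[1], sigma)
    y <- stats::rnorm(m, geom$centrosome[2], sigma)
    keep <- in_cell(geom, x, y) & !in_nucleus(geom, x, y)
    out <- rbind(out, cbind(x, y)[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# positions on a microtubule ray at given distances from the centrosome
position_on_ray <- function(geom, ray_angle, dist) {
  cbind(geom$centrosome[1] + dist * cos(ray_angle),
        geom$centrosome[2] + dist * sin(ray_angle))
}

#' Check the structural invariants of a cell geometry
#'
#' Verifies that the nucleus lies strictly inside the cell boundary, the
#' centrosome sits outside the nucleus but inside the cell within 3 um of
#' the nuclear envelope, and every microtubule track starts at the
#' centrosome.
#'
#' @param geom a \code{cell_geometry}.
#' @return TRUE if all invariants hold, otherwise stops with a message.
#' @export
check_geometry <- function(geom) {
  nuc <- geom$nucleus
  th <- seq(0, 2 * pi, length.out = 180)
  ex <- nuc$center[1] + nuc$a * cos(th) * cos(nuc$angle) -
    nuc$b * sin(th) * sin(nuc$angle)
  ey <- nuc$center[2] + nuc$a * cos(th) * sin(nuc$angle) +
    nuc$b * sin(th) * cos(nuc$angle)
  if (!all(in_cell(geom, ex, ey)))
    stop("geometry invariant violated: nucleus not inside cell")
  cs <- geom$centrosome
  if (in_nucleus(geom, cs[1], cs[2]))
    stop("geometry invariant violated: centrosome inside nucleus")
  if (!in_cell(geom, cs[1], cs[2]))
    stop("geometry invariant violated: centrosome outside cell")
  # distance to nuclear envelope along the radial direction bounds the
  # true distance from above
  dd <- sqrt(sum((cs - nuc$center)^2)) -
    ellipse_radius_at(nuc, atan2(cs[2] - nuc$center[2], cs[1] - nuc$center[1]))
  if (dd > 3)
    stop("geometry invariant violated: centrosome not juxtanuclear")
  starts_ok <- vapply(geom$mt_tracks, function(tr) {
    sqrt(sum((tr[1, ] - cs)^2)) < 1e-9
  }, TRUE)
  if (!all(starts_ok))
    stop("geometry invariant violated: MT track does not start at centrosome")
  if (!all(in_nucleus(geom, geom$transcription_sites[, 1],
                      geom$transcription_sites[, 2])))
    stop("geometry invariant violated: transcription site outside nucleus")
  TRUE
}
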