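# Fast-mode single-particle tracking: greedy mutual-nearest-neighbour frame
# linking with single-frame gap closing, per-track speed estimation, and
# mean-squared-displacement motion classification.

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour assignment: a detection links to a track
#' when each is the other's nearest neighbour within \code{max_disp_um}.
#' Candidate pairs are processed in order of increasing distance, ties
#' broken by (track index, spot index). Tracks missing a detection for up
#' to \code{max_gap_frames} frames may be resumed (gap closing); unmatched
#' detections start new tracks.
#'
#' @param per_frame_spots list of data frames (one per frame) with columns
#'   \code{x_um}, \code{y_um}; frames are \code{dt_s} apart.
#' @param max_disp_um maximum displacement per frame for a link.
#' @param max_gap_frames maximum number of missed frames bridged.
#' @param dt_s frame interval, seconds.
#' @return list of tracks, each a data frame (\code{frame}, \code{t_s},
#'   \code{x_um}, \code{y_um}).
#' @export
link_tracks <- function(per_frame_spots, max_disp_um = 1.5,
                        max_gap_frames = 1, dt_s = 0.7) {
  if (length(per_frame_spots) < 2)
    stop("need at least 2 frames of detections", call. = FALSE)
  tracks <- list()        # each: df + last frame seen
  active <- integer(0)    # indices into tracks that may still link

  for (f in seq_along(per_frame_spots)) {
    sp <- per_frame_spots[[f]]
    n_sp <- if (is.null(sp)) 0L else nrow(sp)
    # drop tracks whose gap exceeded the limit
    if (length(active)) {
      last_seen <- vapply(tracks[active], function(tr) max(tr$frame), 0)
      active <- active[f - last_seen <= max_gap_frames + 1L]
    }
    if (n_sp > 0) {
      assigned_sp <- rep(FALSE, n_sp)
      if (length(active)) {
        tx <- vapply(tracks[active], function(tr) tr$x_um[nrow(tr)], 0)
        ty <- vapply(tracks[active], function(tr) tr$y_um[nrow(tr)], 0)
        dmat <- sqrt(outer(tx, sp$x_um, "-")^2 + outer(ty, sp$y_um, "-")^2)
        cand <- which(dmat <= max_disp_um, arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(dmat[cand], cand[, 1], cand[, 2])
          cand <- cand[ord, , drop = FALSE]
          used_tr <- rep(FALSE, length(active))
          for (i in seq_len(nrow(cand))) {
            ti <- cand[i, 1]; si <- cand[i, 2]
            # distance-ordered greedy: once either partner is taken the
            # pair is obsolete, so each surviving pair is mutually nearest
            # among the unassigned
            if (used_tr[ti] || assigned_sp[si]) next
            tr_id <- active[ti]
            tracks[[tr_id]] <- rbind(
              tracks[[tr_id]],
              data.frame(frame = f, t_s = (f - 1) * dt_s,
                         x_um = sp$x_um[si], y_um = sp$y_um[si]))
            used_tr[ti] <- TRUE
            assigned_sp[si] <- TRUE
          }
        }
      }
      for (si in which(!assigned_sp)) {
        tracks[[length(tracks) + 1L]] <- data.frame(
          frame = f, t_s = (f - 1) * dt_s,
          x_um = sp$x_um[si], y_um = sp$y_um[si])
      }
      # every track that has not exceeded its gap remains linkable
      last_seen <- vapply(tracks, function(tr) max(tr$frame), 0)
      active <- which(f - last_seen <= max_gap_frames)
    }
  }
  tracks
}

#' Mean per-step speed of a track
#'
#' Mean of per-step displacement over time over steps whose displacement
#' exceeds \code{noise_floor_um} (steps below the floor are localization
#' jitter of a pausing particle, not motion).
#'
#' @param track data frame from [link_tracks()] (needs >= 5 points).
#' @param noise_floor_um displacement floor, um (twice the localization
#'   sigma by convention).
#' @return list with \code{speed_um_s} and \code{stationary} (TRUE when no
#'   step clears the floor; speed 0).
#' @export
track_speed <- function(track, noise_floor_um = 0.065) {
  if (nrow(track) < 5) stop("track too short for a speed estimate (need 5 points)")
  dx <- diff(track$x_um)
  dy <- diff(track$y_um)
  dt <- diff(track$t_s)
  disp <- sqrt(dx^2 + dy^2)
  keep <- disp > noise_floor_um & dt > 0
  if (!any(keep)) return(list(speed_um_s = 0, stationary = TRUE))
  list(speed_um_s = mean(disp[keep] / dt[keep]), stationary = FALSE)
}

#' Classify track motion from the MSD exponent
#'
#' Fits log mean-squared displacement against log lag over lags
#' \code{1..floor(n/4)} frames. The power-law exponent alpha classifies
#' the motion: \code{directed} for alpha >= 1.3, \code{confined} for
#' alpha <= 0.7, \code{diffusive} otherwise. A degenerate (zero-variance)
#' track is confined.
#'
#' @param track data frame from [link_tracks()] (needs >= 10 points).
#' @return list with \code{class} and \code{alpha}.
#' @export
classify_motion <- function(track) {
  n <- nrow(track)
  if (n < 10) stop("track too short for MSD classification (need 10 points)")
  max_lag <- max(2L, floor(n / 4))
  msd <- vapply(seq_len(max_lag), function(L) {
    mean((track$x_um[(1 + L):n] - track$x_um[1:(n - L)])^2 +
           (track$y_um[(1 + L):n] - track$y_um[1:(n - L)])^2)
  }, 0)
  if (all(msd <= 1e-12)) return(list(class = "confined", alpha = 0))
  lag_s <- seq_len(max_lag) * mean(diff(track$t_s))
  keep <- msd > 0
  fit <- stats::lm(log(msd[keep]) ~ log(lag_s[keep]))
  alpha <- unname(stats::coef(fit)[2])
  cls <- if (alpha >= 1.3) "directed" else if (alpha <= 0.7) "confined"
         else "diffusive"
  list(class = cls, alpha = alpha)
}

#' Detect and track spots across a fast-mode movie
#'
#' Runs [detect_punctae()] on the YFP channel of every frame (cytoplasm
#' only), converts detections to micrometres, links them with
#' [link_tracks()], and summarises every track of sufficient length with
#' [track_speed()] and [classify_motion()].
#'
#' @param movie a fast-mode [render_movie()] result.
#' @param max_disp_um,max_gap_frames linking parameters.
#' @param min_points minimum track length retained in the summary.
#' @return list with \code{tracks} and \code{summary} (data frame:
#'   track_id, n_points, mean_speed_um_s, stationary, msd_alpha, class).
#' @export
track_movie <- function(movie, max_disp_um = 1.5, max_gap_frames = 1,
                        min_points = 5) {
  stopifnot(inherits(movie, "movie"))
  ps <- movie$optics$pixel_size
  sig_px <- movie$optics$psf_sigma / ps
  cyto <- movie$ground_truth$cell_mask & !movie$ground_truth$nucleus_mask
  nT <- dim(movie$data)[1]
  dt_s <- movie$times_h[2] * 3600 - movie$times_h[1] * 3600
  per_frame <- lapply(seq_len(nT), function(fi) {
    img <- movie_frame(movie, fi, "YFP")
    sp <- detect_punctae(img, cyto, sig_px)
    if (nrow(sp) == 0) return(NULL)
    data.frame(x_um = (sp$x_px + 0.5) * ps, y_um = (sp$y_px + 0.5) * ps)
  })
  tracks <- link_tracks(per_frame, max_disp_um, max_gap_frames, dt_s)
  tracks <- Filter(function(tr) nrow(tr) >= min_points, tracks)
  summ <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    sp <- track_speed(tr)
    mo <- if (nrow(tr) >= 10) classify_motion(tr)
          else list(class = NA_character_, alpha = NA_real_)
    data.frame(track_id = i, n_points = nrow(tr),
               mean_speed_um_s = sp$speed_um_s, stationary = sp$stationary,
               msd_alpha = mo$alpha, class = mo$class)
  })
  list(tracks = tracks,
       summary = if (length(summ)) do.call(rbind, summ) else
         data.frame(track_id = integer(), n_points = integer(),
                    mean_speed_um_s = numeric(), stationary = logical(),
                    msd_alpha = numeric(), class = character()))
}
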