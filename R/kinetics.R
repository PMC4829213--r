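# Per-cell time-series analysis: normalization, onset detection, C:N ratio
# kinetics, peak alignment, transition-duration estimation and export-class
# calls.

#' Min-max normalize a series to \[0, 1\]
#'
#' @param series numeric vector with at least two values and max > min.
#' @return \code{(x - min) / (max - min)}.
#' @export
normalize_minmax <- function(series) {
  if (length(series) < 2)
    stop("degenerate trace: need at least 2 frames", call. = FALSE)
  rng <- range(series, na.rm = TRUE)
  if (!(rng[2] > rng[1]))
    stop("degenerate trace: series is constant", call. = FALSE)
  (series - rng[1]) / (rng[2] - rng[1])
}

#' Detect a reporter onset above background
#'
#' First time the series exceeds \code{3 * background_sd}, sustained for 2
#' consecutive frames (single-frame excursions are shot noise).
#'
#' @param series numeric vector (background-subtracted MFI).
#' @param time time axis, hours.
#' @param background_sd scalar noise level of the series.
#' @return onset time in hours, or \code{NA} when never detected.
#' @export
detect_onset <- function(series, time, background_sd) {
  above <- series > 3 * background_sd
  ok <- above & c(above[-1], FALSE)
  if (!any(ok)) return(NA_real_)
  time[which(ok)[1]]
}

#' Align normalized traces to their peaks
#'
#' Shifts each trace so its maximum sits at relative index 0; ties are
#' broken by the earliest maximum. Unfilled cells are \code{NA}.
#'
#' @param cn_traces list of normalized numeric vectors (equal cadence).
#' @return list with \code{matrix} (rows = traces, columns = relative
#'   offsets) and \code{offsets} (column offsets in frames; 0 is the peak).
#' @export
align_to_peak <- function(cn_traces) {
  if (length(cn_traces) == 0) stop("empty trace collection", call. = FALSE)
  peaks <- vapply(cn_traces, function(x) which.max(x), 1L)
  lens <- lengths(cn_traces)
  lo <- min(1L - peaks)
  hi <- max(lens - peaks)
  offs <- lo:hi
  m <- matrix(NA_real_, length(cn_traces), length(offs))
  for (i in seq_along(cn_traces)) {
    idx <- seq_along(cn_traces[[i]]) - peaks[i]
    m[i, match(idx, offs)] <- cn_traces[[i]]
  }
  list(matrix = m, offsets = offs)
}

#' Min-to-max transition duration of a normalized trace
#'
#' Returns \code{(t_last_cross_0.9 - t_first_cross_0.1) / 0.8} with linear
#' interpolation between frames: the full-range duration under a
#' local-linearity assumption, robust to endpoint noise.
#'
#' @param cn_series_normalized series normalized to \[0, 1\].
#' @param time time axis, hours.
#' @return duration in hours, or \code{NA} if the trace never reaches 0.9.
#' @export
transition_duration <- function(cn_series_normalized, time) {
  x <- cn_series_normalized
  if (max(x, na.rm = TRUE) < 0.9) return(NA_real_)
  t10 <- first_crossing(x, time, 0.1)
  t90 <- last_crossing(x, time, 0.9)
  (t90 - t10) / 0.8
}

# first upward crossing of `lvl`, linearly interpolated
first_crossing <- function(x, time, lvl) {
  if (x[1] >= lvl) return(time[1])
  i <- which(x[-1] >= lvl & x[-length(x)] < lvl)[1]
  if (is.na(i)) return(NA_real_)
  frac <- (lvl - x[i]) / (x[i + 1] - x[i])
  time[i] + frac * (time[i + 1] - time[i])
}

# last upward crossing of `lvl`, linearly interpolated
last_crossing <- function(x, time, lvl) {
  i <- which(x[-1] >= lvl & x[-length(x)] < lvl)
  if (!length(i)) {
    if (x[1] >= lvl) return(time[1])
    return(NA_real_)
  }
  i <- i[length(i)]
  frac <- (lvl - x[i]) / (x[i + 1] - x[i])
  time[i] + frac * (time[i + 1] - time[i])
}

#' Classify the nuclear-export behavior of a cell
#'
#' \code{none} when the final raw C:N ratio stays below 1.5 (the transcript
#' never became cytoplasmic-dominant); otherwise \code{burst} when the
#' min-to-max transition completed in under an hour (en-masse nuclear
#' evacuation) and \code{gradual} otherwise.
#'
#' @param cn_raw raw C:N ratio series.
#' @param time time axis, hours.
#' @return list with \code{class} (\code{"burst"}, \code{"gradual"},
#'   \code{"none"}) and \code{duration_h} (NA for \code{none}).
#' @export
classify_export <- function(cn_raw, time) {
  final <- cn_raw[length(cn_raw)]
  if (!is.finite(final) || final < 1.5)
    return(list(class = "none", duration_h = NA_real_))
  dur <- tryCatch(
    transition_duration(normalize_minmax(cn_raw), time),
    error = function(e) NA_real_)
  if (is.na(dur)) {
    warning("transition duration undefined for an exporting cell; ",
            "classifying gradual")
    return(list(class = "gradual", duration_h = NA_real_))
  }
  list(class = if (dur < 1.0) "burst" else "gradual", duration_h = dur)
}

#' Virus-like-particle onset time
#'
#' First time the membrane punctae count reaches at least 3 sustained for 2
#' consecutive frames.
#'
#' @param membrane_punctae_series per-frame membrane punctae counts.
#' @param time time axis, hours.
#' @return onset in hours, or \code{NA} when assembly never starts.
#' @export
vlp_onset <- function(membrane_punctae_series, time) {
  x <- membrane_punctae_series
  ok <- x >= 3 & c(x[-1], -Inf) >= 3
  if (!any(ok, na.rm = TRUE)) return(NA_real_)
  time[which(ok)[1]]
}

#' Build a per-cell trace from frame measurements
#'
#' Collects the per-frame measurements of one cell into a
#' \code{cell_trace}: the YFP C:N ratio series, punctae and membrane
#' counts, and the derived kinetic calls (Rev onset, export class,
#' transition duration, VLP onset).
#'
#' @param measurements data frame from [measure_movie()].
#' @param onset_baseline_frames frames used to estimate the pre-onset noise
#'   of the cytoplasmic mCherry series.
#' @return object of class \code{cell_trace}.
#' @export
cell_trace <- function(measurements, onset_baseline_frames = 6) {
  yfp <- measurements[measurements$channel == "YFP", , drop = FALSE]
  trace <- list(time = yfp$t_h)
  if (nrow(yfp)) {
    cn <- yfp$cytoplasmic_mfi / pmax(yfp$nuclear_mfi, 1e-6)
    trace$cn_ratio <- cn
    trace$nuclear_mfi <- yfp$nuclear_mfi
    trace$cytoplasmic_mfi <- yfp$cytoplasmic_mfi
    trace$punctae_count <- yfp$n_punctae
    cls <- classify_export(cn, yfp$t_h)
    trace$export_class <- cls$class
    trace$transition_duration <- cls$duration_h
  }
  mch <- measurements[measurements$channel == "mCherry", , drop = FALSE]
  if (nrow(mch)) {
    # centre on the pre-expression baseline so the 3-SD rule sees a
    # zero-mean background (cell autofluorescence gives the clamped MFI a
    # small positive floor)
    base <- seq_len(min(onset_baseline_frames, nrow(mch)))
    centred <- mch$cytoplasmic_mfi - mean(mch$cytoplasmic_mfi[base])
    bsd <- max(stats::sd(mch$cytoplasmic_mfi[base]), 1e-6)
    trace$rev_onset <- detect_onset(centred, mch$t_h, bsd)
  }
  cfp <- measurements[measurements$channel == "CFP", , drop = FALSE]
  if (nrow(cfp) && !all(is.na(cfp$n_membrane_punctae))) {
    trace$membrane_punctae <- cfp$n_membrane_punctae
    trace$vlp_onset <- vlp_onset(cfp$n_membrane_punctae, cfp$t_h)
  }
  class(trace) <- "cell_trace"
  trace
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> %d frames; export class %s\n",
              length(x$time), x$export_class %||% "?"))
  invisible(x)
}
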