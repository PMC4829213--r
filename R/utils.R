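# Internal numerical helpers shared across modules.

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler for a normal distribution truncated to
#' \code{[lower, upper]}. Used for per-cell kinetic parameters (transition
#' durations, reporter onsets) that are biologically constrained to be
#' positive or bounded.
#'
#' @param n number of draws.
#' @param mean,sd moments of the untruncated normal.
#' @param lower,upper truncation bounds (may be infinite).
#' @return numeric vector of length \code{n}.
#' @keywords internal
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower <= upper)
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  # guard against u exactly 0/1 in degenerate tails
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u, mean, sd)
}

# Mean and sd of a normal truncated to [lower, upper].
truncnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  t1 <- ifelse(is.finite(a), a * da, 0)
  t2 <- ifelse(is.finite(b), b * db, 0)
  v <- sd^2 * (1 + (t1 - t2) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

#' Solve for underlying normal parameters given truncated moments
#'
#' Finds \code{(mean, sd)} of an untruncated normal such that the
#' distribution truncated to \code{[lower, upper]} has the requested mean and
#' sd. Registry onset parameters are quoted in measured (truncated) space;
#' the generator draws from the matched underlying distribution.
#'
#' @param target_mean,target_sd moments the truncated distribution must have.
#' @param lower,upper truncation bounds.
#' @return list with elements \code{mean} and \code{sd}.
#' @keywords internal
truncnorm_match <- function(target_mean, target_sd, lower = -Inf, upper = Inf) {
  obj <- function(p) {
    m <- truncnorm_moments(p[1], exp(p[2]), lower, upper)
    (m$mean - target_mean)^2 + (m$sd - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mean = fit$par[1], sd = exp(fit$par[2]))
}

# Triangle threshold (Zack et al.) on an intensity histogram. Returns the
# threshold value on the same scale as x. Robust for unimodal backgrounds
# with a bright-tail foreground, which is the regime of the summed-channel
# cell image. Intensities are clipped at the 99.5th percentile first so a
# handful of very bright pixels (e.g. a dense MTOC cluster) cannot define
# the far end of the triangle line and push the threshold above the dim
# cell body.
triangle_threshold <- function(x, n_bins = 256) {
  x <- pmin(x, stats::quantile(x, 0.995, names = FALSE))
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  cnt <- h$counts
  mids <- h$mids
  pk <- which.max(cnt)
  # work on the longer tail side of the peak
  left <- pk - 1L
  right <- length(cnt) - pk
  if (right >= left) {
    idx <- pk:length(cnt)
  } else {
    idx <- rev(seq_len(pk))
  }
  c0 <- cnt[idx]
  # line from peak to histogram end; maximize perpendicular distance
  x1 <- 1; y1 <- c0[1]
  x2 <- length(c0); y2 <- c0[length(c0)]
  xx <- seq_along(c0)
  d <- abs((y2 - y1) * xx - (x2 - x1) * c0 + x2 * y1 - y2 * x1)
  best <- which.max(d)
  mids[idx[best]]
}

# Laplacian-of-Gaussian kernel with scale sigma (pixels); normalized so a
# matched Gaussian blob of unit peak gives a positive response. Odd size.
log_kernel <- function(sigma) {
  k <- max(3L, 2L * as.integer(ceiling(3 * sigma)) + 1L)
  half <- (k - 1L) / 2L
  g <- expand.grid(x = -half:half, y = -half:half)
  r2 <- g$x^2 + g$y^2
  lg <- -(1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
  lg <- lg - mean(lg)  # zero-sum: flat regions give zero response
  matrix(lg, k, k)
}

# 2-D local maxima of a matrix within a logical mask (8-neighbourhood,
# strictly greater than neighbours; border excluded).
local_maxima <- function(m, mask = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- matrix(TRUE, nr, nc)
  ctr <- m[2:(nr - 1), 2:(nc - 1)]
  res <- matrix(FALSE, nr, nc)
  hit <- ctr > m[1:(nr - 2), 2:(nc - 1)] & ctr > m[3:nr, 2:(nc - 1)] &
    ctr > m[2:(nr - 1), 1:(nc - 2)] & ctr > m[2:(nr - 1), 3:nc] &
    ctr > m[1:(nr - 2), 1:(nc - 2)] & ctr > m[3:nr, 3:nc] &
    ctr > m[1:(nr - 2), 3:nc] & ctr > m[3:nr, 1:(nc - 2)]
  res[2:(nr - 1), 2:(nc - 1)] <- hit
  if (!is.null(mask)) res <- res & mask
  which(res, arr.ind = TRUE)
}

# Disk mask pixel offsets for radius r (pixels) around a center; returns
# integer offset matrix (dr, dc).
disk_offsets <- function(r) {
  ri <- as.integer(ceiling(r))
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

# Clip (row, col) index pairs to matrix bounds.
clip_idx <- function(idx, nr, nc) {
  keep <- idx[, 1] >= 1 & idx[, 1] <= nr & idx[, 2] >= 1 & idx[, 2] <= nc
  idx[keep, , drop = FALSE]
}

# Derive a stream of per-cell integer seeds from one master seed, keeping
# them in 32-bit range for set.seed().
derive_seeds <- function(master_seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
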