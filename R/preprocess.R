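## BOLD preprocessing: physiological-noise regression and zero-phase low-pass
## filtering. Both operations preserve array shape, affine and TR.

#' Regress recorded physiological confounds out of a BOLD run
#'
#' Replaces every voxel time series by its least-squares residual against a
#' design of intercept, linear trend, and the cardiac and respiratory traces
#' resampled to the frame times by linear interpolation. Residuals are
#' orthogonal to every retained design column to machine precision. Columns
#' that are (numerically) constant, or redundant given earlier columns, are
#' dropped with a warning rather than making the fit rank-deficient.
#'
#' @param bold a \code{\linkS4class{Bold4D}}.
#' @param physio a \code{\linkS4class{PhysioTrace}} covering the run.
#' @return a \code{\linkS4class{Bold4D}} of residuals (same shape, affine and
#'   TR).
#' @export
regressPhysio <- function(bold, physio) {
  stopifnot(is(bold, "Bold4D"), is(physio, "PhysioTrace"))
  d <- dim(bold@data)
  nT <- d[4]
  frameTimes <- (seq_len(nT) - 1) * bold@trSeconds
  tol <- bold@trSeconds / 2
  if (min(physio@time) > min(frameTimes) + tol ||
      max(physio@time) < max(frameTimes) - tol)
    stop("physiological recording does not cover the BOLD run")

  card <- stats::approx(physio@time, physio@cardiac, xout = frameTimes,
                        rule = 2)$y
  resp <- stats::approx(physio@time, physio@respiratory, xout = frameTimes,
                        rule = 2)$y
  X <- cbind(intercept = 1, trend = frameTimes - mean(frameTimes),
             cardiac = card - mean(card), respiratory = resp - mean(resp))

  keep <- c(TRUE, vapply(2:ncol(X), function(j)
    stats::sd(X[, j]) > 1e-10 * max(1, mean(abs(X[, j]))), logical(1)))
  qrX <- qr(X[, keep, drop = FALSE])
  if (qrX$rank < sum(keep)) {
    dep <- colnames(X)[keep][-seq_len(qrX$rank)]
    keep[match(dep, colnames(X))] <- FALSE
    qrX <- qr(X[, keep, drop = FALSE])
  }
  if (!all(keep))
    warning("dropped degenerate design column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))

  Y <- matrix(bold@data, prod(d[1:3]), nT)
  Q <- qr.Q(qrX)
  resid <- Y - (Y %*% Q) %*% t(Q)
  new("Bold4D", data = array(resid, d), trSeconds = bold@trSeconds,
      affine = bold@affine)
}

# Steady-state initial conditions for a direct-form II transposed IIR filter
# (the scipy lfilter_zi construction): the state vector that keeps a constant
# input at its steady-state output, solved by back-substitution.
iirSteadyState <- function(b, a) {
  K <- length(b) - 1L
  g <- sum(b) / sum(a)
  zi <- numeric(K)
  zi[K] <- b[K + 1] - a[K + 1] * g
  if (K > 1L) for (k in (K - 1L):1L)
    zi[k] <- b[k + 1] - a[k + 1] * g + zi[k + 1]
  zi
}

# Apply an IIR filter along the rows of X (time x series), direct-form II
# transposed, vectorized across series. zi scales the initial state by each
# series' first sample.
iirFilterMatrix <- function(b, a, X, zi = NULL) {
  K <- length(b) - 1L
  nT <- nrow(X)
  Y <- matrix(0, nT, ncol(X))
  z <- if (is.null(zi)) matrix(0, K, ncol(X)) else zi %o% X[1, ]
  for (n in seq_len(nT)) {
    x <- X[n, ]
    y <- b[1] * x + z[1, ]
    if (K > 1L) for (k in seq_len(K - 1L))
      z[k, ] <- b[k + 1] * x + z[k + 1, ] - a[k + 1] * y
    z[K, ] <- b[K + 1] * x - a[K + 1] * y
    Y[n, ] <- y
  }
  Y
}

# Zero-phase (forward-backward) filtering of the columns of X with
# odd-reflection edge padding and steady-state initial conditions.
filtfiltMatrix <- function(b, a, X) {
  nT <- nrow(X)
  padlen <- 3L * max(length(a), length(b))
  if (nT <= padlen + 1L)
    stop("time series too short for zero-phase filtering (need > ",
         padlen + 1L, " samples)")
  pre <- 2 * rep(1, padlen) %o% X[1, ] - X[(padlen + 1L):2L, , drop = FALSE]
  post <- 2 * rep(1, padlen) %o% X[nT, ] -
    X[(nT - 1L):(nT - padlen), , drop = FALSE]
  Xp <- rbind(pre, X, post)
  zi <- iirSteadyState(b, a)
  Y <- iirFilterMatrix(b, a, Xp, zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- iirFilterMatrix(b, a, Y, zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(padlen + 1L):(padlen + nT), , drop = FALSE]
}

#' Zero-phase low-pass filter a BOLD run
#'
#' Filters every voxel time series with a 4th-order Butterworth low-pass
#' applied forward and backward (zero phase, no temporal shift). Because two
#' passes square the magnitude response, the design cutoff is widened by the
#' standard two-pass compensation factor \code{(sqrt(2)-1)^(-1/8)} so the
#' combined response is -3 dB at \code{cutoffHz}; the passband below
#' 0.8 x cutoff retains at least 90\% amplitude and the stopband above
#' 2 x cutoff at most 10\%. DC is preserved exactly.
#'
#' @param bold a \code{\linkS4class{Bold4D}}.
#' @param cutoffHz low-pass cutoff in Hz (default 0.08); must be below the
#'   Nyquist frequency 1/(2 TR).
#' @return a filtered \code{\linkS4class{Bold4D}} (same shape, affine, TR).
#' @export
lowpass <- function(bold, cutoffHz = 0.08) {
  stopifnot(is(bold, "Bold4D"))
  nyquist <- 1 / (2 * bold@trSeconds)
  if (cutoffHz >= nyquist)
    stop(sprintf("cutoff %.3f Hz is not below the Nyquist frequency %.3f Hz",
                 cutoffHz, nyquist))
  order <- 4L
  comp <- (sqrt(2) - 1)^(-1 / (2 * order))
  design <- cutoffHz * comp
  if (design >= nyquist)
    stop("cutoff too close to Nyquist for the two-pass design")
  bf <- signal::butter(order, design / nyquist, type = "low")
  d <- dim(bold@data)
  X <- t(matrix(bold@data, prod(d[1:3]), d[4]))   # time x voxels
  Y <- filtfiltMatrix(bf$b, bf$a, X)
  new("Bold4D", data = array(t(Y), d), trSeconds = bold@trSeconds,
      affine = bold@affine)
}
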