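#' Canonical EEG frequency bands
#'
#' Clinical band edges used throughout the package: delta 1--4 Hz, theta
#' 4--8 Hz, alpha 8--13 Hz, beta 13--30 Hz.  Bands are half-open intervals
#' `[f_lo, f_hi)` so adjacent bands never double-count a frequency bin.
#'
#' @return Data frame with columns `band`, `f_lo`, `f_hi`.
#' @export
band_defs <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta"),
    f_lo = c(1, 4, 8, 13),
    f_hi = c(4, 8, 13, 30),
    stringsAsFactors = FALSE
  )
}

# Resolve a band given as a name or a length-2 numeric (f_lo, f_hi).
resolve_band <- function(band) {
  if (is.character(band)) {
    defs <- band_defs()
    i <- match(band, defs$band)
    if (is.na(i)) {
      stop("unknown band name: ", band, call. = FALSE)
    }
    c(defs$f_lo[i], defs$f_hi[i])
  } else if (is.numeric(band) && length(band) == 2L && band[1] < band[2] &&
             band[1] > 0) {
    as.numeric(band)
  } else {
    stop("`band` must be a band name or c(f_lo, f_hi) with 0 < f_lo < f_hi",
         call. = FALSE)
  }
}

#' Per-channel band power of an epoch
#'
#' Power (in \eqn{\mu V^2}, i.e. signal variance captured by the band) is
#' the mass of the single-taper periodogram falling in the half-open
#' interval `[f_lo, f_hi)`.  Each channel is linearly detrended and Hann
#' tapered (with power normalization) before the FFT, so a pure sinusoid
#' of amplitude \eqn{A} inside a band contributes close to \eqn{A^2/2}.
#'
#' @param epoch channels x samples numeric matrix.
#' @param band band name (see [band_defs()]) or `c(f_lo, f_hi)` in Hz.
#' @param spec an [epoch_spec()] supplying the sampling rate.
#' @return Numeric vector of per-channel power.
#' @examples
#' sp <- epoch_spec()
#' tt <- (seq_len(sp$n_samples) - 1) / sp$fs
#' ep <- matrix(sin(2 * pi * 10 * tt), 1, sp$n_samples)
#' band_power(ep, "alpha", sp)  # close to 0.5
#' @export
band_power <- function(epoch, band, spec = epoch_spec()) {
  stopifnot(is.matrix(epoch))
  fr <- resolve_band(band)
  if (fr[2] > spec$fs / 2 + 1e-9) {
    stop("band extends beyond the Nyquist frequency", call. = FALSE)
  }
  pg <- periodogram(epoch, spec$fs)
  sel <- pg$freq >= fr[1] & pg$freq < fr[2]
  colSums(pg$power[sel, , drop = FALSE])
}

# Single-taper (Hann) periodogram, channels in columns of the returned
# power matrix; power normalized so that summing over all positive
# frequencies approximates the per-channel variance.
periodogram <- function(epoch, fs) {
  n <- ncol(epoch)
  x <- t(epoch)                               # samples x channels
  # linear detrend per channel
  tt <- seq_len(n)
  tc <- tt - mean(tt)
  xc <- sweep(x, 2, colMeans(x))
  slope <- colSums(xc * tc) / sum(tc^2)
  xd <- xc - outer(tc, slope)
  w <- 0.5 - 0.5 * cos(2 * pi * (tt - 1) / (n - 1))
  u <- mean(w^2)
  X <- stats::mvfft(xd * w)
  kmax <- floor(n / 2)
  k <- 2:(kmax + 1)                           # positive-frequency bins
  P <- (Mod(X[k, , drop = FALSE])^2) / (n^2 * u)
  dbl <- !(k == kmax + 1 & n %% 2 == 0)       # Nyquist bin not doubled
  P <- P * ifelse(dbl, 2, 1)
  list(freq = (k - 1) * fs / n, power = P)
}
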