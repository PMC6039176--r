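#' Gamma-shaped hemodynamic response kernel
#'
#' A discrete gamma-variate impulse response at `rate` Hz with unit peak:
#' `h(t) = (t/s)^(shape-1) exp(-(t-peak)/s)` up to normalization, with the
#' scale chosen so the peak falls at `peakDelay`. The default (shape 3,
#' peak 2 s, support 0..8 s) peaks early enough that windowed response
#' means over 3-5 s post-onset sit near the peak of the stimulus-convolved
#' response, and is truncated to zero after `duration` so trial responses
#' never bleed into the next trial's pre-onset baseline.
#'
#' @param peakDelay time to peak in seconds.
#' @param duration kernel support in seconds (zero afterwards).
#' @param rate sampling rate, Hz.
#' @param shape gamma shape parameter (> 1).
#' @return A [HemodynamicModel-class].
#' @examples
#' hrf <- gammaHRF()
#' plot(seq(0, hrf@duration, by = 1), hrf@kernel, type = "h")
#' @export
gammaHRF <- function(peakDelay = 2, duration = 8, rate = 1, shape = 3) {
  if (shape <= 1) stop("shape must exceed 1 for a peaked kernel")
  scale <- peakDelay / (shape - 1)
  t <- seq(0, duration, by = 1 / rate)
  h <- t^(shape - 1) * exp(-t / scale)
  h <- h / max(h)
  new("HemodynamicModel", kernel = h, rate = rate,
      peakDelay = peakDelay, duration = duration)
}

#' Stimulus-convolved response kernel
#'
#' Convolution of a hemodynamic impulse response with a boxcar of the
#' stimulus duration: the noise-free unit-amplitude response time course a
#' voxel produces to one trial.
#'
#' @param hrf a [HemodynamicModel-class].
#' @param stimS stimulus duration in seconds.
#' @return Numeric vector of response samples from stimulus onset.
#' @export
stimulusResponseKernel <- function(hrf, stimS) {
  box <- rep(1, max(1L, round(stimS * hrf@rate)))
  lk <- length(hrf@kernel); lb <- length(box)
  out <- numeric(lk + lb - 1L)
  for (j in seq_len(lb)) out[j:(j + lk - 1L)] <- out[j:(j + lk - 1L)] + hrf@kernel
  out
}
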