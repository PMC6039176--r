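## Internal helpers.

## Evaluate expr under a local RNG state: the caller's .Random.seed is
## restored afterwards, so every generator is a pure function of its seed.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Half-up rounding (round() ties to even; the distance rule wants 0.5 -> 1).
roundHalfUp <- function(x) floor(x + 0.5)

## Order labels numerically when they all parse as numbers, else lexically.
## Returns a factor whose level order is the frequency order.
freqFactor <- function(labels) {
  u <- unique(labels)
  num <- suppressWarnings(as.numeric(u))
  lev <- if (!anyNA(num)) u[order(num)] else sort(u)
  factor(labels, levels = lev)
}

## Closed-window sample selector on a time grid.
windowIndex <- function(time, window) {
  if (length(window) != 2L || window[2L] < window[1L])
    stop("window must be c(from, to) with from <= to")
  idx <- which(time >= window[1L] - 1e-9 & time <= window[2L] + 1e-9)
  if (!length(idx)) stop("empty window: no samples fall inside [",
                         window[1L], ", ", window[2L], "]")
  idx
}

#' Significance tier labels
#'
#' Maps p-values to the conventional star tiers used in the figures:
#' `***` for p < 1e-3, `**` for p < 1e-2, `*` for p < 5e-2, `n.s.`
#' otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of the same length.
#' @examples
#' significanceStars(c(0.0005, 0.004, 0.04, 0.4))
#' @export
significanceStars <- function(p) {
  ifelse(p < 1e-3, "***", ifelse(p < 1e-2, "**", ifelse(p < 5e-2, "*", "n.s.")))
}

#' Blood Doppler frequency for an axial velocity
#'
#' The classical Doppler relation `f_D = 2 v f0 / c` linking axial blood
#' velocity to the slow-time Doppler frequency, used both to synthesize
#' blood signal and to convert a velocity band limit into a low-pass cutoff.
#'
#' @param velocity axial velocity in mm/s.
#' @param transmitFreq carrier frequency in Hz.
#' @param speedOfSound speed of sound in m/s.
#' @return Doppler frequency in Hz.
#' @examples
#' dopplerFrequency(3.1)  # ~60.4 Hz at 15 MHz, 1540 m/s
#' @export
dopplerFrequency <- function(velocity, transmitFreq = 15e6,
                             speedOfSound = 1540) {
  2 * (velocity * 1e-3) * transmitFreq / speedOfSound
}
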