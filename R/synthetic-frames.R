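#' Synthesize a complex ultrafast Doppler frame block
#'
#' Builds the slow-time signal the clutter filter has to separate: a
#' spatially coherent rank-1 tissue component (a shared sub-5 Hz sinusoid
#' scaled by a smooth spatial profile and `tissueAmplitude`), a blood
#' component per voxel (complex exponential at the Doppler frequency
#' `2 v f0 / c` with random initial phase and amplitude
#' `sqrt(bloodFraction)`), and white complex noise. The tissue term is
#' rank-1 by construction, so removing exactly one singular component
#' annihilates it -- giving the SVD clutter filter an analytic oracle.
#'
#' @param config an [AcquisitionConfig-class]; its validity is enforced
#'   (non-positive frame counts are rejected).
#' @param tissueAmplitude scalar >= 0 scaling the tissue component.
#' @param bloodFraction per-voxel blood signal power; scalar or (nz, nx)
#'   matrix.
#' @param bloodVelocity per-voxel axial blood velocity in mm/s; scalar or
#'   (nz, nx) matrix.
#' @param noiseSd standard deviation of the complex noise (total variance
#'   across real and imaginary parts); 1 by default.
#' @param dim spatial grid c(nz, nx), used when `bloodFraction` and
#'   `bloodVelocity` are scalars.
#' @param tissueFrequency frequency of the shared tissue sinusoid, Hz
#'   (must stay below 5 Hz to mimic slow tissue motion).
#' @param seed integer seed; the same seed reproduces the block exactly.
#' @return A [FrameBlock-class].
#' @examples
#' cfg <- acquisitionConfig(framesPerBlock = 100)
#' fb <- makeFrameBlock(cfg, tissueAmplitude = 10, bloodFraction = 1,
#'                      bloodVelocity = 3.1, dim = c(4, 4), seed = 1)
#' @export
makeFrameBlock <- function(config, tissueAmplitude = 0, bloodFraction = 1,
                           bloodVelocity = 0, noiseSd = 1, dim = c(8, 8),
                           tissueFrequency = 2, seed = NULL) {
  validObject(config)
  if (!is.finite(tissueAmplitude) || tissueAmplitude < 0)
    stop("tissueAmplitude must be finite and >= 0")
  if (any(!is.finite(bloodVelocity))) stop("blood velocities must be finite")
  if (is.matrix(bloodFraction)) dim <- base::dim(bloodFraction)
  else if (is.matrix(bloodVelocity)) dim <- base::dim(bloodVelocity)
  nz <- dim[1L]; nx <- dim[2L]; nv <- nz * nx
  bf <- matrix(bloodFraction, nz, nx)
  bv <- matrix(bloodVelocity, nz, nx)
  nt <- config@framesPerBlock
  fs <- config@frameRate
  tt <- (seq_len(nt) - 1L) / fs

  withSeed(seed, {
    ## rank-1 tissue: fixed smooth spatial profile x shared slow sinusoid
    prof <- 1 + 0.5 * outer(cos(2 * pi * (seq_len(nz) - 1L) / nz),
                            cos(2 * pi * (seq_len(nx) - 1L) / nx))
    tis <- tissueAmplitude * outer(as.vector(prof), sin(2 * pi * tissueFrequency * tt))

    fd <- dopplerFrequency(as.vector(bv), config@transmitFreq,
                           config@speedOfSound)
    phi <- runif(nv, 0, 2 * pi)
    blood <- sqrt(as.vector(bf)) *
      exp(1i * (outer(fd, 2 * pi * tt) + phi))

    noise <- if (noiseSd > 0)
      (matrix(rnorm(nv * nt), nv, nt) + 1i * matrix(rnorm(nv * nt), nv, nt)) *
        (noiseSd / sqrt(2))
    else matrix(0 + 0i, nv, nt)

    dat <- tis + blood + noise
    base::dim(dat) <- c(nz, nx, nt)
    frameBlock(dat, config)
  })
}
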