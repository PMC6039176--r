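#' SVD spatio-temporal clutter filter
#'
#' Reshapes the block into its space x time Casorati matrix, takes the
#' singular value decomposition, zeroes the largest singular components
#' (which carry the high-energy, spatially coherent tissue signal) and
#' reconstructs. Either a fixed number of components (`nRemove`) or an
#' energy-fraction rule (`energyFraction`: remove leading components until
#' their cumulative squared singular values reach that fraction of the
#' total) can be used.
#'
#' @param block a [FrameBlock-class].
#' @param nRemove number of leading singular components to remove
#'   (0 <= nRemove < number of frames).
#' @param energyFraction optional alternative to `nRemove`: target
#'   cumulative energy fraction in (0, 1).
#' @return A filtered [FrameBlock-class] of the same shape.
#' @examples
#' fb <- makeFrameBlock(acquisitionConfig(framesPerBlock = 50),
#'                      tissueAmplitude = 100, dim = c(4, 4), seed = 1)
#' filt <- svdClutterFilter(fb, nRemove = 1)
#' @export
svdClutterFilter <- function(block, nRemove = 1, energyFraction = NULL) {
  d <- dim(block@data)
  nt <- d[3L]
  C <- block@data
  dim(C) <- c(d[1L] * d[2L], nt)
  if (!is.null(energyFraction)) {
    if (energyFraction <= 0 || energyFraction >= 1)
      stop("energyFraction must lie in (0, 1)")
    dvals <- svd(C, nu = 0, nv = 0)$d
    nRemove <- which(cumsum(dvals^2) / sum(dvals^2) >= energyFraction)[1L]
  }
  nRemove <- as.integer(nRemove)
  if (nRemove < 0L || nRemove >= nt)
    stop("invalid rank: nRemove must satisfy 0 <= nRemove < ", nt)
  if (nRemove == 0L) return(block)
  sv <- svd(C, nu = nRemove, nv = nRemove)
  k <- seq_len(nRemove)
  clutter <- sv$u %*% (sv$d[k] * Conj(t(sv$v)))
  out <- C - clutter
  dim(out) <- d
  frameBlock(out, block@config)
}

#' Axial blood-velocity band selection
#'
#' Low-pass filters each voxel's complex slow-time signal with a Butterworth
#' filter at the Doppler cutoff `f_c = 2 vmax f0 / c`, retaining only
#' components with axial speed below `vmax`. The filter is applied
#' forward-backward (zero phase), so band selection does not shift the
#' power estimate in time; the complex signal is filtered symmetrically in
#' frequency, i.e. the flow direction (Doppler sign) is not resolved.
#'
#' @param block a [FrameBlock-class].
#' @param vmax maximum retained axial velocity, mm/s.
#' @param order Butterworth order (default 5).
#' @return A filtered [FrameBlock-class].
#' @export
velocityBandFilter <- function(block, vmax, order = 5) {
  if (!is.finite(vmax) || vmax <= 0) stop("vmax must be > 0")
  cfg <- block@config
  fc <- dopplerFrequency(vmax, cfg@transmitFreq, cfg@speedOfSound)
  fs <- cfg@frameRate
  if (fc >= fs / 2)
    stop("invalid cutoff: f_c = ", signif(fc, 4), " Hz reaches the Nyquist ",
         "frequency (", fs / 2, " Hz)")
  bt <- signal::butter(order, fc / (fs / 2), type = "low")
  d <- dim(block@data)
  C <- block@data
  dim(C) <- c(d[1L] * d[2L], d[3L])
  out <- C
  for (v in seq_len(nrow(C))) {
    out[v, ] <- complex(real = signal::filtfilt(bt, Re(C[v, ])),
                        imaginary = signal::filtfilt(bt, Im(C[v, ])))
  }
  dim(out) <- d
  frameBlock(out, cfg)
}

#' Power-Doppler image of a frame block
#'
#' The blood signal energy per voxel: the mean of `|s(t)|^2` over the
#' slow-time samples of the block (the discrete form of the power integral
#' over the block duration). Proportional to cerebral blood volume.
#'
#' @param block a [FrameBlock-class].
#' @return Numeric (nz, nx) matrix of non-negative power values.
#' @export
powerDoppler <- function(block) {
  d <- dim(block@data)
  if (prod(d) == 0L) stop("empty frame block")
  apply(Mod(block@data)^2, c(1L, 2L), mean)
}

#' Stack per-block power images into a series
#'
#' @param blocks list of [FrameBlock-class] objects (one per second).
#' @param band velocity band applied upstream, mm/s, or NA.
#' @return A [PowerDopplerSeries-class].
#' @export
powerDopplerSeries <- function(blocks, band = NA_real_) {
  imgs <- lapply(blocks, powerDoppler)
  d <- dim(imgs[[1L]])
  new("PowerDopplerSeries",
      values = array(unlist(imgs), c(d, length(imgs))),
      band = as.numeric(band))
}

#' Normalize a power-Doppler series to percent CBV
#'
#' Per voxel, `100 * (PD(t) - B) / B` with `B` the mean power over the
#' baseline window. Voxels with a non-positive baseline are flagged and set
#' to `NA`. By construction the mean of the output over the baseline window
#' is zero for every unflagged voxel.
#'
#' @param pd a [PowerDopplerSeries-class] or a (nz, nx, nt) array.
#' @param baselineWindow integer sample indices of the baseline.
#' @return A [CBVSeries-class].
#' @examples
#' pd <- array(100, c(2, 2, 10)); pd[1, 1, 6] <- 120
#' cbv <- percentCBV(pd, 1:5)
#' values(cbv)[1, 1, 6]   # +20 percent
#' @export
percentCBV <- function(pd, baselineWindow) {
  vals <- if (is(pd, "PowerDopplerSeries")) pd@values else pd
  d <- dim(vals)
  baselineWindow <- as.integer(baselineWindow)
  if (!length(baselineWindow) || any(baselineWindow < 1L) ||
      any(baselineWindow > d[3L]))
    stop("baselineWindow must be a non-empty sample range within the series")
  B <- apply(vals[, , baselineWindow, drop = FALSE], c(1L, 2L), mean)
  flagged <- B <= 0
  if (any(flagged))
    warning(sum(flagged), " voxel(s) with non-positive baseline flagged")
  Bsafe <- ifelse(flagged, NA_real_, B)
  out <- 100 * sweep(sweep(vals, c(1L, 2L), Bsafe, "-"), c(1L, 2L),
                     Bsafe, "/")
  cbvSeries(out, baselineWindow = baselineWindow, tr = 1, flagged = flagged)
}
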