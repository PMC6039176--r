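#' Build a ground-truth map
#'
#' @param dim spatial grid c(nz, nx).
#' @param bfIndex best-frequency index (1-based), scalar or matrix.
#' @param tuningCenter continuous tuning center on the frequency-index grid
#'   (defaults to `bfIndex`).
#' @param tuningWidth Gaussian tuning width in frequency steps (`Inf` =
#'   flat across frequencies).
#' @param amplitude peak response amplitude in %CBV.
#' @param responsive logical, scalar or matrix.
#' @param layerIndex optional cortical layer (1..10) per voxel.
#' @return A [GroundTruthMap-class].
#' @export
groundTruthMap <- function(dim, bfIndex = 3, tuningCenter = NULL,
                           tuningWidth = 1, amplitude = 20,
                           responsive = TRUE, layerIndex = NA_integer_) {
  m <- function(x, mode = "numeric") {
    a <- array(x, dim)
    storage.mode(a) <- mode
    a
  }
  if (is.null(tuningCenter)) tuningCenter <- bfIndex
  new("GroundTruthMap",
      bfIndex = m(bfIndex, "integer"), tuningCenter = m(tuningCenter),
      tuningWidth = m(tuningWidth), amplitude = m(amplitude),
      responsive = m(responsive, "logical"),
      layerIndex = m(layerIndex, "integer"))
}

## Gaussian tuning factor on the frequency-index grid; width Inf gives a
## flat factor of 1 (the exponent collapses to 0).
tuningFactor <- function(freqIndex, center, width) {
  exp(-(freqIndex - center)^2 / (2 * width^2))
}

#' Simulate a trial-structured %CBV series with tonotopic ground truth
#'
#' Generates a 1 Hz %CBV series on the ground-truth voxel grid: for each
#' trial with frequency index `i`, every responsive voxel adds
#' `amplitude * exp(-(i - center)^2 / (2 width^2))` times the
#' stimulus-convolved hemodynamic kernel at the trial onset; i.i.d.
#' Gaussian noise of sd `noiseSd` is added per sample. Trials follow each
#' other with a uniform jitter drawn from the protocol's jitter range; the
#' inter-trial gap is rounded to the 1 Hz acquisition grid (acquisition is
#' synchronized with trial starts), so event onsets land on whole seconds.
#'
#' @param protocol a [TrialProtocol-class].
#' @param truth a [GroundTruthMap-class].
#' @param hrf a [HemodynamicModel-class] (at 1 Hz).
#' @param noiseSd per-sample noise sd in %CBV (>= 0).
#' @param seed integer seed.
#' @return A list with elements `cbv` (a [CBVSeries-class]) and `events`
#'   (data.frame with columns `onset_s`, `label`, `freq_index`).
#' @examples
#' tr <- makeTrialSeries(trialProtocol(), groundTruthMap(c(2, 2)),
#'                       noiseSd = 0, seed = 1)
#' head(tr$events)
#' @export
makeTrialSeries <- function(protocol, truth, hrf = gammaHRF(), noiseSd = 1,
                            seed = NULL) {
  validObject(protocol)
  if (!is.finite(noiseSd) || noiseSd < 0) stop("noiseSd must be >= 0")
  freqs <- protocol@frequencies
  nF <- length(freqs)
  nTrial <- nF * protocol@trialsPerFrequency
  dims <- dim(truth@amplitude)
  nv <- prod(dims)
  rk <- stimulusResponseKernel(hrf, protocol@stimS)
  lrk <- length(rk)

  ## per-voxel response scale for each frequency (nF x nv)
  amp <- as.vector(truth@amplitude) * as.vector(truth@responsive)
  ctr <- as.vector(truth@tuningCenter)
  wid <- as.vector(truth@tuningWidth)
  scal <- vapply(seq_len(nF),
                 function(i) amp * tuningFactor(i, ctr, wid),
                 numeric(nv))          # nv x nF

  withSeed(seed, {
    freqIdx <- sample(rep(seq_len(nF), protocol@trialsPerFrequency))
    jit <- runif(nTrial, protocol@jitterRange[1L], protocol@jitterRange[2L])
    gap <- round(protocol@baselineS + protocol@stimS + protocol@postS + jit)
    starts <- cumsum(c(0, gap[-nTrial]))
    onsets <- starts + protocol@baselineS
    total <- starts[nTrial] + gap[nTrial] + lrk

    series <- matrix(0, total, nv)
    for (k in seq_len(nTrial)) {
      idx <- onsets[k] + seq_len(lrk)      # sample index t+1 holds time t
      series[idx, ] <- series[idx, ] + outer(rk, scal[, freqIdx[k]])
    }
    if (noiseSd > 0)
      series <- series + matrix(rnorm(total * nv, sd = noiseSd), total, nv)

    vals <- array(t(series), c(dims[1L], dims[2L], total))
    events <- data.frame(onset_s = onsets,
                         label = as.character(freqs[freqIdx]),
                         freq_index = freqIdx)
    list(cbv = cbvSeries(vals, tr = 1), events = events)
  })
}

#' Simulate a sharp functional transition patch
#'
#' Builds the synthetic input of the functional-resolution analysis: an
#' `nRows` x `nCols` voxel patch whose columns follow either a steep
#' responsiveness gradient (per-column peak amplitudes, flat across
#' frequencies) or a tonotopic gradient (Gaussian tuning whose center
#' drifts by a fixed fraction of a frequency step per column at constant
#' amplitude). Responses are scalar windowed %CBV values, one per trial,
#' frequency and voxel, with i.i.d. Gaussian noise.
#'
#' @param nRows,nCols patch dimensions (rows x columns; the gradient runs
#'   along columns).
#' @param mode `"responsiveness"` or `"tuning"`.
#' @param stepParams mode-specific parameters. Responsiveness:
#'   `columnAmplitudes` (length `nCols`). Tuning: `centerStep` (frequency
#'   steps per column), `width` (frequency steps, default 1), `amplitude`
#'   (default 20), `centerStart` (default centers the drift on the
#'   frequency grid).
#' @param noiseSd trial noise sd in %CBV.
#' @param protocol a [TrialProtocol-class] (frequencies and trial counts).
#' @param seed integer seed.
#' @return A list with `responses` (a [ResponseSet-class] whose coords are
#'   (row, col) in voxel-pitch units) and `truth` (a
#'   [GroundTruthMap-class]).
#' @examples
#' p <- makeTransitionPatch(4, 4, "responsiveness",
#'        list(columnAmplitudes = c(20, 14, 8, 2)), noiseSd = 0, seed = 1)
#' @export
makeTransitionPatch <- function(nRows, nCols,
                                mode = c("responsiveness", "tuning"),
                                stepParams = list(), noiseSd = 0,
                                protocol = trialProtocol(), seed = NULL) {
  mode <- match.arg(mode)
  validObject(protocol)
  nF <- length(protocol@frequencies)
  n <- protocol@trialsPerFrequency
  nv <- nRows * nCols
  col <- rep(seq_len(nCols), each = nRows)

  if (mode == "responsiveness") {
    ca <- stepParams$columnAmplitudes
    if (is.null(ca)) stop("responsiveness mode requires stepParams$columnAmplitudes")
    if (length(ca) != nCols) stop("columnAmplitudes must have one value per column")
    ampV <- ca[col]
    ctrV <- rep((nF + 1) / 2, nv)
    widV <- rep(Inf, nv)
  } else {
    step <- stepParams$centerStep
    if (is.null(step)) stop("tuning mode requires stepParams$centerStep")
    wid <- if (is.null(stepParams$width)) 1 else stepParams$width
    amp <- if (is.null(stepParams$amplitude)) 20 else stepParams$amplitude
    start <- if (is.null(stepParams$centerStart))
      (nF + 1) / 2 - (nCols - 1) * step / 2 else stepParams$centerStart
    ampV <- rep(amp, nv)
    ctrV <- start + (col - 1L) * step
    widV <- rep(wid, nv)
  }

  ## analytic mean response, nF x nv
  mu <- vapply(seq_len(nv),
               function(v) ampV[v] * tuningFactor(seq_len(nF), ctrV[v], widV[v]),
               numeric(nF))
  labels <- rep(as.character(protocol@frequencies), each = n)
  labIdx <- rep(seq_len(nF), each = n)

  vals <- withSeed(seed, {
    m <- mu[labIdx, , drop = FALSE]
    if (noiseSd > 0) m <- m + matrix(rnorm(length(m), sd = noiseSd), nrow(m))
    m
  })

  coords <- cbind(row = rep(seq_len(nRows), nCols), col = col)
  truth <- new("GroundTruthMap",
               bfIndex = array(apply(mu, 2L, which.max), c(nRows, nCols)),
               tuningCenter = array(ctrV, c(nRows, nCols)),
               tuningWidth = array(widV, c(nRows, nCols)),
               amplitude = array(ampV, c(nRows, nCols)),
               responsive = array(ampV > 0, c(nRows, nCols)),
               layerIndex = array(NA_integer_, c(nRows, nCols)))
  list(responses = responseSet(vals, labels, coords), truth = truth)
}
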