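#' @import methods
#' @importFrom stats approx convolve cor cor.test pf pt quantile rnorm runif sd
#'   setNames wilcox.test
#' @importFrom utils combn
NULL

## ---------------------------------------------------------------------------
## Acquisition / protocol configuration
## ---------------------------------------------------------------------------

#' Ultrafast Doppler acquisition configuration
#'
#' Describes one power-Doppler acquisition block: a burst of compound frames
#' acquired at `frameRate` Hz, repeated once per `blockPeriod` seconds, with
#' the ultrasound carrier at `transmitFreq` Hz. The defaults correspond to a
#' 15 MHz probe acquiring 300 frames at 500 Hz every second, with
#' 100 x 100 x 400 um voxels.
#'
#' @slot frameRate slow-time frame rate in Hz.
#' @slot framesPerBlock number of frames per acquisition block.
#' @slot blockPeriod seconds between the starts of consecutive blocks.
#' @slot transmitFreq ultrasound transmit (carrier) frequency in Hz.
#' @slot speedOfSound assumed speed of sound in tissue, m/s.
#' @slot voxelPitch voxel pitch (depth, lateral, elevation) in micrometres.
#'
#' @seealso [acquisitionConfig()]
#' @export
setClass("AcquisitionConfig",
  representation(
    frameRate      = "numeric",
    framesPerBlock = "integer",
    blockPeriod    = "numeric",
    transmitFreq   = "numeric",
    speedOfSound   = "numeric",
    voxelPitch     = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    vals <- c(object@frameRate, object@framesPerBlock, object@blockPeriod,
              object@transmitFreq, object@speedOfSound, object@voxelPitch)
    if (any(!is.finite(vals)) || any(vals <= 0))
      msg <- c(msg, "invalid config: all fields must be finite and strictly positive")
    else if (object@framesPerBlock / object@frameRate > object@blockPeriod + 1e-9)
      msg <- c(msg, "invalid config: framesPerBlock / frameRate must not exceed blockPeriod")
    if (length(object@voxelPitch) != 3L)
      msg <- c(msg, "voxelPitch must have 3 components (depth, lateral, elevation)")
    if (length(msg)) msg else TRUE
  })

#' Create an acquisition configuration
#'
#' @param frameRate slow-time frame rate (Hz).
#' @param framesPerBlock frames per power-Doppler block.
#' @param blockPeriod seconds between block starts.
#' @param transmitFreq ultrasound carrier frequency (Hz).
#' @param speedOfSound speed of sound in tissue (m/s).
#' @param voxelPitch voxel pitch in micrometres, length 3.
#' @return An [AcquisitionConfig-class] object.
#' @examples
#' acquisitionConfig()
#' @export
acquisitionConfig <- function(frameRate = 500, framesPerBlock = 300,
                              blockPeriod = 1, transmitFreq = 15e6,
                              speedOfSound = 1540,
                              voxelPitch = c(100, 100, 400)) {
  new("AcquisitionConfig",
      frameRate = as.numeric(frameRate),
      framesPerBlock = as.integer(framesPerBlock),
      blockPeriod = as.numeric(blockPeriod),
      transmitFreq = as.numeric(transmitFreq),
      speedOfSound = as.numeric(speedOfSound),
      voxelPitch = as.numeric(voxelPitch))
}

#' Trial protocol for event-related stimulation
#'
#' One trial is `baselineS` seconds of silence, `stimS` seconds of stimulus,
#' `postS` seconds of return to baseline, followed by a uniform random jitter
#' in `jitterRange` before the next trial. `frequencies` are the pure-tone
#' frequencies presented (Hz, strictly increasing), each played
#' `trialsPerFrequency` times in random order.
#'
#' @slot baselineS pre-stimulus silence, s.
#' @slot stimS stimulus duration, s.
#' @slot postS post-stimulus silence, s.
#' @slot jitterRange two ordered values, the inter-trial jitter bounds in s.
#' @slot frequencies stimulus frequencies in Hz, strictly increasing.
#' @slot trialsPerFrequency repetitions per frequency (>= 2).
#' @seealso [trialProtocol()]
#' @export
setClass("TrialProtocol",
  representation(
    baselineS = "numeric", stimS = "numeric", postS = "numeric",
    jitterRange = "numeric", frequencies = "numeric",
    trialsPerFrequency = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@frequencies) < 1L)
      msg <- c(msg, "invalid protocol: empty frequency list")
    else if (any(diff(object@frequencies) <= 0))
      msg <- c(msg, "invalid protocol: frequencies must be strictly increasing")
    if (length(object@jitterRange) != 2L || diff(object@jitterRange) < 0)
      msg <- c(msg, "invalid protocol: jitter bounds must be ordered")
    if (object@trialsPerFrequency < 2L)
      msg <- c(msg, "invalid protocol: trialsPerFrequency must be >= 2")
    if (any(c(object@baselineS, object@stimS, object@postS) < 0))
      msg <- c(msg, "invalid protocol: epoch durations must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Create a trial protocol
#'
#' Defaults follow the standard tone-mapping protocol: 10 s baseline, 3 s
#' tone, 8 s return to baseline, 1-3 s jitter, five log-spaced tones between
#' 602 Hz and 19234 Hz, 10 trials per frequency.
#'
#' @param baselineS,stimS,postS epoch durations in seconds.
#' @param jitterRange inter-trial jitter bounds in seconds.
#' @param frequencies tone frequencies in Hz (strictly increasing).
#' @param trialsPerFrequency repetitions per frequency.
#' @return A [TrialProtocol-class] object.
#' @examples
#' trialProtocol()
#' @export
trialProtocol <- function(baselineS = 10, stimS = 3, postS = 8,
                          jitterRange = c(1, 3),
                          frequencies = c(602, 1430, 3400, 8087, 19234),
                          trialsPerFrequency = 10) {
  new("TrialProtocol",
      baselineS = as.numeric(baselineS), stimS = as.numeric(stimS),
      postS = as.numeric(postS), jitterRange = as.numeric(jitterRange),
      frequencies = as.numeric(frequencies),
      trialsPerFrequency = as.integer(trialsPerFrequency))
}

#' Discrete hemodynamic response model
#'
#' A non-negative impulse response sampled at `rate` Hz with unit peak,
#' playing the role the canonical HRF plays in fMRI: the typical vascular
#' response to a brief stimulus.
#'
#' @slot kernel impulse response samples, non-negative, max = 1.
#' @slot rate sampling rate in Hz.
#' @slot peakDelay time to peak, s.
#' @slot duration kernel support, s (kernel is zero afterwards).
#' @seealso [gammaHRF()]
#' @export
setClass("HemodynamicModel",
  representation(kernel = "numeric", rate = "numeric",
                 peakDelay = "numeric", duration = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@kernel < 0) || any(!is.finite(object@kernel)))
      msg <- c(msg, "kernel must be finite and non-negative")
    if (abs(max(object@kernel) - 1) > 1e-9)
      msg <- c(msg, "kernel must have unit peak")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Complex ultrafast Doppler frame block
#'
#' One acquisition block: the beamformed complex slow-time signal over a
#' (depth x lateral x frame) grid, with its acquisition configuration.
#' The slow-time axis holds `framesPerBlock` samples at `frameRate` Hz.
#'
#' @slot data complex array, dim (nz, nx, nt).
#' @slot config an [AcquisitionConfig-class].
#' @export
setClass("FrameBlock",
  representation(data = "array", config = "AcquisitionConfig"),
  validity = function(object) {
    msg <- character()
    if (!is.complex(object@data))
      msg <- c(msg, "data must be a complex array")
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must have dim (nz, nx, nt)")
    else if (dim(object@data)[3L] != object@config@framesPerBlock)
      msg <- c(msg, "slow-time length must equal config@framesPerBlock")
    if (any(!is.finite(object@data)))
      msg <- c(msg, "data must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a frame block
#' @param data complex array (nz, nx, nt).
#' @param config an [AcquisitionConfig-class].
#' @return A [FrameBlock-class].
#' @export
frameBlock <- function(data, config) new("FrameBlock", data = data, config = config)

#' Power-Doppler image series
#'
#' One non-negative power value per voxel per block (typically 1 Hz). The
#' `band` slot records the axial-velocity band selection applied before the
#' power integral (`NA` if none, otherwise the vmax in mm/s).
#'
#' @slot values non-negative array, dim (nz, nx, nblocks).
#' @slot band maximum axial velocity retained, mm/s, or `NA`.
#' @export
setClass("PowerDopplerSeries",
  representation(values = "array", band = "numeric"),
  validity = function(object) {
    if (any(object@values < 0, na.rm = TRUE))
      "power-Doppler values must be non-negative" else TRUE
  })

#' Percent cerebral blood volume series
#'
#' Per-voxel percent change of power Doppler relative to a baseline window,
#' sampled at `1/tr` Hz. Voxels whose baseline was non-positive are flagged
#' and set to `NA`.
#'
#' @slot values array, dim (nz, nx, nt), percent change.
#' @slot baselineWindow integer sample indices used for normalization
#'   (possibly empty when the series was synthesized directly in %CBV units).
#' @slot tr sampling period in seconds.
#' @slot flagged logical (nz, nx) matrix marking degenerate-baseline voxels.
#' @export
setClass("CBVSeries",
  representation(values = "array", baselineWindow = "integer",
                 tr = "numeric", flagged = "matrix"))

#' Create a %CBV series
#' @param values array (nz, nx, nt) of percent change.
#' @param baselineWindow integer sample indices used for normalization.
#' @param tr sampling period (s).
#' @param flagged logical matrix of degenerate-baseline voxels.
#' @return A [CBVSeries-class].
#' @export
cbvSeries <- function(values, baselineWindow = integer(), tr = 1,
                      flagged = NULL) {
  d <- dim(values)
  if (is.null(flagged)) flagged <- matrix(FALSE, d[1L], d[2L])
  new("CBVSeries", values = values, baselineWindow = as.integer(baselineWindow),
      tr = as.numeric(tr), flagged = flagged)
}

#' Ground-truth map for synthetic data
#'
#' Per-voxel ground truth used by the synthetic generators and by
#' parameter-recovery tests. `bfIndex` is 1-based into the protocol's
#' frequency list; `tuningCenter` keeps the (possibly non-integer) tuning
#' center on the same index grid; `tuningWidth` is in frequency-step units
#' (`Inf` = untuned / flat across frequencies).
#'
#' @slot bfIndex integer array, best-frequency index (1-based), NA where
#'   unresponsive.
#' @slot tuningCenter numeric array, continuous tuning center on the
#'   frequency-index grid.
#' @slot tuningWidth numeric array, Gaussian tuning width in frequency steps.
#' @slot amplitude numeric array, peak response amplitude in %CBV (>= 0).
#' @slot responsive logical array.
#' @slot layerIndex integer array, cortical layer (1..10) or NA.
#' @export
setClass("GroundTruthMap",
  representation(bfIndex = "array", tuningCenter = "array",
                 tuningWidth = "array", amplitude = "array",
                 responsive = "array", layerIndex = "array"),
  validity = function(object) {
    msg <- character()
    if (any(object@amplitude < 0, na.rm = TRUE))
      msg <- c(msg, "amplitude must be non-negative")
    if (any(object@responsive & is.na(object@bfIndex)))
      msg <- c(msg, "bfIndex must be defined wherever responsive is TRUE")
    if (length(msg)) msg else TRUE
  })

#' Trial-epoched %CBV tensor
#'
#' Peristimulus %CBV over (trial, peristimulus second, voxel), with one
#' stimulus label per trial and a common peristimulus time grid (seconds
#' relative to stimulus onset).
#'
#' @slot values array, dim (ntrial, ntime, nvoxel).
#' @slot labels character, one stimulus label per trial.
#' @slot time numeric peristimulus grid (s relative to onset).
#' @slot coords voxel coordinates, nvoxel x 2 matrix (may have 0 rows).
#' @export
setClass("TrialTensor",
  representation(values = "array", labels = "character",
                 time = "numeric", coords = "matrix"),
  validity = function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 3L) msg <- c(msg, "values must be (trial, time, voxel)")
    else {
      if (length(object@labels) != d[1L])
        msg <- c(msg, "one label per trial required")
      if (length(object@time) != d[2L])
        msg <- c(msg, "time grid must match the peristimulus axis")
      if (nrow(object@coords) > 0L && nrow(object@coords) != d[3L])
        msg <- c(msg, "coords must have one row per voxel")
    }
    if (length(msg)) msg else TRUE
  })

#' Scalar windowed responses per trial and voxel
#'
#' A trial x voxel matrix of scalar responses (windowed %CBV), one stimulus
#' label per trial, with optional in-plane voxel coordinates (voxel-pitch
#' units). This is the common currency of the tuning, decoding and
#' resolution analyses.
#'
#' @slot values numeric matrix, trial x voxel.
#' @slot labels character, one per trial.
#' @slot coords nvoxel x 2 matrix of in-plane coordinates (may have 0 rows).
#' @seealso [responseSet()]
#' @export
setClass("ResponseSet",
  representation(values = "matrix", labels = "character", coords = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@labels))
      msg <- c(msg, "one label per trial (row) required")
    if (nrow(object@coords) > 0L && nrow(object@coords) != ncol(object@values))
      msg <- c(msg, "coords must have one row per voxel (column)")
    if (length(msg)) msg else TRUE
  })

#' Create a response set
#' @param values trial x voxel matrix of scalar responses.
#' @param labels stimulus label per trial.
#' @param coords optional nvoxel x 2 coordinate matrix.
#' @return A [ResponseSet-class].
#' @export
responseSet <- function(values, labels, coords = NULL) {
  if (is.null(coords)) coords <- matrix(numeric(), 0L, 2L)
  new("ResponseSet", values = as.matrix(values),
      labels = as.character(labels), coords = as.matrix(coords))
}

#' Per-voxel frequency tuning statistics
#'
#' Mean tuning curve (response per frequency) with its standard error,
#' best-frequency index, one-way ANOVA p-value across frequencies, and
#' pairwise Wilcoxon rank-sum post-hoc p-values (computed only where the
#' ANOVA passed its threshold). `bfCourse`/`time` optionally hold the mean
#' peristimulus time course at each voxel's best frequency.
#'
#' @slot curve nfreq x nvoxel matrix of mean responses (%CBV).
#' @slot sem nfreq x nvoxel matrix of standard errors across trials.
#' @slot frequencies character, ordered frequency labels.
#' @slot bfIndex integer per voxel, argmax of the curve (1-based).
#' @slot anovaP numeric per voxel.
#' @slot posthocP npair x nvoxel matrix (NA where not computed).
#' @slot valid logical per voxel (FALSE when a frequency had < 2 trials).
#' @slot bfCourse ntime x nvoxel matrix (0 x 0 when unavailable).
#' @slot time peristimulus grid of `bfCourse`.
#' @export
setClass("TuningMap",
  representation(curve = "matrix", sem = "matrix", frequencies = "character",
                 bfIndex = "integer", anovaP = "numeric", posthocP = "matrix",
                 valid = "logical", bfCourse = "matrix", time = "numeric"),
  validity = function(object) {
    msg <- character()
    ok <- !is.na(object@anovaP)
    if (any(object@anovaP[ok] < 0 | object@anovaP[ok] > 1))
      msg <- c(msg, "anovaP must lie in [0, 1]")
    mism <- which(object@valid &
                  object@bfIndex != apply(object@curve, 2L, which.max))
    if (length(mism))
      msg <- c(msg, "bfIndex must be the argmax of the tuning curve")
    if (length(msg)) msg else TRUE
  })

#' FIR impulse-response estimates
#'
#' Per-voxel, per-frequency impulse responses at 1 Hz lags, estimated by an
#' FIR GLM (one free coefficient per frequency x lag).
#'
#' @slot kernels array, dim (nlag, nfreq, nvoxel).
#' @slot lags numeric lag grid in seconds.
#' @slot frequencies character frequency labels.
#' @export
setClass("ImpulseResponseSet",
  representation(kernels = "array", lags = "numeric", frequencies = "character"),
  validity = function(object) {
    if (dim(object@kernels)[1L] != length(object@lags))
      "kernel length must equal the lag window length" else TRUE
  })

#' Best-frequency map with display mask
#'
#' A (possibly smoothed, hence non-integer) best-frequency value per voxel
#' on a 3-D grid, a logical display mask, and the provenance of the
#' thresholds that produced the mask.
#'
#' @slot bf numeric 3-D array (NA where BF undefined).
#' @slot mask logical 3-D array; masked voxels always have a defined BF.
#' @slot provenance list of thresholds used.
#' @export
setClass("BFMap",
  representation(bf = "array", mask = "array", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@bf), dim(object@mask)))
      msg <- c(msg, "bf and mask must share dimensions")
    else if (any(object@mask & is.na(object@bf)))
      msg <- c(msg, "mask must be a subset of voxels with defined bf")
    if (length(msg)) msg else TRUE
  })

#' Create a best-frequency map
#' @param bf numeric array of best-frequency values (NA allowed).
#' @param mask logical array, same dim.
#' @param provenance list of thresholds used to build the mask.
#' @return A [BFMap-class].
#' @export
bfMap <- function(bf, mask, provenance = list()) {
  bf <- as.array(bf); mask <- as.array(mask)
  if (length(dim(bf)) == 2L) { dim(bf) <- c(dim(bf), 1L); dim(mask) <- dim(bf) }
  new("BFMap", bf = bf, mask = mask, provenance = provenance)
}

#' Multivoxel decoding dataset
#'
#' Trial x voxel response matrix with one class label per trial and an
#' optional slice/session group per trial.
#'
#' @slot X numeric trial x voxel matrix.
#' @slot y character class label per trial.
#' @slot groups character per trial (length 0 when absent).
#' @seealso [decodingDataset()]
#' @export
setClass("DecodingDataset",
  representation(X = "matrix", y = "character", groups = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@X) != length(object@y))
      msg <- c(msg, "rows of X must match the label vector")
    if (length(object@y) && min(table(object@y)) < 2L)
      msg <- c(msg, "every class needs at least 2 trials")
    if (length(object@groups) && length(object@groups) != length(object@y))
      msg <- c(msg, "groups must have one entry per trial")
    if (length(msg)) msg else TRUE
  })

#' Create a decoding dataset
#' @param X trial x voxel response matrix.
#' @param y class label per trial.
#' @param groups optional slice/session id per trial.
#' @return A [DecodingDataset-class].
#' @export
decodingDataset <- function(X, y, groups = character()) {
  new("DecodingDataset", X = as.matrix(X), y = as.character(y),
      groups = as.character(groups))
}

#' Decoding result
#'
#' @slot accuracy overall leave-one-out accuracy in \[0, 1\].
#' @slot perClass named per-class accuracies.
#' @slot null accuracies under label permutation (length 0 when no
#'   permutation test was run).
#' @slot pValue permutation p-value, floored at 1/n_perm (NA without test).
#' @slot significant logical, observed accuracy above the null quantile.
#' @slot details list (decoder, predictions, seeds, flags).
#' @export
setClass("DecodingResult",
  representation(accuracy = "numeric", perClass = "numeric", null = "numeric",
                 pValue = "numeric", significant = "logical", details = "list"),
  validity = function(object) {
    if (object@accuracy < 0 || object@accuracy > 1)
      "accuracy must lie in [0, 1]" else TRUE
  })

#' Functional spatial-resolution curves
#'
#' Fractions of voxel pairs judged dissimilar (voxel main effect =
#' responsiveness; voxel x frequency interaction = tuning) per inter-voxel
#' distance, the per-distance 95th percentile of a randomization null, and
#' the shortest significant distance per criterion in micrometres.
#'
#' @slot distances integer distances in voxel-pitch units.
#' @slot nPairs pairs per distance.
#' @slot fracResponsiveness observed dissimilar fraction per distance.
#' @slot fracTuning observed dissimilar fraction per distance.
#' @slot nullP95 ndist x 2 matrix (columns responsiveness, tuning).
#' @slot resolution named length-2 numeric (um; NA when never significant).
#' @slot pitch voxel pitch in micrometres.
#' @slot alpha per-pair significance level.
#' @export
setClass("ResolutionCurve",
  representation(distances = "integer", nPairs = "integer",
                 fracResponsiveness = "numeric", fracTuning = "numeric",
                 nullP95 = "matrix", resolution = "numeric",
                 pitch = "numeric", alpha = "numeric"),
  validity = function(object) {
    fr <- c(object@fracResponsiveness, object@fracTuning)
    msg <- character()
    if (any(fr < 0 | fr > 1, na.rm = TRUE))
      msg <- c(msg, "fractions must lie in [0, 1]")
    res <- object@resolution[!is.na(object@resolution)]
    if (length(res) && !all((res / object@pitch) %in% object@distances))
      msg <- c(msg, "resolution must correspond to one of the tested distances")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig:", object@framesPerBlock, "frames @",
      object@frameRate, "Hz every", object@blockPeriod, "s; f0 =",
      object@transmitFreq / 1e6, "MHz; c =", object@speedOfSound, "m/s\n")
})

setMethod("show", "TrialProtocol", function(object) {
  cat("TrialProtocol:", object@baselineS, "s baseline +", object@stimS,
      "s stim +", object@postS, "s post; jitter [",
      object@jitterRange[1], ",", object@jitterRange[2], "] s;",
      length(object@frequencies), "frequencies x",
      object@trialsPerFrequency, "trials\n")
})

setMethod("show", "FrameBlock", function(object) {
  d <- dim(object@data)
  cat("FrameBlock:", d[1], "x", d[2], "voxels x", d[3], "frames @",
      object@config@frameRate, "Hz\n")
})

setMethod("show", "CBVSeries", function(object) {
  d <- dim(object@values)
  cat("CBVSeries:", d[1], "x", d[2], "voxels x", d[3], "samples (TR",
      object@tr, "s);", sum(object@flagged), "flagged voxels\n")
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@values)
  cat("TrialTensor:", d[1], "trials x", d[2], "peristimulus samples x",
      d[3], "voxels;", length(unique(object@labels)), "stimulus labels\n")
})

setMethod("show", "ResponseSet", function(object) {
  cat("ResponseSet:", nrow(object@values), "trials x", ncol(object@values),
      "voxels;", length(unique(object@labels)), "labels\n")
})

setMethod("show", "TuningMap", function(object) {
  cat("TuningMap:", nrow(object@curve), "frequencies x", ncol(object@curve),
      "voxels;", sum(object@anovaP < 1e-3, na.rm = TRUE),
      "voxels with ANOVA p < 1e-3\n")
})

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult: accuracy", format(object@accuracy, digits = 3))
  if (length(object@null))
    cat(", p", format(object@pValue, digits = 3), "(",
        length(object@null), "permutations )")
  cat("\n")
})

setMethod("show", "ResolutionCurve", function(object) {
  fmt <- function(x) if (is.na(x)) "undefined" else paste0(x, " um")
  cat("ResolutionCurve: responsiveness",
      fmt(object@resolution[["responsiveness"]]), "; tuning",
      fmt(object@resolution[["tuning"]]), "\n")
})
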