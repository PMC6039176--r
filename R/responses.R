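#' Epoch a %CBV series into trials
#'
#' Cuts the series into peristimulus windows around each event onset,
#' re-referencing time to the onset and subtracting each trial's own
#' pre-onset mean (per-trial baseline correction; global baselines drift
#' over long sessions). Trials whose window would overrun the series are
#' dropped with a warning.
#'
#' @param cbv a [CBVSeries-class] (1 Hz).
#' @param events data.frame with columns `onset_s` (seconds, on the 1 Hz
#'   grid) and `label`.
#' @param window peristimulus window c(from, to) in seconds relative to
#'   onset (closed, inclusive of both endpoints on the grid).
#' @return A [TrialTensor-class]; voxels are the flattened (z, x) grid with
#'   coordinates in the `coords` slot.
#' @export
epochTrials <- function(cbv, events, window = c(-10, 11)) {
  d <- dim(cbv@values)
  nT <- d[3L]
  offs <- seq(ceiling(window[1L]), floor(window[2L]))
  onsets <- round(events$onset_s)
  keep <- onsets + offs[1L] >= 0 & onsets + offs[length(offs)] <= nT - 1L
  nDrop <- sum(!keep)
  if (nDrop > 0L)
    warning(nDrop, " trial(s) dropped: peristimulus window outside series")
  if (!any(keep)) stop("no trial fits inside the series")
  onsets <- onsets[keep]
  vox <- matrix(cbv@values, d[1L] * d[2L], nT)  # voxel x time
  nv <- nrow(vox)
  vals <- array(NA_real_, c(length(onsets), length(offs), nv))
  pre <- which(offs < 0)
  for (k in seq_along(onsets)) {
    tr <- t(vox[, onsets[k] + offs + 1L, drop = FALSE])  # time x voxel
    if (length(pre)) tr <- sweep(tr, 2L, colMeans(tr[pre, , drop = FALSE]))
    vals[k, , ] <- tr
  }
  coords <- cbind(z = rep(seq_len(d[1L]), d[2L]),
                  x = rep(seq_len(d[2L]), each = d[1L]))
  new("TrialTensor", values = vals,
      labels = as.character(events$label)[keep],
      time = as.numeric(offs), coords = coords)
}

#' Windowed scalar response per trial and voxel
#'
#' Arithmetic mean of the peristimulus samples whose time lies in the
#' closed window. On the 1 Hz grid, a 3-5 s window averages the samples at
#' 3, 4 and 5 s after onset.
#'
#' @param tensor a [TrialTensor-class].
#' @param window c(from, to) in seconds post-onset.
#' @return Numeric trial x voxel matrix.
#' @export
windowedResponse <- function(tensor, window = c(3, 5)) {
  idx <- windowIndex(tensor@time, window)
  d <- dim(tensor@values)
  out <- apply(tensor@values[, idx, , drop = FALSE], c(1L, 3L), mean)
  dim(out) <- c(d[1L], d[3L])
  out
}

#' Windowed responses as a ResponseSet
#'
#' Convenience wrapper around [windowedResponse()] keeping the trial labels
#' and voxel coordinates together with the response matrix.
#'
#' @inheritParams windowedResponse
#' @return A [ResponseSet-class].
#' @export
windowedResponses <- function(tensor, window = c(3, 5)) {
  responseSet(windowedResponse(tensor, window), tensor@labels, tensor@coords)
}

## Vectorized one-way ANOVA across voxels (columns).
## Returns list(F, p, means (K x V), sem, nk). Zero within-group variance
## with a non-zero effect yields F = Inf, p = 0.
onewayF <- function(vals, fac) {
  K <- nlevels(fac); n <- nrow(vals)
  nk <- as.numeric(table(fac))
  grp <- rowsum(vals, fac)                  # K x V sums, in level order
  gm <- grp / nk
  grand <- colMeans(vals)
  ssb <- colSums(nk * (gm - rep(grand, each = K))^2)
  sst <- colSums(vals^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  Fv <- (ssb / (K - 1)) / (ssw / (n - K))
  eps <- 1e-12 * pmax(sst, 1e-300)      # degenerate (noise-free) inputs
  Fv[ssw <= eps & ssb > eps] <- Inf
  Fv[ssw <= eps & ssb <= eps] <- 0
  p <- pf(Fv, K - 1, n - K, lower.tail = FALSE)
  ## within-group sem per cell
  devsq <- rowsum(vals^2, fac) - nk * gm^2
  semm <- sqrt(pmax(devsq, 0) / (nk - 1)) / sqrt(nk)
  list(F = Fv, p = p, means = gm, sem = semm, nk = nk)
}

#' Per-voxel frequency tuning statistics
#'
#' For each voxel: the mean tuning curve and its standard error across
#' trials, the best frequency (argmax of the curve), a one-way ANOVA
#' across stimulus frequencies, and -- for voxels whose ANOVA p-value falls
#' below `posthocAlpha` -- pairwise Wilcoxon rank-sum post-hoc tests
#' between frequencies.
#'
#' When `x` is a [TrialTensor-class] the windowed responses are computed
#' first and the mean peristimulus time course at each voxel's best
#' frequency is attached (used by the display-mask correlation criterion).
#'
#' @param x a [TrialTensor-class], a [ResponseSet-class], or a trial x
#'   voxel response matrix.
#' @param labelsVec stimulus label per trial (only when `x` is a matrix).
#' @param window response window in seconds (tensor input only).
#' @param posthocAlpha ANOVA threshold gating the post-hoc tests.
#' @param posthoc logical; skip the Wilcoxon tests entirely when FALSE.
#' @return A [TuningMap-class].
#' @examples
#' rs <- makeTransitionPatch(2, 2, "responsiveness",
#'         list(columnAmplitudes = c(20, 2)), noiseSd = 1, seed = 1)$responses
#' tm <- tuningStats(rs)
#' @export
tuningStats <- function(x, labelsVec = NULL, window = c(3, 5),
                        posthocAlpha = 1e-3, posthoc = TRUE) {
  bfCourse <- matrix(numeric(), 0L, 0L); tgrid <- numeric()
  if (is(x, "TrialTensor")) {
    vals <- windowedResponse(x, window)
    labelsVec <- x@labels
    tensor <- x
  } else if (is(x, "ResponseSet")) {
    vals <- x@values; labelsVec <- x@labels; tensor <- NULL
  } else {
    vals <- as.matrix(x); tensor <- NULL
    if (is.null(labelsVec)) stop("labelsVec required for matrix input")
  }
  fac <- freqFactor(labelsVec)
  K <- nlevels(fac); V <- ncol(vals)
  validVox <- rep(min(table(fac)) >= 2L, V)

  ow <- onewayF(vals, fac)
  bf <- apply(ow$means, 2L, which.max)

  pairs <- combn(levels(fac), 2L)
  php <- matrix(NA_real_, ncol(pairs), V,
                dimnames = list(paste(pairs[1L, ], pairs[2L, ], sep = "-"),
                                NULL))
  if (posthoc && any(validVox)) {
    sel <- which(ow$p < posthocAlpha & validVox)
    for (v in sel) {
      for (j in seq_len(ncol(pairs))) {
        a <- vals[fac == pairs[1L, j], v]
        b <- vals[fac == pairs[2L, j], v]
        php[j, v] <- if (all(c(a, b) == c(a, b)[1L])) 1 else
          suppressWarnings(
            wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
      }
    }
  }

  if (!is.null(tensor)) {
    tgrid <- tensor@time
    bfCourse <- matrix(NA_real_, length(tgrid), V)
    for (lev in seq_len(K)) {
      sel <- which(bf == lev)
      if (!length(sel)) next
      sub <- tensor@values[fac == levels(fac)[lev], , sel, drop = FALSE]
      bfCourse[, sel] <- apply(sub, c(2L, 3L), mean)
    }
  }

  an <- ow$p
  an[!validVox] <- NA_real_
  new("TuningMap", curve = ow$means, sem = ow$sem,
      frequencies = levels(fac), bfIndex = as.integer(bf),
      anovaP = an, posthocP = php, valid = validVox,
      bfCourse = bfCourse, time = tgrid)
}

#' Mean hemodynamic response of a structure
#'
#' The average peristimulus time course over all voxels responding to sound
#' with a z-score above threshold, normalized to unit peak. The z-score is
#' defined across trials: mean windowed response divided by its standard
#' error over trials.
#'
#' @param tensor a [TrialTensor-class].
#' @param zThreshold inclusion threshold (default 3).
#' @param window response window used for the z-score, s.
#' @return Numeric time course (unit peak) with the peristimulus grid as
#'   names and the number of contributing voxels as attribute `nVoxels`.
#' @export
meanHemodynamicResponse <- function(tensor, zThreshold = 3,
                                    window = c(3, 5)) {
  wr <- windowedResponse(tensor, window)
  n <- nrow(wr)
  mu <- colMeans(wr)
  se <- apply(wr, 2L, sd) / sqrt(n)
  z <- mu / se
  sel <- which(is.finite(z) & z > zThreshold)
  if (!length(sel))
    stop("no voxel passes z > ", zThreshold,
         "; consider lowering the threshold")
  course <- apply(tensor@values[, , sel, drop = FALSE], 2L, mean)
  course <- course / max(course)
  names(course) <- tensor@time
  attr(course, "nVoxels") <- length(sel)
  course
}

#' Stimulation-evoked ROI response per condition
#'
#' For each stimulation condition (trial label): the ROI-averaged windowed
#' %CBV per trial, summarized as mean +/- 2 sem, with a two-sided Wilcoxon
#' signed-rank test against zero and the conventional significance tiers
#' (`***` p < 1e-3, `**` p < 1e-2, `*` p < 5e-2).
#'
#' @param tensor a [TrialTensor-class] whose labels encode the condition
#'   (e.g. electrode position).
#' @param roi logical vector over voxels, or integer voxel indices.
#' @param window response window in seconds (default 3-6 s).
#' @return data.frame with columns `label`, `n`, `mean`, `sem`, `lo`, `hi`,
#'   `p`, `stars`.
#' @export
stimRoiResponse <- function(tensor, roi, window = c(3, 6)) {
  nv <- dim(tensor@values)[3L]
  vox <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (!length(vox) || any(vox < 1L | vox > nv)) stop("empty or invalid ROI")
  wr <- windowedResponse(tensor, window)          # trial x voxel
  roiResp <- rowMeans(wr[, vox, drop = FALSE])
  labs <- unique(tensor@labels)
  out <- do.call(rbind, lapply(labs, function(lb) {
    x <- roiResp[tensor@labels == lb]
    m <- mean(x); s <- sd(x) / sqrt(length(x))
    p <- if (all(x == 0)) 1 else
      suppressWarnings(wilcox.test(x, mu = 0, exact = FALSE)$p.value)
    data.frame(label = lb, n = length(x), mean = m, sem = s,
               lo = m - 2 * s, hi = m + 2 * s, p = p,
               stars = significanceStars(p))
  }))
  rownames(out) <- NULL
  out
}
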