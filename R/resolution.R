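## Functional spatial resolution: pairwise two-way ANOVAs over voxel
## pairs, dissimilar-pair fractions vs distance, randomization null.

#' Inter-voxel distance in voxel-pitch units
#'
#' The rounded Euclidean in-plane distance between two voxels,
#' `round(sqrt((x1-x2)^2 + (y1-y2)^2))`, with half-up rounding (0.5 goes
#' to 1). Vectorized over coordinate rows.
#'
#' @param coordA,coordB numeric vectors (or matrices with rows) of voxel
#'   indices (x, y).
#' @return Integer distance(s).
#' @examples
#' pairDistance(c(0, 0), c(1, 1))   # round(1.414) = 1
#' pairDistance(c(0, 0), c(2, 1))   # round(2.236) = 2
#' @export
pairDistance <- function(coordA, coordB) {
  a <- rbind(coordA); b <- rbind(coordB)
  as.integer(roundHalfUp(sqrt(rowSums((a - b)^2))))
}

## Balanced two-factor (voxel x frequency) fixed-effects decomposition for
## many voxel pairs at once, from per-voxel sufficient statistics.
##   m: nF x V cell means;  w: length-V within-cell SS;  n: trials per cell
##   ia, ib: pair index vectors
## Returns F statistics and p-values for the voxel main effect and the
## voxel x frequency interaction.
pairAnovaStats <- function(m, w, n, ia, ib) {
  nF <- nrow(m)
  va <- colMeans(m)[ia]; vb <- colMeans(m)[ib]
  dv <- va - vb
  dd <- m[, ia, drop = FALSE] - m[, ib, drop = FALSE]       # nF x P
  ssV <- n * nF * dv^2 / 2
  ssI <- (n / 2) * colSums((dd - rep(dv, each = nF))^2)
  ssE <- w[ia] + w[ib]
  dfE <- nF * 2L * (n - 1L)
  tot <- ssV + ssI + ssE + 1e-300
  eps <- 1e-12 * pmax(tot, 1e-300)
  Fv <- (ssV / 1) / (ssE / dfE)
  Fi <- (ssI / (nF - 1)) / (ssE / dfE)
  degen <- ssE <= eps
  Fv[degen] <- ifelse(ssV[degen] > eps[degen], Inf, 0)
  Fi[degen] <- ifelse(ssI[degen] > eps[degen], Inf, 0)
  list(Fvoxel = Fv, pVoxel = pf(Fv, 1, dfE, lower.tail = FALSE),
       Finteraction = Fi,
       pInteraction = pf(Fi, nF - 1, dfE, lower.tail = FALSE))
}

## Reshape a ResponseSet into per-voxel cell means and within-cell SS.
cellStats <- function(vals, fac) {
  nk <- as.integer(table(fac))
  if (length(unique(nk)) != 1L)
    stop("unbalanced design: equal trials per frequency required")
  m <- rowsum(vals, fac) / nk[1L]
  w <- colSums(vals^2) - nk[1L] * colSums(m^2)
  list(m = m, w = pmax(w, 0), n = nk[1L])
}

#' Pairwise two-way ANOVA between two voxels
#'
#' Balanced two-factor fixed-effects ANOVA with voxel and frequency as
#' factors, applied to the tuning responses of a voxel pair. A significant
#' voxel main effect marks the pair as dissimilar in overall
#' responsiveness; a significant voxel x frequency interaction marks it as
#' dissimilar in tuning, independently of overall responsiveness.
#'
#' @param responsesA,responsesB trial x frequency matrices (equal
#'   dimensions; every cell needs >= 2 trials).
#' @param alpha per-test significance level (default 0.05).
#' @return List with `Fvoxel`, `pVoxel`, `Finteraction`, `pInteraction`,
#'   and logical flags `dissimilarResponsiveness`, `dissimilarTuning`.
#' @examples
#' a <- matrix(rnorm(20), 4); b <- a + 10
#' pairAnova(a, b)$dissimilarResponsiveness
#' @export
pairAnova <- function(responsesA, responsesB, alpha = 5e-2) {
  responsesA <- as.matrix(responsesA); responsesB <- as.matrix(responsesB)
  if (!identical(dim(responsesA), dim(responsesB)))
    stop("unbalanced design: both voxels need the same trial x frequency grid")
  n <- nrow(responsesA); nF <- ncol(responsesA)
  if (n < 2L) stop("need >= 2 trials per cell")
  vals <- cbind(as.vector(responsesA), as.vector(responsesB))  # trials x 2
  fac <- factor(rep(seq_len(nF), each = n))
  cs <- cellStats(vals, fac)
  st <- pairAnovaStats(cs$m, cs$w, cs$n, 1L, 2L)
  list(Fvoxel = st$Fvoxel, pVoxel = st$pVoxel,
       Finteraction = st$Finteraction, pInteraction = st$pInteraction,
       dissimilarResponsiveness = st$pVoxel < alpha,
       dissimilarTuning = st$pInteraction < alpha)
}

## Internal: observed dissimilar fractions per distance for one response
## matrix. pairsIdx/dist precomputed by resolutionPairs().
curvesFromValues <- function(vals, fac, pairsIdx, dist, alpha) {
  cs <- cellStats(vals, fac)
  st <- pairAnovaStats(cs$m, cs$w, cs$n, pairsIdx[1L, ], pairsIdx[2L, ])
  dlev <- sort(unique(dist))
  fr <- vapply(dlev, function(dd) {
    sel <- dist == dd
    c(mean(st$pVoxel[sel] < alpha), mean(st$pInteraction[sel] < alpha))
  }, numeric(2))
  list(distance = dlev, fracResponsiveness = fr[1L, ], fracTuning = fr[2L, ],
       nPairs = as.integer(table(factor(dist, levels = dlev))))
}

resolutionPairs <- function(rs, contour = NULL) {
  V <- ncol(rs@values)
  keep <- if (is.null(contour)) seq_len(V) else {
    k <- if (is.logical(contour)) which(contour) else as.integer(contour)
    if (length(k) < 2L) stop("need >= 2 voxels inside the contour")
    k
  }
  if (!nrow(rs@coords)) stop("response set has no voxel coordinates")
  coords <- rs@coords[keep, , drop = FALSE]
  pr <- combn(length(keep), 2L)
  dist <- pairDistance(coords[pr[1L, ], , drop = FALSE],
                       coords[pr[2L, ], , drop = FALSE])
  list(keep = keep, pairs = pr, dist = dist)
}

#' Observed dissimilar-pair fractions versus distance
#'
#' Tests every unordered voxel pair inside the contour with the pairwise
#' two-way ANOVA and bins the fractions of dissimilar pairs (voxel main
#' effect and interaction criteria) by rounded inter-voxel distance.
#'
#' @param rs a [ResponseSet-class] with voxel coordinates (e.g. from
#'   [makeTransitionPatch()] or [windowedResponses()]).
#' @param alpha per-pair significance level.
#' @param contour optional logical mask or index vector restricting the
#'   voxels (the analysis is meant for a contour drawn around a sharp
#'   functional transition).
#' @return data.frame with columns `distance`, `nPairs`,
#'   `fracResponsiveness`, `fracTuning`.
#' @export
dissimilarityCurves <- function(rs, alpha = 5e-2, contour = NULL) {
  rp <- resolutionPairs(rs, contour)
  fac <- freqFactor(rs@labels)
  cv <- curvesFromValues(rs@values[, rp$keep, drop = FALSE], fac,
                         rp$pairs, rp$dist, alpha)
  data.frame(distance = cv$distance, nPairs = cv$nPairs,
             fracResponsiveness = cv$fracResponsiveness,
             fracTuning = cv$fracTuning)
}

#' Randomization null for the dissimilarity curves
#'
#' Randomizes the scalar responses jointly over all voxels, trials and
#' frequencies (a global exchange of response values), recomputes the
#' dissimilarity curves each time, and returns the per-distance upper
#' quantile of the null fractions for both criteria.
#'
#' @inheritParams dissimilarityCurves
#' @param nRand number of randomizations (default 50).
#' @param probs null quantile (default 0.95).
#' @param seed integer seed.
#' @return data.frame with columns `distance`, `respP95`, `tuneP95`.
#' @export
nullCurves <- function(rs, alpha = 5e-2, nRand = 50, probs = 0.95,
                       seed = NULL, contour = NULL) {
  if (nRand < 2L) stop("nRand must be >= 2")
  rp <- resolutionPairs(rs, contour)
  fac <- freqFactor(rs@labels)
  vals <- rs@values[, rp$keep, drop = FALSE]
  withSeed(seed, {
    fr <- array(NA_real_, c(nRand, length(unique(rp$dist)), 2L))
    for (r in seq_len(nRand)) {
      perm <- matrix(sample(vals), nrow(vals), ncol(vals))
      cv <- curvesFromValues(perm, fac, rp$pairs, rp$dist, alpha)
      fr[r, , 1L] <- cv$fracResponsiveness
      fr[r, , 2L] <- cv$fracTuning
    }
    dlev <- sort(unique(rp$dist))
    data.frame(distance = dlev,
               respP95 = apply(fr[, , 1L, drop = FALSE], 2L, quantile,
                               probs = probs, names = FALSE),
               tuneP95 = apply(fr[, , 2L, drop = FALSE], 2L, quantile,
                               probs = probs, names = FALSE))
  })
}

#' Functional spatial resolution from observed and null curves
#'
#' The shortest inter-voxel distance at which the observed fraction of
#' dissimilar pairs exceeds the null's upper percentile, converted to
#' micrometres via the voxel pitch; `NA` when no distance qualifies.
#'
#' @param observed data.frame from [dissimilarityCurves()].
#' @param null data.frame from [nullCurves()] on the same distance grid.
#' @param pitch voxel pitch in micrometres (default 100).
#' @return Named numeric length 2: `responsiveness` and `tuning`
#'   resolutions in micrometres (NA when undefined).
#' @export
functionalResolution <- function(observed, null, pitch = 100) {
  if (!identical(observed$distance, null$distance))
    stop("observed and null curves must share one distance grid")
  pick <- function(frac, lim) {
    d <- observed$distance[frac > lim]
    if (length(d)) min(d) * pitch else NA_real_
  }
  c(responsiveness = pick(observed$fracResponsiveness, null$respP95),
    tuning = pick(observed$fracTuning, null$tuneP95))
}

#' Complete functional-resolution analysis
#'
#' Runs [dissimilarityCurves()], [nullCurves()] and
#' [functionalResolution()] on a response set and returns them bundled.
#'
#' @inheritParams nullCurves
#' @param pitch voxel pitch in micrometres.
#' @return A [ResolutionCurve-class].
#' @examples
#' p <- makeTransitionPatch(4, 4, "responsiveness",
#'        list(columnAmplitudes = c(20, 14, 8, 2)), noiseSd = 2, seed = 1)
#' resolutionAnalysis(p$responses, seed = 1)
#' @export
resolutionAnalysis <- function(rs, alpha = 5e-2, nRand = 50, probs = 0.95,
                               seed = NULL, pitch = 100, contour = NULL) {
  obs <- dissimilarityCurves(rs, alpha, contour)
  nul <- nullCurves(rs, alpha, nRand, probs, seed, contour)
  res <- functionalResolution(obs, nul, pitch)
  new("ResolutionCurve",
      distances = as.integer(obs$distance), nPairs = obs$nPairs,
      fracResponsiveness = obs$fracResponsiveness,
      fracTuning = obs$fracTuning,
      nullP95 = cbind(responsiveness = nul$respP95, tuning = nul$tuneP95),
      resolution = res, pitch = pitch, alpha = alpha)
}
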