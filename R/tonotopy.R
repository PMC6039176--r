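#' Display mask for a tonotopic map
#'
#' A voxel is kept for display iff (i) its maximal tuning-curve response
#' reaches `minResponse` %CBV and (ii) the mean response time course at its
#' best frequency is significantly Pearson-correlated (p < `corrAlpha`)
#' with the structure's mean hemodynamic response. The correlation is
#' evaluated over the post-onset window `corrWindow`.
#'
#' @param tuning a [TuningMap-class] computed from a [TrialTensor-class]
#'   (so that per-voxel best-frequency time courses are available).
#' @param meanHrf mean hemodynamic response on the same peristimulus grid
#'   as `tuning` (e.g. from [meanHemodynamicResponse()]).
#' @param minResponse minimal peak response in %CBV (default 15).
#' @param corrAlpha correlation significance threshold (default 1e-3).
#' @param corrWindow post-onset window for the correlation, s.
#' @return Logical vector over voxels.
#' @export
displayMask <- function(tuning, meanHrf, minResponse = 15,
                        corrAlpha = 1e-3, corrWindow = c(0, 8)) {
  if (!nrow(tuning@bfCourse))
    stop("tuning map has no best-frequency time courses; ",
         "compute it from a TrialTensor")
  if (length(meanHrf) != length(tuning@time))
    stop("grid mismatch: meanHrf must be on the tuning map's ",
         "peristimulus grid")
  idx <- windowIndex(tuning@time, corrWindow)
  h <- as.numeric(meanHrf)[idx]
  V <- ncol(tuning@curve)
  peak <- apply(tuning@curve, 2L, max)
  keep <- peak >= minResponse
  for (v in which(keep)) {
    y <- tuning@bfCourse[idx, v]
    if (sd(y) == 0 || sd(h) == 0) { keep[v] <- FALSE; next }
    keep[v] <- cor.test(h, y)$p.value < corrAlpha
  }
  keep
}

## Shift a 3-D array by (dz, dx, ds) with replicate (nearest) padding.
shiftPad <- function(a, dz, dx, ds) {
  d <- dim(a)
  iz <- pmin(pmax(seq_len(d[1L]) + dz, 1L), d[1L])
  ix <- pmin(pmax(seq_len(d[2L]) + dx, 1L), d[2L])
  is <- pmin(pmax(seq_len(d[3L]) + ds, 1L), d[3L])
  a[iz, ix, is, drop = FALSE]
}

#' Smooth a best-frequency map and clean its mask
#'
#' BF values are smoothed in-plane with a 3 x 3 x 1 Gaussian kernel
#' (sd 0.5 voxel) whose weights are renormalized over the voxels that have
#' a defined BF, so undefined neighbours do not bleed into the map; the
#' display mask is cleaned with a 3 x 3 x 3 median filter (majority over
#' the 27-neighbourhood, replicate padding at the borders), which removes
#' isolated voxels. Smoothed BF values are kept as interpolated
#' (non-integer) values for display.
#'
#' @param bf a [BFMap-class].
#' @param sigma Gaussian sd in voxels (default 0.5).
#' @return A smoothed [BFMap-class].
#' @export
smoothMaps <- function(bf, sigma = 0.5) {
  vals <- bf@bf; mask <- bf@mask
  d <- dim(vals)
  def <- !is.na(vals)
  v0 <- ifelse(def, vals, 0)
  num <- array(0, d); den <- array(0, d)
  for (dz in -1:1) for (dx in -1:1) {
    w <- exp(-(dz^2 + dx^2) / (2 * sigma^2))
    ## in-plane shift with zero padding: out-of-grid neighbours contribute 0
    sv <- array(0, d); sm <- array(0, d)
    izS <- seq_len(d[1L]) + dz; ixS <- seq_len(d[2L]) + dx
    okz <- izS >= 1L & izS <= d[1L]; okx <- ixS >= 1L & ixS <= d[2L]
    sv[okz, okx, ] <- v0[izS[okz], ixS[okx], , drop = FALSE]
    sm[okz, okx, ] <- def[izS[okz], ixS[okx], , drop = FALSE]
    num <- num + w * sv
    den <- den + w * sm
  }
  sm <- ifelse(def & den > 0, num / den, NA_real_)

  cnt <- array(0L, d)
  for (dz in -1:1) for (dx in -1:1) for (ds in -1:1)
    cnt <- cnt + shiftPad(mask, dz, dx, ds)
  newMask <- cnt >= 14L                    # median of 27 booleans
  newMask <- newMask & !is.na(sm)
  new("BFMap", bf = sm, mask = newMask,
      provenance = c(bf@provenance,
                     list(smoothing = list(sigma = sigma,
                                           median = c(3L, 3L, 3L)))))
}

#' Surface view of a best-frequency volume
#'
#' Projects the BF volume onto the cortical surface: for each surface
#' position, the mean BF over the masked voxels lying `depthRange[1]` to
#' `depthRange[2]` voxels below the manually delimited surface (along the
#' vertical axis, the surface-normal approximation used throughout).
#' Positions with no masked voxel in the depth band are `NA`.
#'
#' @param bf a [BFMap-class] whose first array dimension is depth.
#' @param surface integer surface depth index per (x, slice) position:
#'   a matrix of dim `dim(bf)[2:3]` (or a vector recycled to it).
#' @param depthRange voxels below the surface to average, default 5-10.
#' @return Numeric matrix over the (x, slice) positions.
#' @export
surfaceView <- function(bf, surface, depthRange = c(5, 10)) {
  d <- dim(bf@bf)
  surf <- matrix(surface, d[2L], d[3L])
  out <- matrix(NA_real_, d[2L], d[3L])
  offs <- depthRange[1L]:depthRange[2L]
  for (x in seq_len(d[2L])) for (s in seq_len(d[3L])) {
    dep <- surf[x, s] + offs
    dep <- dep[dep >= 1L & dep <= d[1L]]
    if (!length(dep)) next
    sel <- bf@mask[dep, x, s]
    if (any(sel)) out[x, s] <- mean(bf@bf[dep, x, s][sel])
  }
  out
}

#' Re-match a recording plane within a vascular volume
#'
#' Finds the slice of a reference 3-D vascular stack that best matches a
#' 2-D power-Doppler image, by normalized cross-correlation (intensities
#' z-scored per slice). Used to reposition recording planes across
#' sessions. Ties are broken toward the lowest slice index and flagged.
#'
#' @param image 2-D numeric matrix.
#' @param stack 3-D numeric array, slices along the third dimension.
#' @return List with `index` (best slice), `score` (correlation), `tie`
#'   (logical) and `scores` (all slices).
#' @export
matchPlane <- function(image, stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[3L] < 1L)
    stop("stack must be a non-empty 3-D array")
  iv <- as.vector(image)
  scores <- vapply(seq_len(d[3L]), function(s) {
    sv <- as.vector(stack[, , s])
    if (sd(sv) == 0 || sd(iv) == 0) return(NA_real_)
    cor(iv, sv)
  }, numeric(1))
  if (all(is.na(scores))) stop("no slice with non-zero variance")
  best <- which.max(scores)
  tie <- sum(scores >= scores[best] - 1e-12, na.rm = TRUE) > 1L
  list(index = best, score = scores[best], tie = tie, scores = scores)
}
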