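#' Assign cortical depth layers between two delineation curves
#'
#' Given a manually traced cortical surface curve and a deep-limit curve
#' (polylines in voxel coordinates, columns `x` then `z`, z growing with
#' depth), assigns each voxel of the grid a layer index: the relative depth
#' along the local surface-to-deep segment is split into `nLayers` equal
#' bands (layer 1 at the surface). Voxels above the surface or below the
#' deep curve get `NA`. Surface normals are approximated by the vertical
#' axis, appropriate for the flat synthetic geometries generated here.
#'
#' @param surfaceCurve,deepCurve two-column matrices (x, z); the surface
#'   must lie strictly above the deep curve (smaller z) over the grid.
#' @param gridShape c(nz, nx) voxel grid.
#' @param nLayers number of depth bands (default 10).
#' @return Integer matrix (nz, nx) of layer indices in 1..nLayers, NA
#'   outside the cortex.
#' @examples
#' lay <- makeLayeredCortex(cbind(1:20, 2), cbind(1:20, 12), c(15, 20))
#' @export
makeLayeredCortex <- function(surfaceCurve, deepCurve, gridShape,
                              nLayers = 10) {
  surfaceCurve <- as.matrix(surfaceCurve); deepCurve <- as.matrix(deepCurve)
  nz <- gridShape[1L]; nx <- gridShape[2L]
  xg <- seq_len(nx)
  zs <- approx(surfaceCurve[, 1L], surfaceCurve[, 2L], xout = xg,
               rule = 2)$y
  zd <- approx(deepCurve[, 1L], deepCurve[, 2L], xout = xg, rule = 2)$y
  if (any(zd <= zs))
    stop("geometry error: surface and deep curves cross or touch")
  rel <- (matrix(seq_len(nz), nz, nx) - matrix(zs, nz, nx, byrow = TRUE)) /
    matrix(zd - zs, nz, nx, byrow = TRUE)
  lay <- floor(nLayers * rel) + 1L
  lay[rel >= 1] <- nLayers                      # voxel exactly on deep curve
  lay[rel < 0 | rel > 1] <- NA_integer_
  storage.mode(lay) <- "integer"
  lay
}
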