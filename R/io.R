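## File interfaces: NIfTI for voxel series and maps, CSV for event
## tables, JSON for configurations and decoding results. Complex frame
## blocks are stored as a real/imaginary NIfTI pair plus a JSON sidecar
## holding the acquisition configuration.

#' Write / read a %CBV series as 4-D NIfTI
#'
#' The (nz, nx, nt) series is stored as a 4-D volume (singleton third
#' axis) with the 1 Hz sampling period recorded in the 4th pixdim.
#'
#' @param cbv a [CBVSeries-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `writeCBV` returns `path` invisibly; `readCBV` returns a
#'   [CBVSeries-class].
#' @export
writeCBV <- function(cbv, path) {
  d <- dim(cbv@values)
  arr <- array(cbv@values, c(d[1L], d[2L], 1L, d[3L]))
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- c(1, 1, 1, cbv@tr)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname writeCBV
#' @param baselineWindow baseline sample indices to record on the way in.
#' @export
readCBV <- function(path, baselineWindow = integer()) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  tr <- RNifti::pixdim(im)[4L]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  vals <- array(as.numeric(im), c(d[1L], d[2L], d[4L]))
  cbvSeries(vals, baselineWindow = baselineWindow, tr = tr)
}

#' Write / read an event table as CSV
#'
#' Columns `onset_s` and `label` (plus any extra columns present).
#'
#' @param events data.frame with at least `onset_s` and `label`.
#' @param path output `.csv` path.
#' @return `writeEvents` returns `path` invisibly; `readEvents` the
#'   data.frame.
#' @export
writeEvents <- function(events, path) {
  stopifnot(all(c("onset_s", "label") %in% names(events)))
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  ev <- utils::read.csv(path, colClasses = c(label = "character"))
  stopifnot(all(c("onset_s", "label") %in% names(ev)))
  ev
}

#' Write / read a complex frame block
#'
#' Stores the real and imaginary parts as `<stem>_real.nii.gz` /
#' `<stem>_imag.nii.gz` and the acquisition configuration as
#' `<stem>.json`.
#'
#' @param block a [FrameBlock-class].
#' @param stem path stem (no extension).
#' @return `writeFrameBlock` returns `stem` invisibly; `readFrameBlock`
#'   a [FrameBlock-class].
#' @export
writeFrameBlock <- function(block, stem) {
  RNifti::writeNifti(RNifti::asNifti(Re(block@data)),
                     paste0(stem, "_real.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(block@data)),
                     paste0(stem, "_imag.nii.gz"))
  cfg <- block@config
  jsonlite::write_json(
    list(frameRate = cfg@frameRate, framesPerBlock = cfg@framesPerBlock,
         blockPeriod = cfg@blockPeriod, transmitFreq = cfg@transmitFreq,
         speedOfSound = cfg@speedOfSound, voxelPitch = cfg@voxelPitch),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname writeFrameBlock
#' @export
readFrameBlock <- function(stem) {
  re <- as.array(RNifti::readNifti(paste0(stem, "_real.nii.gz")))
  im <- as.array(RNifti::readNifti(paste0(stem, "_imag.nii.gz")))
  j <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  cfg <- acquisitionConfig(frameRate = j$frameRate,
                           framesPerBlock = j$framesPerBlock,
                           blockPeriod = j$blockPeriod,
                           transmitFreq = j$transmitFreq,
                           speedOfSound = j$speedOfSound,
                           voxelPitch = j$voxelPitch)
  frameBlock(array(complex(real = re, imaginary = im), dim(re)), cfg)
}

#' Write a decoding result as JSON
#'
#' @param result a [DecodingResult-class].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
writeDecodingResult <- function(result, path) {
  jsonlite::write_json(
    list(accuracy = result@accuracy,
         perClass = as.list(result@perClass),
         pValue = result@pValue,
         significant = result@significant,
         null = result@null,
         decoder = result@details$decoder),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
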