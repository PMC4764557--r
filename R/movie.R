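# Synthetic calcium movies with ground truth, ROI sets, and TIFF I/O.

# Shift a matrix by integer (dy, dx): the scene moves down by dy rows and
# right by dx columns; exposed pixels are filled with `fill`.
shiftMatrix <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  srcRows <- seq_len(h) - dy
  srcCols <- seq_len(w) - dx
  okR <- srcRows >= 1 & srcRows <= h
  okC <- srcCols >= 1 & srcCols <= w
  out[okR, okC] <- m[srcRows[okR], srcCols[okC]]
  out
}

dilateMask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0
}

#' Build an ROI set with neuropil annuli
#'
#' The neuropil annulus of each ROI is the doughnut between \code{inner} and
#' \code{outer} pixels from the ROI boundary, excluding the pixels of every
#' ROI in the set (so somatic signal never leaks into its own, or another
#' cell's, neuropil estimate).
#'
#' @param masks list of logical H x W matrices
#' @param inner inner annulus margin, pixels (default 3)
#' @param outer outer annulus margin, pixels (default 8)
#' @param labels optional ROI labels
#' @return a \code{RoiSet}
#' @export
roiSet <- function(masks, inner = 3, outer = 8, labels = NULL) {
  stopifnot(length(masks) >= 1, outer > inner)
  if (is.null(labels)) labels <- sprintf("roi%03d", seq_along(masks))
  allRoi <- Reduce(`|`, masks)
  annuli <- lapply(masks, function(m) {
    dilateMask(m, outer) & !dilateMask(m, inner) & !allRoi
  })
  new("RoiSet", masks = masks, annuli = annuli, labels = labels)
}

#' Circular ROI masks laid out on a jittered grid
#'
#' Fixture helper: places \code{n} disc-shaped ROIs on a regular grid with a
#' margin, returning a list of logical masks. Grid positions are jittered
#' (deterministically, given \code{seed}) so the synthetic field of view is
#' not spatially periodic — a periodic lattice of identical cells would make
#' rigid registration ambiguous up to the lattice period, which real tissue
#' never is.
#'
#' @param height,width frame size in pixels
#' @param n number of ROIs
#' @param radius ROI radius in pixels
#' @param margin margin from the frame border, pixels (keep larger than the
#'   outer annulus margin plus the largest rigid shift plus \code{jitter})
#' @param jitter maximum absolute position jitter, pixels
#' @param seed seed for the jitter
#' @return list of logical matrices
#' @export
makeRoiGrid <- function(height, width, n, radius = 4, margin = 16,
                        jitter = 3, seed = 1L) {
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  ys <- round(seq(margin, height - margin, length.out = nrow))
  xs <- round(seq(margin, width - margin, length.out = ncol))
  centers <- expand.grid(y = ys, x = xs)[seq_len(n), ]
  if (jitter > 0) {
    set.seed(seed)
    centers$y <- pmin(pmax(centers$y +
      sample(seq(-jitter, jitter), n, TRUE), radius + 1), height - radius)
    centers$x <- pmin(pmax(centers$x +
      sample(seq(-jitter, jitter), n, TRUE), radius + 1), width - radius)
  }
  rowIdx <- matrix(seq_len(height), height, width)
  colIdx <- matrix(seq_len(width), height, width, byrow = TRUE)
  lapply(seq_len(n), function(i) {
    (rowIdx - centers$y[i])^2 + (colIdx - centers$x[i])^2 <= radius^2
  })
}

#' Render a synthetic calcium movie
#'
#' Each pixel's resting brightness is \code{baselineF}, raised by
#' \code{roiContrast} inside somata (so cells are visible in the mean image,
#' as in real data, and registration has anatomical structure to work with).
#' Fluorescence dynamics multiply the local resting brightness:
#' \code{F = F_rest * (1 + roiDff * mask + neuropilDff * profile)}. Frames
#' are rigidly shifted by the frame's integer (dy, dx) and corrupted with
#' additive Gaussian noise. The injected masks, shifts and traces are stored
#' as ground truth on the returned movie.
#'
#' @param rois a \code{RoiSet} (its masks define the somata)
#' @param roiDff T x R matrix of somatic dF/F traces
#' @param frameTimes frame times, seconds
#' @param neuropilDff length-T shared neuropil dF/F trace (default 0)
#' @param neuropilProfile H x W spatial profile of the neuropil signal
#'   (default: uniform 1 everywhere)
#' @param shifts T x 2 integer matrix of per-frame rigid shifts (dy, dx),
#'   default all zero
#' @param kernel a \code{CalciumKernelParams}; supplies \code{baselineF} and
#'   \code{noiseSd}
#' @param roiContrast resting brightness of somata relative to background
#'   (default 0.3, i.e. 30 percent brighter)
#' @param seed integer seed for the pixel noise
#' @param spikes optional list of ground-truth spike-time vectors per ROI
#' @return a \code{CalciumMovie} with \code{groundTruth} filled in
#' @export
renderMovie <- function(rois, roiDff, frameTimes, neuropilDff = NULL,
                        neuropilProfile = NULL, shifts = NULL,
                        kernel = calciumKernelParams(), roiContrast = 0.3,
                        seed = 1L, spikes = NULL) {
  stopifnot(is(rois, "RoiSet"), is.matrix(roiDff))
  masks <- rois@masks
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  nT <- length(frameTimes)
  nR <- length(masks)
  stopifnot(nrow(roiDff) == nT, ncol(roiDff) == nR)
  if (is.null(neuropilDff)) neuropilDff <- numeric(nT)
  if (is.null(neuropilProfile)) neuropilProfile <- matrix(1, h, w)
  if (is.null(shifts)) shifts <- matrix(0L, nT, 2)
  stopifnot(nrow(shifts) == nT, ncol(shifts) == 2)
  shifts <- matrix(as.integer(round(shifts)), nT, 2)

  maxDy <- max(abs(shifts[, 1])); maxDx <- max(abs(shifts[, 2]))
  for (m in masks) {
    idx <- which(m, arr.ind = TRUE)
    if (min(idx[, 1]) - maxDy < 1 || max(idx[, 1]) + maxDy > h ||
        min(idx[, 2]) - maxDx < 1 || max(idx[, 2]) + maxDx > w)
      stop("renderMovie: a rigid shift pushes an ROI out of the frame")
  }

  set.seed(seed)
  Fb <- kernel@baselineF
  maskIdx <- lapply(masks, which)
  rest <- matrix(Fb, h, w)
  for (r in seq_len(nR)) rest[maskIdx[[r]]] <- Fb * (1 + roiContrast)
  frames <- array(0, dim = c(h, w, nT))
  for (t in seq_len(nT)) {
    dyn <- 1 + neuropilProfile * neuropilDff[t]
    for (r in seq_len(nR))
      dyn[maskIdx[[r]]] <- dyn[maskIdx[[r]]] + roiDff[t, r]
    scene <- rest * dyn
    if (shifts[t, 1] != 0 || shifts[t, 2] != 0)
      scene <- shiftMatrix(scene, shifts[t, 1], shifts[t, 2],
                           fill = stats::median(scene))
    if (kernel@noiseSd > 0)
      scene <- scene + matrix(stats::rnorm(h * w, 0, kernel@noiseSd), h, w)
    frames[, , t] <- pmax(scene, 0)
  }
  new("CalciumMovie", frames = frames, frameTimes = frameTimes, plane = 1L,
      groundTruth = list(masks = masks, shifts = shifts, roiDff = roiDff,
                         neuropilDff = neuropilDff, spikes = spikes,
                         roiContrast = roiContrast))
}

#' Write / read a calcium movie as multi-frame TIFF
#'
#' Intensities are scaled into [0, 1] by a stored factor; frame times and
#' the scale are written to a JSON sidecar (same path with extension
#' \code{.json}) so the round trip is lossless up to float precision.
#' Ground-truth annotations are not serialized.
#'
#' @param movie a \code{CalciumMovie}
#' @param path output TIFF path
#' @return \code{writeMovieTiff} returns \code{path} invisibly;
#'   \code{readMovieTiff} returns a \code{CalciumMovie}
#' @export
writeMovieTiff <- function(movie, path) {
  stopifnot(is(movie, "CalciumMovie"))
  mx <- max(movie@frames, 1e-12)
  fr <- lapply(seq_len(dim(movie@frames)[3]),
               function(t) movie@frames[, , t] / mx)
  tiff::writeTIFF(fr, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = mx, frameTimes = movie@frameTimes, plane = movie@plane),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path) {
  fr <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(nrow(fr[[1]]), ncol(fr[[1]]), length(fr)))
  for (t in seq_along(fr)) frames[, , t] <- fr[[t]] * side$scale
  new("CalciumMovie", frames = frames,
      frameTimes = as.numeric(side$frameTimes),
      plane = as.integer(side$plane), groundTruth = list())
}
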