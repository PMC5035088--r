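#' Frame series: ordered grayscale frames plus calibration
#'
#' The common container for real and synthetic image stacks. Frames are
#' numeric matrices `I[y, x]` in `[0, 1]`; all frames share dimensions.
#' Calibration carries the pixel size (um/px) and the time base, either as a
#' fixed frame interval (minutes) or as explicit per-frame timestamps
#' (hours). Fluorescence channels are optional parallel frame lists that may
#' have `NULL` entries where no fluorescence image was acquired (sparser
#' acquisition schedules are common; such gaps are recorded as absent, never
#' interpolated).
#'
#' Frames are indexed 1-based in R code; reported pixel coordinates are
#' 0-based half-open intervals, and user-facing tables report 1-based time
#' points.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param pixel_size_um pixel size in micrometres per pixel (> 0). Required:
#'   physical cell-length filtering is meaningless without it.
#' @param frame_interval_min minutes between frames (> 0); ignored when
#'   `timestamps_h` is given.
#' @param timestamps_h optional strictly increasing per-frame times (hours).
#' @param fluor optional named list of fluorescence channels, each a list of
#'   matrices or `NULL`s parallel to `frames`.
#' @param position position label.
#' @return an object of class `mm_frame_series`.
#' @export
frame_series <- function(frames, pixel_size_um, frame_interval_min = NULL,
                         timestamps_h = NULL, fluor = list(),
                         position = "pos1") {
  if (!length(frames)) stop("need at least one frame")
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f)) stop("frames must be matrices")
    f
  })
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must share identical dimensions")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive number (configuration error)")
  T_ <- length(frames)
  if (is.null(timestamps_h)) {
    if (is.null(frame_interval_min) || frame_interval_min <= 0)
      stop("need `frame_interval_min` > 0 or explicit `timestamps_h`")
    timestamps_h <- (seq_len(T_) - 1) * frame_interval_min / 60
  } else {
    if (length(timestamps_h) != T_ || any(diff(timestamps_h) <= 0))
      stop("`timestamps_h` must be strictly increasing, one per frame")
    if (is.null(frame_interval_min) && T_ > 1)
      frame_interval_min <- mean(diff(timestamps_h)) * 60
  }
  for (ch in names(fluor)) {
    fl <- fluor[[ch]]
    if (length(fl) != T_)
      stop("fluorescence channel '", ch, "' must be parallel to frames")
    ok <- vapply(fl, function(f) is.null(f) || identical(dim(f), d), logical(1))
    if (!all(ok)) stop("fluorescence frames must share frame dimensions")
  }
  structure(
    list(frames = frames, fluor = fluor,
         calibration = list(pixel_size_um = pixel_size_um,
                            frame_interval_min = frame_interval_min,
                            timestamps_h = timestamps_h),
         position = position),
    class = "mm_frame_series")
}

#' @export
length.mm_frame_series <- function(x) length(x$frames)

#' @export
print.mm_frame_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<mm_frame_series> %s: %d frames of %d x %d px, %.4g um/px\n",
              x$position, length(x$frames), d[2], d[1],
              x$calibration$pixel_size_um))
  if (length(x$fluor))
    cat("  fluorescence:",
        paste(sprintf("%s (%d frames)", names(x$fluor),
                      vapply(x$fluor, function(f) sum(!vapply(f, is.null, logical(1))), 0L)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Temporal subsampling of a frame series
#'
#' Keeps frames at indices 1, 1+stride, 1+2*stride, ... and scales the frame
#' interval accordingly. Used to mimic longer imaging intervals from a
#' densely sampled stack when studying how tracking quality degrades with
#' imaging frequency.
#'
#' @param series an [frame_series()] object.
#' @param stride positive integer step.
#' @return an `mm_frame_series` with `ceiling(T/stride)` frames.
#' @export
subsample <- function(series, stride) {
  stopifnot(inherits(series, "mm_frame_series"))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("`stride` must be >= 1")
  if (stride == 1L) return(series)
  idx <- seq(1L, length(series$frames), by = stride)
  fluor <- lapply(series$fluor, function(fl) fl[idx])
  cal <- series$calibration
  frame_series(series$frames[idx], cal$pixel_size_um,
               frame_interval_min = cal$frame_interval_min * stride,
               timestamps_h = cal$timestamps_h[idx],
               fluor = fluor, position = series$position)
}

# Pull PhysicalSizeX (um/px) out of an OME-XML description string, if any.
ome_pixel_size <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(NULL)
  m <- regmatches(desc, regexpr('PhysicalSizeX="[0-9.eE+-]+"', desc))
  if (!length(m)) return(NULL)
  as.numeric(sub('PhysicalSizeX="([0-9.eE+-]+)"', "\\1", m))
}

#' Load a TIFF / OME-TIFF stack as a frame series
#'
#' Pages of the (multi-page) TIFF become frames, ordered as stored. The
#' pixel size is taken from OME-XML metadata (`PhysicalSizeX`) when present,
#' otherwise from the `pixel_size_um` argument; metadata wins over the
#' argument, and a hard error is raised when neither is available. Pixel
#' values are never altered by loading.
#'
#' Fluorescence channels may be supplied as separate single- or multi-page
#' TIFFs together with the 1-based frame indices their pages correspond to;
#' frames without a fluorescence acquisition are recorded as absent.
#'
#' @param path TIFF file path.
#' @param pixel_size_um fallback pixel size (um/px) when the file carries no
#'   OME calibration.
#' @param frame_interval_min minutes between frames.
#' @param timestamps_h optional explicit per-frame times (hours).
#' @param fluor optional named list; each entry `list(path =, frames =)`
#'   maps the pages of a fluorescence TIFF to frame indices.
#' @param position position label.
#' @return an `mm_frame_series`.
#' @export
load_stack <- function(path, pixel_size_um = NULL, frame_interval_min = NULL,
                       timestamps_h = NULL, fluor = list(),
                       position = basename(path)) {
  if (!file.exists(path)) stop("cannot read image stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  ps <- ome_pixel_size(attr(pages[[1]], "description"))
  if (is.null(ps)) ps <- pixel_size_um
  if (is.null(ps))
    stop("no pixel size in metadata and no `pixel_size_um` override ",
         "(configuration error)")
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L] # collapse greyscale-as-RGB
    attributes(p) <- list(dim = dim(p))
    p
  })
  T_ <- length(frames)
  fl_out <- list()
  for (ch in names(fluor)) {
    spec_ <- fluor[[ch]]
    fp <- tiff::readTIFF(spec_$path, all = TRUE)
    if (is.matrix(fp)) fp <- list(fp)
    fp <- lapply(fp, function(p) { attributes(p) <- list(dim = dim(p)); p })
    slots <- vector("list", T_)
    idx <- as.integer(spec_$frames)
    if (length(idx) != length(fp) || any(idx < 1L | idx > T_))
      stop("fluorescence frame index map invalid for channel '", ch, "'")
    slots[idx] <- fp
    fl_out[[ch]] <- slots
  }
  frame_series(frames, ps, frame_interval_min = frame_interval_min,
               timestamps_h = timestamps_h, fluor = fl_out,
               position = position)
}

#' Write frames as a 16-bit multi-page TIFF
#'
#' Frames must lie in `[0, 1]`; they are stored as 16-bit greyscale. The
#' synthetic renderer quantises its output to the 16-bit grid, so a write /
#' [load_stack()] round trip reproduces synthetic frames bit-identically.
#'
#' @param frames list of matrices in `[0, 1]` (or an `mm_frame_series`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  if (inherits(frames, "mm_frame_series")) frames <- frames$frames
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}
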