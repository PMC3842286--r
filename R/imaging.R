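#' Construct a frame sequence
#'
#' An ordered set of 8-bit grayscale frames with a fixed inter-frame
#' interval and spatial calibration. Frames are integer matrices indexed
#' `[row, col]` = `[y + 1, x + 1]` with 0-based pixel coordinates, x
#' rightward and y downward; `mouth_position` is (x, y) in px and anchors
#' the cm coordinate system used downstream (x positive along the
#' expectoration direction).
#'
#' @param frames list of integer matrices, all the same dimensions,
#'   values 0-255.
#' @param dt inter-frame interval, s (default 1/300).
#' @param pixel_size calibration, cm per px.
#' @param mouth_position (x, y) of the mouth in px.
#' @return A `frame_sequence` object with timestamps `(i - 1) * dt`.
#' @export
frame_sequence <- function(frames, dt = 1 / 300, pixel_size = 4.4 / 21,
                           mouth_position = c(0, 0)) {
  stopifnot(is.list(frames), length(frames) >= 1L, dt > 0, pixel_size > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frame_sequence: all frames must share dimensions")
  structure(list(frames = frames,
                 dt = dt,
                 pixel_size = pixel_size,
                 mouth_position = mouth_position,
                 timestamps = (seq_along(frames) - 1L) * dt),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_sequence: %d frames of %dx%d px, dt = %.5g s (%.5g s total), %.4g cm/px\n",
              length(x$frames), d[2], d[1], x$dt,
              x$timestamps[length(x$timestamps)], x$pixel_size))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

read_gray_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(f),
           tif = ,
           tiff = tiff::readTIFF(f),
           stop("unsupported image format: .", ext)),
    error = function(e) stop("load_frames: cannot decode '", f, "': ",
                             conditionMessage(e)))
  if (length(dim(img)) == 3L) img <- img[, , 1]   # collapse gray-as-RGB
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Load a frame sequence from numbered image files
#'
#' Files matching `path_pattern` (a glob, e.g. `"frames/frame_*.png"`) are
#' read as 8-bit grayscale in lexicographic order — zero-padded numbering
#' sorts correctly. PNG and single-page TIFF are supported.
#'
#' @param path_pattern glob pattern for the frame files.
#' @param dt inter-frame interval, s.
#' @param pixel_size cm per px.
#' @param mouth_position (x, y) in px.
#' @return A [frame_sequence()].
#' @export
load_frames <- function(path_pattern, dt = 1 / 300, pixel_size = 4.4 / 21,
                        mouth_position = c(0, 0)) {
  files <- sort(Sys.glob(path_pattern))
  if (length(files) == 0L)
    stop("load_frames: no files match pattern '", path_pattern, "'")
  frames <- lapply(files, read_gray_image)
  dims <- vapply(frames, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stop("load_frames: frame dimensions differ at '", files[bad[1]], "'")
  frame_sequence(frames, dt = dt, pixel_size = pixel_size,
                 mouth_position = mouth_position)
}

#' Write a frame sequence as zero-padded numbered PNGs
#'
#' @param seq a [frame_sequence()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return The written file paths, invisibly.
#' @export
write_frames <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(seq$frames)
  width <- max(4L, nchar(as.character(n)))
  paths <- file.path(dir, sprintf("%s_%0*d.png", prefix, width, seq_len(n)))
  for (i in seq_len(n))
    png::writePNG(seq$frames[[i]] / 255, paths[i])
  invisible(paths)
}

#' Binary image enhancement
#'
#' Thresholds a grayscale frame to a two-valued image: pixels at or above
#' the threshold map to 255, the rest to 0. This is the enhancement step
#' that makes faint particle clusters stand out; tracking itself runs on
#' the original graylevels by default, since binarization discards the
#' subpixel intensity structure the correlation peak interpolation relies
#' on.
#'
#' @param frame an integer matrix (one frame), values 0-255.
#' @param threshold a value in \[0, 255\], or `"auto"` for Otsu's
#'   histogram-bimodality criterion (via \pkg{EBImage}).
#' @return An integer matrix of 0s and 255s.
#' @export
binarize <- function(frame, threshold = "auto") {
  stopifnot(is.matrix(frame))
  if (identical(threshold, "auto")) {
    rng <- range(frame)
    threshold <- if (rng[1] == rng[2]) rng[1] else
      255 * EBImage::otsu(EBImage::Image(frame / 255),
                          range = c(0, 1), levels = 256)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 255)
  matrix(as.integer(ifelse(frame >= threshold, 255L, 0L)),
         nrow(frame), ncol(frame))
}
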