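#' Load an endoscopic image as a grayscale intensity matrix
#'
#' Reads a JPEG or PNG image and returns a numeric matrix in `[0, 1]` with
#' the (row, col) convention: rows increase downward, entry `[r, c]` is the
#' pixel in image row `r`, column `c`. RGB input is collapsed to a single
#' channel through the green channel by default — under narrow-band light
#' hemoglobin absorbs most strongly in green, so vessels have the best
#' contrast there — or through Rec. 601 luminance.
#'
#' @param path Path to a JPEG or PNG file.
#' @param channel `"green"` (default) or `"luminance"`.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
load_image_gray <- function(path, channel = c("green", "luminance")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("failed to read image ", path, ": ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)
  if (length(a) == 0 || any(dim(a)[1:2] == 0))
    stop("zero-size image: ", path)
  if (length(dim(a)) == 2) {
    m <- t(a)  # EBImage stores (x = col, y = row)
  } else {
    nch <- dim(a)[3]
    if (nch >= 3) {
      m <- if (channel == "green") t(a[, , 2]) else
        t(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
    } else {
      m <- t(a[, , 1])
    }
  }
  m <- pmin(pmax(m, 0), 1)
  storage.mode(m) <- "double"
  m
}

#' Write a grayscale matrix as a PNG image
#'
#' Inverse of [load_image_gray()] for single-channel data: the matrix uses
#' the (row, col) convention and values in `[0, 1]`.
#'
#' @param m Numeric matrix in `[0, 1]`.
#' @param path Output path ending in `.png` (or `.jpg` for lossy output).
#' @return `path`, invisibly.
#' @export
write_image_gray <- function(m, path) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(m, 0), 1))), path)
  invisible(path)
}
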