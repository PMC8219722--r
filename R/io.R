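#' Load an ultrasound image as a grey-value matrix
#'
#' Reads an 8-bit PNG, TIFF or BMP raster and returns a numeric matrix of
#' grey values in \[0, 255\], indexed (row, col) with the origin at the
#' top-left. Colour inputs are converted to luminance with the ITU-R BT.601
#' weights (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path path to a PNG/TIFF/BMP file.
#' @return numeric matrix of grey values in \[0, 255\].
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeImagePng(matrix(runif(64 * 64, 0, 255), 64), f)
#' img <- loadImage(f)
#' dim(img)
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(.readBmp(path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image '", path, "': ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)   # [0,1], x = column-major width first
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    a <- if (nch >= 3L) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a[, , 1]
    }
  }
  if (length(a) == 0L) stop("zero-size image: ", path)
  # EBImage stores (x, y); transpose into (row, col)
  px <- t(a) * 255
  px[px < 0] <- 0; px[px > 255] <- 255
  px
}

# Minimal reader for uncompressed 8-bit (palette/grey) and 24-bit BMP files.
# BMP rows are stored bottom-up and padded to 4-byte multiples.
.readBmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop("unreadable BMP file: ", path)
  le <- function(idx) sum(as.integer(raw[idx]) * 256^(seq_along(idx) - 1))
  offset <- le(11:14)
  w <- le(19:22); h <- le(23:26)
  bpp <- le(29:30); comp <- le(31:34)
  if (comp != 0) stop("compressed BMP not supported: ", path)
  if (w < 1 || h < 1) stop("zero-size image: ", path)
  if (!bpp %in% c(8L, 24L)) stop("unsupported BMP bit depth: ", bpp)
  bytesPerPx <- bpp / 8L
  stride <- 4L * ceiling(w * bytesPerPx / 4)
  need <- offset + stride * h
  if (length(raw) < need) stop("truncated BMP file: ", path)
  px <- matrix(0, h, w)
  for (i in seq_len(h)) {
    rowStart <- offset + (i - 1L) * stride
    bytes <- as.integer(raw[rowStart + seq_len(w * bytesPerPx)])
    vals <- if (bpp == 8L) {
      bytes
    } else {  # stored B, G, R
      b <- bytes[seq(1, length(bytes), 3)]
      g <- bytes[seq(2, length(bytes), 3)]
      r <- bytes[seq(3, length(bytes), 3)]
      0.299 * r + 0.587 * g + 0.114 * b
    }
    px[h - i + 1L, ] <- vals   # bottom-up storage
  }
  px
}

#' Write a grey matrix as an 8-bit PNG
#'
#' @param px numeric matrix of grey values in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImagePng <- function(px, path) {
  stopifnot(is.matrix(px))
  EBImage::writeImage(EBImage::Image(t(px) / 255), path, type = "png")
  invisible(path)
}

#' Mirror an image along its axes
#'
#' Applying the same flip twice restores the original grid exactly. Used
#' when the scan does not show the medial border on the left and the
#' lateral border at the bottom, the layout the outline finder assumes.
#'
#' @param px grey matrix (row, col).
#' @param horizontal mirror left-right (columns reversed).
#' @param vertical mirror top-bottom (rows reversed).
#' @return flipped matrix.
#' @export
flipImage <- function(px, horizontal = FALSE, vertical = FALSE) {
  stopifnot(is.matrix(px))
  if (horizontal) px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
  if (vertical)   px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
  px
}
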