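#' Construct an image grid
#'
#' The package's internal image container: a 2-D grayscale raster stored as a
#' numeric matrix together with the dynamic-range peak used by [psnr()]. All
#' algorithmic modules operate on the 255-peak gray convention, so micrographs
#' stored as raw floats are normally passed through [rescale_to_peak()] (the
#' default behaviour of [read_image()] for MRC).
#'
#' @param pixels Numeric matrix of gray levels (rows = image rows).
#' @param peak Positive scalar: the nominal dynamic-range maximum (default 255).
#' @return An object of class `ImageGrid`.
#' @export
image_grid <- function(pixels, peak = 255) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("image contains non-finite pixel values")
  if (!is.numeric(peak) || length(peak) != 1L || peak <= 0)
    stop("`peak` must be a positive scalar")
  structure(list(pixels = pixels, peak = as.numeric(peak)),
            class = "ImageGrid")
}

#' @export
print.ImageGrid <- function(x, ...) {
  cat(sprintf("ImageGrid %d x %d, peak %g, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$peak,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ImageGrid <- function(x) dim(x$pixels)

as_image_grid <- function(x, peak = 255) {
  if (inherits(x, "ImageGrid")) x else image_grid(as.matrix(x), peak = peak)
}

# ---- MRC2014 (little-endian, modes 0/1/2/6) ---------------------------------
# Header layout (bytes): nx,ny,nz,mode at 0..15; nsymbt at 92; "MAP " at 208.
# Data start at 1024 + nsymbt.

mrc_mode_info <- function(mode) {
  switch(as.character(mode),
         "0" = list(what = "integer", size = 1L, signed = TRUE),
         "1" = list(what = "integer", size = 2L, signed = TRUE),
         "2" = list(what = "numeric", size = 4L, signed = TRUE),
         "6" = list(what = "integer", size = 2L, signed = FALSE),
         stop(sprintf("unsupported MRC mode %s (supported: 0, 1, 2, 6)", mode)))
}

read_mrc <- function(path, slice = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  nsymbt <- hdr_int[24]
  if (is.na(nx) || nx < 1 || ny < 1 || nz < 1 || nx > 1e6 || ny > 1e6)
    stop(sprintf("'%s' does not look like a little-endian MRC file", path))
  if (nz > 1L && is.null(slice))
    stop(sprintf(paste0("'%s' is a 3-D stack of %d sections; pass `slice` ",
                        "(CLI flag --slice) to select one"), path, nz))
  if (is.null(slice)) slice <- 1L
  if (slice < 1L || slice > nz)
    stop(sprintf("slice %d out of range 1..%d", slice, nz))
  info <- mrc_mode_info(mode)
  seek(con, where = 1024 + nsymbt + (slice - 1) * nx * ny * info$size)
  raw <- readBin(con, info$what, n = nx * ny, size = info$size,
                 signed = info$signed, endian = "little")
  if (length(raw) != nx * ny)
    stop(sprintf("'%s': truncated MRC data section", path))
  # MRC stores columns (x) fastest; map to an ny x nx R matrix (row = y).
  matrix(as.numeric(raw), nrow = ny, ncol = nx, byrow = TRUE)
}

write_mrc <- function(pixels, path) {
  ny <- nrow(pixels); nx <- ncol(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- integer(256)
  hdr[1:4] <- c(nx, ny, 1L, 2L)           # nx, ny, nz, mode 2 (float32)
  hdr[8:10] <- c(nx, ny, 1L)              # mx, my, mz
  hdr[17:19] <- c(1L, 2L, 3L)             # mapc, mapr, maps
  writeBin(hdr[1:19], con, size = 4L, endian = "little")
  writeBin(c(min(pixels), max(pixels), mean(pixels)), con, size = 4L,
           endian = "little")             # dmin, dmax, dmean
  writeBin(integer(30), con, size = 4L, endian = "little")  # ispg..extra
  writeBin(charToRaw("MAP "), con)                          # word 53
  writeBin(c(0x44L, 0x44L, 0x00L, 0x00L), con, size = 1L)   # LE machine stamp
  writeBin(0, con, size = 4L, endian = "little")            # rms (placeholder)
  writeBin(integer(256 - 55), con, size = 4L, endian = "little")
  writeBin(as.numeric(t(pixels)), con, size = 4L, endian = "little")
  invisible(NULL)
}

guess_kind <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mrc = "mrc", mrcs = "mrc", map = "mrc",
         tif = "tiff", tiff = "tiff",
         png = "png",
         stop(sprintf("cannot infer image format from extension '.%s'; pass `kind`",
                      ext)))
}

#' Read a grayscale image
#'
#' Reads MRC2014 (modes 0, 1, 2, 6), grayscale TIFF or 8/16-bit grayscale PNG
#' into an [image_grid()]. MRC floats are by default affinely rescaled onto
#' the 0..255 gray convention used throughout the package (disable with
#' `rescale = FALSE`); TIFF/PNG values are returned on the 0..`peak` scale.
#'
#' @param path Path to the image file.
#' @param kind One of `"auto"`, `"mrc"`, `"tiff"`, `"png"`.
#' @param peak Dynamic-range peak of the returned image (default 255).
#' @param rescale For MRC input: rescale pixel range onto `[0, peak]`
#'   (default `TRUE`; constant images are left as stored).
#' @param slice For 3-D MRC stacks: 1-based section to read.
#' @return An `ImageGrid`.
#' @export
read_image <- function(path, kind = "auto", peak = 255, rescale = TRUE,
                       slice = NULL) {
  if (dir.exists(path))
    stop(sprintf("'%s' is a directory, not an image file", path))
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path))
  if (identical(kind, "auto")) kind <- guess_kind(path)
  px <- switch(kind,
    mrc = read_mrc(path, slice = slice),
    tiff = {
      m <- tiff::readTIFF(path)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      m * peak
    },
    png = {
      m <- png::readPNG(path)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      m * peak
    },
    stop(sprintf("unknown image kind '%s'", kind)))
  if (!is.matrix(px)) px <- as.matrix(px)
  img <- image_grid(px, peak = peak)
  if (identical(kind, "mrc") && rescale && diff(range(px)) > 0)
    img <- rescale_to_peak(img, peak)
  img
}

#' Write a grayscale image
#'
#' MRC is written as mode 2 (32-bit float) with pixel values as stored, so an
#' MRC round trip is exact at float32 precision. TIFF is written as 32-bit
#' float with values scaled by the image peak (TIFF floats live in `[0, 1]`).
#' PNG is 8-bit; out-of-range values are clipped when `clip = TRUE`, otherwise
#' they are an error.
#'
#' @param img An `ImageGrid`.
#' @param path Output path.
#' @param kind One of `"auto"`, `"mrc"`, `"tiff"`, `"png"`.
#' @param clip For PNG: clip values to `[0, peak]` before 8-bit quantization.
#' @export
write_image <- function(img, path, kind = "auto", clip = FALSE) {
  img <- as_image_grid(img)
  if (identical(kind, "auto")) kind <- guess_kind(path)
  px <- img$pixels
  switch(kind,
    mrc = write_mrc(px, path),
    tiff = {
      if (min(px) < 0 || max(px) > img$peak)
        stop("TIFF output requires values in [0, peak]; see rescale_to_peak()")
      tiff::writeTIFF(px / img$peak, path, bits.per.sample = 32L)
    },
    png = {
      if (!clip && (min(px) < 0 || max(px) > img$peak))
        stop("PNG values outside [0, peak]; pass clip = TRUE or rescale first")
      q <- pmin(pmax(px, 0), img$peak) / img$peak
      png::writePNG(q, path)
    },
    stop(sprintf("unknown image kind '%s'", kind)))
  invisible(NULL)
}

#' Rescale an image onto a target peak
#'
#' Affine map of the pixel range onto `[0, peak]`: the minimum maps to 0 and
#' the maximum to `peak`. Used to bring raw-float micrographs onto the 255
#' gray convention assumed by the block-size rule and the PSNR formula.
#'
#' @param img An `ImageGrid` (or matrix).
#' @param peak Target peak (default 255).
#' @param from Optional length-2 source range overriding the observed range
#'   (required for constant images).
#' @return A rescaled `ImageGrid` with `peak` set accordingly.
#' @export
rescale_to_peak <- function(img, peak = 255, from = NULL) {
  img <- as_image_grid(img)
  if (is.null(from)) from <- range(img$pixels)
  if (diff(from) <= 0)
    stop("constant image: scale undefined; pass an explicit `from` range")
  image_grid((img$pixels - from[1]) / diff(from) * peak, peak = peak)
}
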