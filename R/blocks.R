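#' Noise-adaptive block size
#'
#' Chooses the patch side length from the noise standard deviation on the
#' 255-peak gray scale: p = 6 for sigma in (0, 20], 7 in (20, 30], 8 in
#' (30, 50], 9 in (50, 100). An explicit user choice always takes precedence
#' over this rule.
#'
#' @param sigma Noise standard deviation, gray units (255 scale).
#' @return Integer block side length.
#' @export
select_block_size <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma))
    stop("`sigma` must be a finite scalar")
  if (sigma <= 0 || sigma >= 100)
    stop("block-size rule covers 0 < sigma < 100; pass the block size `p` explicitly")
  if (sigma <= 20) 6L else if (sigma <= 30) 7L else if (sigma <= 50) 8L else 9L
}

#' Overlapping patch extraction
#'
#' Extracts the stride grid of p-by-p patches covering the whole image: patch
#' top-left rows are `0, stride, ...` plus the clamped last position
#' `height - p` (likewise for columns), so border pixels are always covered
#' without padding.
#'
#' @param img `ImageGrid` or matrix.
#' @param p Patch side length (>= 2).
#' @param stride Grid step, `1 <= stride <= p` for full coverage guarantees.
#' @return A `PatchSet`: list with `coords` (n x 2 integer matrix of 0-based
#'   top-left row/col), `p`, `stride`, `height`, `width`.
#' @export
extract_patches <- function(img, p, stride = 1L) {
  img <- as_image_grid(img)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  p <- as.integer(p); stride <- as.integer(stride)
  if (p < 2L) stop("`p` must be at least 2")
  if (p > h || p > w)
    stop(sprintf("patch size %d exceeds image dimensions %d x %d", p, h, w))
  if (stride < 1L) stop("`stride` must be positive")
  rows <- unique(c(seq.int(0L, h - p, by = stride), h - p))
  cols <- unique(c(seq.int(0L, w - p, by = stride), w - p))
  coords <- cbind(row = rep(rows, times = length(cols)),
                  col = rep(cols, each = length(rows)))
  structure(list(coords = coords, p = p, stride = stride,
                 height = h, width = w),
            class = "PatchSet")
}

#' @export
print.PatchSet <- function(x, ...) {
  cat(sprintf("PatchSet: %d patches of %d x %d (stride %d) over %d x %d image\n",
              nrow(x$coords), x$p, x$p, x$stride, x$height, x$width))
  invisible(x)
}

# n x p^2 matrix of patch vectors (column-major within each patch).
patch_matrix <- function(pixels, coords, p) {
  h <- nrow(pixels)
  # linear index of each patch's top-left pixel (1-based, column-major)
  base <- coords[, 1L] + coords[, 2L] * h + 1L
  # offsets of the p x p window in the column-major image
  off <- as.vector(outer(seq_len(p) - 1L, (seq_len(p) - 1L) * h, `+`))
  m <- pixels[rep(base, times = p * p) + rep(off, each = length(base))]
  dim(m) <- c(length(base), p * p)
  m
}

#' Extract patch vectors as a matrix
#'
#' @param img `ImageGrid` or matrix.
#' @param patches A `PatchSet` from [extract_patches()].
#' @return Numeric matrix, one row per patch (length p^2, column-major pixels).
#' @export
patch_values <- function(img, patches) {
  img <- as_image_grid(img)
  patch_matrix(img$pixels, patches$coords, patches$p)
}

#' Aggregate denoised patches into an image
#'
#' Every output pixel is the weighted average of all patch estimates covering
#' it (uniform weights by default, i.e. the plain mean of overlapping
#' estimates). Errors if any pixel is left uncovered.
#'
#' @param values Matrix of patch vectors, one row per patch (as from
#'   [patch_values()], possibly denoised).
#' @param coords n x 2 matrix of 0-based top-left coordinates.
#' @param p Patch side length.
#' @param dims Length-2 output dimensions `c(height, width)`.
#' @param weights Optional per-patch positive weights.
#' @param peak Peak for the returned `ImageGrid`.
#' @return An `ImageGrid`.
#' @export
aggregate_patches <- function(values, coords, p, dims, weights = NULL,
                              peak = 255) {
  n <- nrow(coords)
  if (nrow(values) != n) stop("`values` and `coords` disagree on patch count")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("`weights` must be positive, one per patch")
  h <- dims[1]; w <- dims[2]
  base <- coords[, 1L] + coords[, 2L] * h + 1L
  off <- as.vector(outer(seq_len(p) - 1L, (seq_len(p) - 1L) * h, `+`))
  idx <- rep(base, times = p * p) + rep(off, each = n)
  acc <- numeric(h * w)
  wt <- numeric(h * w)
  wv <- as.vector(values) * weights       # weights recycle down rows
  # accumulate by linear pixel index
  sums <- rowsum(cbind(wv, rep(weights, times = p * p)), group = idx)
  pix <- as.integer(rownames(sums))
  acc[pix] <- sums[, 1L]
  wt[pix] <- sums[, 2L]
  if (any(wt == 0))
    stop("aggregation left uncovered pixels; patch grid does not tile the image")
  image_grid(matrix(acc / wt, h, w), peak = peak)
}
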