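# Image quality indicators: MSE, PSNR, SNR, SSIM.

check_same_shape <- function(x, y) {
  if (!all(dim(x$pixels) == dim(y$pixels)))
    stop("images have different shapes")
}

#' Mean squared error
#'
#' Mean squared per-pixel difference, `1/(H*W) * sum (xhat - x)^2`.
#'
#' @param x,xhat Images (`ImageGrid` or matrix) of the same shape.
#' @return Non-negative scalar.
#' @export
mse <- function(x, xhat) {
  x <- as_image_grid(x); xhat <- as_image_grid(xhat)
  check_same_shape(x, xhat)
  mean((x$pixels - xhat$pixels)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB; `Inf` for identical images. The default
#' peak 255 matches the package's gray convention, under which adding
#' Gaussian noise of standard deviation sigma to a large image yields
#' approximately `10*log10(255^2/sigma^2)` dB.
#'
#' @param x,xhat Images of the same shape.
#' @param peak Dynamic-range peak (default: `x`'s peak, normally 255).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(x, xhat, peak = NULL) {
  x <- as_image_grid(x)
  if (is.null(peak)) peak <- x$peak
  m <- mse(x, xhat)
  if (m == 0) Inf else 10 * log10(peak^2 / m)
}

#' Signal-to-noise ratio from powers
#'
#' `10 * log10(P_s / P_n)` in dB.
#'
#' @param signal_power,noise_power Positive powers.
#' @return SNR in dB.
#' @export
snr <- function(signal_power, noise_power) {
  if (signal_power <= 0 || noise_power <= 0)
    stop("powers must be positive")
  10 * log10(signal_power / noise_power)
}

# box-filter local sums over all w x w sliding windows via an integral image
box_sums <- function(m, w) {
  S <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # transposed integral image
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  h <- nrow(m); wd <- ncol(m)
  r <- seq_len(h - w + 1L); c <- seq_len(wd - w + 1L)
  S[r + w, c + w, drop = FALSE] - S[r, c + w, drop = FALSE] -
    S[r + w, c, drop = FALSE] + S[r, c, drop = FALSE]
}

#' Structural similarity index
#'
#' Local means, variances and covariance over uniform sliding windows plugged
#' into `(2*mu1*mu2 + c1)*(2*cov + c2) / ((mu1^2 + mu2^2 + c1)*(var1 + var2 +
#' c2))`, averaged over all windows, with the standard constants
#' `c1 = (0.01*peak)^2`, `c2 = (0.03*peak)^2`. `literal = TRUE` uses `c1` in
#' place of `c2` in the variance term of the denominator (a published variant
#' of the formula retained for comparability).
#'
#' @param x,xhat Images of the same shape.
#' @param peak Dynamic-range peak (default: `x`'s peak).
#' @param window Window side length (default 8, uniform weights).
#' @param literal Use c1 as the variance-term constant in the denominator.
#' @return Mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, xhat, peak = NULL, window = 8L, literal = FALSE) {
  x <- as_image_grid(x); xhat <- as_image_grid(xhat)
  check_same_shape(x, xhat)
  if (is.null(peak)) peak <- x$peak
  a <- x$pixels; b <- xhat$pixels
  if (window > min(dim(a))) stop("SSIM window exceeds the image")
  n <- window^2
  mu1 <- box_sums(a, window) / n
  mu2 <- box_sums(b, window) / n
  v1 <- box_sums(a^2, window) / n - mu1^2
  v2 <- box_sums(b^2, window) / n - mu2^2
  cv <- box_sums(a * b, window) / n - mu1 * mu2
  c1 <- (0.01 * peak)^2
  c2 <- (0.03 * peak)^2
  cden <- if (literal) c1 else c2
  s <- ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + cden))
  mean(s)
}

#' All quality indicators at once
#'
#' @param x Reference (clean) image.
#' @param xhat Test (denoised) image.
#' @param peak Dynamic-range peak.
#' @param window SSIM window.
#' @return List with `mse`, `psnr`, `snr` (signal power = mean square of the
#'   reference, noise power = MSE) and `ssim`.
#' @export
quality_scores <- function(x, xhat, peak = NULL, window = 8L) {
  x <- as_image_grid(x); xhat <- as_image_grid(xhat)
  if (is.null(peak)) peak <- x$peak
  m <- mse(x, xhat)
  list(mse = m,
       psnr = psnr(x, xhat, peak),
       snr = if (m > 0) snr(mean(x$pixels^2), m) else Inf,
       ssim = ssim(x, xhat, peak, window))
}
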