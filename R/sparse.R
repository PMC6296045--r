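# Weighted soft-threshold sparse coding in the group dictionary.

#' Eigenvalue-dependent sparse coding weights
#'
#' `w_i = c * 2*sqrt(2) * sigma^2 / (lambda_i + eps)`: atoms with large
#' eigenvalues (strong recurring structure) are shrunk little, noise-dominated
#' atoms are shrunk hard. `sigma` is the current iteration's noise level.
#'
#' @param spectrum Non-negative eigenvalues lambda of the group dictionary.
#' @param sigma Noise standard deviation (gray units).
#' @param c Positive scaling constant (default 50).
#' @param eps Positive stabilizer added to the eigenvalues (default 1e-6).
#' @return Vector of positive weights (zero when `sigma = 0`).
#' @export
coding_weights <- function(spectrum, sigma, c = 50, eps = 1e-6) {
  if (eps <= 0) stop("`eps` must be positive")
  if (c <= 0) stop("`c` must be positive")
  if (any(spectrum < 0)) stop("eigenvalues must be non-negative")
  c * 2 * sqrt(2) * sigma^2 / (spectrum + eps)
}

#' Soft thresholding (SoftMAP)
#'
#' `sgn(z_i) * max(|z_i| - tau_i, 0)`, the closed-form minimizer of the
#' separable objective `0.5*(a - z_i)^2 + tau_i*|a|`.
#'
#' @param z Transform coefficients (vector or matrix; a matrix is thresholded
#'   column-wise with `tau` recycled down the rows).
#' @param tau Non-negative threshold(s).
#' @return Shrunk coefficients, same shape as `z`.
#' @export
soft_map <- function(z, tau) {
  if (any(tau < 0)) stop("`tau` must be non-negative")
  sign(z) * pmax(abs(z) - tau, 0)
}

#' Denoise one centered patch in its group dictionary
#'
#' Analysis, weighted shrinkage, synthesis: `z = t(D) %*% ybar`,
#' `alpha = soft_map(z, w/2)` with `w` from [coding_weights()], and the
#' estimate `mu_y + D %*% alpha`. With an orthonormal D and `sigma = 0` this
#' is the identity `mu_y + D t(D) ybar = y`.
#'
#' @param group_mean Group mean `mu_y` (length p^2).
#' @param dict A `GroupDictionary`.
#' @param member Centered member `ybar_m` (length p^2, or p^2 x M matrix of
#'   centered members to denoise a whole group at once).
#' @param sigma Current noise level.
#' @param c,eps Weight constants, see [coding_weights()].
#' @return Denoised patch vector(s), same shape as `member` plus the mean.
#' @export
denoise_patch <- function(group_mean, dict, member, sigma, c = 50,
                          eps = 1e-6) {
  D <- dict$basis
  if (NROW(member) != nrow(D))
    stop("patch dimension does not match the dictionary")
  w <- coding_weights(dict$spectrum, sigma, c, eps)
  z <- crossprod(D, member)
  alpha <- soft_map(z, w / 2)
  group_mean + D %*% alpha
}
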