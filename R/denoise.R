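#' Denoising configuration
#'
#' Collects the tunable parameters of the iterative patch-group denoiser.
#' Defaults are chosen for 640x640-class micrographs on the 255-peak gray
#' scale; every value can be overridden per run (and from the CLI).
#'
#' @param sigma Assumed noise standard deviation, gray units (required).
#' @param p Block side length; 0 selects it from `sigma` via
#'   [select_block_size()].
#' @param stride Patch-grid stride of the outer loop (default 3; 1 is the
#'   densest, most expensive choice).
#' @param n_refs Number of reference blocks N (default `ceiling(n/64)`).
#' @param group_size Group size M for the nearest-M analysis path (the
#'   denoising loop itself partitions all patches by nearest reference).
#' @param K Mixture components (default 32).
#' @param em_iters EM iterations per prior fit (default 100).
#' @param outer_iters Outer denoising iterations (default 4).
#' @param eta Noise-update factor in (0, 1] (default 0.79).
#' @param c,eps Sparse-coding weight constants, see [coding_weights()].
#' @param metric Block-matching metric, `"geodesic"` or `"euclidean"`.
#' @param seed Integer seed controlling reference draws and EM initialization.
#' @param tan_cap Finite stand-in for tan(pi/2) in the geodesic metric.
#' @param fit_once Fit the prior on the first iteration only and reuse it.
#' @param noise_update_raw Use the literal unnormalized residual norm in the
#'   noise update instead of the per-pixel mean square.
#' @return A `DenoiseConfig` list.
#' @export
denoise_config <- function(sigma, p = 0L, stride = 3L, n_refs = NULL,
                           group_size = 64L, K = 32L, em_iters = 100L,
                           outer_iters = 4L, eta = 0.79, c = 50,
                           eps = 1e-6, metric = c("geodesic", "euclidean"),
                           seed = 1L, tan_cap = tan(pi / 2 - 0.01),
                           fit_once = FALSE, noise_update_raw = FALSE) {
  metric <- match.arg(metric)
  if (sigma <= 0) stop("`sigma` must be positive")
  if (eta <= 0 || eta > 1) stop("`eta` must lie in (0, 1]")
  if (outer_iters < 1L) stop("`outer_iters` must be at least 1")
  structure(list(sigma = sigma, p = as.integer(p), stride = as.integer(stride),
                 n_refs = n_refs, group_size = as.integer(group_size),
                 K = as.integer(K), em_iters = as.integer(em_iters),
                 outer_iters = as.integer(outer_iters), eta = eta, c = c,
                 eps = eps, metric = metric, seed = as.integer(seed),
                 tan_cap = tan_cap, fit_once = fit_once,
                 noise_update_raw = noise_update_raw),
            class = "DenoiseConfig")
}

#' Iteration noise update
#'
#' `sigma_t = sqrt(eta * max(sigma0^2 - meanSq(y - y_prev), 0))`: the variance
#' already explained by the previous estimate is subtracted from the nominal
#' noise variance and the remainder damped by `eta`. The residual norm is the
#' per-pixel mean square by default (`raw = TRUE` uses the unnormalized sum,
#' which is only meaningful for tiny images).
#'
#' @param sigma0 Initial noise standard deviation.
#' @param y Observed image.
#' @param y_prev Previous estimate.
#' @param eta Damping factor in (0, 1].
#' @param raw Use the unnormalized squared norm.
#' @return Updated noise standard deviation (non-negative).
#' @export
update_noise <- function(sigma0, y, y_prev, eta, raw = FALSE) {
  y <- as_image_grid(y); y_prev <- as_image_grid(y_prev)
  if (!all(dim(y$pixels) == dim(y_prev$pixels)))
    stop("image shapes differ")
  if (eta <= 0 || eta > 1) stop("`eta` must lie in (0, 1]")
  r2 <- (y$pixels - y_prev$pixels)^2
  resid <- if (raw) sum(r2) else mean(r2)
  sqrt(eta * max(sigma0^2 - resid, 0))
}

#' Denoise a micrograph
#'
#' The full iterative pipeline: extract overlapping patches of the current
#' estimate, partition them into similar-block groups by nearest reference
#' under the configured metric, learn (or reuse) the Gaussian mixture prior
#' over the centered groups, pick each group's best component, take the
#' eigenvector dictionary of its covariance, denoise the group's patches from
#' the ORIGINAL noisy image by weighted soft-threshold sparse coding around
#' the group mean, aggregate the estimates by averaging, and update the noise
#' level; repeated `outer_iters` times. Fully deterministic for a fixed seed.
#'
#' @param y Observed `ImageGrid` (or matrix).
#' @param cfg A [denoise_config()].
#' @param clean Optional clean reference image; when given, the report traces
#'   per-iteration PSNR.
#' @return List with `estimate` (`ImageGrid`) and `report`: per-iteration
#'   noise levels `sigma_t`, `psnr_t` (if `clean` given), group-count trace,
#'   and elapsed seconds per iteration.
#' @export
denoise_image <- function(y, cfg, clean = NULL) {
  y <- as_image_grid(y)
  if (!inherits(cfg, "DenoiseConfig")) stop("`cfg` must be a denoise_config()")
  p <- if (cfg$p > 0L) cfg$p else select_block_size(cfg$sigma)
  dims <- dim(y$pixels)
  if (!is.null(clean)) clean <- as_image_grid(clean)

  x_cur <- y
  sigma_t <- cfg$sigma
  sig_trace <- numeric(0); psnr_trace <- numeric(0)
  ngroup_trace <- integer(0); time_trace <- numeric(0)
  prior <- NULL

  for (t in seq_len(cfg$outer_iters)) {
    t0 <- proc.time()[["elapsed"]]
    groups <- tryCatch(
      build_groups(x_cur, p = p, stride = cfg$stride, n_refs = cfg$n_refs,
                   metric = cfg$metric, seed = cfg$seed + t - 1L,
                   partition = TRUE, tan_cap = cfg$tan_cap),
      error = function(e) stop("block grouping failed: ", conditionMessage(e)))
    patches <- attr(groups, "patches")
    # data-fidelity patches come from the original noisy image
    V_y <- patch_values(y, patches)

    if (is.null(prior) || !cfg$fit_once) {
      K_eff <- min(cfg$K, length(groups))
      prior <- tryCatch(
        fit_gmm(groups, K = K_eff, iters = cfg$em_iters,
                seed = cfg$seed + 1000L + t,
                reg = max(1e-4 * cfg$sigma^2, 1e-8)),
        error = function(e) stop("prior learning failed: ", conditionMessage(e)))
    }

    est <- matrix(0, nrow(V_y), ncol(V_y))
    for (g in groups) {
      Yg <- t(V_y[g$members, , drop = FALSE])
      mu <- rowMeans(Yg)
      k <- select_component(g, prior)
      dict <- dictionary_from_component(prior$covs[[k]])
      est[g$members, ] <- t(denoise_patch(mu, dict, Yg - mu, sigma_t,
                                          cfg$c, cfg$eps))
    }
    x_new <- tryCatch(
      aggregate_patches(est, patches$coords, p, dims, peak = y$peak),
      error = function(e) stop("aggregation failed: ", conditionMessage(e)))

    sigma_t <- update_noise(cfg$sigma, y, x_new, cfg$eta,
                            raw = cfg$noise_update_raw)
    sig_trace <- c(sig_trace, sigma_t)
    ngroup_trace <- c(ngroup_trace, length(groups))
    time_trace <- c(time_trace, proc.time()[["elapsed"]] - t0)
    if (!is.null(clean)) psnr_trace <- c(psnr_trace, psnr(clean, x_new))
    x_cur <- x_new
  }
  list(estimate = x_cur,
       report = list(sigma_t = sig_trace, psnr_t = psnr_trace,
                     n_groups = ngroup_trace, seconds = time_trace,
                     p = p, config = unclass(cfg)))
}
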