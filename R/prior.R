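# Gaussian mixture prior over centered patch groups.
#
# The mixture is learned at the GROUP level: one latent component is shared by
# all M members of a similar-block group, so the E-step responsibility of
# component k for group n involves the product over members of the member
# densities (a sum of log-densities).

chol_logdens <- function(X, mean, Sigma) {
  # columns of X; returns per-column log N(x | mean, Sigma)
  d <- nrow(X)
  R <- chol(Sigma)
  Z <- backsolve(R, X - mean, transpose = TRUE)
  -0.5 * colSums(Z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

#' Fit a Gaussian mixture prior over centered patch groups
#'
#' Maximizes the group-level mixture log-likelihood
#' `sum_n log( sum_k pi_k prod_m N(ybar_{n,m} | mu_k, Sigma_k) )`
#' by EM with component responsibilities shared across each group's members.
#' The prior is learned directly on the noisy centered patches (no clean
#' training set). Covariances are floored at `reg * I`. Initialization is a
#' seeded k-means over (a subsample of) the centered patch vectors.
#'
#' @param groups List of `PatchGroup`s from [build_groups()].
#' @param K Number of mixture components.
#' @param iters EM iterations.
#' @param seed Seed for the k-means initialization.
#' @param reg Covariance regularization floor (added as `reg * I`).
#' @return A `GMMPrior`: list with `K`, `d`, `mix`, `means` (d x K),
#'   `covs` (list of d x d), `loglik` (per-iteration trace).
#' @export
fit_gmm <- function(groups, K = 32L, iters = 100L, seed = 1L, reg = 1e-4) {
  N <- length(groups)
  K <- as.integer(K); iters <- as.integer(iters)
  if (K < 1L) stop("K must be at least 1")
  if (K > N) stop(sprintf("K = %d exceeds the %d available groups", K, N))
  X <- do.call(cbind, lapply(groups, `[[`, "Yc"))   # d x total
  gidx <- rep(seq_len(N), vapply(groups, function(g) ncol(g$Yc), 1L))
  d <- nrow(X); total <- ncol(X)
  if (total < K) stop("fewer centered patches than components")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  sub <- if (total > 5000L) sample.int(total, 5000L) else seq_len(total)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(t(X[, sub, drop = FALSE]), centers = K,
                                   iter.max = 25L, nstart = 1L)),
    error = function(e) {
      # degenerate data (e.g. duplicated points): seeded random partition
      cl <- sample(rep_len(seq_len(K), length(sub)))
      list(cluster = cl,
           centers = t(vapply(seq_len(K),
                              function(k) rowMeans(X[, sub[cl == k], drop = FALSE]),
                              numeric(nrow(X)))))
    })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  mix <- as.numeric(table(factor(km$cluster, levels = seq_len(K)))) / length(sub)
  mix <- pmax(mix, 1e-8); mix <- mix / sum(mix)
  means <- unname(t(km$centers))                     # d x K
  covs <- lapply(seq_len(K), function(k) {
    Xi <- X[, sub[km$cluster == k], drop = FALSE]
    S <- if (ncol(Xi) > d) stats::cov(t(Xi)) else diag(stats::var(as.vector(X)), d)
    S + reg * diag(d)
  })

  loglik <- numeric(iters)
  logg <- matrix(0, N, K)
  for (it in seq_len(iters)) {
    # E-step: group-level log responsibilities
    for (k in seq_len(K)) {
      ld <- chol_logdens(X, means[, k], covs[[k]])
      logg[, k] <- log(mix[k]) + rowsum(ld, gidx)[, 1L]
    }
    m <- apply(logg, 1L, max)
    lse <- m + log(rowSums(exp(logg - m)))
    loglik[it] <- sum(lse)
    if (!is.finite(loglik[it]))
      stop("non-finite mixture log-likelihood; raise `reg`")
    G <- exp(logg - lse)                             # N x K responsibilities
    # M-step (member weight = its group's responsibility)
    Wm <- G[gidx, , drop = FALSE]                    # total x K
    Nk <- colSums(Wm)
    mix <- colSums(G) / N
    mix <- pmax(mix, 1e-10); mix <- mix / sum(mix)
    new_means <- sweep(X %*% Wm, 2L, pmax(Nk, 1e-12), `/`)
    for (k in seq_len(K)) {
      if (Nk[k] < 1e-8) next   # starved component: keep previous parameters
      means[, k] <- new_means[, k]
      Xc <- X - means[, k]
      covs[[k]] <- tcrossprod(sweep(Xc, 2L, Wm[, k], `*`), Xc) / Nk[k] +
        reg * diag(d)
    }
  }
  structure(list(K = K, d = d, mix = mix, means = means, covs = covs,
                 loglik = loglik, reg = reg),
            class = "GMMPrior")
}

#' @export
print.GMMPrior <- function(x, ...) {
  cat(sprintf("GMMPrior: K = %d components over %d-dim centered patches\n",
              x$K, x$d))
  invisible(x)
}

#' Select the mixture component best explaining a group
#'
#' Bayesian component choice: `argmax_k sum_m log N(ybar_m | 0, Sigma_k)`.
#' The group is scored against each component's covariance with mean zero
#' (the centered group already has mean zero); the normalizing constant is
#' the same for every k and drops out of the argmax. Ties break to the
#' lowest component index.
#'
#' @param group A `PatchGroup`.
#' @param prior A `GMMPrior` fitted at the same patch dimension.
#' @return Integer component index in `1..K`.
#' @export
select_component <- function(group, prior) {
  if (nrow(group$Yc) != prior$d)
    stop("patch dimension of the group does not match the prior")
  scores <- component_scores(group$Yc, prior)
  which.max(scores)
}

component_scores <- function(Yc, prior) {
  vapply(seq_len(prior$K),
         function(k) sum(chol_logdens(Yc, 0, prior$covs[[k]])),
         numeric(1))
}

#' Orthonormal dictionary from a component covariance
#'
#' Eigendecomposition (SVD of a symmetric PSD matrix) of the selected
#' component's covariance: the dictionary D is the eigenvector basis sorted
#' by non-increasing eigenvalue; the spectrum supplies the per-atom sparse
#' coding weights. Sign convention: the largest-magnitude entry of each
#' column is positive.
#'
#' @param cov Symmetric positive semi-definite matrix.
#' @param tol Symmetry tolerance (relative).
#' @return A `GroupDictionary`: list with `basis` (orthonormal D), `spectrum`
#'   (non-increasing eigenvalues, floored at 0).
#' @export
dictionary_from_component <- function(cov, tol = 1e-8) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop("`cov` must be a square matrix")
  if (max(abs(cov - t(cov))) > tol * max(1, max(abs(cov))))
    stop("`cov` is not symmetric")
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  D <- e$vectors
  flip <- apply(D, 2L, function(col) col[which.max(abs(col))] < 0)
  D[, flip] <- -D[, flip]
  structure(list(basis = D, spectrum = pmax(e$values, 0)),
            class = "GroupDictionary")
}

#' Save / load a fitted prior
#'
#' Flat little-endian binary layout: magic "GMMP", int32 K, int32 d, then
#' doubles: mix (K), means (d*K column-major), covariances (d*d*K, one
#' column-major matrix per component).
#'
#' @param prior A `GMMPrior`.
#' @param path File path.
#' @export
save_prior <- function(prior, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("GMMP"), con)
  writeBin(as.integer(c(prior$K, prior$d)), con, size = 4L, endian = "little")
  writeBin(as.numeric(prior$mix), con, size = 8L, endian = "little")
  writeBin(as.numeric(prior$means), con, size = 8L, endian = "little")
  for (S in prior$covs)
    writeBin(as.numeric(S), con, size = 8L, endian = "little")
  invisible(NULL)
}

#' @rdname save_prior
#' @return `load_prior` returns the `GMMPrior`.
#' @export
load_prior <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  if (!identical(rawToChar(readBin(con, "raw", 4L)), "GMMP"))
    stop(sprintf("'%s' is not a saved prior", path))
  hd <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  K <- hd[1]; d <- hd[2]
  mix <- readBin(con, "numeric", K, size = 8L, endian = "little")
  means <- matrix(readBin(con, "numeric", d * K, size = 8L, endian = "little"),
                  d, K)
  covs <- lapply(seq_len(K), function(k)
    matrix(readBin(con, "numeric", d * d, size = 8L, endian = "little"), d, d))
  structure(list(K = K, d = d, mix = mix, means = means, covs = covs,
                 loglik = numeric(0), reg = NA_real_),
            class = "GMMPrior")
}
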