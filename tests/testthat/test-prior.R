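# groups can be built directly for prior tests: fit_gmm touches only $Yc
fake_group <- function(Yc) structure(list(Yc = Yc), class = "PatchGroup")

test_that("single-component fit recovers the closed-form M-step", {
  set.seed(51)
  d <- 6
  groups <- lapply(1:12, function(i) fake_group(matrix(rnorm(d * 8), d, 8)))
  fit <- fit_gmm(groups, K = 1, iters = 5, seed = 1, reg = 1e-6)
  X <- do.call(cbind, lapply(groups, `[[`, "Yc"))
  expect_equal(fit$mix, 1)
  expect_equal(as.vector(fit$means), rowMeans(X), tolerance = 1e-8)
  S <- tcrossprod(X - rowMeans(X)) / ncol(X)
  expect_equal(fit$covs[[1]], S + 1e-6 * diag(d), tolerance = 1e-8)
})

test_that("EM log-likelihood is non-decreasing and recovery works", {
  set.seed(52)
  d <- 4
  mA <- rep(-4, d); mB <- rep(4, d)
  groups <- c(
    lapply(1:30, function(i) fake_group(mA + matrix(rnorm(d * 8), d, 8))),
    lapply(1:30, function(i) fake_group(mB + matrix(rnorm(d * 8), d, 8))))
  fit <- fit_gmm(groups, K = 2, iters = 40, seed = 2, reg = 1e-6)
  ll <- fit$loglik
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-length(ll)])))
  # means within 3 standard errors of truth (240 draws per component, sd 1)
  se <- 1 / sqrt(240)
  ord <- order(fit$means[1, ])
  expect_true(all(abs(fit$means[, ord[1]] - mA) < 3 * se))
  expect_true(all(abs(fit$means[, ord[2]] - mB) < 3 * se))
  expect_equal(sum(fit$mix), 1)
})

test_that("fit_gmm validates its inputs", {
  g <- lapply(1:3, function(i) fake_group(matrix(rnorm(8), 4, 2)))
  expect_error(fit_gmm(g, K = 5, iters = 2, seed = 1), "exceeds")
  expect_error(fit_gmm(g, K = 0, iters = 2, seed = 1), "at least 1")
})

test_that("component selection matches the brute-force scorer", {
  set.seed(53)
  d <- 5
  covs <- list(diag(d), 0.3 * diag(d) + 0.2, 100 * diag(d))
  prior <- structure(list(K = 3, d = d, mix = rep(1 / 3, 3),
                          means = matrix(0, d, 3), covs = covs),
                     class = "GMMPrior")
  for (s in 1:40) {
    set.seed(s)
    Yc <- matrix(rnorm(d * 6), d, 6)
    g <- fake_group(Yc)
    scores <- geodenoise:::component_scores(Yc, prior)
    expect_equal(scores, naive_component_scores(Yc, covs), tolerance = 1e-8)
    expect_identical(select_component(g, prior), which.max(scores))
  }
  # argmax invariant to adding a constant to all scores (log C drops out)
  Yc <- matrix(rnorm(d * 6), d, 6)
  s0 <- geodenoise:::component_scores(Yc, prior)
  expect_identical(which.max(s0), which.max(s0 + 123.4))
})

test_that("a group drawn from a covariance prefers that covariance", {
  set.seed(54)
  d <- 6
  A <- crossprod(matrix(rnorm(d * d), d)) / d + diag(d)
  prior <- structure(list(K = 2, d = d, mix = c(0.5, 0.5),
                          means = matrix(0, d, 2),
                          covs = list(A, A * 100)),
                     class = "GMMPrior")
  Yc <- t(chol(A)) %*% matrix(rnorm(d * 20), d, 20)
  expect_identical(select_component(fake_group(Yc), prior), 1L)
  expect_error(select_component(fake_group(matrix(0, 3, 2)), prior),
               "dimension")
})

test_that("dictionary extraction is an orthonormal eigendecomposition", {
  d2 <- dictionary_from_component(diag(c(4, 1)))
  expect_equal(d2$spectrum, c(4, 1))
  expect_equal(abs(d2$basis), diag(2))

  iso <- dictionary_from_component(diag(3))
  expect_equal(iso$spectrum, rep(1, 3))
  expect_equal(crossprod(iso$basis), diag(3), tolerance = 1e-10)

  set.seed(55)
  M <- matrix(rnorm(49), 7)
  S <- crossprod(M)
  dict <- dictionary_from_component(S)
  expect_equal(crossprod(dict$basis), diag(7), tolerance = 1e-8)
  expect_true(all(diff(dict$spectrum) <= 1e-12))
  expect_equal(dict$basis %*% diag(dict$spectrum) %*% t(dict$basis), S,
               tolerance = 1e-8)
  # sign convention: largest-magnitude entry of each column positive
  expect_true(all(apply(dict$basis, 2, function(v) v[which.max(abs(v))]) > 0))

  expect_error(dictionary_from_component(matrix(1:4, 2)), "symmetric")
})

test_that("a saved prior loads back identically", {
  set.seed(56)
  groups <- lapply(1:8, function(i) fake_group(matrix(rnorm(4 * 6), 4, 6)))
  fit <- fit_gmm(groups, K = 2, iters = 10, seed = 3, reg = 1e-5)
  path <- withr::local_tempfile(fileext = ".gmm")
  save_prior(fit, path)
  back <- load_prior(path)
  expect_identical(back$K, fit$K)
  expect_equal(back$mix, fit$mix)
  expect_equal(back$means, fit$means)
  expect_equal(back$covs, fit$covs)
  expect_error(load_prior(withr::local_tempfile(fileext = ".gmm",
                                                lines = "junk")), "prior")
})
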