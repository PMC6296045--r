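#' Quantized gradient angles
#'
#' The five allowed gradient orientations: 0, pi/4, pi/2, 3*pi/4, pi.
#' @keywords internal
ANGLE_LEVELS <- c(0, pi / 4, pi / 2, 3 * pi / 4, pi)

shift_mat <- function(m, dr, dc) {
  # replicate-border shift: value of the neighbour at (r + dr, c + dc)
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Per-pixel gradient features of an image
#'
#' For every pixel the eight neighbouring gray differences are examined along
#' the four orientations 0, pi/4, pi/2, 3*pi/4 (horizontal, diagonal,
#' vertical, anti-diagonal). The gradient magnitude is the largest absolute
#' gray change over the eight neighbours; the gradient angle is the
#' orientation along which that maximum occurs, quantized to the five allowed
#' levels (ties resolve to the smallest angle; a constant neighbourhood gives
#' magnitude 0 and angle 0). Border pixels use replicated neighbours.
#'
#' @param img `ImageGrid` or matrix.
#' @return List with matrices `mag` (gradient magnitudes) and `angle_idx`
#'   (1-based index into [ANGLE_LEVELS]).
#' @export
gradient_features <- function(img) {
  m <- as_image_grid(img)$pixels
  # neighbour offsets grouped by orientation: 0, pi/4, pi/2, 3pi/4.
  # Orientation 0 is the horizontal (column) direction; angles grow
  # counter-clockwise, so pi/4 pairs up-right/down-left.
  nbrs <- list(
    list(c(0L, 1L),  c(0L, -1L)),    # 0
    list(c(-1L, 1L), c(1L, -1L)),    # pi/4
    list(c(-1L, 0L), c(1L, 0L)),     # pi/2
    list(c(-1L, -1L), c(1L, 1L)))    # 3pi/4
  # diagonal neighbours sit sqrt(2) pixels away: normalize their gray
  # difference by the step length so the directional change is comparable
  steplen <- c(1, sqrt(2), 1, sqrt(2))
  mag <- matrix(0, nrow(m), ncol(m))
  idx <- matrix(1L, nrow(m), ncol(m))
  for (o in seq_along(nbrs)) {
    d <- pmax(abs(shift_mat(m, nbrs[[o]][[1]][1], nbrs[[o]][[1]][2]) - m),
              abs(shift_mat(m, nbrs[[o]][[2]][1], nbrs[[o]][[2]][2]) - m)) /
      steplen[o]
    upd <- d > mag            # strict: ties keep the smaller angle
    mag[upd] <- d[upd]
    idx[upd] <- o
  }
  list(mag = mag, angle_idx = idx)
}

#' Gradient features of one patch
#'
#' Features are computed on the full image (so patch borders see their true
#' neighbours) and restricted to the patch window.
#'
#' @param patch List with `row`, `col` (0-based top-left) and `p`, or a
#'   `PatchSet` row index via `coords`.
#' @param img The source `ImageGrid`.
#' @param features Optional precomputed [gradient_features()] of `img`.
#' @return List with `values`, `grad_mag` (p x p) and `grad_angle` (p x p,
#'   radians from the quantized set).
#' @export
compute_features <- function(patch, img, features = NULL) {
  img <- as_image_grid(img)
  if (is.null(features)) features <- gradient_features(img)
  r <- patch$row + seq_len(patch$p)
  c <- patch$col + seq_len(patch$p)
  list(values = img$pixels[r, c, drop = FALSE],
       grad_mag = features$mag[r, c, drop = FALSE],
       grad_angle = matrix(ANGLE_LEVELS[features$angle_idx[r, c]],
                           patch$p, patch$p))
}

angle_to_idx <- function(a) {
  q <- a / (pi / 4)
  i <- round(q)
  if (any(abs(q - i) > 1e-9) || any(i < 0) || any(i > 4))
    stop("gradient angles must come from {0, pi/4, pi/2, 3pi/4, pi}")
  as.integer(i) + 1L
}

# 5 x 5 table of tan(folded |alpha - beta|); orientations are modulo pi and
# the difference is folded into [0, pi/2]. tan(pi/2) is replaced by a finite
# cap so distances stay finite while preserving the ordering.
angle_cost_table <- function(tan_cap = tan(pi / 2 - 0.01)) {
  d <- abs(outer(ANGLE_LEVELS, ANGLE_LEVELS, `-`)) %% pi
  d <- pmin(d, pi - d)
  ifelse(abs(d - pi / 2) < 1e-12, tan_cap, tan(d))
}

#' Per-pixel geodesic distance term
#'
#' The dissimilarity of two aligned pixels:
#' `0.5*(value_a - value_b)^2 + 0.5*(t_a + t_b + tan|alpha - beta|)`,
#' where the angle difference is folded into `[0, pi/2]` (orientations, not
#' directions) before the tangent, and a folded difference of pi/2 maps to a
#' finite cap.
#'
#' @param value_a,value_b Gray values.
#' @param t_a,t_b Gradient magnitudes (non-negative).
#' @param alpha,beta Quantized gradient angles (radians).
#' @param tan_cap Finite stand-in for tan(pi/2).
#' @return Non-negative dissimilarity (vectorized over its arguments).
#' @export
pixel_distance <- function(value_a, value_b, t_a, t_b, alpha, beta,
                           tan_cap = tan(pi / 2 - 0.01)) {
  C <- angle_cost_table(tan_cap)
  ang <- C[cbind(angle_to_idx(alpha), angle_to_idx(beta))]
  0.5 * (value_a - value_b)^2 + 0.5 * (t_a + t_b + ang)
}

#' Geodesic distance between two feature patches
#'
#' Mean of [pixel_distance()] over the p^2 aligned pixel pairs. Note the
#' printed form is not a metric: identical patches with non-zero gradients
#' have a positive self-distance (the `t_a + t_b` term survives);
#' `strict = TRUE` subtracts the self-distance baseline `0.5*(t_a + t_b)`
#' evaluated at alpha = beta for users wanting d(A, A) = 0.
#'
#' @param a,b Feature lists as from [compute_features()].
#' @param tan_cap Finite stand-in for tan(pi/2).
#' @param strict Subtract the self-distance so d(A, A) = 0.
#' @return Non-negative scalar.
#' @export
geodesic_distance <- function(a, b, tan_cap = tan(pi / 2 - 0.01),
                              strict = FALSE) {
  if (!all(dim(a$values) == dim(b$values)))
    stop("patch sizes differ")
  d <- mean(pixel_distance(a$values, b$values, a$grad_mag, b$grad_mag,
                           a$grad_angle, b$grad_angle, tan_cap))
  if (strict) d <- d - 0.5 * mean(a$grad_mag + b$grad_mag)
  d
}

#' Euclidean patch distance
#'
#' Mean squared gray difference over the p^2 pixels (the same 1/p^2
#' normalization as the geodesic distance, so the two are comparable).
#'
#' @param a,b Patch value matrices (or feature lists).
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  if (is.list(a)) a <- a$values
  if (is.list(b)) b <- b$values
  if (!all(dim(a) == dim(b))) stop("patch sizes differ")
  mean((a - b)^2)
}

# ---- vectorized cross-distances ---------------------------------------------
# VA, TA: n_a x p^2 value / gradient-magnitude rows; AA: n_a x p^2 angle index
# rows. Returns the n_a x n_b distance matrix.

cross_sqdist <- function(VA, VB) {
  d2 <- outer(rowSums(VA^2), rowSums(VB^2), `+`) - 2 * tcrossprod(VA, VB)
  pmax(d2, 0)
}

cross_geodesic <- function(VA, TA, AA, VB, TB, AB,
                           tan_cap = tan(pi / 2 - 0.01)) {
  p2 <- ncol(VA)
  C <- angle_cost_table(tan_cap)
  D <- 0.5 * cross_sqdist(VA, VB) / p2 +
    0.5 * outer(rowMeans(TA), rowMeans(TB), `+`)
  ang <- matrix(0, nrow(VA), nrow(VB))
  for (a in 1:5) {
    Ia <- AA == a
    if (!any(Ia)) next
    for (b in 1:5) {
      if (C[a, b] == 0) next
      Ib <- AB == b
      if (!any(Ib)) next
      ang <- ang + C[a, b] * tcrossprod(Ia + 0, Ib + 0)
    }
  }
  D + 0.5 * ang / p2
}

cross_euclidean <- function(VA, VB) cross_sqdist(VA, VB) / ncol(VA)

patch_feature_rows <- function(img, patches, features = NULL) {
  img <- as_image_grid(img)
  if (is.null(features)) features <- gradient_features(img)
  list(V = patch_matrix(img$pixels, patches$coords, patches$p),
       T = patch_matrix(features$mag, patches$coords, patches$p),
       A = patch_matrix(features$angle_idx + 0, patches$coords, patches$p))
}

#' Match candidate blocks to reference blocks
#'
#' Assigns every candidate patch to its minimum-distance reference under the
#' chosen metric, scanning the whole image (no local search window). With a
#' threshold `T`, candidates whose minimum distance is not below `T` stay
#' unassigned (`NA`). Ties break to the lowest reference index.
#'
#' @param img Source `ImageGrid`.
#' @param patches `PatchSet` of candidate blocks.
#' @param ref_idx Indices (into the patch set) of the reference blocks.
#' @param metric `"geodesic"` or `"euclidean"`.
#' @param threshold Optional similarity threshold T (disabled by default).
#' @param tan_cap Finite stand-in for tan(pi/2) in the geodesic metric.
#' @param chunk Number of candidates per distance-matrix block (memory knob).
#' @return List with `assignments` (per-candidate reference position, `NA` if
#'   above threshold) and `distances` (the corresponding minima).
#' @export
match_blocks <- function(img, patches, ref_idx,
                         metric = c("geodesic", "euclidean"),
                         threshold = NULL, tan_cap = tan(pi / 2 - 0.01),
                         chunk = 4096L) {
  metric <- match.arg(metric)
  if (length(ref_idx) < 1L) stop("need at least one reference block")
  feats <- if (metric == "geodesic") patch_feature_rows(img, patches)
           else list(V = patch_values(img, patches))
  n <- nrow(patches$coords)
  assign <- integer(n); dmin <- numeric(n)
  VR <- feats$V[ref_idx, , drop = FALSE]
  if (metric == "geodesic") {
    TR <- feats$T[ref_idx, , drop = FALSE]
    AR <- feats$A[ref_idx, , drop = FALSE]
  }
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    D <- if (metric == "geodesic")
      cross_geodesic(feats$V[s:e, , drop = FALSE], feats$T[s:e, , drop = FALSE],
                     feats$A[s:e, , drop = FALSE], VR, TR, AR, tan_cap)
    else
      cross_euclidean(feats$V[s:e, , drop = FALSE], VR)
    assign[s:e] <- max.col(-D, ties.method = "first")
    dmin[s:e] <- D[cbind(seq_len(e - s + 1L), assign[s:e])]
  }
  if (!is.null(threshold)) assign[dmin >= threshold] <- NA_integer_
  list(assignments = assign, distances = dmin)
}

#' Build similar-block groups
#'
#' Draws `n_refs` reference patches uniformly (seeded) from the patch grid and
#' groups candidates by similarity under the chosen metric, searching the
#' whole image. Two grouping modes: the default keeps each reference's
#' `group_size` nearest candidates; `partition = TRUE` instead assigns every
#' candidate to its nearest reference (variable group sizes, full coverage) —
#' the mode the denoising loop uses so that aggregation covers every pixel.
#'
#' @param img Source `ImageGrid`.
#' @param p Patch side length.
#' @param stride Patch-grid stride.
#' @param n_refs Number of reference blocks N (default `ceiling(n/64)`).
#' @param group_size Members per group M (nearest-M mode; default 64).
#' @param metric `"geodesic"` or `"euclidean"`.
#' @param seed Integer seed for the reference draw.
#' @param partition Assign every candidate to its nearest reference instead of
#'   keeping the M nearest per reference.
#' @param tan_cap Finite stand-in for tan(pi/2).
#' @return List of `PatchGroup`s: each has `ref` (candidate index of the
#'   reference), `members` (candidate indices), `Y` (p^2 x M member columns),
#'   `mu` (group mean), `Yc` (centered members), `coords`, `p`.
#' @export
build_groups <- function(img, p, stride = 1L, n_refs = NULL, group_size = 64L,
                         metric = c("geodesic", "euclidean"), seed = 1L,
                         partition = FALSE, tan_cap = tan(pi / 2 - 0.01)) {
  metric <- match.arg(metric)
  img <- as_image_grid(img)
  patches <- extract_patches(img, p, stride)
  n <- nrow(patches$coords)
  if (is.null(n_refs)) n_refs <- as.integer(ceiling(n / 64))
  if (n_refs < 1L) stop("need at least one reference block")
  if (!partition && group_size > n)
    stop(sprintf("group_size %d exceeds the %d available patches", group_size, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  ref_idx <- sort(sample.int(n, min(n_refs, n)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  V <- patch_values(img, patches)
  groups <- if (partition) {
    mres <- match_blocks(img, patches, ref_idx, metric, tan_cap = tan_cap)
    lapply(seq_along(ref_idx), function(j) {
      members <- which(mres$assignments == j)
      if (length(members) == 0L) return(NULL)
      make_group(V, members, ref_idx[j], patches)
    })
  } else {
    feats <- if (metric == "geodesic") patch_feature_rows(img, patches)
    lapply(ref_idx, function(r) {
      d <- if (metric == "geodesic")
        cross_geodesic(feats$V[r, , drop = FALSE], feats$T[r, , drop = FALSE],
                       feats$A[r, , drop = FALSE], feats$V, feats$T, feats$A,
                       tan_cap)[1L, ]
      else
        cross_euclidean(V[r, , drop = FALSE], V)[1L, ]
      members <- order(d)[seq_len(group_size)]
      make_group(V, members, r, patches)
    })
  }
  groups <- Filter(Negate(is.null), groups)
  attr(groups, "patches") <- patches
  groups
}

make_group <- function(V, members, ref, patches) {
  Y <- t(V[members, , drop = FALSE])     # p^2 x M
  mu <- rowMeans(Y)
  structure(list(ref = ref, members = members, Y = Y, mu = mu,
                 Yc = Y - mu, coords = patches$coords[members, , drop = FALSE],
                 p = patches$p),
            class = "PatchGroup")
}
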