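# Synthetic micrograph phantoms: repeated particle motifs on a flat
# background, with ground-truth labels for grouping-purity evaluation.

#' Phantom specification
#'
#' Describes a micrograph-like phantom: `n_particles` copies of one or more
#' particle motifs on a flat background. Rings mimic the projected shell of a
#' capsid; disks a filled particle; `"hex"` a hexagonal (icosahedral
#' silhouette) projection.
#'
#' @param size Image side length in pixels (square), default 640.
#' @param n_particles Number of particles, default 20.
#' @param motif Motif name(s): `"ring"`, `"disk"`, `"hex"`; a vector is
#'   recycled across particles (two motifs give the labeled two-class
#'   benchmark).
#' @param radius Motif radius in pixels, default 24.
#' @param level Motif gray level, default 200.
#' @param background Background gray level, default 50.
#' @param jitter Sub-pixel center jitter (uniform, pixels), default 0.5.
#' @param overlap Allow overlapping particles (default `FALSE`).
#' @param seed Placement seed.
#' @return A `PhantomSpec` list.
#' @export
phantom_spec <- function(size = 640L, n_particles = 20L, motif = "ring",
                         radius = 24, level = 200, background = 50,
                         jitter = 0.5, overlap = FALSE, seed = 1L) {
  motif <- match.arg(motif, c("ring", "disk", "hex"), several.ok = TRUE)
  structure(list(size = as.integer(size), n_particles = as.integer(n_particles),
                 motif = motif, radius = radius, level = level,
                 background = background, jitter = jitter, overlap = overlap,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

render_motif <- function(px, lab, cy, cx, motif, radius, level, class_id) {
  n <- nrow(px)
  r0 <- max(1L, floor(cy - radius - 1)); r1 <- min(n, ceiling(cy + radius + 1))
  c0 <- max(1L, floor(cx - radius - 1)); c1 <- min(n, ceiling(cx + radius + 1))
  yy <- r0:r1; xx <- c0:c1
  dy <- outer(yy - cy, rep(1, length(xx)))
  dx <- outer(rep(1, length(yy)), xx - cx)
  d <- sqrt(dy^2 + dx^2)
  inside <- switch(motif,
    disk = d <= radius,
    ring = d <= radius & d >= radius * 0.72,
    hex = {
      # pointy-top regular hexagon of circumradius `radius`
      u <- abs(dx); v <- abs(dy)
      u <= sqrt(3) * radius / 2 & v <= radius - u / sqrt(3)
    })
  px[yy, xx][inside] <- level
  lab[yy, xx][inside] <- class_id
  list(px = px, lab = lab)
}

#' Generate a phantom micrograph
#'
#' Renders the particles at seeded uniform positions (rejection-sampled to
#' keep particles fully inside the frame and non-overlapping unless allowed),
#' returning the clean image and its ground truth. Ground-truth pixel labels
#' are MOTIF CLASSES (0 = background, 1.. = index into `unique(spec$motif)`),
#' so grouping purity measures motif identity, not particle identity.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (`ImageGrid`), `truth`: list with `labels`
#'   (integer matrix), `centers` (n x 2), `motif` (per particle), `classes`
#'   (unique motif names).
#' @export
make_phantom <- function(spec) {
  n <- spec$size
  px <- matrix(spec$background, n, n)
  lab <- matrix(0L, n, n)
  classes <- unique(spec$motif)
  motifs <- rep_len(spec$motif, max(spec$n_particles, 1L))
  centers <- matrix(numeric(0), 0, 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  if (spec$n_particles > 0L) {
    margin <- spec$radius + 2
    for (i in seq_len(spec$n_particles)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        cy <- stats::runif(1, margin, n - margin) +
          stats::runif(1, -spec$jitter, spec$jitter)
        cx <- stats::runif(1, margin, n - margin) +
          stats::runif(1, -spec$jitter, spec$jitter)
        if (!spec$overlap && nrow(centers) > 0 &&
            min(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)) <
              2 * spec$radius + 2) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place %d non-overlapping particles of radius %g in a %d x %d frame",
                     spec$n_particles, spec$radius, n, n))
      centers <- rbind(centers, c(cy, cx))
      res <- render_motif(px, lab, cy, cx, motifs[i], spec$radius, spec$level,
                          match(motifs[i], classes))
      px <- res$px; lab <- res$lab
    }
  }
  list(image = image_grid(px, peak = 255),
       truth = list(labels = lab, centers = centers,
                    motif = motifs[seq_len(spec$n_particles)],
                    classes = classes))
}

#' Add calibrated Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma`. Values
#' are NOT clipped by default, so the empirical PSNR against the clean image
#' matches the analytic `10*log10(peak^2/sigma^2)`.
#'
#' @param img `ImageGrid` or matrix.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Noise seed.
#' @param clip Clip the result to `[0, peak]`.
#' @return Noisy `ImageGrid`.
#' @export
add_gaussian_noise <- function(img, sigma, seed = 1L, clip = FALSE) {
  img <- as_image_grid(img)
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (sigma == 0) return(img)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  px <- img$pixels + matrix(stats::rnorm(length(img$pixels), 0, sigma),
                            nrow(img$pixels), ncol(img$pixels))
  if (clip) px <- pmin(pmax(px, 0), img$peak)
  image_grid(px, peak = img$peak)
}

dominant_label <- function(labels, row, col, p) {
  win <- labels[row + seq_len(p), col + seq_len(p)]
  tab <- tabulate(win + 1L)      # label 0 -> bin 1
  which.max(tab) - 1L            # ties -> lowest label
}

#' Grouping purity against ground truth
#'
#' Fraction of group members whose dominant pixel label (motif class, with 0
#' = background) matches the dominant label of their group's reference patch.
#' Invariant to group order.
#'
#' @param groups List of `PatchGroup`s (as from [build_groups()]); the
#'   attached `PatchSet` supplies the reference coordinates.
#' @param truth Ground truth from [make_phantom()].
#' @return Purity in `[0, 1]`.
#' @export
grouping_purity <- function(groups, truth) {
  patches <- attr(groups, "patches")
  if (is.null(patches)) stop("groups are missing their PatchSet attribute")
  lab <- truth$labels
  if (patches$height > nrow(lab) || patches$width > ncol(lab))
    stop("patch coordinates fall outside the ground-truth labels")
  hits <- 0L; total <- 0L
  for (g in groups) {
    rc <- patches$coords[g$ref, ]
    ref_lab <- dominant_label(lab, rc[1], rc[2], g$p)
    mem_lab <- apply(g$coords, 1L, function(z)
      dominant_label(lab, z[1], z[2], g$p))
    hits <- hits + sum(mem_lab == ref_lab)
    total <- total + length(mem_lab)
  }
  hits / total
}
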