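#' Recipe for a synthetic 3D phantom volume
#'
#' Describes an ellipsoidal "brain" phantom inside an otherwise empty grid:
#' every slice within `[margin, extent - margin)` on each axis intersects
#' the foreground, while the `margin` boundary slices on each side are
#' exactly zero — the empty-edge structure that motivates the `k1`/`k2`
#' trims of the slice extractor.
#'
#' @param extents Three integers: array extents along axes 1 (sagittal
#'   normal), 2 (coronal normal), 3 (axial normal).
#' @param margin Empty boundary slices per side (same on all axes).
#' @param intensity Peak foreground intensity.
#' @param noise_sd Standard deviation of Gaussian intensity noise applied to
#'   foreground voxels only (boundary slices stay exactly zero).
#' @param seed RNG seed; the generated volume is a pure function of the
#'   recipe.
#' @return A `volume_recipe` object.
#' @export
volume_recipe <- function(extents = c(96L, 80L, 80L), margin = 8L,
                          intensity = 1, noise_sd = 0.05, seed = 1L) {
  extents <- as.integer(extents)
  stopifnot(length(extents) == 3, all(extents >= 3))
  margin <- as.integer(margin)
  if (margin < 0 || any(2L * margin >= extents)) {
    stop("margin ", margin, " leaves no interior for extents ",
         paste(extents, collapse = "x"), call. = FALSE)
  }
  structure(list(extents = extents, margin = margin, intensity = intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "volume_recipe")
}

#' Generate a phantom volume from a recipe
#'
#' The foreground is an axis-aligned ellipsoid centred in the grid whose
#' semi-axes slightly exceed the interior half-extents, guaranteeing that
#' every interior slice has nonzero foreground while no boundary slice does.
#'
#' @param recipe A [volume_recipe()].
#' @return A [cq_volume()].
#' @export
make_volume <- function(recipe) {
  stopifnot(inherits(recipe, "volume_recipe"))
  e <- recipe$extents
  ctr <- (e - 1) / 2
  semi <- ctr - recipe$margin + 0.45   # spills just past the interior face
  d1 <- ((0:(e[1] - 1) - ctr[1]) / semi[1])^2
  d2 <- ((0:(e[2] - 1) - ctr[2]) / semi[2])^2
  d3 <- ((0:(e[3] - 1) - ctr[3]) / semi[3])^2
  dist2 <- outer(outer(d1, d2, `+`), d3, `+`)
  inside <- dist2 <= 1
  vox <- array(0, dim = e)
  # smooth radial falloff keeps interior slices visually brain-like
  vox[inside] <- recipe$intensity * (1 - 0.5 * dist2[inside])
  if (recipe$noise_sd > 0) {
    restore <- .Random.seed_exists()
    on.exit(restore(), add = TRUE)
    set.seed(recipe$seed)
    vox[inside] <- pmax(0, vox[inside] + rnorm(sum(inside), 0, recipe$noise_sd))
    # keep the foreground invariant: noise must not zero out a whole slice
    vox[inside] <- pmax(vox[inside], 1e-3)
  }
  cq_volume(vox, source = sprintf("synthetic(seed=%d)", recipe$seed))
}

#' Recipe for a two-class synthetic 2D image set
#'
#' Both classes share a large central blob; a smaller secondary blob sits at
#' a class-dependent position, displaced horizontally by `delta` pixels in
#' class 1. `delta = 0` makes the two class distributions identical (the
#' near-identical "MRI-like" regime in which hybrid models stall); large
#' `delta` gives visually separable "MNIST-like" classes. Per-image position
#' jitter and pixel noise make samples within a class vary.
#'
#' @param n_per_class Images per class (>= 20).
#' @param side Image edge length in pixels (default 128).
#' @param delta Inter-class displacement of the secondary blob, in pixels.
#' @param noise_sd Pixel Gaussian noise standard deviation.
#' @param jitter_sd Within-class positional jitter of both blobs, in pixels.
#' @param seed RNG seed.
#' @return A `class_pair_recipe` object.
#' @export
class_pair_recipe <- function(n_per_class = 100L, side = 128L, delta = 20,
                              noise_sd = 0.05, jitter_sd = 1.5, seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 20) stop("n_per_class must be >= 20", call. = FALSE)
  stopifnot(side >= 16, delta >= 0, noise_sd >= 0)
  structure(list(n_per_class = n_per_class, side = as.integer(side),
                 delta = delta, noise_sd = noise_sd, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "class_pair_recipe")
}

.gauss_blob <- function(side, cx, cy, sd, amp) {
  gx <- exp(-((1:side - cx)^2) / (2 * sd^2))
  gy <- exp(-((1:side - cy)^2) / (2 * sd^2))
  amp * outer(gx, gy)
}

.render_pair_image <- function(side, label, delta, noise_sd, jitter_sd) {
  c0 <- (side + 1) / 2
  jit <- rnorm(4, 0, jitter_sd)
  img <- .gauss_blob(side, c0 + jit[1], c0 + jit[2], sd = side / 5, amp = 0.8)
  # secondary blob: class 1 displaced horizontally by delta
  sx <- c0 + side / 6 + jit[3] + if (label == 1L) delta else 0
  sy <- c0 - side / 6 + jit[4]
  img <- img + .gauss_blob(side, sx, sy, sd = side / 12, amp = 0.6)
  if (noise_sd > 0) img <- img + matrix(rnorm(side^2, 0, noise_sd), side, side)
  pmin(pmax(img, 0), 1)
}

#' Generate a labeled two-class image dataset
#'
#' Produces a balanced, seeded dataset with a stratified 90:10 train/test
#' split.
#'
#' @param recipe A [class_pair_recipe()].
#' @return A tibble with columns `id`, `label` (integer 0/1), `split`
#'   (`"train"`/`"test"`), and the list-column `image` (side x side matrices
#'   in `[0, 1]`).
#' @export
#' @examples
#' ds <- make_class_pair(class_pair_recipe(n_per_class = 20, side = 32))
#' dplyr::count(ds, label, split)
make_class_pair <- function(recipe) {
  stopifnot(inherits(recipe, "class_pair_recipe"))
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(recipe$seed)
  n <- recipe$n_per_class
  labels <- rep(c(0L, 1L), each = n)
  images <- lapply(labels, function(lb) {
    .render_pair_image(recipe$side, lb, recipe$delta,
                       recipe$noise_sd, recipe$jitter_sd)
  })
  n_test <- max(1L, round(0.1 * n))
  split <- unlist(lapply(c(0L, 1L), function(lb) {
    s <- rep("train", n)
    s[sample.int(n, n_test)] <- "test"
    s
  }))
  tibble::tibble(id = seq_along(labels), label = labels, split = split,
                 image = images)
}

#' Mean image of each class
#'
#' @param dataset A [make_class_pair()] tibble (or any tibble with `label`
#'   and `image` columns).
#' @return Named list of two matrices, `"0"` and `"1"`.
#' @export
class_means <- function(dataset) {
  lapply(stats::setNames(c(0L, 1L), c("0", "1")), function(lb) {
    imgs <- dataset$image[dataset$label == lb]
    Reduce(`+`, imgs) / length(imgs)
  })
}
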