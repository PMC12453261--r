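#' Slice interval for even extraction
#'
#' Interval between consecutive extracted slices when `n` slices are
#' requested out of `m` available: `i = floor(m / n)`.
#'
#' @param m Total slice count along the plane normal (integer >= 1).
#' @param n Requested slice count (1 <= n <= m).
#' @return Integer interval, always >= 1.
#' @export
#' @examples
#' compute_interval(192, 15)
compute_interval <- function(m, n) {
  if (!is.numeric(m) || !is.numeric(n) || length(m) != 1 || length(n) != 1) {
    stop("m and n must be scalar integers", call. = FALSE)
  }
  m <- as.integer(m); n <- as.integer(n)
  if (n <= 0 || m < 1 || n > m) {
    stop("invalid slice request: n = ", n, " out of m = ", m,
         " (need 1 <= n <= m)", call. = FALSE)
  }
  m %/% n
}

.plane_labels <- c("axial", "coronal", "sagittal")

#' Plan an edge-trimmed, evenly spaced slice extraction
#'
#' Computes the extraction schedule for one volume and plane: the interval
#' `i = floor(m / n)`, the valid count
#' `n_slices = ceiling(m / i) - (k1 + k2)`, and the selected indices
#' `s = k1 + j * i` for `j = 0, ..., n_slices - 1`, keeping only indices
#' with `s < m - k2`. Indices are 0-based.
#'
#' @inheritParams compute_interval
#' @param k1,k2 Leading/trailing boundary-slice exclusion counts (default 2
#'   each; boundary MRI slices are typically empty space or non-brain
#'   tissue).
#' @param plane One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @return A `slice_plan`: list with `plane`, `m`, `n`, `k1`, `k2`,
#'   `interval`, `n_slices`, and the integer vector `indices`.
#' @seealso [extract_slices()], [plan_as_tibble()]
#' @export
#' @examples
#' plan_slices(160, 15, k1 = 1, k2 = 0, plane = "axial")
plan_slices <- function(m, n, k1 = 2L, k2 = 2L, plane = "axial") {
  plane <- match.arg(plane, .plane_labels)
  i <- compute_interval(m, n)
  m <- as.integer(m); n <- as.integer(n)
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (k1 < 0 || k2 < 0) stop("k1 and k2 must be non-negative", call. = FALSE)
  raw <- as.integer(ceiling(m / i))
  if (k1 + k2 >= raw) {
    stop("empty plan: k1 + k2 = ", k1 + k2,
         " removes all ", raw, " candidate slices", call. = FALSE)
  }
  n_slices <- raw - (k1 + k2)
  idx <- k1 + (0:(n_slices - 1L)) * i
  idx <- idx[idx < m - k2]
  structure(list(plane = plane, m = m, n = n, k1 = k1, k2 = k2,
                 interval = i, n_slices = n_slices, indices = idx),
            class = "slice_plan")
}

#' @export
print.slice_plan <- function(x, ...) {
  cat("<slice_plan> plane:", x$plane, " m:", x$m, " n:", x$n,
      " k1:", x$k1, " k2:", x$k2, "\n")
  cat("  interval:", x$interval, " n_slices:", x$n_slices,
      " retained:", length(x$indices), "\n")
  cat("  indices:", paste(x$indices, collapse = " "), "\n")
  if (length(x$indices) != x$n) {
    cat("  note: retained count differs from requested n =", x$n, "\n")
  }
  invisible(x)
}

#' Tabular view of a slice plan
#'
#' @param plan A [plan_slices()] result.
#' @return A tibble with one row per retained slice index.
#' @export
plan_as_tibble <- function(plan) {
  stopifnot(inherits(plan, "slice_plan"))
  tibble::tibble(plane = plan$plane, j = seq_along(plan$indices) - 1L,
                 index = plan$indices, interval = plan$interval)
}

.default_axis_map <- c(sagittal = 1L, coronal = 2L, axial = 3L)

#' Construct a 3D volume object
#'
#' @param voxels 3D numeric array.
#' @param axis_map Named integer vector mapping each plane normal to an array
#'   axis; must be a bijection onto axes 1:3. Default: axis 1 is the
#'   sagittal normal (x), axis 2 coronal (y), axis 3 axial (z).
#' @param source Provenance string.
#' @return A `cq_volume` object.
#' @export
cq_volume <- function(voxels, axis_map = .default_axis_map, source = "<memory>") {
  if (length(dim(voxels)) != 3) {
    stop("voxels must be a 3D array, got ", length(dim(voxels)),
         " dimensions", call. = FALSE)
  }
  if (any(dim(voxels) < 1)) stop("all three extents must be >= 1", call. = FALSE)
  if (!setequal(names(axis_map), .plane_labels) ||
      !setequal(axis_map, 1:3)) {
    stop("axis_map must map axial/coronal/sagittal bijectively onto axes 1:3",
         call. = FALSE)
  }
  structure(list(voxels = voxels, axis_map = axis_map[.plane_labels],
                 source = source),
            class = "cq_volume")
}

#' @export
print.cq_volume <- function(x, ...) {
  cat("<cq_volume>", paste(dim(x$voxels), collapse = " x "),
      "voxels from", x$source, "\n")
  cat("  plane normals:",
      paste(names(x$axis_map), "-> axis", x$axis_map, collapse = ", "), "\n")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Accepts `.nii` and `.nii.gz`. The orientation affine is inspected only to
#' warn on non-axis-aligned volumes; no resampling or reorientation is done.
#'
#' @param path Path to a NIfTI-1 file.
#' @param axis_map See [cq_volume()].
#' @return A `cq_volume`.
#' @export
read_volume <- function(path, axis_map = .default_axis_map) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) {
    stop("'", path, "' is not a 3D volume (found ",
         length(dim(arr)), " dimensions)", call. = FALSE)
  }
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  if (!is.null(xf)) {
    rot <- xf[1:3, 1:3]
    offdiag <- abs(rot[row(rot) != col(rot)])
    if (any(offdiag > 1e-3 * max(abs(diag(rot))))) {
      warning("volume '", path, "' has an oblique orientation affine; ",
              "slices are taken along raw array axes", call. = FALSE)
    }
  }
  cq_volume(array(as.numeric(arr), dim(arr)), axis_map = axis_map,
            source = path)
}

#' Write a volume as NIfTI
#'
#' @param vol A `cq_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "cq_volume"))
  RNifti::writeNifti(RNifti::asNifti(vol$voxels), path)
  invisible(path)
}

#' Extract the planned 2D slices from a volume
#'
#' Pure selection along the plane normal: no resampling, no intensity
#' change. Array axes orthogonal to the plane normal are returned in their
#' native order.
#'
#' @param vol A [cq_volume()].
#' @param plan A [plan_slices()] result whose `m` equals the volume extent
#'   along the plan's plane normal.
#' @return A `slice_set`: list with `slices` (list of matrices), `plan`, and
#'   `normalized = FALSE`.
#' @export
extract_slices <- function(vol, plan) {
  stopifnot(inherits(vol, "cq_volume"), inherits(plan, "slice_plan"))
  axis <- vol$axis_map[[plan$plane]]
  extent <- dim(vol$voxels)[axis]
  if (extent != plan$m) {
    stop("plan expects m = ", plan$m, " along the ", plan$plane,
         " normal but the volume extent on axis ", axis, " is ", extent,
         call. = FALSE)
  }
  slices <- lapply(plan$indices + 1L, function(s) {
    switch(axis,
           vol$voxels[s, , ],
           vol$voxels[, s, ],
           vol$voxels[, , s])
  })
  structure(list(slices = slices, plan = plan, normalized = FALSE),
            class = "slice_set")
}

#' @export
print.slice_set <- function(x, ...) {
  cat("<slice_set>", length(x$slices), x$plan$plane, "slice(s)",
      if (x$normalized) "(normalized)" else "", "\n")
  invisible(x)
}

.minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps) array(0, dim(x))
  else (x - rng[1]) / diff(rng)
}

#' Min-max normalize and bilinearly resize a slice
#'
#' Intensities are mapped to `[0, 1]` per slice (a constant slice maps to
#' all zeros), then the image is resized to `side x side` with bilinear
#' interpolation.
#'
#' @param slice 2D numeric matrix with positive extents.
#' @param side Output edge length in pixels (default 128, >= 8).
#' @return A `side x side` numeric matrix in `[0, 1]`.
#' @export
normalize_and_resize <- function(slice, side = 128L) {
  if (!is.matrix(slice) || any(dim(slice) < 1)) {
    stop("slice must be a non-degenerate 2D matrix", call. = FALSE)
  }
  if (side < 8) stop("side must be >= 8", call. = FALSE)
  slice <- .minmax01(slice)
  if (all(dim(slice) == side)) return(slice)
  out <- EBImage::resize(slice, w = side, h = side, filter = "bilinear")
  pmin(pmax(unclass(out), 0), 1)
}

#' Write a slice set as grayscale PNGs
#'
#' @param set A [extract_slices()] result (normalized or raw; raw slices are
#'   min-max normalized per slice before quantization).
#' @param dir Output directory (created if missing).
#' @param subject Subject tag used in filenames.
#' @param side Optional resize edge; `NULL` keeps native slice shape.
#' @return Character vector of written paths, in slice-index order, named
#'   `"{subject}_{plane}_{index %03d}.png"` so lexicographic order equals
#'   index order. Images are written as 8-bit grayscale.
#' @export
write_slices <- function(set, dir, subject = "subj", side = NULL) {
  stopifnot(inherits(set, "slice_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(seq_along(set$slices), function(k) {
    img <- set$slices[[k]]
    img <- if (is.null(side)) .minmax01(img) else normalize_and_resize(img, side)
    idx <- set$plan$indices[k]
    path <- file.path(dir, sprintf("%s_%s_%03d.png", subject, set$plan$plane, idx))
    png::writePNG(img, path, dpi = NULL)
    path
  }, character(1))
}

#' Read a grayscale PNG back as a matrix
#'
#' @param path PNG path.
#' @return Numeric matrix in `[0, 1]` (first channel if multi-channel).
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
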