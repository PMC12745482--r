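#' CT volume container
#'
#' A minimal container for a 3-D grid of Hounsfield-unit (HU) values with
#' voxel-spacing metadata. Axis order is fixed as (slice, row, column); slice 1
#' is the proximal end of the bone and "ventral" is the larger row index.
#'
#' @param voxels Numeric 3-D array of HU values, dimension (slice, row, col).
#' @param spacing Numeric length-3 vector `(dz, dy, dx)` in mm; defaults to
#'   1 mm slices with 0.25 mm in-plane pixels.
#' @return An object of class `ct_volume` with elements `voxels` and `spacing`.
#' @examples
#' v <- ct_volume(array(0, c(2, 4, 4)))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 0.25, 0.25)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3-D array (slice, row, col)", call. = FALSE)
  if (any(dim(voxels) < 1)) stop("voxel grid must be non-empty", call. = FALSE)
  if (!is.numeric(voxels)) stop("voxels must be numeric HU values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (dz, dy, dx)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d slices x %d rows x %d cols, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Calibration-phantom layout
#'
#' Describes the in-field hydroxyapatite phantom: one cylinder per reference
#' concentration, placed ventrally to (below) the bone in every slice of
#' `slice_range`.
#'
#' @param centers Numeric matrix with one `(row, col)` pixel center per
#'   cylinder (same order as `concentrations`).
#' @param radius_mm Cylinder radius in mm (common to all cylinders).
#' @param concentrations Known hydroxyapatite concentrations in mgHA/cm3;
#'   default `c(0, 100, 200)` (water, mid, bone reference).
#' @param pixel_mm In-plane pixel size in mm (to place the cylinders on the
#'   grid).
#' @param slice_range Integer range of slices where the phantom is present;
#'   `NULL` means every slice.
#' @return An object of class `phantom_layout`.
#' @export
phantom_layout <- function(centers, radius_mm = 2, concentrations = c(0, 100, 200),
                           pixel_mm = 0.25, slice_range = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2 || nrow(centers) != length(concentrations))
    stop("need one (row, col) center per concentration", call. = FALSE)
  if (any(concentrations < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (anyDuplicated(concentrations))
    stop("exactly one cylinder per concentration", call. = FALSE)
  if (radius_mm <= 0 || pixel_mm <= 0)
    stop("radius_mm and pixel_mm must be positive", call. = FALSE)
  r_px <- radius_mm / pixel_mm
  if (nrow(centers) > 1) {
    d <- as.matrix(stats::dist(centers))
    if (any(d[upper.tri(d)] <= 2 * r_px))
      stop("phantom cylinders overlap", call. = FALSE)
  }
  structure(list(centers = centers, radius_mm = radius_mm, radius_px = r_px,
                 concentrations = concentrations, pixel_mm = pixel_mm,
                 slice_range = slice_range),
            class = "phantom_layout")
}

# Standard placement: cylinders in a ventral row near the bottom of the grid.
default_phantom_layout <- function(n_row, n_col, pixel_mm = 0.25, radius_mm = 2,
                                   concentrations = c(0, 100, 200)) {
  cols <- round(n_col * seq(0.28, 0.72, length.out = length(concentrations)))
  centers <- cbind(rep(n_row - 18, length(cols)), cols)
  phantom_layout(centers, radius_mm = radius_mm, concentrations = concentrations,
                 pixel_mm = pixel_mm)
}

# Logical in-plane masks, one per cylinder (optionally grown by margin_px).
cylinder_masks <- function(layout, dim2, margin_px = 0) {
  r <- layout$radius_px + margin_px
  rows <- matrix(seq_len(dim2[1]), dim2[1], dim2[2])
  cols <- matrix(seq_len(dim2[2]), dim2[1], dim2[2], byrow = TRUE)
  lapply(seq_len(nrow(layout$centers)), function(k) {
    (rows - layout$centers[k, 1])^2 + (cols - layout$centers[k, 2])^2 <= r^2
  })
}

#' Phantom exclusion mask
#'
#' In-plane mask covering all phantom cylinders plus a safety margin, used to
#' keep bone segmentation and seeding away from the 200 mgHA/cm3 reference.
#'
#' @param layout A [phantom_layout()].
#' @param dim2 Integer `(n_row, n_col)` of the slice.
#' @param margin_px Margin added around each cylinder, in pixels.
#' @return Logical matrix.
#' @export
phantom_mask <- function(layout, dim2, margin_px = 2) {
  Reduce(`|`, cylinder_masks(layout, dim2, margin_px))
}

#' Render one phantom-bearing slice
#'
#' Builds a 2-D HU image containing the phantom cylinders on a soft-tissue
#' background, each cylinder at a configured HU level plus optional Gaussian
#' sampling noise. Mostly a test substrate for phantom reading.
#'
#' @param layout A [phantom_layout()].
#' @param hu_per_concentration Named numeric vector mapping each configured
#'   concentration (as a name, e.g. `"200"`) to its HU level.
#' @param noise_sd Gaussian HU noise SD (0 = noiseless).
#' @param dim2 Image size `(n_row, n_col)`.
#' @param background_hu Soft-tissue background level.
#' @param seed Optional RNG seed for the noise.
#' @return Numeric HU matrix.
#' @export
make_phantom_slice <- function(layout, hu_per_concentration, noise_sd = 0,
                               dim2 = c(128, 128), background_hu = 40, seed = NULL) {
  need <- as.character(layout$concentrations)
  if (!all(need %in% names(hu_per_concentration)))
    stop("hu_per_concentration must cover every configured concentration", call. = FALSE)
  r <- layout$radius_px
  bad <- layout$centers[, 1] - r < 1 | layout$centers[, 1] + r > dim2[1] |
         layout$centers[, 2] - r < 1 | layout$centers[, 2] + r > dim2[2]
  if (any(bad)) stop("phantom cylinder extends outside the image", call. = FALSE)
  img <- matrix(background_hu, dim2[1], dim2[2])
  masks <- cylinder_masks(layout, dim2)
  for (k in seq_along(masks)) {
    img[masks[[k]]] <- hu_per_concentration[[need[k]]]
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(img), 0, noise_sd)
             else with_seed(seed, stats::rnorm(length(img), 0, noise_sd))
    img <- img + matrix(noise, dim2[1], dim2[2])
  }
  img
}

#' Write / read a CT volume as NIfTI
#'
#' Thin wrappers around RNifti. The internal axis order (slice, row, col) is
#' stored as NIfTI (x = col, y = row, z = slice) with matching pixdim, so
#' volumes round-trip exactly.
#'
#' @param volume A [ct_volume()] (or a logical 3-D mask array for
#'   `write_mask_nifti`, stored as 0/1 integers with the given spacing).
#' @param path Output file, conventionally ending in `.nii` or `.nii.gz`.
#' @param mask,spacing For `write_mask_nifti`: the logical array and its
#'   spacing.
#' @return `path`, invisibly; `read_ct_nifti` returns a [ct_volume()].
#' @export
write_ct_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing[c(3, 2, 1)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ct_nifti
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  ct_volume(aperm(as.array(img), c(3, 2, 1)), spacing = sp[c(3, 2, 1)])
}

#' @rdname write_ct_nifti
#' @export
write_mask_nifti <- function(mask, path, spacing = c(1, 0.25, 0.25)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  arr <- aperm(array(as.integer(mask), dim(mask)), c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing[c(3, 2, 1)]
  RNifti::writeNifti(img, path)
  invisible(path)
}
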