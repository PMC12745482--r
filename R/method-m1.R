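#' Geometric center of a mask
#'
#' Unweighted area centroid (mean of pixel coordinates, sub-pixel), the
#' origin of the quadrant axes.
#'
#' @param mask Logical matrix.
#' @return Numeric `(row, col)`.
#' @export
geometric_center <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no geometric center", call. = FALSE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Partition a bone mask into four anatomical quadrants
#'
#' Pixels are assigned by their angle about the geometric center into four
#' 90-degree sectors whose boundaries lie on the image diagonals, so each
#' sector is centered on a cardinal direction. Default anatomical mapping:
#' up (smaller row) = anterior, down = posterior, left = medial, right =
#' lateral. A pixel exactly on a diagonal goes to the counter-clockwise
#' sector; the center pixel itself (angle undefined) goes to anterior.
#'
#' @param mask Logical bone mask for the slice.
#' @param center `(row, col)` origin, typically [geometric_center()].
#' @return A `quadrant_set`: list with `center` and `masks`, a named list of
#'   four disjoint logical masks whose union is `mask`.
#' @export
quadrant_partition <- function(mask, center = geometric_center(mask)) {
  stopifnot(is.logical(mask), is.matrix(mask))
  dr <- matrix(seq_len(nrow(mask)) - center[1], nrow(mask), ncol(mask))
  dc <- matrix(seq_len(ncol(mask)) - center[2], nrow(mask), ncol(mask), byrow = TRUE)
  theta <- atan2(dc, -dr)  # 0 = up/anterior, pi/2 = right/lateral, clockwise on screen
  q <- list(
    anterior  = mask & theta > -pi / 4     & theta <= pi / 4,
    lateral   = mask & theta > pi / 4      & theta <= 3 * pi / 4,
    posterior = mask & (theta > 3 * pi / 4 | theta <= -3 * pi / 4),
    medial    = mask & theta > -3 * pi / 4 & theta <= -pi / 4
  )
  structure(list(center = center, masks = q), class = "quadrant_set")
}

# Integer pixel offsets of a disk of the given radius around a center that is
# itself offset by a sub-pixel `jitter = (dr, dc)`.
disk_offsets <- function(radius, jitter = c(0, 0)) {
  r <- ceiling(radius + 1)
  g <- expand.grid(di = -r:r, dj = -r:r)
  keep <- (g$di - jitter[1])^2 + (g$dj - jitter[2])^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Place one circular cortical ROI in a quadrant
#'
#' Searches a candidate grid of disk centers (every pixel whose jittered disk
#' lies entirely inside the quadrant's bone mask) and selects the ROI with the
#' highest mean BMD subject to the homogeneity constraint
#' `SD <= homogeneity_limit * mean` (population SD). If no candidate meets
#' the constraint the unconstrained max-mean ROI is taken. Ties are broken by
#' the smallest `(row, col)` lexicographically. If the quadrant cannot fit
#' the disk, the radius shrinks one pixel at a time down to `min_radius`
#' before failing. A jittered disk covering fewer than `min_pixels` pixels is
#' expanded in 0.1 px steps (at most +1 px) to honour the pixel-count floor.
#'
#' @param quadrant_mask Logical mask of the quadrant's bone pixels.
#' @param values Numeric BMD slice.
#' @param radius Disk radius in pixels (default 2, about 0.5 mm at 0.25 mm
#'   pixels).
#' @param homogeneity_limit Maximum relative SD inside the ROI (`Inf`
#'   disables the constraint).
#' @param jitter Sub-pixel `(row, col)` offset of the candidate grid origin;
#'   replicates use different jitters.
#' @param min_pixels Minimum pixels inside the disk.
#' @param min_radius Smallest radius tried when shrinking.
#' @return A `circular_roi`: list with `center` (jittered, sub-pixel),
#'   `radius`, `mean`, `sd`, `n_pixels`.
#' @export
place_cortical_roi <- function(quadrant_mask, values, radius = 2,
                               homogeneity_limit = 0.15, jitter = c(0, 0),
                               min_pixels = 12, min_radius = 2) {
  stopifnot(is.logical(quadrant_mask), is.matrix(quadrant_mask))
  for (r in seq(radius, min_radius)) {
    # a jittered disk can hold fewer pixels than the unjittered one; grow it
    # in 0.1 px steps (at most +1 px) to honour the pixel-count floor
    r_eff <- r
    offs <- disk_offsets(r_eff, jitter)
    while (nrow(offs) < min_pixels && r_eff < r + 1) {
      r_eff <- r_eff + 0.1
      offs <- disk_offsets(r_eff, jitter)
    }
    if (nrow(offs) < min_pixels) next
    # admissible centers: every disk pixel inside the image and in the mask
    adm <- quadrant_mask
    s1 <- matrix(0, nrow(values), ncol(values))
    s2 <- matrix(0, nrow(values), ncol(values))
    for (k in seq_len(nrow(offs))) {
      adm <- adm & shift_mat(quadrant_mask, offs[k, 1], offs[k, 2])
      v <- shift_mat(values, offs[k, 1], offs[k, 2], fill = 0)
      s1 <- s1 + v
      s2 <- s2 + v * v
    }
    if (!any(adm)) next
    n <- nrow(offs)
    cand <- which(adm, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    idx_lin <- (cand[, 2] - 1) * nrow(values) + cand[, 1]
    mu <- s1[idx_lin] / n
    sdv <- sqrt(pmax(s2[idx_lin] / n - mu^2, 0))
    ok <- if (is.finite(homogeneity_limit)) sdv <= homogeneity_limit * mu else
      rep(TRUE, length(mu))
    constrained <- any(ok)
    if (!constrained) ok <- rep(TRUE, length(mu))
    pool <- which(ok)
    best <- pool[which.max(mu[pool])]  # candidates already in (row, col) order
    return(structure(list(center = c(row = unname(cand[best, 1]) + jitter[1],
                                     col = unname(cand[best, 2]) + jitter[2]),
                          base_center = unname(c(cand[best, 1], cand[best, 2])),
                          radius = r_eff, mean = mu[best], sd = sdv[best],
                          n_pixels = n, constrained = constrained),
                     class = "circular_roi"))
  }
  stop("quadrant too thin: no admissible ROI center at any radius", call. = FALSE)
}

#' Quadrant-method BMD for one slice (M1)
#'
#' Full method-1 measurement of one calibrated slice: segment the bone, draw
#' orthogonal axes from its geometric center, split into four anatomical
#' quadrants, place one max-density homogeneous circular ROI per quadrant,
#' and report the slice BMD as the arithmetic mean of the four ROI means.
#'
#' @param values Numeric BMD slice (mgHA/cm3).
#' @param low,high Density window for the bone mask.
#' @param exclude Optional logical matrix masked out before segmentation
#'   (phantom region).
#' @param radius,homogeneity_limit,min_pixels,min_radius ROI parameters, see
#'   [place_cortical_roi()].
#' @param jitter Sub-pixel candidate-grid offset for this replicate.
#' @param mask Optional precomputed bone mask (skips segmentation).
#' @param threshold_values Optional matrix thresholded in place of `values`
#'   when building the bone mask (used for HU-space thresholding); ROI means
#'   are always computed on `values`.
#' @return List with `slice_bmd`, `rois` (named list of four `circular_roi`),
#'   `quadrants`, `mask`.
#' @export
m1_slice_bmd <- function(values, low = 200, high = 2000, exclude = NULL,
                         radius = 2, homogeneity_limit = 0.15,
                         min_pixels = 12, min_radius = 2, jitter = c(0, 0),
                         mask = NULL, threshold_values = NULL) {
  if (is.null(mask)) {
    mask <- bone_mask(threshold_values %||% values, low = low, high = high,
                      exclude = exclude)
  }
  qs <- quadrant_partition(mask)
  rois <- lapply(qs$masks, place_cortical_roi, values = values, radius = radius,
                 homogeneity_limit = homogeneity_limit, jitter = jitter,
                 min_pixels = min_pixels, min_radius = min_radius)
  means <- vapply(rois, function(r) r$mean, numeric(1))
  list(slice_bmd = mean(means), rois = rois, quadrants = qs, mask = mask)
}
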