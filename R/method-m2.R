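#' Seed selection for region-growing replicates
#'
#' Replicate `r` seeds at the `r`-th highest-BMD in-range pixel among pixels
#' at least `min_dist` px (Euclidean) from all previously used seeds; ties in
#' BMD are broken by smallest `(row, col)` lexicographically. This makes the
#' three replicates deterministic while starting them from distinct pixels.
#'
#' @param values Numeric BMD slice.
#' @param replicate Replicate index (1-based).
#' @param low,high Inclusive density window.
#' @param exclude Optional logical matrix of forbidden pixels (phantom).
#' @param min_dist Minimum distance between seeds, in pixels.
#' @return Integer `(row, col)` seed for that replicate.
#' @export
pick_seed <- function(values, replicate = 1, low = 200, high = 2000,
                      exclude = NULL, min_dist = 3) {
  seeds <- pick_seeds(values, n = replicate, low = low, high = high,
                      exclude = exclude, min_dist = min_dist)
  seeds[replicate, ]
}

#' @rdname pick_seed
#' @param n Number of seeds to return (rows of the result).
#' @export
pick_seeds <- function(values, n = 3, low = 200, high = 2000,
                       exclude = NULL, min_dist = 3) {
  in_range <- values >= low & values <= high
  if (!is.null(exclude)) in_range[exclude] <- FALSE
  if (!any(in_range)) stop("no in-range pixel to seed from", call. = FALSE)
  idx <- which(in_range, arr.ind = TRUE)
  v <- values[(idx[, 2] - 1) * nrow(values) + idx[, 1]]
  o <- order(-v, idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]
  chosen <- matrix(NA_integer_, 0, 2)
  for (k in seq_len(nrow(idx))) {
    p <- idx[k, ]
    if (nrow(chosen) == 0 ||
        all((chosen[, 1] - p[1])^2 + (chosen[, 2] - p[2])^2 >= min_dist^2)) {
      chosen <- rbind(chosen, p)
      if (nrow(chosen) == n) break
    }
  }
  if (nrow(chosen) < n)
    stop("not enough admissible seed pixels for the requested replicates",
         call. = FALSE)
  dimnames(chosen) <- list(NULL, c("row", "col"))
  chosen
}

#' Summary statistics of a segmented region (M2)
#'
#' Mean, population SD (divisor n: the mask is the full population of
#' selected pixels), min, max, pixel count, in-plane area and the volume the
#' slice contributes (area times slice thickness).
#'
#' @param mask Logical segmentation mask.
#' @param values Numeric BMD slice.
#' @param spacing `(dz, dy, dx)` voxel spacing in mm.
#' @return A `segmentation_stats` list: `mean`, `sd`, `min`, `max`,
#'   `n_pixels`, `area_mm2`, `volume_mm3`.
#' @export
m2_slice_stats <- function(mask, values, spacing = c(1, 0.25, 0.25)) {
  stopifnot(is.logical(mask), any(mask))
  v <- values[mask]
  area <- sum(mask) * spacing[2] * spacing[3]
  structure(list(mean = mean(v), sd = pop_sd(v), min = min(v), max = max(v),
                 n_pixels = sum(mask), area_mm2 = area,
                 volume_mm3 = area * spacing[1]),
            class = "segmentation_stats")
}

#' Whole-bone segmentation BMD for one slice (M2)
#'
#' Full method-2 measurement of one calibrated slice: pick the replicate's
#' seed, grow the region inside the density window, and summarize the grown
#' mask. Because any two seeds inside the same thresholded component grow to
#' the identical mask, replicate variation for this method is expected to be
#' essentially zero.
#'
#' @param values Numeric BMD slice (mgHA/cm3).
#' @param replicate Replicate index (chooses the seed).
#' @param low,high Density window.
#' @param exclude Optional logical matrix masked out before seeding/growing.
#' @param connectivity 8 (default) or 4.
#' @param spacing Voxel spacing `(dz, dy, dx)` mm.
#' @param threshold_values Optional matrix used for the window test instead of
#'   `values` (HU-space thresholding); statistics are always on `values`.
#' @return List with `stats` (a `segmentation_stats`), `mask`, `seed`.
#' @export
m2_slice_bmd <- function(values, replicate = 1, low = 200, high = 2000,
                         exclude = NULL, connectivity = 8,
                         spacing = c(1, 0.25, 0.25), threshold_values = NULL) {
  tv <- threshold_values %||% values
  seed <- pick_seed(tv, replicate = replicate, low = low, high = high,
                    exclude = exclude)
  mask <- grow_region(tv, seed, low = low, high = high,
                      connectivity = connectivity, exclude = exclude)
  list(stats = m2_slice_stats(mask, values, spacing), mask = mask, seed = seed)
}
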