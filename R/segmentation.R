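#' Seeded region growing within a density window
#'
#' Expands from a seed pixel to all connected pixels whose value lies in
#' `[low, high]` (8-connectivity in-plane by default), the core primitive of
#' the whole-bone segmentation method. The implementation propagates a
#' frontier with vectorized neighbour shifts, which is equivalent to a
#' breadth-first flood fill and deterministic for fixed input.
#'
#' @param values Numeric matrix (one transverse slice, typically calibrated
#'   BMD in mgHA/cm3).
#' @param seed Integer `(row, col)` seed pixel; must itself be in range.
#' @param low,high Inclusive density window; defaults 200 and 2000.
#' @param connectivity 8 (default) or 4.
#' @param exclude Optional logical matrix of pixels that may never be
#'   included (e.g. the phantom region).
#' @return Logical matrix: the connected in-range component containing the
#'   seed.
#' @export
grow_region <- function(values, seed, low = 200, high = 2000,
                        connectivity = 8, exclude = NULL) {
  stopifnot(is.matrix(values), length(seed) == 2)
  seed <- as.integer(seed)
  if (seed[1] < 1 || seed[1] > nrow(values) || seed[2] < 1 || seed[2] > ncol(values))
    stop("seed outside the image", call. = FALSE)
  in_range <- values >= low & values <= high
  if (!is.null(exclude)) in_range[exclude] <- FALSE
  if (!in_range[seed[1], seed[2]])
    stop("seed density outside the growing range", call. = FALSE)
  offs <- neighbour_offsets(connectivity)
  visited <- matrix(FALSE, nrow(values), ncol(values))
  visited[seed[1], seed[2]] <- TRUE
  frontier <- visited
  repeat {
    nb <- Reduce(`|`, lapply(offs, function(o) shift_mat(frontier, o[1], o[2])))
    frontier <- nb & in_range & !visited
    if (!any(frontier)) break
    visited <- visited | frontier
  }
  visited
}

# Label the connected components of a logical mask (row-major discovery
# order, so labels are deterministic). Returns an integer matrix, 0 outside.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  lab <- 0L
  while (any(remaining)) {
    idx <- which(remaining, arr.ind = TRUE)
    first <- idx[order(idx[, 1], idx[, 2])[1], ]
    comp <- grow_region(ifelse(remaining, 1, 0), first, low = 1, high = 1,
                        connectivity = connectivity)
    lab <- lab + 1L
    labels[comp] <- lab
    remaining <- remaining & !comp
  }
  labels
}

# Largest connected component of a logical mask (ties broken by the component
# discovered first in row-major order).
largest_component <- function(mask, connectivity = 8) {
  labels <- label_components(mask, connectivity)
  if (max(labels) == 0L) stop("empty mask", call. = FALSE)
  sizes <- tabulate(labels[labels > 0L])
  labels == which.max(sizes)
}

#' Segment the bone on a calibrated slice
#'
#' Thresholds the slice to `[low, high]`, removes the phantom region, and
#' keeps the largest connected component; this is the working bone mask shared
#' by both measurement methods.
#'
#' @inheritParams grow_region
#' @return Logical bone mask.
#' @export
bone_mask <- function(values, low = 200, high = 2000, exclude = NULL,
                      connectivity = 8) {
  in_range <- values >= low & values <= high
  if (!is.null(exclude)) in_range[exclude] <- FALSE
  if (!any(in_range))
    stop("no voxels inside the density window: empty bone mask", call. = FALSE)
  largest_component(in_range, connectivity)
}
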