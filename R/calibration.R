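#' Read the calibration phantom from a volume
#'
#' Averages HU over a central circular ROI of each phantom cylinder, across
#' every slice where the phantom is present. The ROI radius is
#' `roi_radius_fraction` of the cylinder radius (default 0.7) to keep
#' partial-volume voxels at the cylinder edge out of the reference reading.
#'
#' @param volume A [ct_volume()].
#' @param layout A [phantom_layout()].
#' @param roi_radius_fraction Fraction of the cylinder radius sampled.
#' @return A `phantom_reading`: list with `hu` (named by concentration),
#'   `n_pixels` per cylinder, and `roi_radius_fraction`.
#' @export
read_phantom <- function(volume, layout, roi_radius_fraction = 0.7) {
  stopifnot(inherits(volume, "ct_volume"), inherits(layout, "phantom_layout"))
  d <- dim(volume$voxels)
  r <- layout$radius_px
  bad <- layout$centers[, 1] - r < 1 | layout$centers[, 1] + r > d[2] |
         layout$centers[, 2] - r < 1 | layout$centers[, 2] + r > d[3]
  if (any(bad)) stop("phantom cylinder lies outside the field of view", call. = FALSE)
  slices <- if (is.null(layout$slice_range)) seq_len(d[1]) else
    seq(max(1, layout$slice_range[1]), min(d[1], layout$slice_range[2]))
  rows <- matrix(seq_len(d[2]), d[2], d[3])
  cols <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  rr <- roi_radius_fraction * r
  hu <- numeric(length(layout$concentrations))
  npx <- integer(length(layout$concentrations))
  for (k in seq_along(layout$concentrations)) {
    m <- (rows - layout$centers[k, 1])^2 + (cols - layout$centers[k, 2])^2 <= rr^2
    vox <- matrix(volume$voxels[slices, , , drop = FALSE], nrow = length(slices))
    vals <- as.vector(vox[, as.vector(m), drop = FALSE])
    hu[k] <- mean(vals)
    npx[k] <- sum(m) * length(slices)
  }
  names(hu) <- as.character(layout$concentrations)
  reading <- structure(list(hu = hu, n_pixels = stats::setNames(npx, names(hu)),
                            roi_radius_fraction = roi_radius_fraction),
                       class = "phantom_reading")
  if (all(c("0", "200") %in% names(hu)) && hu[["200"]] <= hu[["0"]])
    stop("degenerate phantom: bone reference not denser than water reference",
         call. = FALSE)
  reading
}

#' Construct a phantom reading directly
#'
#' Convenience constructor for tests and for calibrating from externally
#' measured phantom means.
#'
#' @param hu Named numeric vector of per-cylinder mean HU; names are the
#'   concentrations in mgHA/cm3 (e.g. `c("0" = 1.5, "200" = 205)`).
#' @param n_pixels Optional ROI pixel counts.
#' @return A `phantom_reading`.
#' @export
phantom_reading <- function(hu, n_pixels = NULL) {
  if (is.null(names(hu)) || anyNA(suppressWarnings(as.numeric(names(hu)))))
    stop("hu must be named by concentration (mgHA/cm3)", call. = FALSE)
  structure(list(hu = hu, n_pixels = n_pixels, roi_radius_fraction = NA_real_),
            class = "phantom_reading")
}

#' Fit the HU-to-BMD calibration line
#'
#' Two modes. `"two_point"` implements the phantom equation verbatim:
#' `BMD = 200 * HUt / (HUb - HUw)`, i.e. slope `200 / (HUb - HUw)` and
#' intercept 0, where `HUb` and `HUw` are the 200 and 0 mgHA/cm3 cylinder
#' readings. Note the published form does not subtract `HUw` from the
#' measured HU, so for `HUw != 0` the line does not pass through the water
#' point; `water_correct = TRUE` switches to the interpolating variant
#' `200 * (HUt - HUw) / (HUb - HUw)` (intercept `-slope * HUw`).
#' `"least_squares"` fits `density ~ HU` by ordinary least squares over all
#' cylinders.
#'
#' @param reading A `phantom_reading`.
#' @param mode `"two_point"` (default) or `"least_squares"`.
#' @param water_correct Two-point mode only: subtract the water reading from
#'   the numerator (off by default, matching the published equation).
#' @return A `calibration_model` with `slope` (> 0) and `intercept`.
#' @export
fit_calibration <- function(reading, mode = c("two_point", "least_squares"),
                            water_correct = FALSE) {
  stopifnot(inherits(reading, "phantom_reading"))
  mode <- match.arg(mode)
  hu <- reading$hu
  if (mode == "two_point") {
    if (!all(c("0", "200") %in% names(hu)))
      stop("two-point calibration needs the 0 and 200 mgHA/cm3 cylinders", call. = FALSE)
    huw <- hu[["0"]]; hub <- hu[["200"]]
    if (hub <= huw)
      stop("degenerate phantom: HUb must exceed HUw", call. = FALSE)
    slope <- 200 / (hub - huw)
    intercept <- if (water_correct) -slope * huw else 0
  } else {
    conc <- as.numeric(names(hu))
    if (length(unique(hu)) < 2)
      stop("singular fit: identical cylinder HU readings", call. = FALSE)
    fit <- stats::lm(conc ~ hu)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    if (!is.finite(slope) || slope <= 0)
      stop("calibration slope must be positive", call. = FALSE)
  }
  structure(list(mode = mode, slope = slope, intercept = intercept,
                 water_correct = water_correct, reading = reading),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: BMD = %.6g * HU %+.6g  (mgHA/cm3)\n",
              x$mode, x$slope, x$intercept))
  invisible(x)
}

#' Convert HU to BMD
#'
#' Voxelwise affine application of a [fit_calibration()] model. Accepts a full
#' [ct_volume()] (returning a `bmd_map` with the same shape and spacing) or
#' any numeric array/matrix/vector of HU values.
#'
#' @param x HU values: a [ct_volume()] or numeric data.
#' @param model A `calibration_model`.
#' @return A `bmd_map` (for volumes) or numeric data of the same shape.
#' @export
hu_to_bmd <- function(x, model) UseMethod("hu_to_bmd")

#' @export
hu_to_bmd.ct_volume <- function(x, model) {
  stopifnot(inherits(model, "calibration_model"))
  structure(list(voxels = model$slope * x$voxels + model$intercept,
                 spacing = x$spacing, model = model),
            class = "bmd_map")
}

#' @export
hu_to_bmd.default <- function(x, model) {
  stopifnot(is.numeric(x), inherits(model, "calibration_model"))
  model$slope * x + model$intercept
}

#' @export
print.bmd_map <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<bmd_map> %d x %d x %d voxels (mgHA/cm3), %s calibration\n",
              d[1], d[2], d[3], x$model$mode))
  invisible(x)
}
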