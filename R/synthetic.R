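#' Synthetic-cohort specification
#'
#' Parameters of the synthetic CT generator. The defaults emulate the study
#' conditions the pipeline is meant to exercise: 48 excised hen tibiae scanned
#' at 1 mm slice thickness/interval with an in-field three-cylinder
#' hydroxyapatite phantom placed ventrally to the bone, a dense cortical shell
#' whose true density varies azimuthally and radially, a lower-density
#' medullary interior, Gaussian HU noise and a mild partial-volume blur.
#'
#' The scanner forward model is affine: `HU = hu_slope * density +
#' hu_intercept` on bone and phantom voxels (default slope 1, intercept 0, so
#' HU is numerically equal to density and the two-point phantom calibration is
#' exactly invertible). Soft tissue sits at `soft_tissue_hu`, air at `air_hu`.
#'
#' @param n_bones Number of bones in the cohort.
#' @param length_mm Bone length; one slice per mm.
#' @param n_row,n_col In-plane grid size.
#' @param pixel_mm In-plane pixel size (mm); slices are `slice_thickness_mm`
#'   apart.
#' @param slice_thickness_mm Slice thickness = interval (mm).
#' @param cortical_density_mean,cortical_density_sd Mean and between-bone SD
#'   of the cortical density (mgHA/cm3).
#' @param azimuthal_amplitude,azimuthal_amplitude_sd Relative amplitude of the
#'   sinusoidal azimuthal density modulation of the cortex, and its
#'   between-bone SD. This heterogeneity is what the quadrant method's
#'   max-density ROI search exploits.
#' @param radial_gradient Periosteal-minus-mid radial density gradient
#'   amplitude (mgHA/cm3; denser at the outer surface).
#' @param endosteal_fraction,endosteal_fraction_sd Endosteal boundary as a
#'   fraction of the outer ellipse (0 = no medullary cavity), and its
#'   between-bone SD.
#' @param medullary_density_mean,medullary_density_sd Mean and between-bone SD
#'   of medullary-bone density (mgHA/cm3).
#' @param density_texture_sd Within-tissue per-voxel density texture SD.
#' @param hu_noise_sd Gaussian HU noise SD.
#' @param blur_sigma Partial-volume blur sigma in pixels (0 = none).
#' @param soft_tissue_hu,air_hu Background HU levels.
#' @param hu_slope,hu_intercept Scanner forward model coefficients.
#' @param bone_semi_row_mm,bone_semi_col_mm Mid-shaft outer semi-axes of the
#'   elliptic cross-section (mm).
#' @param flare Relative widening of the cross-section at the bone ends.
#' @param axial_profile Two-column matrix (relative position in `[0, 1]`,
#'   density multiplier), linearly interpolated along the shaft. The default
#'   makes the midshaft (medial level) densest, then distal, then proximal.
#' @param bone_center `(row, col)` pixel center of the bone, or `NULL` for the
#'   default placement above the phantom.
#' @param layout A [phantom_layout()], or `NULL` for the default ventral
#'   placement.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_bones = 48,
                        length_mm = 110,
                        n_row = 128, n_col = 128,
                        pixel_mm = 0.25, slice_thickness_mm = 1,
                        cortical_density_mean = 1000, cortical_density_sd = 160,
                        azimuthal_amplitude = 0.12, azimuthal_amplitude_sd = 0.04,
                        radial_gradient = 60,
                        endosteal_fraction = 0.58, endosteal_fraction_sd = 0.05,
                        medullary_density_mean = 300, medullary_density_sd = 40,
                        density_texture_sd = 25,
                        hu_noise_sd = 30,
                        blur_sigma = 0.5,
                        soft_tissue_hu = 40, air_hu = -1000,
                        hu_slope = 1, hu_intercept = 0,
                        bone_semi_row_mm = 4.0, bone_semi_col_mm = 4.5,
                        flare = 0.25,
                        axial_profile = cbind(c(0, 0.25, 0.5, 0.75, 1),
                                              c(0.960, 0.972, 1.028, 1.000, 0.980)),
                        bone_center = NULL,
                        layout = NULL) {
  if (n_bones < 1) stop("n_bones must be >= 1", call. = FALSE)
  sds <- c(cortical_density_sd, azimuthal_amplitude_sd, endosteal_fraction_sd,
           medullary_density_sd, density_texture_sd, hu_noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (cortical_density_mean <= medullary_density_mean)
    stop("cortical density mean must exceed medullary density mean", call. = FALSE)
  if (hu_slope <= 0) stop("hu_slope must be positive", call. = FALSE)
  if (pixel_mm <= 0 || slice_thickness_mm <= 0 || length_mm <= 0)
    stop("geometry must be strictly positive", call. = FALSE)
  if (endosteal_fraction < 0 || endosteal_fraction >= 1)
    stop("endosteal_fraction must be in [0, 1)", call. = FALSE)
  if (is.null(layout)) layout <- default_phantom_layout(n_row, n_col, pixel_mm)
  if (is.null(bone_center)) bone_center <- c(round(0.4 * n_row), round(0.5 * n_col))
  spec <- list(n_bones = as.integer(n_bones), length_mm = length_mm,
               n_slices = max(1L, as.integer(round(length_mm / slice_thickness_mm))),
               n_row = as.integer(n_row), n_col = as.integer(n_col),
               pixel_mm = pixel_mm, slice_thickness_mm = slice_thickness_mm,
               cortical_density_mean = cortical_density_mean,
               cortical_density_sd = cortical_density_sd,
               azimuthal_amplitude = azimuthal_amplitude,
               azimuthal_amplitude_sd = azimuthal_amplitude_sd,
               radial_gradient = radial_gradient,
               endosteal_fraction = endosteal_fraction,
               endosteal_fraction_sd = endosteal_fraction_sd,
               medullary_density_mean = medullary_density_mean,
               medullary_density_sd = medullary_density_sd,
               density_texture_sd = density_texture_sd,
               hu_noise_sd = hu_noise_sd, blur_sigma = blur_sigma,
               soft_tissue_hu = soft_tissue_hu, air_hu = air_hu,
               hu_slope = hu_slope, hu_intercept = hu_intercept,
               bone_semi_row_mm = bone_semi_row_mm, bone_semi_col_mm = bone_semi_col_mm,
               flare = flare, axial_profile = axial_profile,
               bone_center = bone_center, layout = layout)
  structure(spec, class = "cohort_spec")
}

# Normalized 1-D Gaussian convolution as a dense band matrix (edge-renormalized).
gauss_band <- function(n, sigma) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) stats::dnorm(i - j, sd = sigma))
  K[abs(outer(idx, idx, "-")) > ceiling(3 * sigma)] <- 0
  K / rowSums(K)
}

#' Generate one synthetic tibia volume with ground truth
#'
#' Builds a CT volume containing an elliptic-annulus cortical shell (azimuthal
#' and radial density modulation), a medullary interior, the calibration
#' phantom in every configured slice, Gaussian HU noise and optional
#' partial-volume blur. The HU field is an affine function of the true density
#' (the generator's forward model of the scanner), so with zero noise and blur
#' the phantom calibration recovers the ground-truth density exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed; identical `(spec, seed)` give identical
#'   output.
#' @return A list with elements `volume` (a [ct_volume()]) and `truth`, a
#'   `ground_truth` object holding `density`, `bone_mask`, `cortical_mask`,
#'   `medullary_mask`, `true_mean_bmd` (mean density over the bone mask) and
#'   the per-bone drawn parameters.
#' @export
make_tibia_volume <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    p <- list(
      cortical_mu = stats::rnorm(1, spec$cortical_density_mean, spec$cortical_density_sd),
      azimuthal_amp = max(0, stats::rnorm(1, spec$azimuthal_amplitude,
                                          spec$azimuthal_amplitude_sd)),
      theta0 = stats::runif(1, 0, 2 * pi),
      endosteal_f = clamp(stats::rnorm(1, spec$endosteal_fraction,
                                       spec$endosteal_fraction_sd),
                          max(0, spec$endosteal_fraction - 2.5 * spec$endosteal_fraction_sd),
                          min(0.9, spec$endosteal_fraction + 2.5 * spec$endosteal_fraction_sd)),
      medullary_mu = clamp(stats::rnorm(1, spec$medullary_density_mean,
                                        spec$medullary_density_sd),
                           max(0, spec$medullary_density_mean - 2.5 * spec$medullary_density_sd),
                           spec$medullary_density_mean + 2.5 * spec$medullary_density_sd)
    )
    p$medullary_mu <- min(p$medullary_mu, p$cortical_mu - 100)
    p$cortical_mu <- max(p$cortical_mu, p$medullary_mu + 100)

    nz <- spec$n_slices; nr <- spec$n_row; nc <- spec$n_col
    sr0 <- spec$bone_semi_row_mm / spec$pixel_mm
    sc0 <- spec$bone_semi_col_mm / spec$pixel_mm
    ctr <- spec$bone_center
    sr_max <- sr0 * (1 + spec$flare)
    sc_max <- sc0 * (1 + spec$flare)
    phantom_top <- min(spec$layout$centers[, 1]) - spec$layout$radius_px - 2
    if (ctr[1] - sr_max < 2 || ctr[1] + sr_max > min(nr - 1, phantom_top) ||
        ctr[2] - sc_max < 2 || ctr[2] + sc_max > nc - 1)
      stop("bone cross-section exceeds the field of view", call. = FALSE)

    dr <- matrix(seq_len(nr) - ctr[1], nr, nc)
    dc <- matrix(seq_len(nc) - ctr[2], nr, nc, byrow = TRUE)
    theta <- atan2(dc, -dr)  # 0 = anterior (up), pi/2 = lateral (right)
    az <- 1 + p$azimuthal_amp * cos(theta - p$theta0)

    zf <- (seq_len(nz) - 0.5) / nz
    gz <- stats::approx(spec$axial_profile[, 1], spec$axial_profile[, 2],
                        xout = zf, rule = 2)$y
    fl <- 1 + spec$flare * (2 * zf - 1)^2

    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    body <- ((rows - 0.55 * nr) / (0.45 * nr))^2 +
            ((cols - 0.5 * nc) / (0.46 * nc))^2 <= 1

    in_phantom_range <- function(z) {
      rng <- spec$layout$slice_range
      is.null(rng) || (z >= rng[1] && z <= rng[2])
    }
    ph_masks <- cylinder_masks(spec$layout, c(nr, nc))

    density <- array(0, c(nz, nr, nc))
    hu <- array(0, c(nz, nr, nc))
    bone_mask <- array(FALSE, c(nz, nr, nc))
    cort_mask <- array(FALSE, c(nz, nr, nc))
    med_mask <- array(FALSE, c(nz, nr, nc))
    umid <- (1 + p$endosteal_f) / 2
    half_w <- max(1 - p$endosteal_f, 1e-9)

    Kr <- if (spec$blur_sigma > 0) gauss_band(nr, spec$blur_sigma)
    Kc <- if (spec$blur_sigma > 0) t(gauss_band(nc, spec$blur_sigma))

    for (z in seq_len(nz)) {
      u <- sqrt((dr / (sr0 * fl[z]))^2 + (dc / (sc0 * fl[z]))^2)
      bone <- u <= 1
      med <- if (p$endosteal_f > 0) u <= p$endosteal_f else bone & FALSE
      cort <- bone & !med
      dens <- matrix(0, nr, nc)
      dens[cort] <- gz[z] * p$cortical_mu * az[cort] +
        spec$radial_gradient * 2 * (u[cort] - umid) / half_w
      dens[med] <- gz[z] * p$medullary_mu
      if (spec$density_texture_sd > 0) {
        txt <- matrix(stats::rnorm(nr * nc, 0, spec$density_texture_sd), nr, nc)
        dens[bone] <- dens[bone] + txt[bone]
      }
      dens[bone] <- pmax(dens[bone], 0)
      hu_s <- ifelse(body, spec$soft_tissue_hu, spec$air_hu)
      hu_s[bone] <- spec$hu_slope * dens[bone] + spec$hu_intercept
      if (in_phantom_range(z)) {
        for (k in seq_along(ph_masks)) {
          conc <- spec$layout$concentrations[k]
          dens[ph_masks[[k]]] <- conc
          hu_s[ph_masks[[k]]] <- spec$hu_slope * conc + spec$hu_intercept
        }
      }
      if (!is.null(Kr)) hu_s <- Kr %*% hu_s %*% Kc
      density[z, , ] <- dens
      hu[z, , ] <- hu_s
      bone_mask[z, , ] <- bone
      cort_mask[z, , ] <- cort
      med_mask[z, , ] <- med
    }
    if (spec$hu_noise_sd > 0)
      hu <- hu + array(stats::rnorm(length(hu), 0, spec$hu_noise_sd), dim(hu))

    volume <- ct_volume(hu, spacing = c(spec$slice_thickness_mm,
                                        spec$pixel_mm, spec$pixel_mm))
    truth <- structure(list(density = density, bone_mask = bone_mask,
                            cortical_mask = cort_mask, medullary_mask = med_mask,
                            true_mean_bmd = mean(density[bone_mask]),
                            params = p, seed = seed),
                       class = "ground_truth")
    list(volume = volume, truth = truth)
  })
}

#' Residual SD for a target population R-squared
#'
#' For a linear trait model `t = a + b * D + e`, returns the residual SD `s`
#' such that the population coefficient of determination of `t ~ D` equals
#' `target_r2`: `s = |b| * sqrt(var_d * (1 - R2) / R2)`.
#'
#' @param slope Linear slope `b` of the trait on true BMD.
#' @param var_d Variance of true BMD across bones (must be > 0).
#' @param target_r2 Target population R-squared, strictly in (0, 1).
#' @return Residual SD.
#' @examples
#' noise_sd_for_target_r2(1, 1, 0.5)  # 1
#' @export
noise_sd_for_target_r2 <- function(slope, var_d, target_r2) {
  if (!is.finite(target_r2) || target_r2 <= 0 || target_r2 >= 1)
    stop("target_r2 must be strictly inside (0, 1)", call. = FALSE)
  if (!is.finite(var_d) || var_d <= 0) stop("var_d must be > 0", call. = FALSE)
  abs(slope) * sqrt(var_d * (1 - target_r2) / target_r2)
}

#' Linear trait model for the simulated cohort
#'
#' Per-trait linear coefficients (intercept, slope on true BMD, residual SD)
#' for the bone and eggshell traits. Default slopes are positive for bone
#' weight and volume, negative for eggshell weight/thickness/breaking strength
#' and for mineral mass, and zero (pure noise) for bone length, mineral
#' percentage and the Seedor index. Residual SDs are derived from target
#' population R-squared values via [noise_sd_for_target_r2()] at the
#' generator's nominal between-bone BMD variance.
#'
#' @param var_d Nominal variance of true BMD used to convert R-squared targets
#'   into residual SDs.
#' @param ref_bmd Reference BMD at which `means` are anchored
#'   (`intercept = mean - slope * ref_bmd`).
#' @param means,slopes Named trait means (at `ref_bmd`) and slopes per
#'   mgHA/cm3.
#' @param r2_targets Target R-squared per trait (`NA` for zero-slope traits).
#' @param flat_sds Residual SDs for the zero-slope traits.
#' @return An object of class `trait_model` whose `coefficients` data frame
#'   has columns `trait`, `intercept`, `slope`, `resid_sd`.
#' @export
trait_model <- function(var_d = 115^2, ref_bmd = 740,
                        means = c(bone_weight_g = 8, bone_length_mm = 110,
                                  bone_volume_cm3 = 7, mineral_g = 3.6,
                                  mineral_pct = 44, seedor_mg_mm = 73,
                                  eggshell_weight_g = 5.8,
                                  eggshell_thickness_mm = 0.37,
                                  eggshell_strength_n = 38),
                        slopes = c(0.010, 0, 0.005, -0.004, 0, 0,
                                   -0.005, -0.00055, -0.05),
                        r2_targets = c(0.60, NA, 0.85, 0.50, NA, NA,
                                       0.55, 0.45, 0.40),
                        flat_sds = c(NA, 4, NA, NA, 2.5, 6, NA, NA, NA)) {
  stopifnot(length(slopes) == length(means), length(r2_targets) == length(means),
            length(flat_sds) == length(means))
  resid_sd <- ifelse(is.na(r2_targets), flat_sds,
                     mapply(function(b, r2) if (is.na(r2)) NA_real_ else
                       noise_sd_for_target_r2(b, var_d, r2), slopes, r2_targets))
  if (any(is.na(resid_sd)) || any(resid_sd < 0))
    stop("every trait needs a non-negative residual SD", call. = FALSE)
  coefs <- data.frame(trait = names(means),
                      intercept = unname(means - slopes * ref_bmd),
                      slope = unname(slopes),
                      resid_sd = unname(resid_sd),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, var_d = var_d, ref_bmd = ref_bmd),
            class = "trait_model")
}

#' Simulate a trait table from true per-bone BMD
#'
#' Draws `t_i = a_t + b_t * D_i + e_i`, `e_i ~ N(0, s_t)`, independently per
#' trait, from a [trait_model()].
#'
#' @param model A [trait_model()].
#' @param true_bmd Numeric vector of per-bone true mean BMD (mgHA/cm3).
#' @param seed RNG seed.
#' @param bone_ids Bone identifiers (default `1:n`).
#' @return Data frame with `bone_id` plus one column per trait.
#' @export
simulate_traits <- function(model, true_bmd, seed = 1,
                            bone_ids = seq_along(true_bmd)) {
  stopifnot(inherits(model, "trait_model"))
  n <- length(true_bmd)
  with_seed(seed, {
    out <- data.frame(bone_id = bone_ids)
    for (k in seq_len(nrow(model$coefficients))) {
      co <- model$coefficients[k, ]
      out[[co$trait]] <- co$intercept + co$slope * true_bmd +
        stats::rnorm(n, 0, co$resid_sd)
    }
    out
  })
}

#' Generate a full synthetic cohort
#'
#' One volume + ground truth per bone (per-bone parameters drawn from the
#' cohort spec) and a trait table linearly tied to the realized per-bone true
#' BMD. Reproducible under a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param tm A [trait_model()].
#' @param seed Master RNG seed (per-bone sub-seeds are derived from it).
#' @param keep_volumes Keep the generated volumes in the result? With the
#'   default 48-bone spec the volumes occupy roughly 1.7 GB; the measurement
#'   pipeline ([run_pipeline()]) streams bones instead of calling this with
#'   `keep_volumes = TRUE`.
#' @return A list with `bones` (list of `list(volume, truth)`, or `NULL`
#'   entries when `keep_volumes = FALSE`), `true_bmd`, `traits`, `bone_seeds`,
#'   `trait_seed`, `spec`, `seed`.
#' @export
make_cohort <- function(spec = cohort_spec(), tm = trait_model(), seed = 1,
                        keep_volumes = TRUE) {
  seeds <- derive_seeds(seed, spec$n_bones + 1L)
  bone_seeds <- seeds[seq_len(spec$n_bones)]
  trait_seed <- seeds[spec$n_bones + 1L]
  bones <- vector("list", spec$n_bones)
  true_bmd <- numeric(spec$n_bones)
  for (i in seq_len(spec$n_bones)) {
    b <- make_tibia_volume(spec, seed = bone_seeds[i])
    true_bmd[i] <- b$truth$true_mean_bmd
    if (keep_volumes) bones[[i]] <- b
  }
  traits <- simulate_traits(tm, true_bmd, seed = trait_seed)
  list(bones = bones, true_bmd = true_bmd, traits = traits,
       bone_seeds = bone_seeds, trait_seed = trait_seed, spec = spec, seed = seed)
}
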