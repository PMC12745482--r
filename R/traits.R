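#' Seedor index
#'
#' Bone weight divided by bone length, in mg/mm — a gross bone-robustness
#' measure.
#'
#' @param bone_weight Bone weight, in mg by default.
#' @param bone_length_mm Bone length in mm (> 0).
#' @param weight_unit `"mg"` (default) or `"g"` (converted to mg).
#' @return Seedor index in mg/mm.
#' @examples
#' seedor_index(1000, 100)              # 10
#' seedor_index(1, 100, weight_unit = "g")  # 10
#' @export
seedor_index <- function(bone_weight, bone_length_mm, weight_unit = c("mg", "g")) {
  weight_unit <- match.arg(weight_unit)
  if (any(bone_length_mm <= 0)) stop("bone length must be positive", call. = FALSE)
  w_mg <- if (weight_unit == "g") bone_weight * 1000 else bone_weight
  w_mg / bone_length_mm
}

#' Volume-normalize BMD
#'
#' Divides BMD by bone volume, the size adjustment applied before the trait
#' regression screen.
#'
#' @param bmd BMD values (mgHA/cm3).
#' @param bone_volume_cm3 Bone volume (> 0), cm3.
#' @return `bmd / bone_volume_cm3`.
#' @export
normalize_bmd <- function(bmd, bone_volume_cm3) {
  if (any(bone_volume_cm3 <= 0)) stop("bone volume must be positive", call. = FALSE)
  bmd / bone_volume_cm3
}

#' Simple linear regression of a trait on BMD
#'
#' OLS of the trait on BMD, reporting the slope, intercept, correlation,
#' R-squared, the signed R-squared (`sign(slope) * R2`, the reporting
#' convention in which a negative coefficient of determination marks an
#' inverse association), and the slope-t-test p-value.
#'
#' @param trait Numeric trait values.
#' @param bmd Numeric BMD values (paired with `trait`), non-zero variance.
#' @return One-row data frame: `slope`, `intercept`, `r`, `r2`, `signed_r2`,
#'   `p`, `n`.
#' @export
regress_trait <- function(trait, bmd) {
  check_pairs(trait, bmd)
  if (stats::var(bmd) == 0) stop("zero variance in BMD", call. = FALSE)
  fit <- stats::lm(trait ~ bmd)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  r2 <- sm$r.squared
  data.frame(slope = slope, intercept = unname(stats::coef(fit)[1]),
             r = sign(slope) * sqrt(r2), r2 = r2,
             signed_r2 = sign(slope) * r2,
             p = sm$coefficients[2, 4], n = length(trait))
}

#' Trait regression screen
#'
#' One simple linear regression per (trait x method) of the trait on the
#' method's per-bone BMD, optionally volume-normalized first (the default,
#' matching the study procedure). Bones missing from either table are logged
#' and excluded pairwise. A Benjamini-Hochberg adjusted p-value column is
#' emitted as supplementary output only; the primary screen is unadjusted.
#'
#' @param trait_table Data frame with `bone_id` and trait columns (must
#'   include `bone_volume_cm3` when normalizing).
#' @param bmd_table Data frame with columns `bone_id`, `method`, `bmd`
#'   (per-bone whole-bone BMD per method).
#' @param volume_normalize Divide BMD by `bone_volume_cm3` before regressing
#'   (default TRUE).
#' @return Data frame with one row per trait x method: `trait`, `method`,
#'   `slope`, `intercept`, `r`, `r2`, `signed_r2`, `p`, `p_bh`, `n`.
#' @export
trait_screen <- function(trait_table, bmd_table, volume_normalize = TRUE) {
  stopifnot(all(c("bone_id", "method", "bmd") %in% names(bmd_table)))
  traits <- setdiff(names(trait_table), "bone_id")
  out <- list()
  for (m in unique(bmd_table$method)) {
    sub <- bmd_table[bmd_table$method == m, ]
    merged <- merge(trait_table, sub, by = "bone_id")
    dropped <- (nrow(trait_table) - nrow(merged)) + (nrow(sub) - nrow(merged))
    if (dropped > 0)
      message(sprintf("trait_screen: %d unmatched bone_id row(s) excluded for %s",
                      dropped, m))
    x <- if (volume_normalize) {
      if (!"bone_volume_cm3" %in% names(merged))
        stop("volume normalization requires a bone_volume_cm3 column", call. = FALSE)
      normalize_bmd(merged$bmd, merged$bone_volume_cm3)
    } else merged$bmd
    for (tr in traits) {
      row <- regress_trait(merged[[tr]], x)
      out[[length(out) + 1]] <- cbind(data.frame(trait = tr, method = m), row)
    }
  }
  res <- do.call(rbind, out)
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res$trait <- factor(res$trait, levels = traits)
  res[order(res$trait, res$method), ]
}

#' Heatmap-ready signed-R-squared matrix
#'
#' Reshapes a [trait_screen()] result into a traits x methods matrix of
#' signed R-squared values.
#'
#' @param screen Output of [trait_screen()].
#' @return Numeric matrix (rows = traits, columns = methods).
#' @export
signed_r2_matrix <- function(screen) {
  traits <- levels(screen$trait)
  methods <- sort(unique(screen$method))
  m <- matrix(NA_real_, length(traits), length(methods),
              dimnames = list(traits, methods))
  for (k in seq_len(nrow(screen)))
    m[as.character(screen$trait[k]), screen$method[k]] <- screen$signed_r2[k]
  m
}
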