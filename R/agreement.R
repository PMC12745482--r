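#' Pearson correlation of paired measurements
#'
#' Product-moment correlation with its p-value from the t transform on n - 2
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors (no missing values), n >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  check_pairs(x, y)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

check_pairs <- function(x, y, n_min = 3) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values within pairs", call. = FALSE)
  if (length(x) < n_min) stop(sprintf("need at least %d pairs", n_min), call. = FALSE)
  invisible(TRUE)
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` using population
#' (divisor n) moments, decomposed as precision times accuracy:
#' `ccc = r * cb` with `cb` the bias-correction factor. The confidence
#' interval uses the Fisher z-transform of ccc with Lin's asymptotic standard
#' error, back-transformed.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param conf Confidence level (default 0.95).
#' @return List with `ccc`, `cb`, `r`, `ci` (length 2), `n`.
#' @export
lin_ccc <- function(x, y, conf = 0.95) {
  check_pairs(x, y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) stop("undefined concordance: both variances zero",
                                 call. = FALSE)
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  cb <- ccc / r
  # Lin's asymptotic SE on the z scale (corrected form); u is the
  # standardized location shift (mx - my) / sqrt(sx * sy)
  u <- (mx - my) / ((sx2 * sy2)^0.25)
  ci <- c(NA_real_, NA_real_)
  if (abs(ccc) < 1 && abs(r) > 0) {
    z <- atanh(ccc)
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
            2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
            ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    q <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- tanh(z + c(-1, 1) * q * sqrt(max(sz2, 0)))
  }
  list(ccc = ccc, cb = cb, r = r, ci = ci, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `d = y - x` (method 2 minus method 1). Reports the mean
#' bias, 95% limits of agreement `bias +/- 1.96 * SD(d)` (sample SD), and the
#' proportional-bias regression of the differences on the pair means
#' `(x + y) / 2` (OLS slope with its p-value). With constant differences the
#' slope is undefined and flagged (`degenerate = TRUE`, slope `NA`).
#'
#' @param x,y Paired numeric vectors, n >= 3 (`x` = method 1, `y` = method 2).
#' @return List with `bias`, `loa_lower`, `loa_upper`, `sd_diff`, `beta`,
#'   `beta_p`, `degenerate`, `n`.
#' @export
bland_altman <- function(x, y) {
  check_pairs(x, y)
  d <- y - x
  m <- (x + y) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  if (sd_d < .Machine$double.eps^0.5 * max(1, abs(bias)) || stats::var(m) == 0) {
    beta <- NA_real_; beta_p <- NA_real_; degenerate <- TRUE
  } else {
    fit <- summary(stats::lm(d ~ m))$coefficients
    beta <- fit[2, 1]; beta_p <- fit[2, 4]; degenerate <- FALSE
  }
  list(bias = bias, loa_lower = loa[1], loa_upper = loa[2], sd_diff = sd_d,
       beta = beta, beta_p = beta_p, degenerate = degenerate, n = length(x))
}

#' Deming (errors-in-variables) regression
#'
#' Fits `y = alpha + beta * x` allowing measurement error in both variables,
#' with `lambda` the ratio of error variances (error_y / error_x; `lambda = 1`
#' is classical orthogonal regression). The slope is the closed form
#' `beta = (s_y^2 - lambda s_x^2 + sqrt((s_y^2 - lambda s_x^2)^2 +
#' 4 lambda s_xy^2)) / (2 s_xy)`; 95% confidence intervals come from a
#' leave-one-out jackknife with t quantiles on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param lambda Error-variance ratio, > 0.
#' @param conf Confidence level.
#' @param jackknife Compute jackknife CIs (default TRUE).
#' @return List with `alpha`, `beta`, `alpha_ci`, `beta_ci`, `alpha_se`,
#'   `beta_se`, `lambda`, `n`.
#' @export
deming <- function(x, y, lambda = 1, conf = 0.95, jackknife = TRUE) {
  check_pairs(x, y)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  est <- deming_point(x, y, lambda)
  if (!jackknife) {
    return(c(est, list(alpha_ci = c(NA, NA), beta_ci = c(NA, NA),
                       alpha_se = NA_real_, beta_se = NA_real_,
                       lambda = lambda, n = length(x))))
  }
  n <- length(x)
  ab <- vapply(seq_len(n), function(i) {
    e <- deming_point(x[-i], y[-i], lambda)
    c(e$alpha, e$beta)
  }, numeric(2))
  se <- sqrt((n - 1) / n * rowSums((ab - rowMeans(ab))^2))
  q <- stats::qt(1 - (1 - conf) / 2, df = n - 2)
  list(alpha = est$alpha, beta = est$beta,
       alpha_ci = est$alpha + c(-1, 1) * q * se[1],
       beta_ci = est$beta + c(-1, 1) * q * se[2],
       alpha_se = se[1], beta_se = se[2], lambda = lambda, n = n)
}

deming_point <- function(x, y, lambda) {
  sx2 <- stats::var(x); sy2 <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) stop("degenerate Deming slope: zero covariance", call. = FALSE)
  q <- sy2 - lambda * sx2
  beta <- (q + sqrt(q^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  list(alpha = mean(y) - beta * mean(x), beta = beta)
}

#' Coefficient of variation (percent)
#'
#' `100 * SD / mean` (sample SD). Either pass a vector of values, or a mean
#' as `x` together with its `sd`.
#'
#' @param x Numeric vector of values, or a single mean when `sd` is given.
#' @param sd Optional standard deviation accompanying a mean.
#' @return CV in percent.
#' @examples
#' cv_percent(1152.49, sd = 218.54)  # 18.96
#' @export
cv_percent <- function(x, sd = NULL) {
  if (is.null(sd)) {
    m <- mean(x)
    if (m == 0) stop("undefined CV: zero mean", call. = FALSE)
    100 * stats::sd(x) / m
  } else {
    if (length(x) != 1 || x == 0) stop("x must be a single nonzero mean", call. = FALSE)
    100 * sd / x
  }
}

#' Full method-agreement report
#'
#' Bundles the agreement suite for paired per-bone BMD values: Pearson r,
#' Lin's CCC with bias-correction factor and CI, Bland-Altman bias and limits
#' of agreement with the proportional-bias slope, Deming regression with
#' jackknife CIs, and per-method mean/SD/CV.
#'
#' @param x,y Paired numeric vectors (`x` = method 1, `y` = method 2, one
#'   value per bone), n >= 3.
#' @param lambda Deming error-variance ratio (default 1; the ratio is not
#'   identifiable from the paired values themselves).
#' @param check_normality If TRUE, run Shapiro-Wilk on both vectors and warn
#'   (never stop) when either p < 0.05.
#' @return An `agreement_report` list; see the individual statistics for the
#'   fields. The identities `ccc = r * cb` and `loa_lower + loa_upper =
#'   2 * bias` hold exactly.
#' @export
agreement_report <- function(x, y, lambda = 1, check_normality = FALSE) {
  check_pairs(x, y)
  if (check_normality) {
    for (v in list(M1 = x, M2 = y)) {
      p <- stats::shapiro.test(v)$p.value
      if (p < 0.05)
        warning(sprintf("Shapiro-Wilk p = %.3g: non-normal marginal; agreement statistics reported anyway", p),
                call. = FALSE)
    }
  }
  pr <- pearson_r(x, y)
  cc <- lin_ccc(x, y)
  ba <- bland_altman(x, y)
  dm <- deming(x, y, lambda = lambda)
  per_method <- data.frame(
    method = c("M1", "M2"), n = length(x),
    mean = c(mean(x), mean(y)),
    sd = c(stats::sd(x), stats::sd(y)),
    cv = c(cv_percent(x), cv_percent(y)))
  structure(list(pearson = pr, ccc = cc, bland_altman = ba, deming = dm,
                 per_method = per_method,
                 meta = list(ccc_ci_method = "Fisher z, Lin asymptotic SE",
                             deming_ci_method = "leave-one-out jackknife, t(n-2)",
                             bias_direction = "M2 - M1", lambda = lambda)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Method agreement (M1 vs M2)\n")
  cat(sprintf("  Pearson r        %.*f  (p = %.3g)\n", digits, x$pearson$r, x$pearson$p))
  cat(sprintf("  Lin CCC          %.*f  (95%% CI %.2f-%.2f)\n", digits,
              x$ccc$ccc, x$ccc$ci[1], x$ccc$ci[2]))
  cat(sprintf("  Bias factor Cb   %.*f\n", digits, x$ccc$cb))
  cat(sprintf("  Mean bias (M2-M1) %.1f  [LoA %.1f; %.1f]\n",
              x$bland_altman$bias, x$bland_altman$loa_lower, x$bland_altman$loa_upper))
  cat(sprintf("  BA slope         %.*f  (p = %.3g)\n", digits,
              x$bland_altman$beta, x$bland_altman$beta_p))
  cat(sprintf("  Deming alpha     %.1f  (95%% CI %.1f; %.1f)\n",
              x$deming$alpha, x$deming$alpha_ci[1], x$deming$alpha_ci[2]))
  cat(sprintf("  Deming beta      %.*f  (95%% CI %.2f; %.2f)\n", digits,
              x$deming$beta, x$deming$beta_ci[1], x$deming$beta_ci[2]))
  print(x$per_method, row.names = FALSE, digits = digits + 2)
  invisible(x)
}

#' Descriptive per-method tables
#'
#' Per-method overall and per-region mean, sample SD and CV of per-bone BMD.
#' The region value of a bone is the mean of its three replicates; the overall
#' value is the whole-bone mean across regions. Empty cells are reported as
#' `NA`, never zero.
#'
#' @param bone_summary A bone summary as returned by [summarize_bones()].
#' @return List with data frames `overall` (one row per method) and
#'   `by_region` (method x region).
#' @export
descriptive_table <- function(bone_summary) {
  w <- bone_summary$whole
  r <- bone_summary$regions
  stat_row <- function(v) {
    if (length(v) == 0) return(data.frame(n = 0L, mean = NA_real_,
                                          sd = NA_real_, cv = NA_real_))
    s <- if (length(v) > 1) stats::sd(v) else 0  # single bone: no dispersion
    data.frame(n = length(v), mean = mean(v), sd = s,
               cv = if (mean(v) != 0) 100 * s / mean(v) else NA_real_)
  }
  overall <- do.call(rbind, lapply(split(w$whole_bmd, w$method), stat_row))
  overall <- cbind(method = rownames(overall), overall)
  rownames(overall) <- NULL
  cells <- expand.grid(method = unique(r$method),
                       region = c("proximal", "medial", "distal"),
                       stringsAsFactors = FALSE)
  by_region <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    v <- r$region_bmd[r$method == cells$method[k] & r$region == cells$region[k]]
    cbind(cells[k, ], stat_row(v))
  }))
  rownames(by_region) <- NULL
  list(overall = overall, by_region = by_region)
}

#' Bland-Altman and Deming scatter plots
#'
#' Base-graphics diagnostic plots of an [agreement_report()].
#'
#' @param x,y The paired per-bone values (`x` = M1, `y` = M2).
#' @param report Optional precomputed [agreement_report()].
#' @return Invisibly, the report used.
#' @export
plot_bland_altman <- function(x, y, report = agreement_report(x, y)) {
  d <- y - x; m <- (x + y) / 2
  plot(m, d, xlab = "Mean of methods (mgHA/cm3)",
       ylab = "Difference M2 - M1 (mgHA/cm3)", pch = 19,
       main = "Bland-Altman")
  graphics::abline(h = report$bland_altman$bias, lty = 1)
  graphics::abline(h = c(report$bland_altman$loa_lower,
                         report$bland_altman$loa_upper), lty = 2)
  if (!report$bland_altman$degenerate)
    graphics::abline(stats::lm(d ~ m), col = "grey40")
  invisible(report)
}

#' @rdname plot_bland_altman
#' @export
plot_deming <- function(x, y, report = agreement_report(x, y)) {
  plot(x, y, xlab = "M1 BMD (mgHA/cm3)", ylab = "M2 BMD (mgHA/cm3)",
       pch = 19, main = "Deming regression")
  graphics::abline(report$deming$alpha, report$deming$beta)
  graphics::abline(0, 1, lty = 3)
  invisible(report)
}
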