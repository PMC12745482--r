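test_that("Pearson correlation matches hand computation and edge cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3))$r, 0.6)  # longhand via the definition
  expect_error(pearson_r(x, rep(5, 4)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("Lin's CCC matches its moment formula and decomposition", {
  set.seed(1)
  x <- rnorm(20, 100, 10); y <- 0.8 * x + rnorm(20, 25, 5)
  cc <- lin_ccc(x, y)
  expect_equal(cc$ccc, ccc_moment_oracle(x, y), tolerance = 1e-12)
  expect_equal(cc$ccc, cc$r * cc$cb, tolerance = 1e-12)
  expect_lte(abs(cc$ccc), abs(cc$r))
  expect_gt(cc$cb, 0); expect_lte(cc$cb, 1 + 1e-12)
  expect_true(cc$ci[1] <= cc$ccc && cc$ccc <= cc$ci[2])

  # perfect concordance
  expect_equal(lin_ccc(x, x)$ccc, 1)
  expect_equal(lin_ccc(x, x)$cb, 1)

  # constant offset: closed form 2 s^2 / (2 s^2 + c^2), population s^2
  s2 <- mean((x - mean(x))^2)
  cc2 <- lin_ccc(x, x + 50)
  expect_equal(cc2$ccc, 2 * s2 / (2 * s2 + 50^2), tolerance = 1e-12)
})

test_that("Bland-Altman bias, limits and proportional-bias slope are exact", {
  set.seed(2)
  x <- rnorm(30, 1000, 150)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_lower, 0)
  expect_true(ba0$degenerate)

  ba <- bland_altman(x, x - 458)
  expect_equal(ba$bias, -458)
  expect_equal(ba$loa_lower, -458); expect_equal(ba$loa_upper, -458)
  expect_true(ba$degenerate)  # constant differences: slope flagged

  y <- 0.6 * x + rnorm(30, 300, 40)
  ba2 <- bland_altman(x, y)
  d <- y - x; m <- (x + y) / 2
  expect_equal(ba2$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba2$loa_upper, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba2$loa_lower + ba2$loa_upper, 2 * ba2$bias, tolerance = 1e-9)
  expect_equal(ba2$beta, unname(coef(lm(d ~ m))[2]), tolerance = 1e-12)
  expect_lt(ba2$beta, 0)  # b < 1 implies proportional bias with negative slope

  # the published interval is internally consistent: upper + lower ~ 2 * bias
  expect_lt(abs((-181.1 + -735.0) - 2 * -458.0), 0.2)
})

test_that("Deming slope matches the numerical loss minimizer and invariances", {
  x <- c(1, 2, 3, 4, 5)
  d0 <- deming(x, 2 * x + 1, jackknife = FALSE)
  expect_equal(d0$beta, 2, tolerance = 1e-12)
  expect_equal(d0$alpha, 1, tolerance = 1e-12)

  set.seed(3)
  for (lam in c(0.5, 1, 4)) {
    xx <- rnorm(15, 50, 10); yy <- 1.4 * xx - 20 + rnorm(15, 0, 6)
    est <- deming(xx, yy, lambda = lam, jackknife = FALSE)
    orc <- deming_numeric_oracle(xx, yy, lambda = lam)
    expect_equal(est$beta, orc$beta, tolerance = 1e-6)
    expect_equal(est$alpha, orc$alpha, tolerance = 1e-5)
  }

  # scaling both variables by c > 0 leaves beta, scales alpha
  xx <- rnorm(20, 100, 15); yy <- 0.7 * xx + 30 + rnorm(20, 0, 5)
  e1 <- deming(xx, yy, jackknife = FALSE)
  e2 <- deming(3 * xx, 3 * yy, jackknife = FALSE)
  expect_equal(e2$beta, e1$beta, tolerance = 1e-12)
  expect_equal(e2$alpha, 3 * e1$alpha, tolerance = 1e-9)

  # lambda -> infinity approaches OLS of y on x
  e_inf <- deming(xx, yy, lambda = 1e8, jackknife = FALSE)
  expect_equal(e_inf$beta, unname(coef(lm(yy ~ xx))[2]), tolerance = 1e-6)

  # swapping x and y inverts the slope under lambda = 1
  e_s <- deming(yy, xx, jackknife = FALSE)
  expect_equal(e_s$beta, 1 / e1$beta, tolerance = 1e-12)

  expect_error(deming(xx, yy, lambda = 0), "lambda")
  expect_error(deming(c(1, 2, 3), c(1, 1, 1)), "covariance")
})

test_that("Deming jackknife intervals cover the generating slope", {
  set.seed(4)
  x_true <- rnorm(40, 100, 20)
  x <- x_true + rnorm(40, 0, 5)
  y <- 10 + 0.8 * x_true + rnorm(40, 0, 5)
  dm <- deming(x, y, lambda = 1)
  expect_true(dm$beta_ci[1] < 0.8 && 0.8 < dm$beta_ci[2])
  expect_true(dm$alpha_ci[1] < dm$alpha && dm$alpha < dm$alpha_ci[2])
  expect_gt(dm$beta_se, 0)
})

test_that("coefficient of variation handles vectors and summary moments", {
  expect_equal(round(cv_percent(1152.49, sd = 218.54), 2), 18.96)
  expect_equal(round(cv_percent(711.22, sd = 118.45), 2), 16.65)
  expect_equal(cv_percent(rep(7, 5)), 0)
  v <- c(99, 100, 101)
  expect_equal(cv_percent(v), 100 * sd(v) / mean(v))
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("agreement report satisfies its internal identities", {
  set.seed(5)
  x <- rnorm(48, 1150, 200)
  y <- 115 + 0.5 * x + rnorm(48, 0, 60)
  rep <- agreement_report(x, y)
  expect_equal(rep$ccc$ccc, rep$pearson$r * rep$ccc$cb, tolerance = 1e-12)
  expect_equal(rep$bland_altman$loa_lower + rep$bland_altman$loa_upper,
               2 * rep$bland_altman$bias, tolerance = 1e-9)
  expect_lte(abs(rep$ccc$ccc), abs(rep$pearson$r))
  # qualitative signature of a b < 1 measurement relation with offset:
  # positive correlation, concordance far below it, negative bias and slope
  expect_gt(rep$pearson$r, 0)
  expect_lt(rep$ccc$ccc, rep$pearson$r / 2)
  expect_lt(rep$bland_altman$bias, 0)
  expect_lt(rep$bland_altman$beta, 0)
  expect_output(print(rep), "Deming beta")

  expect_warning(agreement_report(exp(rnorm(20, 0, 2)), rnorm(20, 5, 1),
                                  check_normality = TRUE),
                 "Shapiro")
})

test_that("descriptive tables aggregate by method and region correctly", {
  records <- expand.grid(bone_id = 1:2, method = c("M1", "M2"),
                         region = c("proximal", "medial", "distal"),
                         replicate = 1:3, stringsAsFactors = FALSE)
  records$mean_bmd <- ifelse(records$method == "M1", 900, 700) +
    100 * (records$bone_id - 1.5)  # bones at -50 / +50 around the method mean
  bs <- summarize_bones(records)
  dt <- descriptive_table(bs)
  m1 <- dt$overall[dt$overall$method == "M1", ]
  expect_equal(m1$mean, 900)
  expect_equal(m1$sd, sd(c(850, 950)))  # two bones
  expect_equal(m1$cv, 100 * sd(c(850, 950)) / 900)
  expect_equal(nrow(dt$by_region), 6)
  expect_true(all(dt$by_region$n == 2))

  # single bone with equal replicates: SD and CV are zero
  rec1 <- records[records$bone_id == 1 & records$method == "M1", ]
  bs1 <- summarize_bones(rec1)
  dt1 <- descriptive_table(bs1)
  expect_equal(dt1$overall$sd, 0)
  expect_equal(dt1$overall$cv, 0)
})
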