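test_that("linear fits recover exact lines and match the closed form", {
  x <- c(1, 2, 3, 4)
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # zero covariance: slope 0, R2 0
  xo <- c(-1, 0, 1)
  yo <- c(1, 0, 1)
  fo <- fit_linear(xo, yo)
  expect_equal(fo$slope, 0, tolerance = 1e-12)
  expect_equal(fo$r_squared, 0, tolerance = 1e-12)

  set.seed(12)
  xr <- stats::runif(10)
  yr <- stats::runif(10)
  fr <- fit_linear(xr, yr)
  sxy <- sum((xr - mean(xr)) * (yr - mean(yr)))
  sxx <- sum((xr - mean(xr))^2)
  expect_equal(fr$slope, sxy / sxx, tolerance = 1e-10)
  expect_equal(fr$intercept, mean(yr) - (sxy / sxx) * mean(xr), tolerance = 1e-10)
  expect_error(fit_linear(rep(1, 5), 1:5), "degenerate")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("LOOCV is exact on linear data and matches a hand-worked K = 3 case", {
  x <- seq_len(8)
  r <- loocv_evaluate(x, 3 * x - 2)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$rmse, 0, tolerance = 1e-10)
  expect_equal(r$cv, 0, tolerance = 1e-10)

  # (0,0), (1,1), (2,4): fold-by-fold by hand ->
  #  hold (0,0): fit on (1,1),(2,4): y = 3x - 2, pred -2, residual  2
  #  hold (1,1): fit on (0,0),(2,4): y = 2x,     pred  2, residual -1
  #  hold (2,4): fit on (0,0),(1,1): y = x,      pred  2, residual  2
  r3 <- loocv_evaluate(c(0, 1, 2), c(0, 1, 4))
  expect_equal(r3$folds$residual, c(2, -1, 2), tolerance = 1e-10)
  expect_equal(r3$folds$r2_train, rep(1, 3), tolerance = 1e-10)
  expect_equal(r3$rmse, sqrt((4 + 1 + 4) / 3), tolerance = 1e-10)
  expect_equal(r3$r2, 1, tolerance = 1e-10)
  expect_equal(r3$cv, 100 * sqrt(3) / (5 / 3), tolerance = 1e-10)
  # per-fold CV variant: mean of 100|E_i|/mean(y_train)
  r3b <- loocv_evaluate(c(0, 1, 2), c(0, 1, 4), cv_variant = "per_fold")
  expect_equal(r3b$cv, mean(100 * c(2 / 2.5, 1 / 2, 2 / 0.5)), tolerance = 1e-10)
  expect_error(loocv_evaluate(1:2, 1:2), "at least 3")
})

test_that("LOOCV RMSE tracks the generator noise for the true-driver model", {
  rmses <- vapply(1:12, function(s) {
    tr <- generate_trial(trial_design(seed = s))
    loocv_evaluate(tr$plots$predictor_true, tr$plots$yield_kg_ha)$rmse
  }, numeric(1))
  expect_lt(abs(mean(rmses) - 200) / 200, 0.25)
})

test_that("plot aggregation means layers over ROIs and flags empty plots", {
  sensor <- sensor_quad4()
  vals <- array(0.25, dim = c(6, 6, 4))
  vals[, , 4] <- 0.5
  img <- refl_image(vals, sensor)
  ab <- array(1 / 3, dim = c(6, 6, 3))
  abund <- abundance_image(ab)
  plots <- tibble::tibble(plot_id = "A", row0 = 1L, row1 = 5L, col0 = 1L,
                          col1 = 5L, yield_kg_ha = 2000)
  tab <- plot_aggregate(img, abund, plots, vis = "NDVI")
  expect_equal(tab$blue, 0.25)
  expect_equal(tab$nir1, 0.5)
  expect_equal(tab$abd_lf, 1 / 3, tolerance = 1e-12)
  expect_equal(tab$NDVI, (0.5 - 0.25) / 0.75, tolerance = 1e-12)
  expect_equal(tab$NDVI_x_lf, tab$NDVI / 3, tolerance = 1e-12)

  # ROI of 4 pixels with values 1, 2, 3, 4 -> mean 2.5
  v2 <- array(0.5, dim = c(2, 2, 4))
  v2[, , 4] <- matrix(c(1, 2, 3, 4) / 10, 2, 2)
  tab2 <- plot_aggregate(refl_image(v2, sensor), abundance_image(array(1 / 3, dim = c(2, 2, 3))),
                         tibble::tibble(plot_id = "B", row0 = 0L, row1 = 2L,
                                        col0 = 0L, col1 = 2L, yield_kg_ha = 1),
                         vis = character(0))
  expect_equal(tab2$nir1, 0.25)

  # fully masked ROI is excluded with a warning
  img$mask[] <- FALSE
  expect_warning(out <- plot_aggregate(img, abund, plots, vis = "NDVI"),
                 "no valid pixels")
  expect_equal(nrow(out), 0L)
})

test_that("noise-free plot means match the trial truth", {
  tr <- generate_trial(trial_design(seed = 14))
  E <- build_endmember_matrix(tr$library, tr$sensor)
  sc <- render_scene(tr, snr_db = Inf, jitter_conc = Inf)
  ab <- unmix_image(sc$reflectance, E)
  tab <- plot_aggregate(sc$reflectance, ab, tr$plots, vis = "EVI")
  ord <- match(tab$plot_id, tr$plots$plot_id)
  expect_equal(tab$abd_fl, tr$plots$abd_fl[ord], tolerance = 1e-7)
  expect_equal(tab$abd_lf, tr$plots$abd_lf[ord], tolerance = 1e-7)
  expect_equal(tab$EVI, tr$plots$evi_true[ord], tolerance = 1e-7)
})

test_that("end-to-end noise-free fit recovers the generator betas", {
  tr <- generate_trial(trial_design(seed = 15), yield_noise_sd = 0)
  E <- build_endmember_matrix(tr$library, tr$sensor)
  sc <- render_scene(tr, snr_db = Inf, jitter_conc = Inf)
  ab <- unmix_image(sc$reflectance, E)
  tab <- plot_aggregate(sc$reflectance, ab, tr$plots, vis = "EVI")
  fit <- fit_linear(tab$EVI_x_lf, tab$yield_kg_ha)
  expect_equal(fit$slope, unname(tr$beta["beta1"]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(tr$beta["beta0"]), tolerance = 1e-6)
})

test_that("model ranking orders by R2, marks top models and is order invariant", {
  tr <- generate_trial(trial_design(seed = 16))
  E <- build_endmember_matrix(tr$library, tr$sensor)
  sc <- render_scene(tr)
  ab <- unmix_image(sc$reflectance, E)
  tab <- plot_aggregate(sc$reflectance, ab, tr$plots)
  rk <- rank_models(tab)
  expect_equal(nrow(rk), 27L)
  ok <- !is.na(rk$r2)
  expect_true(all(diff(rk$r2[ok]) <= 1e-12))
  expect_equal(sum(rk$top), 6L)
  expect_true(all(rk$family[rk$top] != "vi_x_fl"))
  # the construction-implied ranking: EVI x Abd_LF beats plain EVI
  expect_gt(rk$r2[rk$vi == "EVI" & rk$family == "vi_x_lf"],
            rk$r2[rk$vi == "EVI" & rk$family == "vi"])

  perm <- sample(nrow(tab))
  rk2 <- rank_models(tab[perm, ])
  expect_equal(tibble::as_tibble(rk2), tibble::as_tibble(rk), tolerance = 1e-12)
})

test_that("degenerate responses are handled without crashing", {
  tab <- tibble::tibble(
    plot_id = sprintf("P%d", 1:6),
    NDVI = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    NDVI_x_fl = c(0.02, 0.04, 0.06, 0.08, 0.10, 0.12),
    NDVI_x_lf = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3),
    yield_kg_ha = rep(2000, 6)
  )
  rk <- rank_models(tab, vis = "NDVI")
  expect_true(all(is.na(rk$r2) | rk$r2 < 1e-9))
})

test_that("cv_report tidiers expose folds and summaries", {
  r <- loocv_evaluate(1:6, c(1.2, 1.9, 3.3, 3.8, 5.1, 6.2), label = "demo")
  expect_equal(nrow(tidy(r)), 6L)
  g <- glance(r)
  expect_named(g, c("label", "r2", "r2_pooled", "rmse", "cv", "slope",
                    "intercept", "n"))
  expect_gte(g$rmse, 0)
  expect_s3_class(autoplot(r), "ggplot")
})
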