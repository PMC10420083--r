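test_that("generated endmember spectra honour the flowering-canopy ordering", {
  for (seed in 1:2) {
    lib <- generate_endmember_library(seed)
    expect_true(all(lib$reflectance >= 0 & lib$reflectance <= 1))
    at <- function(nm, w) lib$reflectance[lib$name == nm & lib$wavelength_nm == w]
    # flowers brighter than leaves in green and red, darker in NIR
    expect_gt(at("FL", 550), at("LF", 550))
    expect_gt(at("FL", 670), at("LF", 670))
    expect_lt(at("FL", 800), at("LF", 800))
    # leaf green peak and red absorption dip
    lf <- lib[lib$name == "LF", ]
    expect_gt(at("LF", 550), at("LF", 490))
    expect_gt(at("LF", 550), at("LF", 610))
    expect_lt(at("LF", 670), at("LF", 610))
    expect_lt(at("LF", 670), at("LF", 700))
    # soil monotonically non-decreasing
    sl <- lib[lib$name == "SL", ]
    expect_false(is.unsorted(sl$reflectance))
  }
  expect_false(identical(generate_endmember_library(1)$reflectance,
                         generate_endmember_library(2)$reflectance))
})

test_that("trial truth follows the nitrogen-response design on the simplex", {
  tr <- generate_trial(trial_design(seed = 11))
  p <- tr$plots
  expect_equal(nrow(p), 24L)
  expect_equal(p$abd_fl + p$abd_lf + p$abd_sl, rep(1, 24), tolerance = 1e-12)
  expect_true(all(p$abd_fl > 0 & p$abd_lf > 0 & p$abd_sl >= 0))
  expect_true(all(p$yield_true > 0))

  # scatter-free construction: leaf abundance peaks at N225 and beyond
  tr0 <- generate_trial(trial_design(seed = 11), fl_sd = 0, lf_sd = 0,
                        yield_noise_sd = 0)
  by_rate <- tapply(tr0$plots$abd_lf, tr0$plots$nitrogen_rate, mean)
  expect_true(all(by_rate["225"] >= by_rate[as.character(c(0, 45, 90, 135, 180))]))
  # yield peaks at N225 too
  y_rate <- tapply(tr0$plots$yield_true, tr0$plots$nitrogen_rate, mean)
  expect_equal(names(which.max(y_rate)), "225")
  expect_equal(unname(range(tr0$plots$yield_true)), c(1000, 3400), tolerance = 1e-6)
})

test_that("noisy yields are unbiased for the true yields", {
  # Monte Carlo over seeds: mean noise within 2 standard errors of zero
  diffs <- unlist(lapply(1:30, function(s) {
    tr <- generate_trial(trial_design(seed = s))
    tr$plots$yield_kg_ha - tr$plots$yield_true
  }))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se)
})

test_that("yield regression on the true driver recovers the betas exactly", {
  tr <- generate_trial(trial_design(seed = 4), yield_noise_sd = 0)
  fit <- stats::lm(yield_kg_ha ~ predictor_true, data = tr$plots)
  expect_equal(unname(stats::coef(fit)), unname(tr$beta), tolerance = 1e-9)
})

test_that("scene rendering implements the forward linear mixing model", {
  tr <- generate_trial(trial_design(seed = 2))
  E <- build_endmember_matrix(tr$library, tr$sensor)
  sc <- render_scene(tr, snr_db = Inf, jitter_conc = Inf)
  # every pixel reflectance equals E %*% abundance exactly
  d <- dim(sc$reflectance$values)
  R <- matrix(sc$reflectance$values, d[1] * d[2], d[3])
  A <- matrix(sc$truth$values, d[1] * d[2], 3)
  expect_equal(R, unname(A %*% t(unclass(E))), tolerance = 1e-12)
  # gutter pixels are pure soil: reflectance equals the soil column
  expect_equal(unname(R[1, ]), unname(unclass(E)[, "SL"]), tolerance = 1e-12)
  # a pure-flower abundance maps to the flower column
  expect_equal(as.numeric(unclass(E) %*% c(1, 0, 0)), unname(unclass(E)[, "FL"]))
  expect_error(render_scene(tr, snr_db = -3), "positive")
})

test_that("per-band noise matches the requested SNR over >= 1e4 pixels", {
  tr <- generate_trial(trial_design(seed = 3, plot_shape = c(21L, 21L)))
  clean <- render_scene(tr, snr_db = Inf, jitter_conc = Inf, seed = 99)
  noisy <- render_scene(tr, snr_db = 40, jitter_conc = Inf, seed = 99)
  d <- dim(clean$reflectance$values)
  expect_gte(d[1] * d[2], 1e4)
  for (b in seq_len(d[3])) {
    sig <- clean$reflectance$values[, , b]
    res <- noisy$reflectance$values[, , b] - sig
    nominal <- sqrt(mean(sig^2)) / 10^(40 / 20)
    expect_lt(abs(stats::sd(res) - nominal) / nominal, 0.10)
  }
})

test_that("DN encoding quantises, clamps and embeds exact panels", {
  tr <- generate_trial(trial_design(seed = 5))
  sc <- render_scene(tr, snr_db = Inf, jitter_conc = Inf)
  dn <- encode_dn(sc$reflectance, gains = 0.006, bias = 0)
  # rho = 0.48 -> DN 80 at gain 0.006
  expect_equal(round(0.48 / 0.006), 80)
  panels <- extract_panels(dn)
  expect_equal(sort(unique(panels$known_reflectance)), c(0.06, 0.24, 0.48))
  expect_equal(panels$mean_dn, panels$known_reflectance / 0.006, tolerance = 1e-12)

  # reflectance below the bias clamps to DN 0
  low <- refl_image(array(0.001, dim = c(2, 16, 1)), sensor_model("one", 550, 10))
  dn_low <- encode_dn(low, gains = 0.006, bias = 0.01, panel_shape = c(2L, 2L))
  expect_equal(unique(as.vector(dn_low$values[1:2, , 1])), 0)

  # round trip: decode with the true gain is exact to half a quantisation step
  dec <- dn$values[seq_len(dim(sc$reflectance$values)[1]), , , drop = FALSE] * 0.006
  expect_lte(max(abs(dec - sc$reflectance$values)), 0.006 / 2 + 1e-12)
  expect_error(encode_dn(sc$reflectance, gains = 0), "nonzero")
})
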