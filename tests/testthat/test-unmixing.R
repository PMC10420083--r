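test_that("FCLS recovers pure pixels and consistent mixtures", {
  E <- fixture_E(1)
  pure <- fcls_pixel(unclass(E)[, "LF"], E)
  expect_equal(unname(pure$abundance), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(pure$residual, 0, tolerance = 1e-10)

  a <- c(0.5, 0.3, 0.2)
  mix <- fcls_pixel(as.numeric(unclass(E) %*% a), E)
  expect_equal(unname(mix$abundance), a, tolerance = 1e-8)
  expect_lte(mix$residual, 1e-10)
  expect_equal(sum(mix$abundance), 1, tolerance = 1e-12)
})

test_that("FCLS output always satisfies the simplex constraints", {
  E <- fixture_E(2)
  set.seed(101)
  for (i in 1:50) {
    rho <- stats::runif(6, 0, 1)
    a <- fcls_pixel(rho, E)$abundance
    expect_true(all(a >= -1e-12))
    expect_equal(sum(a), 1, tolerance = 1e-9)
  }
  expect_error(fcls_pixel(c(NA, rep(0.2, 5)), E), "non-finite")
})

test_that("the grid oracle finds lattice vertices and consistent lattice points", {
  E <- fixture_E(3)
  expect_equal(unname(oracle_fcls(unclass(E)[, "SL"], E, step = 0.5)),
               c(0, 0, 1))
  rho <- as.numeric(unclass(E) %*% c(0.5, 0.5, 0))
  expect_equal(unname(oracle_fcls(rho, E, step = 0.5)), c(0.5, 0.5, 0))
  expect_error(oracle_fcls(rho, E, step = -0.1), "positive")
  expect_error(oracle_fcls(rho, E, step = 0.3), "divide 1")
})

test_that("FCLS matches the exhaustive grid oracle under noise", {
  E <- fixture_E(1)
  a_true <- c(0.5, 0.3, 0.2)
  clean <- as.numeric(unclass(E) %*% a_true)
  set.seed(7)
  noise_sd <- sqrt(mean(clean^2)) / 10^(40 / 20)
  rho <- clean + stats::rnorm(6, 0, noise_sd)
  fc <- fcls_pixel(rho, E)
  orc <- oracle_fcls(rho, E, step = 1e-3)
  expect_lt(max(abs(fc$abundance - orc)), 2e-3)
  # the FCLS objective never exceeds the grid oracle objective beyond the
  # lattice-resolution bound
  obj <- function(a) sum((unclass(E) %*% a - rho)^2)
  snorm <- norm(unclass(E), "2")
  bound <- 2 * snorm * 1e-3 * sqrt(obj(orc)) + (snorm * 1e-3)^2
  expect_lte(obj(fc$abundance), obj(orc) + bound)
})

test_that("rank-deficient endmember matrices warn and still solve", {
  E <- fixture_E(1)
  Edef <- unclass(E)
  Edef[, 3] <- Edef[, 2]  # soil column duplicates leaf
  attr(Edef, "sensor") <- attr(E, "sensor")
  class(Edef) <- class(E)
  expect_warning(out <- fcls_pixel(unclass(E)[, "FL"], Edef), "rank-deficient")
  expect_equal(sum(out$abundance), 1, tolerance = 1e-9)
  expect_equal(unname(out$abundance[1]), 1, tolerance = 1e-2)
})

test_that("permuting endmember columns permutes the abundances identically", {
  E <- fixture_E(4)
  perm <- c(2, 3, 1)
  Ep <- unclass(E)[, perm]
  class(Ep) <- class(E)
  set.seed(5)
  rho <- as.numeric(unclass(E) %*% c(0.2, 0.5, 0.3)) + stats::rnorm(6, 0, 0.002)
  a <- fcls_pixel(rho, E)$abundance
  ap <- fcls_pixel(rho, Ep)$abundance
  expect_equal(unname(ap), unname(a[perm]), tolerance = 1e-8)
})

test_that("six-band and four-band systems agree when extra bands are redundant", {
  E4 <- unclass(fixture_E(1, sensor_quad4()))
  # two extra bands as fixed linear combinations of the first four
  M <- rbind(c(0.2, 0.3, 0.4, 0.1), c(0.1, 0.1, 0.5, 0.3))
  E6 <- rbind(E4, M %*% E4)
  class(E6) <- class(E4) <- c("endmember_matrix", "matrix")
  for (a_true in list(c(0.3, 0.45, 0.25), c(0, 0.6, 0.4), c(1, 0, 0))) {
    rho4 <- as.numeric(E4 %*% a_true)
    rho6 <- c(rho4, as.numeric(M %*% rho4))
    expect_equal(unname(fcls_pixel(rho6, E6)$abundance),
                 unname(fcls_pixel(rho4, E4)$abundance), tolerance = 1e-6)
  }
})

test_that("image unmixing recovers noise-free scenes and masks propagate", {
  tr <- generate_trial(trial_design(seed = 6))
  E <- build_endmember_matrix(tr$library, tr$sensor)
  sc <- render_scene(tr, snr_db = Inf, jitter_conc = 300, seed = 13)
  ab <- unmix_image(sc$reflectance, E)
  expect_lt(max(abs(ab$values - sc$truth$values)), 1e-6)
  sums <- apply(ab$values, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # all-masked image: all-invalid output, no error
  img <- sc$reflectance
  img$mask[] <- FALSE
  ab2 <- unmix_image(img, E)
  expect_true(all(is.na(ab2$values)))

  wrongE <- fixture_E(1, sensor_quad4())
  expect_error(unmix_image(sc$reflectance, wrongE), "band count mismatch")
})

test_that("abundance RMSE at 40 dB stays within 0.02 per endmember", {
  tr <- generate_trial(trial_design(seed = 9, plot_shape = c(14L, 14L)))
  E <- build_endmember_matrix(tr$library, tr$sensor)
  sc <- render_scene(tr, snr_db = 40, jitter_conc = 300, seed = 31)
  ab <- unmix_image(sc$reflectance, E)
  for (k in 1:3) {
    rmse <- sqrt(mean((ab$values[, , k] - sc$truth$values[, , k])^2))
    expect_lte(rmse, 0.02)
  }
})
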