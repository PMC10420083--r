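#' Synthetic flowering-stage rapeseed trial
#'
#' The generator emulates a nitrogen-gradient rapeseed field trial imaged at
#' peak flowering: endmember spectra for flower/leaf/soil, a randomised plot
#' layout, mixed-pixel reflectance scenes under a linear mixing model, raw
#' digital-number (DN) images with embedded calibration panels, and plot
#' yields driven by a leaf-abundance-weighted canopy signal. Every quantity
#' is returned with its ground truth so downstream estimators can be tested
#' for parameter recovery.
#'
#' @name synthetic
NULL

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic endmember spectral library
#'
#' Builds flower (FL), leaf (LF) and soil (SL) reflectance spectra on a 1-nm
#' grid over 400--1000 nm as piecewise-linear curves through seeded anchor
#' points. The curves honour the spectral ordering seen in flowering
#' rapeseed canopies: yellow flowers reflect more than leaves in the green
#' (550 nm) and red (670 nm) but less in the NIR (800 nm); leaves show the
#' classic green peak near 550 nm and chlorophyll absorption minimum near
#' 670 nm; soil is monotonically non-decreasing with wavelength.
#'
#' @param seed Integer seed; different seeds give different curves that all
#'   satisfy the same ordering constraints.
#' @return A long spectral library tibble (`name`, `wavelength_nm`,
#'   `reflectance`).
#' @export
generate_endmember_library <- function(seed = 1L) {
  with_seed(seed, {
    wl <- 400:1000
    jit <- function(x, f = 0.1) x * stats::runif(length(x), 1 - f, 1 + f)
    leaf_x <- c(400, 490, 550, 610, 670, 700, 740, 800, 900, 1000)
    leaf_y <- c(0.04, 0.05, jit(0.13), 0.08, jit(0.045, 0.08), 0.12,
                0.40, jit(0.47, 0.06), 0.48, 0.47)
    flow_x <- c(400, 490, 550, 610, 670, 720, 800, 900, 1000)
    flow_y <- c(0.06, jit(0.09), jit(0.30), 0.38, jit(0.42, 0.06), 0.40,
                jit(0.37, 0.05), 0.36, 0.35)
    soil_x <- c(400, 550, 700, 850, 1000)
    soil_incr <- jit(c(0.05, 0.06, 0.05, 0.04), 0.3)
    soil_y <- cumsum(c(jit(0.10, 0.2), soil_incr))
    pl <- function(x, y) stats::approx(x, y, xout = wl)$y
    lib <- dplyr::bind_rows(
      endmember_spectrum("FL", wl, pmin(pmax(pl(flow_x, flow_y), 0), 1)),
      endmember_spectrum("LF", wl, pmin(pmax(pl(leaf_x, leaf_y), 0), 1)),
      endmember_spectrum("SL", wl, pmin(pmax(pl(soil_x, soil_y), 0), 1))
    )
    at <- function(nm, w) lib$reflectance[lib$name == nm & lib$wavelength_nm == w]
    stopifnot(
      at("FL", 550) > at("LF", 550), at("FL", 670) > at("LF", 670),
      at("FL", 800) < at("LF", 800),
      !is.unsorted(lib$reflectance[lib$name == "SL"])
    )
    lib
  })
}

#' Describe a nitrogen-gradient trial design
#'
#' Defaults mirror a single-season rapeseed fertilisation trial: eight
#' nitrogen rates, three randomised replicates each (24 plots), imaged as a
#' 4 x 6 grid of rectangular plots separated by bare-soil gutters.
#'
#' @param n_rates Nitrogen rates in kg/ha.
#' @param replicates Plots per rate.
#' @param plot_shape `c(rows, cols)` pixel footprint per plot.
#' @param gutter Bare-soil gutter width (pixels) between and around plots.
#' @param seed Integer seed for plot randomisation, abundance scatter and
#'   yield noise.
#' @return A `trial_design` list.
#' @export
trial_design <- function(n_rates = c(0, 45, 90, 135, 180, 225, 270, 360),
                         replicates = 3L, plot_shape = c(8L, 6L),
                         gutter = 2L, seed = 1L) {
  stopifnot(replicates >= 1L, length(plot_shape) == 2L, all(plot_shape >= 3L),
            gutter >= 1L)
  structure(
    list(n_rates = as.numeric(n_rates), replicates = as.integer(replicates),
         plot_shape = as.integer(plot_shape), gutter = as.integer(gutter),
         seed = as.integer(seed)),
    class = "trial_design"
  )
}

# Rectangular grid layout for the plots of a design: 0-based half-open
# footprints and boundary-avoiding ROIs (1-px inset).
scene_layout <- function(design) {
  n_plots <- length(design$n_rates) * design$replicates
  ncol_grid <- max(1L, ceiling(sqrt(n_plots * 1.5)))
  ncol_grid <- min(ncol_grid, n_plots)
  nrow_grid <- ceiling(n_plots / ncol_grid)
  g <- design$gutter
  pr <- design$plot_shape[1L]
  pc <- design$plot_shape[2L]
  idx <- seq_len(n_plots) - 1L
  gr <- idx %/% ncol_grid
  gc <- idx %% ncol_grid
  tibble::tibble(
    foot_row0 = g + gr * (pr + g), foot_row1 = g + gr * (pr + g) + pr,
    foot_col0 = g + gc * (pc + g), foot_col1 = g + gc * (pc + g) + pc,
    row0 = g + gr * (pr + g) + 1L, row1 = g + gr * (pr + g) + pr - 1L,
    col0 = g + gc * (pc + g) + 1L, col1 = g + gc * (pc + g) + pc - 1L
  )
}

scene_dims <- function(design) {
  lay <- scene_layout(design)
  c(max(lay$foot_row1) + design$gutter, max(lay$foot_col1) + design$gutter)
}

# Design curves for plot-mean abundances along the nitrogen gradient:
# saturating leaf response with a slight decline at supra-optimal N
# (lodging/mutual shading), mildly decreasing flower fraction.
abundance_design_curve <- function(n_rate) {
  tibble::tibble(
    abd_lf = 0.2 + 0.5 * pmin(n_rate, 225) / 225 -
      0.04 * pmax(n_rate - 225, 0) / 135,
    abd_fl = 0.22 - 0.04 * n_rate / 360
  )
}

#' Generate trial ground truth: plot abundances and yields
#'
#' Plot-mean leaf abundance follows a saturating curve rising from 0.2 at
#' 0 kg/ha N to 0.7 at 225 kg/ha, near-flat beyond with a slight decline
#' (0.66 at 360 kg/ha) reflecting lodging and mutual shading under
#' over-fertilisation; flower abundance stays
#' near 0.2 with a mild decreasing trend; soil takes the simplex remainder.
#' Per-plot Gaussian scatter (truncated so the simplex is respected) makes
#' replicates differ, notably in flower fraction. True yield is linear in
#' the product of the plot's true-spectrum enhanced vegetation index and its
#' leaf abundance, `yield = beta0 + beta1 * (EVI_true x Abd_LF)`, with the
#' intercept/slope solved so the scatter-free design curve spans
#' `yield_range[1]` at N0 to `yield_range[2]` at N225 (yield therefore peaks
#' at N225 and declines slightly after). Observed yield adds zero-mean
#' Gaussian noise.
#'
#' @param design A [trial_design()].
#' @param library Endmember library; default [generate_endmember_library()]
#'   with the design's seed.
#' @param sensor Sensor used to evaluate the true canopy spectrum.
#' @param fl_sd,lf_sd Per-plot scatter (s.d.) of flower and leaf abundance.
#' @param yield_noise_sd Yield measurement noise s.d. (kg/ha).
#' @param yield_range `c(low, high)` kg/ha for the design curve at N0/N225.
#' @return A `truth_bundle` list: `plots` tibble (layout, truth and noisy
#'   yields), `beta` (intercept, slope), plus the design, library and sensor.
#' @export
generate_trial <- function(design = trial_design(),
                           library = generate_endmember_library(design$seed),
                           sensor = sensor_uav6(),
                           fl_sd = 0.03, lf_sd = 0.04,
                           yield_noise_sd = 200, yield_range = c(1000, 3400)) {
  E <- build_endmember_matrix(library, sensor)
  curve <- abundance_design_curve(design$n_rates)
  if (any(1 - curve$abd_fl - curve$abd_lf < 0)) {
    stop("design nitrogen rates give negative soil abundance", call. = FALSE)
  }
  # betas from the scatter-free design curve at N0 and N225
  pr_at <- function(fl, lf) {
    a <- c(fl, lf, 1 - fl - lf)
    evi_from_bands(E %*% a, sensor) * lf
  }
  c0 <- abundance_design_curve(0)
  c225 <- abundance_design_curve(225)
  p0 <- pr_at(c0$abd_fl, c0$abd_lf)
  p225 <- pr_at(c225$abd_fl, c225$abd_lf)
  beta1 <- diff(yield_range) / (p225 - p0)
  beta0 <- yield_range[1L] - beta1 * p0
  n_plots <- length(design$n_rates) * design$replicates
  with_seed(design$seed, {
    plots <- tibble::tibble(
      plot_id = sprintf("P%02d", seq_len(n_plots)),
      nitrogen_rate = rep(design$n_rates, each = design$replicates),
      replicate = rep(seq_len(design$replicates), times = length(design$n_rates))
    )
    # randomised field layout: plots shuffled over grid positions
    pos <- sample.int(n_plots)
    plots <- dplyr::bind_cols(plots, scene_layout(design)[pos, ])
    cc <- abundance_design_curve(plots$nitrogen_rate)
    trunc_norm <- function(n, sd) pmax(pmin(stats::rnorm(n, 0, sd), 2.5 * sd), -2.5 * sd)
    fl <- pmax(cc$abd_fl + trunc_norm(n_plots, fl_sd), 0.02)
    lf <- pmax(cc$abd_lf + trunc_norm(n_plots, lf_sd), 0.02)
    over <- fl + lf > 0.97
    scale <- ifelse(over, 0.97 / (fl + lf), 1)
    plots$abd_fl <- fl * scale
    plots$abd_lf <- lf * scale
    plots$abd_sl <- 1 - plots$abd_fl - plots$abd_lf
    A <- rbind(plots$abd_fl, plots$abd_lf, plots$abd_sl)
    plots$evi_true <- evi_from_bands(E %*% A, sensor)
    plots$predictor_true <- plots$evi_true * plots$abd_lf
    plots$yield_true <- beta0 + beta1 * plots$predictor_true
    plots$yield_kg_ha <- plots$yield_true +
      stats::rnorm(n_plots, 0, yield_noise_sd)
    structure(
      list(plots = plots, beta = c(beta0 = beta0, beta1 = beta1),
           design = design, library = library, sensor = sensor,
           yield_noise_sd = yield_noise_sd),
      class = "truth_bundle"
    )
  })
}

# EVI evaluated on a B x P matrix of band reflectances via sensor roles.
evi_from_bands <- function(R, sensor) {
  R <- as.matrix(R)
  i <- function(role) match(role, sensor$role)
  b <- R[i("blue"), ]; r <- R[i("red"), ]; n <- R[i("nir1"), ]
  as.numeric(2.5 * (n - r) / (n + 6 * r - 7.5 * b + 1))
}

#' Render a mixed-pixel reflectance scene
#'
#' Forward linear mixing model: each pixel's reflectance is the endmember
#' matrix times its abundance vector. Pixel abundances are the plot means
#' perturbed by Dirichlet jitter (concentration `jitter_conc * mean`), which
#' stays on the simplex by construction; gutter pixels are pure soil.
#' Per-band Gaussian noise is scaled so the band's signal-to-noise ratio
#' equals `snr_db` (RMS signal over noise s.d.); the result is clipped to
#' `[0, 1]` with the clipped fraction recorded in `meta$clip_fraction`.
#'
#' @param trial A `truth_bundle` from [generate_trial()].
#' @param library,sensor Override the bundle's library/sensor.
#' @param snr_db Per-band SNR in decibels; `Inf` disables noise.
#' @param jitter_conc Dirichlet concentration; `Inf` disables jitter.
#' @param seed Seed for jitter and noise (default: the design seed + 1).
#' @return List with `reflectance` ([refl_image]) and `truth`
#'   ([abundance_image]).
#' @export
render_scene <- function(trial, library = trial$library, sensor = trial$sensor,
                         snr_db = 40, jitter_conc = 300,
                         seed = trial$design$seed + 1L) {
  if (!is.infinite(snr_db) && snr_db <= 0) {
    stop("`snr_db` must be positive", call. = FALSE)
  }
  E <- build_endmember_matrix(library, sensor)
  d <- scene_dims(trial$design)
  H <- d[1L]; W <- d[2L]; B <- nrow(E)
  # start everything as pure soil, then fill plot footprints
  A <- matrix(rep(c(0, 0, 1), each = H * W), H * W, 3L)
  plot_of <- matrix(NA_integer_, H, W)
  for (p in seq_len(nrow(trial$plots))) {
    pr <- trial$plots[p, ]
    rows <- (pr$foot_row0 + 1L):pr$foot_row1
    cols <- (pr$foot_col0 + 1L):pr$foot_col1
    plot_of[rows, cols] <- p
  }
  with_seed(seed, {
    inplot <- which(!is.na(plot_of))
    means <- cbind(trial$plots$abd_fl, trial$plots$abd_lf, trial$plots$abd_sl)
    if (is.infinite(jitter_conc)) {
      A[inplot, ] <- means[plot_of[inplot], ]
    } else {
      alpha <- jitter_conc * means[plot_of[inplot], ]
      g <- matrix(stats::rgamma(length(inplot) * 3L, shape = alpha), ncol = 3L)
      A[inplot, ] <- g / rowSums(g)
    }
    R <- A %*% t(unclass(E))  # pixels x bands
    clip_n <- 0L
    if (!is.infinite(snr_db)) {
      sig_rms <- sqrt(colMeans(R^2))
      noise_sd <- sig_rms / 10^(snr_db / 20)
      R <- R + matrix(stats::rnorm(length(R)), nrow(R), B) %*% diag(noise_sd, B)
      clip_n <- sum(R < 0 | R > 1)
      R <- pmin(pmax(R, 0), 1)
    }
    refl <- refl_image(array(R, dim = c(H, W, B)), sensor,
                       meta = list(seed = seed, snr_db = snr_db,
                                   jitter_conc = jitter_conc,
                                   clip_fraction = clip_n / length(R)))
    truth <- abundance_image(array(A, dim = c(H, W, 3L)),
                             residual = matrix(0, H, W),
                             meta = list(seed = seed))
    list(reflectance = refl, truth = truth)
  })
}

#' Encode a reflectance image to raw digital numbers with calibration panels
#'
#' Inverse of the empirical-line calibration: `DN = round((rho - bias)/gain)`
#' clamped to `[0, 2^bit_depth - 1]` per band. A panel strip is appended
#' below the scene containing three uniform calibration targets of known
#' reflectance (defaults 0.06/0.24/0.48); their 0-based half-open pixel
#' rectangles are recorded in `meta$panels`.
#'
#' The default per-band gains are exact divisors of the panel reflectances
#' (0.004/0.005 reflectance per count, bias 0), matching calibration targets
#' that are factory-matched to the camera's radiometric range.
#'
#' @param image A [refl_image].
#' @param gains Per-band gain (reflectance per DN count); recycled.
#' @param bias Per-band bias (reflectance offset); recycled.
#' @param bit_depth 8, 10, 12 or 16 (default 8).
#' @param panel_reflectance Reflectances of the embedded panels.
#' @param panel_shape `c(rows, cols)` pixel size of each panel.
#' @return A [dn_image] with `meta$gains`, `meta$bias`, `meta$panels` and
#'   `meta$scene_rows` (rows belonging to the original scene).
#' @export
encode_dn <- function(image, gains = NULL, bias = 0, bit_depth = 8L,
                      panel_reflectance = c(0.06, 0.24, 0.48),
                      panel_shape = c(4L, 4L)) {
  d <- dim(image$values)
  B <- d[3L]
  if (is.null(gains)) gains <- rep(c(0.004, 0.005), length.out = B)
  gains <- rep_len(as.numeric(gains), B)
  bias <- rep_len(as.numeric(bias), B)
  if (any(gains == 0)) stop("`gains` must be nonzero", call. = FALSE)
  if (any(gains < 0)) warning("negative gain supplied")
  bit_depth <- as.integer(bit_depth)
  stopifnot(bit_depth %in% c(8L, 10L, 12L, 16L))
  dn_max <- 2^bit_depth - 1
  strip_h <- panel_shape[1L] + 2L
  H <- d[1L] + strip_h
  vals <- array(0, dim = c(H, d[2L], B))
  refl <- array(0, dim = c(strip_h, d[2L], B))  # panel strip reflectance, 0 background
  panels <- vector("list", length(panel_reflectance))
  for (k in seq_along(panel_reflectance)) {
    c0 <- 1L + (k - 1L) * (panel_shape[2L] + 1L)
    c1 <- c0 + panel_shape[2L]
    if (c1 > d[2L]) stop("image too narrow to host the calibration panels", call. = FALSE)
    refl[2:(1L + panel_shape[1L]), (c0 + 1L):c1, ] <- panel_reflectance[k]
    panels[[k]] <- list(reflectance = panel_reflectance[k],
                        row0 = d[1L] + 1L, row1 = d[1L] + 1L + panel_shape[1L],
                        col0 = c0, col1 = c1)
  }
  for (b in seq_len(B)) {
    full <- rbind(image$values[, , b], refl[, , b])
    vals[, , b] <- pmin(pmax(round((full - bias[b]) / gains[b]), 0), dn_max)
  }
  dn_image(vals, image$sensor, bit_depth = bit_depth,
           mask = rbind(image$mask, matrix(TRUE, strip_h, d[2L])),
           meta = c(image$meta, list(gains = gains, bias = bias,
                                     panels = panels, scene_rows = d[1L])))
}

#' Drop the calibration-panel strip from an image
#'
#' @param image An image whose metadata records `scene_rows` (see
#'   [encode_dn()]).
#' @return The image cropped back to the original scene rows.
#' @export
drop_panel_strip <- function(image) {
  sr <- image$meta$scene_rows
  if (is.null(sr)) return(image)
  image$values <- image$values[seq_len(sr), , , drop = FALSE]
  image$mask <- image$mask[seq_len(sr), , drop = FALSE]
  if (!is.null(image$residual)) image$residual <- image$residual[seq_len(sr), , drop = FALSE]
  image$meta$scene_rows <- NULL
  image$meta$panels <- NULL
  image
}

#' Plot abundance and yield trends along the nitrogen gradient
#'
#' @param plots The `plots` tibble of a `truth_bundle` (or any tibble with
#'   `nitrogen_rate`, `abd_fl`, `abd_lf`, `abd_sl`, `yield_kg_ha`).
#' @return A ggplot faceted over the three abundances and yield.
#' @export
plot_nitrogen_response <- function(plots) {
  long <- tidyr::pivot_longer(
    plots[, c("nitrogen_rate", "abd_fl", "abd_lf", "abd_sl", "yield_kg_ha")],
    -"nitrogen_rate", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$nitrogen_rate, .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "nitrogen rate (kg/ha)", y = NULL) +
    ggplot2::theme_minimal()
}
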