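# Shared fixtures, all built in code.

# Three constant spectra covering 350--2500 nm.
constant_library <- function(fl = 0.1, lf = 0.5, sl = 0.9) {
  wl <- seq(350, 2500, by = 5)
  dplyr::bind_rows(
    endmember_spectrum("FL", wl, rep(fl, length(wl))),
    endmember_spectrum("LF", wl, rep(lf, length(wl))),
    endmember_spectrum("SL", wl, rep(sl, length(wl)))
  )
}

# A well-conditioned 6 x 3 endmember matrix from the seeded generator.
fixture_E <- function(seed = 1, sensor = sensor_uav6()) {
  build_endmember_matrix(generate_endmember_library(seed), sensor)
}

# Tiny reflectance image holding the given pixel spectra (one per column).
image_from_pixels <- function(px, sensor) {
  H <- 1L
  W <- ncol(px)
  refl_image(array(t(px), dim = c(H, W, nrow(px))), sensor)
}
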