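#' Create an endmember spectrum
#'
#' An endmember spectrum is a fine-grained reflectance curve for one pure
#' scene component (flower `"FL"`, leaf `"LF"`, soil `"SL"`, or any free-text
#' label), stored as a tidy tibble with one row per wavelength.
#'
#' @param name Single string naming the endmember.
#' @param wavelength_nm Numeric vector of wavelengths in nanometres, strictly
#'   increasing.
#' @param reflectance Numeric vector of unitless reflectances in `[0, 1]`,
#'   same length as `wavelength_nm`.
#'
#' @return A tibble with columns `name`, `wavelength_nm`, `reflectance`.
#' @examples
#' sp <- endmember_spectrum("LF", 400:1000, rep(0.3, 601))
#' @export
endmember_spectrum <- function(name, wavelength_nm, reflectance) {
  stopifnot(is.character(name), length(name) == 1L)
  wavelength_nm <- as.numeric(wavelength_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelength_nm) != length(reflectance)) {
    stop("`wavelength_nm` and `reflectance` must have the same length", call. = FALSE)
  }
  if (length(wavelength_nm) < 2L) {
    stop("a spectrum needs at least two wavelengths", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("`wavelength_nm` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(reflectance)) || any(reflectance < 0) || any(reflectance > 1)) {
    stop("`reflectance` must be finite and within [0, 1]", call. = FALSE)
  }
  tibble::tibble(name = name, wavelength_nm = wavelength_nm, reflectance = reflectance)
}

#' Define a multispectral sensor band set
#'
#' A sensor model is an ordered set of spectral bands, each a boxcar response
#' of a given centre and full width at half maximum (FWHM), with optional
#' semantic roles (`"blue"`, `"green"`, `"red"`, `"red-edge"`, `"nir1"`,
#' `"nir2"`) used to resolve vegetation-index formulas.
#'
#' @param name Single string naming the sensor.
#' @param center_nm Numeric vector of band centres (nm), in declared band
#'   order (not required to be increasing).
#' @param fwhm_nm Numeric vector of band FWHMs (nm), recycled if length 1.
#' @param role Character vector of band roles (`NA` for none); each role may
#'   be used at most once.
#'
#' @return An object of class `sensor_model`: a tibble with columns `band`,
#'   `center_nm`, `fwhm_nm`, `role` and a `sensor_name` attribute.
#' @seealso [sensor_uav6()], [sensor_quad4()]
#' @export
sensor_model <- function(name, center_nm, fwhm_nm, role = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  center_nm <- as.numeric(center_nm)
  fwhm_nm <- rep_len(as.numeric(fwhm_nm), length(center_nm))
  role <- rep_len(as.character(role), length(center_nm))
  if (any(!is.finite(center_nm)) || any(!is.finite(fwhm_nm)) || any(fwhm_nm <= 0)) {
    stop("band centres must be finite and FWHMs positive", call. = FALSE)
  }
  dup <- role[!is.na(role)][duplicated(role[!is.na(role)])]
  if (length(dup) > 0L) {
    stop("each band role may map to at most one band: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    band = seq_along(center_nm),
    center_nm = center_nm,
    fwhm_nm = fwhm_nm,
    role = role
  )
  attr(out, "sensor_name") <- name
  class(out) <- c("sensor_model", class(out))
  out
}

#' Six-band UAV camera preset
#'
#' Band set of a six-camera UAV multispectral array: 490\@10 (blue), 550\@10
#' (green), 670\@10 (red), 720\@10 (red edge), 800\@10 (NIR1) and 900\@20 nm
#' (NIR2), centre\@FWHM.
#'
#' @return A [sensor_model()].
#' @export
sensor_uav6 <- function() {
  sensor_model(
    "UAV6",
    center_nm = c(490, 550, 670, 720, 800, 900),
    fwhm_nm = c(10, 10, 10, 10, 10, 20),
    role = c("blue", "green", "red", "red-edge", "nir1", "nir2")
  )
}

#' Generic four-band satellite preset
#'
#' Blue/green/red/NIR band set standing in for wide-field-view satellite
#' sensors; centres mirror the UAV roles (490/550/670/800 nm, FWHM 10 nm) so
#' synthetic satellite scenes can reuse the same endmember spectra.
#'
#' @return A [sensor_model()].
#' @export
sensor_quad4 <- function() {
  sensor_model(
    "QUAD4",
    center_nm = c(490, 550, 670, 800),
    fwhm_nm = 10,
    role = c("blue", "green", "red", "nir1")
  )
}

#' Resample a fine-grained spectrum to sensor bands
#'
#' Each band is a boxcar (uniform) response over
#' `[center - fwhm/2, center + fwhm/2]`; the band value is the mean
#' reflectance over that support, integrated by the trapezoid rule on the
#' spectrum's native wavelength grid (with linearly interpolated endpoints).
#'
#' @param spectrum A spectrum tibble from [endmember_spectrum()] (or any
#'   tibble with `wavelength_nm` and `reflectance` for a single endmember).
#' @param sensor A [sensor_model()].
#'
#' @return A tibble with one row per band: `band`, `center_nm`, `role`,
#'   `reflectance`.
#' @examples
#' sp <- endmember_spectrum("LF", 350:2500, pmin(1, 0.001 * (350:2500 - 350)))
#' resample_to_bands(sp, sensor_uav6())
#' @export
resample_to_bands <- function(spectrum, sensor) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (length(unique(spectrum$name)) > 1L) {
    stop("`spectrum` must contain a single endmember; see build_endmember_matrix()",
         call. = FALSE)
  }
  vals <- band_boxcar_means(spectrum$wavelength_nm, spectrum$reflectance, sensor)
  tibble::tibble(
    band = sensor$band,
    center_nm = sensor$center_nm,
    role = sensor$role,
    reflectance = vals
  )
}

# Trapezoid-rule boxcar mean of (wl, y) over each band support of `sensor`.
band_boxcar_means <- function(wl, y, sensor) {
  vapply(seq_len(nrow(sensor)), function(i) {
    lo <- sensor$center_nm[i] - sensor$fwhm_nm[i] / 2
    hi <- sensor$center_nm[i] + sensor$fwhm_nm[i] / 2
    if (lo < wl[1L] || hi > wl[length(wl)]) {
      stop(sprintf(
        "band %d (%g@%g nm) support [%g, %g] not covered by spectrum range [%g, %g]",
        sensor$band[i], sensor$center_nm[i], sensor$fwhm_nm[i], lo, hi,
        wl[1L], wl[length(wl)]
      ), call. = FALSE)
    }
    inside <- wl > lo & wl < hi
    xs <- c(lo, wl[inside], hi)
    ys <- c(
      stats::approx(wl, y, xout = lo)$y,
      y[inside],
      stats::approx(wl, y, xout = hi)$y
    )
    sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2) / (hi - lo)
  }, numeric(1L))
}

#' Build the endmember matrix for a sensor
#'
#' Stacks the band-resampled reflectances of the flower (`FL`), leaf (`LF`)
#' and soil (`SL`) endmembers into the B x 3 mixing matrix used by linear
#' spectral unmixing; rows follow sensor band order, columns are normalised
#' to the fixed order (FL, LF, SL) regardless of the order given.
#'
#' @param library A spectral library: one tibble with columns `name`,
#'   `wavelength_nm`, `reflectance` containing exactly the endmembers
#'   `FL`, `LF` and `SL` (e.g. from [generate_endmember_library()]), or a
#'   list of single-endmember spectra.
#' @param sensor A [sensor_model()].
#'
#' @return An `endmember_matrix`: a numeric B x 3 matrix with column names
#'   `c("FL", "LF", "SL")`, row names the band centres, and the sensor
#'   attached as attribute `"sensor"`.
#' @export
build_endmember_matrix <- function(library, sensor) {
  if (is.data.frame(library)) {
    library <- split(library, library$name)
  }
  names(library) <- vapply(library, function(s) s$name[1L], character(1L))
  wanted <- c("FL", "LF", "SL")
  if (anyDuplicated(names(library)) || !setequal(names(library), wanted)) {
    stop("`library` must contain exactly the endmembers FL, LF and SL (got: ",
         paste(names(library), collapse = ", "), ")", call. = FALSE)
  }
  cols <- lapply(wanted, function(nm) resample_to_bands(library[[nm]], sensor)$reflectance)
  E <- do.call(cbind, cols)
  dimnames(E) <- list(paste0("b", sensor$center_nm), wanted)
  attr(E, "sensor") <- sensor
  class(E) <- c("endmember_matrix", class(E))
  E
}

#' Read / write an endmember library CSV
#'
#' The canonical (wide) layout has columns `wavelength_nm, FL, LF, SL`; a
#' long layout with columns `name, wavelength_nm, reflectance` is also
#' accepted on read.
#'
#' @param path Path to a CSV file.
#' @return `read_endmember_library()` returns a long spectral library tibble;
#'   `write_endmember_library()` invisibly returns `path`.
#' @export
read_endmember_library <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("name", "wavelength_nm", "reflectance") %in% names(df))) {
    lib <- tibble::as_tibble(df[, c("name", "wavelength_nm", "reflectance")])
  } else if ("wavelength_nm" %in% names(df)) {
    lib <- tidyr::pivot_longer(
      tibble::as_tibble(df), -"wavelength_nm",
      names_to = "name", values_to = "reflectance"
    )
    lib <- dplyr::arrange(lib[, c("name", "wavelength_nm", "reflectance")],
                          .data$name, .data$wavelength_nm)
  } else {
    stop("endmember CSV needs a `wavelength_nm` column", call. = FALSE)
  }
  # validate each member through the constructor
  dplyr::bind_rows(lapply(split(lib, lib$name), function(s) {
    endmember_spectrum(s$name[1L], s$wavelength_nm, s$reflectance)
  }))
}

#' @rdname read_endmember_library
#' @param library A long spectral library tibble.
#' @export
write_endmember_library <- function(library, path) {
  wide <- tidyr::pivot_wider(library, names_from = "name", values_from = "reflectance")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a sensor model as JSON
#'
#' Layout: `{"name": ..., "bands": [{"center": ..., "fwhm": ..., "role": ...}, ...]}`.
#'
#' @param path Path to a JSON file.
#' @return `read_sensor_json()` returns a [sensor_model()];
#'   `write_sensor_json()` invisibly returns `path`.
#' @export
read_sensor_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  role <- j$bands$role
  if (is.null(role)) role <- NA_character_
  sensor_model(j$name, j$bands$center, j$bands$fwhm, role)
}

#' @rdname read_sensor_json
#' @param sensor A [sensor_model()].
#' @export
write_sensor_json <- function(sensor, path) {
  jsonlite::write_json(
    list(
      name = attr(sensor, "sensor_name"),
      bands = data.frame(center = sensor$center_nm, fwhm = sensor$fwhm_nm,
                         role = sensor$role)
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Plot a spectral library
#'
#' @param object A long spectral library tibble (columns `name`,
#'   `wavelength_nm`, `reflectance`).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
plot_spectra <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm, .data$reflectance,
                                       colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance", colour = "endmember") +
    ggplot2::theme_minimal()
}
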