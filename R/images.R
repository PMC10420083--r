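#' Multiband image containers
#'
#' Lightweight S3 containers for co-registered multiband rasters: surface
#' reflectance (`refl_image`), raw digital numbers (`dn_image`) and per-pixel
#' endmember fractions (`abundance_image`). Pixel values live in an
#' `H x W x B` numeric array; `mask` is an `H x W` logical matrix of valid
#' pixels; `meta` carries provenance (sensor, seed, gains, panel coordinates,
#' clip counters).
#'
#' @param values Numeric `H x W x B` array (a matrix is promoted to `B = 1`).
#' @param sensor A [sensor_model()] with one row per band, or `NULL`.
#' @param mask Logical `H x W` matrix, `TRUE` = valid; defaults to all valid.
#' @param meta Named list of metadata.
#'
#' @return An object of class `refl_image`, `dn_image` or `abundance_image`
#'   (all inheriting from `cm_image`).
#' @name cm_image
NULL

new_cm_image <- function(values, class, sensor = NULL, mask = NULL, meta = list()) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!is.null(sensor) && nrow(sensor) != dim(values)[3L]) {
    stop("band count mismatch: image has ", dim(values)[3L], " bands, sensor declares ",
         nrow(sensor), call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, dim(values)[1L], dim(values)[2L])
  stopifnot(identical(dim(mask), dim(values)[1:2]))
  structure(
    list(values = values, sensor = sensor, mask = mask, meta = meta),
    class = c(class, "cm_image")
  )
}

#' @rdname cm_image
#' @export
refl_image <- function(values, sensor = NULL, mask = NULL, meta = list()) {
  new_cm_image(values, "refl_image", sensor, mask, meta)
}

#' @rdname cm_image
#' @param bit_depth Integer bit depth of the DN payload (8, 10, 12 or 16).
#' @export
dn_image <- function(values, sensor = NULL, bit_depth = 8L, mask = NULL, meta = list()) {
  stopifnot(bit_depth %in% c(8L, 10L, 12L, 16L))
  if (any(values != round(values), na.rm = TRUE)) {
    stop("DN values must be integers", call. = FALSE)
  }
  meta$bit_depth <- as.integer(bit_depth)
  new_cm_image(values, "dn_image", sensor, mask, meta)
}

#' @rdname cm_image
#' @param residual `H x W` matrix of per-pixel reconstruction RMSE
#'   (reflectance units).
#' @export
abundance_image <- function(values, residual = NULL, mask = NULL, meta = list()) {
  stopifnot(dim(values)[3L] == 3L)
  if (is.null(residual)) residual <- matrix(NA_real_, dim(values)[1L], dim(values)[2L])
  img <- new_cm_image(values, "abundance_image", NULL, mask, meta)
  img$residual <- residual
  img
}

#' @export
print.cm_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d pixels, %d band(s), %d valid\n",
              class(x)[1L], d[1L], d[2L], d[3L], sum(x$mask)))
  invisible(x)
}

#' @export
dim.cm_image <- function(x) dim(x$values)

#' Convert an image to a tidy pixel table
#'
#' One row per pixel, 0-based `row`/`col` coordinates, one column per band
#' (named after the band role when available, else `b<center>` or `V<k>`).
#'
#' @param x A [cm_image] object.
#' @param ... Ignored.
#' @return A tibble.
#' @export
as_tibble.cm_image <- function(x, ...) {
  d <- dim(x$values)
  nm <- band_labels(x)
  flat <- matrix(x$values, d[1L] * d[2L], d[3L])
  colnames(flat) <- nm
  out <- tibble::tibble(
    row = rep(seq_len(d[1L]) - 1L, times = d[2L]),
    col = rep(seq_len(d[2L]) - 1L, each = d[1L]),
    valid = as.vector(x$mask)
  )
  dplyr::bind_cols(out, tibble::as_tibble(flat))
}

band_labels <- function(x) {
  d3 <- dim(x$values)[3L]
  if (inherits(x, "abundance_image")) return(c("abd_fl", "abd_lf", "abd_sl"))
  if (inherits(x, "vi_image") && !is.null(x$meta$vi)) return(x$meta$vi)
  if (!is.null(x$sensor)) {
    ifelse(is.na(x$sensor$role), paste0("b", x$sensor$center_nm), x$sensor$role)
  } else if (!is.null(dimnames(x$values)[[3L]])) {
    dimnames(x$values)[[3L]]
  } else {
    paste0("V", seq_len(d3))
  }
}

# Pixel values of valid pixels as a P x B matrix (column-major pixel order).
valid_pixel_matrix <- function(image) {
  d <- dim(image$values)
  flat <- matrix(image$values, d[1L] * d[2L], d[3L])
  flat[as.vector(image$mask), , drop = FALSE]
}
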