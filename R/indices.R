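#' The vegetation-index suite
#'
#' Nine indices commonly used for flowering-stage canopy assessment, all
#' algebraic combinations of the blue (490 nm), green (550 nm), red
#' (670 nm) and NIR (800 nm) bands:
#'
#' * `NDVI  = (nir - red) / (nir + red)`
#' * `CIgreen = nir / green - 1`
#' * `VARI  = (green - red) / (green + red)`
#' * `RVI   = nir / red`
#' * `DVI   = nir - red`
#' * `RDVI  = (nir - red) / sqrt(nir + red)`
#' * `EVI   = 2.5 (nir - red) / (nir + 6 red - 7.5 blue + 1)`
#' * `TVI   = 0.5 [120 (nir - green) - 200 (red - green)]`
#' * `NDYI  = (green - blue) / (green + blue)` (yellowness; tracks flower
#'   cover)
#'
#' `RDVI` is the renormalised difference index; a legacy variant identical
#' to NDVI circulates in some tabulations and is available via
#' `rdvi_variant = "ndvi"`.
#'
#' @return `vi_names()` returns the nine index names in canonical order;
#'   `vi_required_roles()` the band roles an index needs.
#' @name vegetation_indices
NULL

#' @rdname vegetation_indices
#' @export
vi_names <- function() {
  c("NDVI", "CIgreen", "VARI", "RVI", "DVI", "RDVI", "EVI", "TVI", "NDYI")
}

#' @rdname vegetation_indices
#' @param vi Index name.
#' @export
vi_required_roles <- function(vi) {
  switch(match.arg(vi, vi_names()),
    NDVI = c("red", "nir1"),
    CIgreen = c("green", "nir1"),
    VARI = c("green", "red"),
    RVI = c("red", "nir1"),
    DVI = c("red", "nir1"),
    RDVI = c("red", "nir1"),
    EVI = c("blue", "red", "nir1"),
    TVI = c("green", "red", "nir1"),
    NDYI = c("blue", "green")
  )
}

# Vectorised index arithmetic on role-named reflectances. Zero denominators
# give NA (invalid pixel), never Inf.
vi_eval <- function(vi, blue = NULL, green = NULL, red = NULL, nir1 = NULL,
                    rdvi_variant = c("sqrt", "ndvi")) {
  rdvi_variant <- match.arg(rdvi_variant)
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  switch(match.arg(vi, vi_names()),
    NDVI = safe_div(nir1 - red, nir1 + red),
    CIgreen = safe_div(nir1, green) - 1,
    VARI = safe_div(green - red, green + red),
    RVI = safe_div(nir1, red),
    DVI = nir1 - red,
    RDVI = if (rdvi_variant == "sqrt") {
      ifelse(nir1 + red <= 0, NA_real_, (nir1 - red) / sqrt(nir1 + red))
    } else {
      safe_div(nir1 - red, nir1 + red)
    },
    EVI = safe_div(2.5 * (nir1 - red), nir1 + 6 * red - 7.5 * blue + 1),
    TVI = 0.5 * (120 * (nir1 - green) - 200 * (red - green)),
    NDYI = safe_div(green - blue, green + blue)
  )
}

#' Compute a vegetation index image
#'
#' Resolves the index's required band roles through the image's sensor
#' model and evaluates the formula per pixel. Pixels with a zero
#' denominator become invalid (`NA`, masked out) and are counted in
#' `meta$n_zero_denominator`.
#'
#' @param image A [refl_image] with a sensor carrying band roles.
#' @param vi Index name (see [vi_names()]).
#' @param rdvi_variant `"sqrt"` (renormalised difference, default) or
#'   `"ndvi"` (legacy NDVI-identical form).
#' @return A single-band [cm_image] of index values.
#' @export
compute_vi <- function(image, vi, rdvi_variant = c("sqrt", "ndvi")) {
  vi <- match.arg(vi, vi_names())
  sensor <- image$sensor
  if (is.null(sensor)) stop("image has no sensor model", call. = FALSE)
  roles <- vi_required_roles(vi)
  pos <- match(roles, sensor$role)
  if (anyNA(pos)) {
    stop(vi, " needs band role(s) ",
         paste(roles[is.na(pos)], collapse = ", "),
         " which the sensor does not declare", call. = FALSE)
  }
  args <- stats::setNames(
    lapply(pos, function(b) image$values[, , b]),
    sub("nir1", "nir1", roles)
  )
  out <- do.call(vi_eval, c(list(vi = vi), args, list(rdvi_variant = rdvi_variant)))
  bad <- is.na(out) & image$mask
  vals <- array(out, dim = c(dim(image$values)[1:2], 1L))
  new_cm_image(vals, "vi_image", mask = image$mask & !is.na(out),
               meta = list(vi = vi, rdvi_variant = rdvi_variant,
                           n_zero_denominator = sum(bad)))
}

#' Compute vegetation indices from tabular reflectances
#'
#' Tidy companion to [compute_vi()]: takes a data frame with role-named
#' reflectance columns (`blue`, `green`, `red`, `nir1`) — e.g. plot-level
#' mean reflectances — and appends one column per requested index.
#'
#' @param data A data frame with the required role columns.
#' @param vis Character vector of index names (default all nine).
#' @param rdvi_variant See [compute_vi()].
#' @return `data` with the index columns appended.
#' @export
add_vi_columns <- function(data, vis = vi_names(),
                           rdvi_variant = c("sqrt", "ndvi")) {
  rdvi_variant <- match.arg(rdvi_variant)
  for (vi in vis) {
    roles <- vi_required_roles(vi)
    miss <- setdiff(roles, names(data))
    if (length(miss) > 0L) {
      stop(vi, " needs column(s) ", paste(miss, collapse = ", "), call. = FALSE)
    }
    args <- stats::setNames(lapply(roles, function(r) data[[r]]), roles)
    data[[vi]] <- do.call(vi_eval, c(list(vi = vi), args,
                                     list(rdvi_variant = rdvi_variant)))
  }
  data
}

#' Theoretical range of a vegetation index
#'
#' The attainable (open) interval of an index when every input reflectance
#' lies in `(0, 1]`. For the linear indices (DVI, TVI) the endpoints come
#' from enumerating the formula over the corners of the reflectance cube.
#'
#' @param vi Index name.
#' @return Numeric `c(lower, upper)` (open bounds; `Inf` where unbounded).
#' @export
vi_bounds <- function(vi) {
  switch(match.arg(vi, vi_names()),
    NDVI = c(-1, 1),
    VARI = c(-1, 1),
    NDYI = c(-1, 1),
    DVI = c(-1, 1),
    RVI = c(0, Inf),
    CIgreen = c(-1, Inf),
    RDVI = c(-1 / sqrt(1), 1 / sqrt(1)),  # |n - r| < sqrt(n + r) for n, r in (0, 1]
    EVI = c(-Inf, Inf),                    # denominator can pass through 0
    TVI = {
      corners <- expand.grid(n = c(0, 1), g = c(0, 1), r = c(0, 1))
      v <- 0.5 * (120 * (corners$n - corners$g) - 200 * (corners$r - corners$g))
      range(v)
    }
  )
}
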