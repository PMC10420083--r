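#' Read and write multiband rasters
#'
#' Images are stored as multi-page TIFF files (one page per band) with a JSON
#' sidecar (`<path>.json`) carrying everything the pixel payload cannot:
#' image kind, band metadata (centre, FWHM, role), bit depth, mask, and any
#' extra metadata such as seeds, gains or panel coordinates. DN images are
#' stored losslessly at their declared bit depth; reflectance and abundance
#' images are stored as 32-bit floats after an affine rescale into `[0, 1]`
#' (offset/scale recorded in the sidecar), so round trips are exact for DN
#' and within float32 precision otherwise.
#'
#' @param image A [cm_image] object.
#' @param path Output TIFF path (sidecar written next to it).
#' @param sensor Optional [sensor_model()] to validate band count on read.
#' @return `write_raster()` invisibly returns `path`; `read_raster()` returns
#'   the reconstructed image object.
#' @export
write_raster <- function(image, path) {
  d <- dim(image$values)
  kind <- class(image)[1L]
  side <- list(
    kind = kind,
    dim = d,
    meta = image$meta
  )
  if (!is.null(image$sensor)) {
    side$sensor <- list(
      name = attr(image$sensor, "sensor_name"),
      bands = data.frame(center = image$sensor$center_nm,
                         fwhm = image$sensor$fwhm_nm,
                         role = image$sensor$role)
    )
  }
  if (!all(image$mask)) side$mask_invalid <- which(!image$mask) - 1L
  # invalid pixels may hold NA; store 0 and restore NA from the mask on read
  pages <- lapply(seq_len(d[3L]), function(b) {
    m <- image$values[, , b]
    m[!is.finite(m)] <- 0
    m
  })
  if (kind == "dn_image") {
    bits <- image$meta$bit_depth
    store_bits <- if (bits <= 8L) 8L else 16L
    denom <- 2^store_bits - 1
    pages <- lapply(pages, function(m) m / denom)
    side$dn_denom <- denom
    tiff::writeTIFF(pages, path, bits.per.sample = store_bits, reduce = FALSE)
  } else {
    rng <- range(vapply(pages, range, numeric(2L)))
    off <- min(0, rng[1L])
    sc <- max(1, rng[2L] - off)
    pages <- lapply(pages, function(m) (m - off) / sc)
    side$float_offset <- off
    side$float_scale <- sc
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  if (kind == "abundance_image" && !is.null(image$residual)) {
    res <- image$residual
    res[!is.finite(res)] <- 0
    rsc <- max(1, max(res))
    side$residual_scale <- rsc
    tiff::writeTIFF(res / rsc, sub("\\.tiff?$", "_residual.tif", path),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, sensor = NULL) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(side$dim)
  values <- array(0, dim = d)
  for (b in seq_len(d[3L])) values[, , b] <- pages[[b]]
  if (identical(side$kind, "dn_image")) {
    values <- round(values * side$dn_denom)
  } else {
    values <- values * side$float_scale + side$float_offset
  }
  sm <- NULL
  if (!is.null(side$sensor)) {
    role <- side$sensor$bands$role
    if (is.null(role)) role <- NA_character_
    sm <- sensor_model(side$sensor$name, side$sensor$bands$center,
                       side$sensor$bands$fwhm, role)
  }
  if (!is.null(sensor)) {
    if (nrow(sensor) != d[3L]) {
      stop("band count mismatch: raster has ", d[3L], " bands, sensor declares ",
           nrow(sensor), call. = FALSE)
    }
    sm <- sensor
  }
  mask <- matrix(TRUE, d[1L], d[2L])
  if (!is.null(side$mask_invalid)) {
    mask[side$mask_invalid + 1L] <- FALSE
    if (identical(side$kind, "abundance_image")) {
      for (b in seq_len(d[3L])) {
        m <- values[, , b]
        m[!mask] <- NA_real_
        values[, , b] <- m
      }
    }
  }
  meta <- if (is.null(side$meta)) list() else side$meta
  out <- switch(side$kind,
    dn_image = dn_image(values, sm, bit_depth = as.integer(meta$bit_depth),
                        mask = mask, meta = meta),
    abundance_image = abundance_image(values, mask = mask, meta = meta),
    refl_image(values, sm, mask = mask, meta = meta)
  )
  if (identical(side$kind, "abundance_image")) {
    res_path <- sub("\\.tiff?$", "_residual.tif", path)
    if (file.exists(res_path) && !is.null(side$residual_scale)) {
      out$residual <- tiff::readTIFF(res_path) * side$residual_scale
    }
  }
  out
}

#' Read a plot definition table
#'
#' Expected columns: `plot_id`, `row0`, `col0`, `row1`, `col1` (0-based,
#' half-open pixel rectangles `[row0, row1) x [col0, col1)`),
#' `nitrogen_rate`, `yield_kg_ha`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_plots_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  need <- c("plot_id", "row0", "col0", "row1", "col1", "nitrogen_rate", "yield_kg_ha")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("plots CSV is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$yield_kg_ha <= 0)) stop("plot yields must be positive", call. = FALSE)
  if (any(df$row1 <= df$row0) || any(df$col1 <= df$col0)) {
    stop("ROIs must be non-empty half-open rectangles [row0,row1) x [col0,col1)",
         call. = FALSE)
  }
  df
}
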