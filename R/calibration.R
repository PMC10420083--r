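#' Extract calibration-panel observations from a DN image
#'
#' Aggregates the DN values inside each panel rectangle recorded in the
#' image metadata (see [encode_dn()]) into one observation per band and
#' panel.
#'
#' @param dn A [dn_image] whose `meta$panels` lists panel rectangles and
#'   known reflectances.
#' @param stat Aggregation over panel pixels: `"mean"` (default) or
#'   `"median"`.
#' @return A tibble with columns `band`, `known_reflectance`, `mean_dn`.
#' @export
extract_panels <- function(dn, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  panels <- dn$meta$panels
  if (is.null(panels) || length(panels) == 0L) {
    stop("image metadata records no calibration panels", call. = FALSE)
  }
  # metadata read back from a JSON sidecar arrives as a data frame
  if (is.data.frame(panels)) panels <- apply(panels, 1L, as.list)
  B <- dim(dn$values)[3L]
  purrr::map_dfr(panels, function(p) {
    rows <- (p$row0 + 1L):p$row1
    cols <- (p$col0 + 1L):p$col1
    tibble::tibble(
      band = seq_len(B),
      known_reflectance = p$reflectance,
      mean_dn = vapply(seq_len(B), function(b) f(dn$values[rows, cols, b]),
                       numeric(1L))
    )
  })
}

#' Fit the empirical linear model (ELM) per band
#'
#' Ordinary least squares of known panel reflectance on mean panel DN,
#' `rho = gain * DN + bias`, giving the per-band gain (slope, reflectance
#' per count) and bias (intercept, reflectance offset) that convert raw
#' digital numbers to surface reflectance.
#'
#' @param observations Tibble of panel observations with columns `band`,
#'   `known_reflectance`, `mean_dn` (see [extract_panels()]); order of rows
#'   is irrelevant.
#' @return A `gain_bias` tibble: one row per band with `gain`, `bias`,
#'   `rmse` (fit residual RMSE) and `n_panels`. A negative fitted gain
#'   triggers a warning.
#' @examples
#' obs <- tibble::tibble(band = 1, known_reflectance = c(0.06, 0.24, 0.48),
#'                       mean_dn = c(10, 40, 80))
#' fit_elm(obs)  # gain 0.006, bias 0
#' @export
fit_elm <- function(observations) {
  stopifnot(all(c("band", "known_reflectance", "mean_dn") %in% names(observations)))
  out <- dplyr::group_modify(
    dplyr::group_by(observations, .data$band),
    function(df, key) {
      if (nrow(df) < 2L || length(unique(df$mean_dn)) < 2L) {
        stop("band ", key$band,
             ": ELM needs at least two panels with distinct DN", call. = FALSE)
      }
      fit <- stats::lm(known_reflectance ~ mean_dn, data = df)
      co <- stats::coef(fit)
      tibble::tibble(
        gain = unname(co[2L]), bias = unname(co[1L]),
        rmse = sqrt(mean(stats::residuals(fit)^2)),
        n_panels = nrow(df)
      )
    }
  )
  out <- dplyr::ungroup(out)
  if (any(out$gain < 0)) warning("negative fitted gain for band(s) ",
                                 paste(out$band[out$gain < 0], collapse = ", "))
  class(out) <- c("gain_bias", class(out))
  out
}

#' Apply an empirical linear model to a DN image
#'
#' Converts digital numbers to surface reflectance per pixel and band,
#' `rho = gain * DN + bias`. Negative results are clipped to 0 and counted;
#' values above 1 are retained but counted (both in `meta$elm`).
#'
#' @param dn A [dn_image].
#' @param gb A `gain_bias` tibble from [fit_elm()] with one row per image
#'   band.
#' @return A [refl_image] with conversion diagnostics in `meta$elm`.
#' @export
apply_elm <- function(dn, gb) {
  B <- dim(dn$values)[3L]
  if (!all(sort(gb$band) == seq_len(B))) {
    stop("`gb` must provide exactly one (gain, bias) per image band (",
         B, " bands)", call. = FALSE)
  }
  gb <- gb[order(gb$band), ]
  vals <- dn$values
  for (b in seq_len(B)) {
    vals[, , b] <- gb$gain[b] * dn$values[, , b] + gb$bias[b]
  }
  n_neg <- sum(vals < 0)
  n_over <- sum(vals > 1)
  vals[vals < 0] <- 0
  refl_image(vals, dn$sensor, mask = dn$mask,
             meta = c(dn$meta,
                      list(elm = list(n_clipped_negative = n_neg,
                                      n_above_one = n_over,
                                      gain = gb$gain, bias = gb$bias))))
}
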