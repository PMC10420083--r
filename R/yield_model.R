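#' Aggregate imagery to a per-plot predictor table
#'
#' For each plot ROI (0-based half-open rectangle `[row0, row1) x
#' [col0, col1)`, boundary-avoiding), takes the arithmetic mean over valid
#' pixels of every reflectance band and the three abundance maps, then
#' computes plot-level vegetation indices. By convention plot-level VIs are
#' evaluated on the plot's mean reflectance (`vi_convention =
#' "mean_reflectance"`, the default); averaging per-pixel VI values over the
#' ROI is available as `"per_pixel_mean"` — the two differ on heterogeneous
#' plots.
#'
#' @param reflectance A [refl_image] with role-bearing sensor.
#' @param abundance An [abundance_image] co-registered with `reflectance`.
#' @param plots Tibble of plot records with `plot_id`, ROI columns `row0`,
#'   `row1`, `col0`, `col1`, and any carried columns (nitrogen rate, yield).
#' @param vis Vegetation indices to compute (default all nine).
#' @param vi_convention `"mean_reflectance"` or `"per_pixel_mean"`.
#' @param rdvi_variant Passed to the index formulas.
#' @return A tibble, one row per plot: carried columns, mean band
#'   reflectances (role-named), `abd_fl`/`abd_lf`/`abd_sl`, one column per
#'   VI, and the products `<VI>_x_fl` and `<VI>_x_lf`. Plots with an empty
#'   ROI are dropped with a warning.
#' @export
plot_aggregate <- function(reflectance, abundance, plots, vis = vi_names(),
                           vi_convention = c("mean_reflectance", "per_pixel_mean"),
                           rdvi_variant = c("sqrt", "ndvi")) {
  vi_convention <- match.arg(vi_convention)
  rdvi_variant <- match.arg(rdvi_variant)
  d <- dim(reflectance$values)
  stopifnot(identical(dim(abundance$values)[1:2], d[1:2]))
  labels <- band_labels(reflectance)
  carried <- plots[, setdiff(names(plots),
                             c("foot_row0", "foot_row1", "foot_col0", "foot_col1")),
                   drop = FALSE]
  # carried ground-truth columns that collide with computed ones get a
  # `_true` suffix (and are dropped if that name is taken too)
  computed <- c(labels, "abd_fl", "abd_lf", "abd_sl", vis,
                paste0(vis, "_x_fl"), paste0(vis, "_x_lf"))
  clash <- intersect(names(carried), computed)
  for (nm in clash) {
    alt <- paste0(nm, "_true")
    if (alt %in% names(carried)) carried[[nm]] <- NULL else
      names(carried)[names(carried) == nm] <- alt
  }
  rows <- purrr::pmap_dfr(
    list(plots$row0, plots$row1, plots$col0, plots$col1, seq_len(nrow(plots))),
    function(r0, r1, c0, c1, i) {
      if (r1 > d[1L] || c1 > d[2L] || r0 < 0 || c0 < 0) {
        stop("plot ", plots$plot_id[i], " ROI exceeds image bounds", call. = FALSE)
      }
      rr <- (r0 + 1L):r1
      cc <- (c0 + 1L):c1
      ok <- reflectance$mask[rr, cc, drop = FALSE] &
        abundance$mask[rr, cc, drop = FALSE]
      if (!any(ok)) {
        warning("plot ", plots$plot_id[i], " has no valid pixels; excluded")
        return(tibble::tibble(.plot_row = i, .empty = TRUE))
      }
      band_mean <- function(arr, b) mean(arr[rr, cc, b][ok])
      refl <- vapply(seq_len(d[3L]), band_mean, numeric(1L), arr = reflectance$values)
      abd <- vapply(1:3, band_mean, numeric(1L), arr = abundance$values)
      out <- tibble::as_tibble(as.list(stats::setNames(refl, labels)))
      out$abd_fl <- abd[1L]; out$abd_lf <- abd[2L]; out$abd_sl <- abd[3L]
      if (vi_convention == "per_pixel_mean") {
        for (vi in vis) {
          img <- compute_vi(reflectance, vi, rdvi_variant = rdvi_variant)
          v <- img$values[rr, cc, 1L]
          out[[vi]] <- mean(v[ok & !is.na(v)])
        }
      }
      out$.plot_row <- i
      out$.empty <- FALSE
      out
    }
  )
  rows <- rows[!rows$.empty, , drop = FALSE]
  if (nrow(rows) == 0L) return(carried[integer(0L), , drop = FALSE])
  tab <- dplyr::bind_cols(carried[rows$.plot_row, , drop = FALSE],
                          rows[, setdiff(names(rows), c(".plot_row", ".empty")),
                               drop = FALSE])
  if (vi_convention == "mean_reflectance") {
    tab <- add_vi_columns(tab, vis, rdvi_variant = rdvi_variant)
  }
  for (vi in vis) {
    tab[[paste0(vi, "_x_fl")]] <- tab[[vi]] * tab$abd_fl
    tab[[paste0(vi, "_x_lf")]] <- tab[[vi]] * tab$abd_lf
  }
  tab
}

#' Simple linear yield model
#'
#' Ordinary least squares `y = slope * x + intercept`; the in-sample
#' coefficient of determination is the squared Pearson correlation of
#' fitted and observed values.
#'
#' @param x Predictor vector (a VI or VI-abundance product).
#' @param y Response vector (yield, kg/ha).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  ols_fit(x, y)
}

# Plain OLS line, valid from 2 points up (used for LOOCV training folds).
ols_fit <- function(x, y) {
  if (stats::sd(x) == 0) stop("degenerate predictor: `x` is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # squared Pearson correlation of fitted vs observed; for a simple linear
  # fit this equals cor(x, y)^2, which is also well defined at slope 0
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  tibble::tibble(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r_squared = r2, n = length(x))
}

#' Leave-one-out cross-validation of a linear yield model
#'
#' Each of the `K` samples is held out once; the model is refitted on the
#' remaining `K - 1` and the held-out residual `E_i = y_i - yhat_i`
#' recorded together with the training-fit R² of that fold. Reported
#' summary statistics:
#'
#' * `r2` — mean of the per-fold training R² values;
#' * `r2_pooled` — squared Pearson correlation of the pooled held-out
#'   predictions with the observations (reported for transparency);
#' * `rmse` — `sqrt(sum(E_i^2) / K)` in the response units;
#' * `cv` — percent; by default `100 * rmse / mean(y)` (the ratio of the
#'   cross-validated RMSE to the mean observed yield). The variant
#'   `cv_variant = "per_fold"` instead averages the per-fold relative
#'   errors `100 * |E_i| / mean(y[-i])`.
#'
#' @param x Predictor vector.
#' @param y Response vector (same length, `K >= 3`).
#' @param label Optional model label carried into reports.
#' @param cv_variant `"rmse_over_mean"` (default) or `"per_fold"`.
#' @return A `cv_report` object; see [tidy.cv_report()] /
#'   [glance.cv_report()].
#' @export
loocv_evaluate <- function(x, y, label = NULL,
                           cv_variant = c("rmse_over_mean", "per_fold")) {
  cv_variant <- match.arg(cv_variant)
  K <- length(x)
  stopifnot(length(y) == K)
  if (K < 3L) stop("leave-one-out needs at least 3 samples", call. = FALSE)
  folds <- purrr::map_dfr(seq_len(K), function(i) {
    xt <- x[-i]; yt <- y[-i]
    if (stats::sd(xt) == 0) {
      stop("degenerate training fold ", i, ": constant predictor", call. = FALSE)
    }
    fit <- ols_fit(xt, yt)
    pred <- fit$slope * x[i] + fit$intercept
    tibble::tibble(fold = i, observed = y[i], predicted = pred,
                   residual = y[i] - pred, r2_train = fit$r_squared,
                   mean_y_train = mean(yt))
  })
  rmse <- sqrt(sum(folds$residual^2) / K)
  cv <- if (cv_variant == "rmse_over_mean") {
    100 * rmse / mean(y)
  } else {
    mean(100 * abs(folds$residual) / folds$mean_y_train)
  }
  r2_pooled <- if (stats::sd(folds$predicted) == 0 || stats::sd(y) == 0) 0 else
    stats::cor(folds$predicted, folds$observed)^2
  full <- fit_linear(x, y)
  structure(
    list(label = label %||% "model", r2 = mean(folds$r2_train),
         r2_pooled = r2_pooled, rmse = rmse, cv = cv, n = K,
         cv_variant = cv_variant, folds = folds,
         slope = full$slope, intercept = full$intercept),
    class = "cv_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: R2 %.3f  RMSE %.1f  CV %.1f%%  (K = %d)\n",
              x$label, x$r2, x$rmse, x$cv, x$n))
  invisible(x)
}

#' Tidiers for cross-validation reports
#'
#' @param x A `cv_report` from [loocv_evaluate()].
#' @param ... Ignored.
#' @return `tidy()` returns the per-fold table (observed, predicted,
#'   residual, training R²); `glance()` a one-row summary (`r2`,
#'   `r2_pooled`, `rmse`, `cv`, full-data `slope`/`intercept`, `n`).
#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(label = x$label), x$folds)
}

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(label = x$label, r2 = x$r2, r2_pooled = x$r2_pooled,
                 rmse = x$rmse, cv = x$cv, slope = x$slope,
                 intercept = x$intercept, n = x$n)
}

#' @rdname tidy.cv_report
#' @param object A `cv_report`.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = object$label,
      subtitle = sprintf("LOOCV: R2 = %.2f, RMSE = %.1f kg/ha, CV = %.1f%%",
                         object$r2, object$rmse, object$cv),
      x = "observed yield (kg/ha)", y = "predicted yield (kg/ha)"
    ) +
    ggplot2::theme_minimal()
}

#' Rank all VI and VI-abundance yield models
#'
#' Evaluates the three model families — yield versus VI, versus
#' VI x Abd_FL, and versus VI x Abd_LF — for every requested index by
#' leave-one-out cross-validation, and ranks the resulting models by R²
#' (descending) with RMSE as tie-break. Models whose evaluation fails
#' (degenerate predictor or response) are kept with `NA` statistics and a
#' note.
#'
#' @param table A predictor table from [plot_aggregate()] (or any tibble
#'   with the VI / product columns and a yield column).
#' @param response Name of the yield column (default `"yield_kg_ha"`).
#' @param vis Indices to evaluate.
#' @param families Subset of `c("vi", "vi_x_fl", "vi_x_lf")`.
#' @param cv_variant Passed to [loocv_evaluate()].
#' @return A `model_ranking` tibble: `vi`, `family`, `predictor`, `r2`,
#'   `r2_pooled`, `rmse`, `cv`, `slope`, `intercept`, `rank`, `top` (the
#'   conventional top-6 marking over the plain-VI and leaf-product
#'   families), `note`.
#' @export
rank_models <- function(table, response = "yield_kg_ha", vis = vi_names(),
                        families = c("vi", "vi_x_fl", "vi_x_lf"),
                        cv_variant = c("rmse_over_mean", "per_fold")) {
  cv_variant <- match.arg(cv_variant)
  families <- match.arg(families, several.ok = TRUE)
  y <- table[[response]]
  if (is.null(y)) stop("no response column `", response, "` in table", call. = FALSE)
  grid <- tidyr::expand_grid(vi = vis, family = families)
  out <- purrr::pmap_dfr(grid, function(vi, family) {
    col <- switch(family, vi = vi, vi_x_fl = paste0(vi, "_x_fl"),
                  vi_x_lf = paste0(vi, "_x_lf"))
    base <- tibble::tibble(vi = vi, family = family, predictor = col)
    res <- tryCatch(
      loocv_evaluate(table[[col]], y, label = col, cv_variant = cv_variant),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      return(dplyr::bind_cols(base, tibble::tibble(
        r2 = NA_real_, r2_pooled = NA_real_, rmse = NA_real_, cv = NA_real_,
        slope = NA_real_, intercept = NA_real_, note = res)))
    }
    dplyr::bind_cols(base, glance(res)[, c("r2", "r2_pooled", "rmse", "cv",
                                           "slope", "intercept")],
                     tibble::tibble(note = NA_character_))
  })
  out <- dplyr::arrange(out, dplyr::desc(!is.na(out$r2)),
                        dplyr::desc(.data$r2), .data$rmse)
  out$rank <- seq_len(nrow(out))
  eligible <- out$family != "vi_x_fl" & !is.na(out$r2)
  out$top <- FALSE
  out$top[which(eligible)[seq_len(min(6L, sum(eligible)))]] <- TRUE
  class(out) <- c("model_ranking", class(out))
  out
}

#' @rdname rank_models
#' @param object A `model_ranking`.
#' @param ... Ignored.
#' @export
autoplot.model_ranking <- function(object, ...) {
  df <- object[!is.na(object$r2), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$vi, .data$r2, fill = .data$family)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(LOOCV ~ R^2), fill = "predictor") +
    ggplot2::theme_minimal()
}
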