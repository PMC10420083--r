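#' Fully constrained least-squares unmixing of one pixel
#'
#' Estimates the abundance vector `a` minimising `||E a - rho||_2` subject
#' to the simplex constraints `a >= 0`, `sum(a) = 1` (the fully constrained
#' least-squares, FCLS, problem of linear spectral mixture analysis). With
#' three endmembers the problem is a tiny quadratic program and is solved
#' exactly by enumerating the seven possible active supports: for each
#' support the equality-constrained least-squares solution is obtained from
#' the KKT system (pseudo-inverted, so rank-deficient supports yield the
#' minimum-norm solution), feasible candidates are ranked by objective, and
#' ties resolve to the largest support, i.e. the minimum-norm minimiser.
#'
#' @param rho Numeric vector of band reflectances (length = rows of `E`).
#' @param E An endmember matrix from [build_endmember_matrix()] (B x 3).
#' @return A list with `abundance` (named, sums to 1 exactly) and
#'   `residual` (`||E a - rho||_2 / sqrt(B)`, i.e. per-band RMS
#'   reconstruction error).
#' @examples
#' lib <- generate_endmember_library(1)
#' E <- build_endmember_matrix(lib, sensor_uav6())
#' fcls_pixel(as.numeric(E %*% c(0.5, 0.3, 0.2)), E)
#' @export
fcls_pixel <- function(rho, E) {
  rho <- as.numeric(rho)
  Em <- unclass(E)
  if (length(rho) != nrow(Em)) {
    stop("`rho` must have one value per endmember-matrix row", call. = FALSE)
  }
  out <- fcls_batch(matrix(rho, ncol = 1L), E)
  list(abundance = stats::setNames(out$abundance[, 1L], colnames(Em)),
       residual = out$residual[1L])
}

# Exact simplex-constrained least squares for a batch of pixels (columns of
# R, a B x P matrix). Returns 3 x P abundances and length-P residuals.
fcls_batch <- function(R, E) {
  Em <- unclass(E)
  B <- nrow(Em)
  N <- ncol(Em)
  stopifnot(N == 3L)
  if (any(!is.finite(R)) || any(!is.finite(Em))) {
    stop("non-finite values in `rho` or `E`", call. = FALSE)
  }
  if (qr(Em)$rank < N) {
    warning("rank-deficient endmember matrix: solution may be non-unique; ",
            "returning the minimum-norm minimiser")
  }
  P <- ncol(R)
  # supports ordered largest first so objective ties resolve to minimum norm
  supports <- list(1:3, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1L, 2L, 3L)
  best_obj <- rep(Inf, P)
  best_a <- matrix(0, N, P)
  r2 <- colSums(R^2)
  for (S in supports) {
    Es <- Em[, S, drop = FALSE]
    k <- length(S)
    # KKT system of min ||Es a - rho||^2 s.t. sum(a) = 1
    K <- rbind(cbind(2 * crossprod(Es), rep(1, k)), c(rep(1, k), 0))
    Kinv <- tryCatch(solve(K), error = function(e) pinv_sym(K))
    # a is affine in rho: a = M %*% rho + m0
    M <- Kinv[seq_len(k), seq_len(k), drop = FALSE] %*% (2 * t(Es))
    m0 <- Kinv[seq_len(k), k + 1L]
    A <- M %*% R + m0
    feas <- colSums(A < -1e-9) == 0L
    if (!any(feas)) next
    # objective ||Es a - rho||^2 = a'Q a - 2 a'c + ||rho||^2
    EA <- Es %*% A
    obj <- colSums(EA^2) - 2 * colSums(EA * R) + r2
    take <- feas & obj < best_obj - 1e-12
    if (any(take)) {
      best_obj[take] <- obj[take]
      best_a[, take] <- 0
      best_a[S, take] <- pmax(A[, take, drop = FALSE], 0)
    }
  }
  # exact simplex membership: clamp solver noise and renormalise
  best_a <- sweep(best_a, 2L, colSums(best_a), "/")
  list(abundance = best_a,
       residual = sqrt(pmax(colSums((Em %*% best_a - R)^2), 0) / B))
}

# Moore-Penrose inverse of a small symmetric matrix via eigendecomposition.
pinv_sym <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-12
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Exhaustive simplex-grid reference solver
#'
#' Brute-force minimiser of the FCLS objective over the lattice
#' `{(i s, j s, 1 - (i + j) s) >= 0}`: evaluates `||E a - rho||_2` at every
#' lattice point and returns the minimiser. Independent of [fcls_pixel()]
#' and used to validate it; accepts a matrix of pixels (columns) and chunks
#' the cross-product so memory stays bounded.
#'
#' @param rho Numeric vector (length B) or B x P matrix of pixel spectra.
#' @param E Endmember matrix (B x 3).
#' @param step Lattice spacing; must divide 1.
#' @return Abundance vector (or 3 x P matrix) of lattice minimisers.
#' @export
oracle_fcls <- function(rho, E, step = 0.01) {
  Em <- unclass(E)
  A <- simplex_lattice(step, ncol(Em))
  EA <- Em %*% A                      # B x M
  c2 <- colSums(EA^2)                 # M
  R <- if (is.matrix(rho)) rho else matrix(rho, ncol = 1L)
  P <- ncol(R)
  out <- matrix(0, nrow(A), P)
  chunk <- max(1L, floor(4e6 / ncol(A)))
  for (s in seq(1L, P, by = chunk)) {
    idx <- s:min(P, s + chunk - 1L)
    G <- crossprod(EA, R[, idx, drop = FALSE])   # M x |idx|
    obj <- c2 - 2 * G                            # + ||rho||^2, constant per pixel
    out[, idx] <- A[, apply(obj, 2L, which.min)]
  }
  rownames(out) <- colnames(Em)
  if (is.matrix(rho)) out else out[, 1L]
}

# All lattice points of the (n-1)-simplex with spacing `step` (columns).
simplex_lattice <- function(step, n = 3L) {
  stopifnot(n == 3L)
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9 || step <= 0) {
    stop("`step` must be positive and divide 1", call. = FALSE)
  }
  ij <- which(outer(0:m, 0:m, `+`) <= m, arr.ind = TRUE) - 1L
  rbind(ij[, 1L] / m, ij[, 2L] / m, 1 - (ij[, 1L] + ij[, 2L]) / m)
}

#' Unmix a reflectance image into abundance maps
#'
#' Applies [fcls_pixel()] to every valid pixel, producing per-pixel flower/
#' leaf/soil fractions and the per-band RMS reconstruction residual. Masked
#' pixels propagate as invalid (`NA` abundances). Pixels with any
#' reflectance above 1 (possible after empirical-line calibration) are
#' unmixed as-is and their count recorded in `meta$n_reflectance_above_one`.
#'
#' @param image A [refl_image] whose band order matches the rows of `E`.
#' @param E An endmember matrix from [build_endmember_matrix()].
#' @return An [abundance_image]; `meta$summary` holds mean abundances and
#'   residual quantiles over valid pixels.
#' @export
unmix_image <- function(image, E) {
  d <- dim(image$values)
  Em <- unclass(E)
  if (d[3L] != nrow(Em)) {
    stop("band count mismatch: image has ", d[3L], " bands, endmember matrix ",
         nrow(Em), " rows", call. = FALSE)
  }
  flat <- matrix(image$values, d[1L] * d[2L], d[3L])
  valid <- as.vector(image$mask)
  ab <- matrix(NA_real_, d[1L] * d[2L], 3L)
  res <- rep(NA_real_, d[1L] * d[2L])
  idx <- which(valid)
  if (length(idx) > 0L) {
    sol <- fcls_batch(t(flat[idx, , drop = FALSE]), E)
    ab[idx, ] <- t(sol$abundance)
    res[idx] <- sol$residual
  }
  meta <- list(
    n_reflectance_above_one = sum(rowSums(flat[valid, , drop = FALSE] > 1) > 0),
    summary = if (length(idx) > 0L) list(
      mean_abundance = stats::setNames(colMeans(ab[idx, , drop = FALSE]),
                                       c("FL", "LF", "SL")),
      residual_quantiles = stats::quantile(res[idx], c(0, 0.5, 0.9, 1))
    )
  )
  abundance_image(array(ab, dim = c(d[1L], d[2L], 3L)),
                  residual = matrix(res, d[1L], d[2L]),
                  mask = image$mask, meta = meta)
}
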