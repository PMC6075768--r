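#' Preprocessing configuration
#'
#' Defaults follow the acquisition-processing settings used for stone
#' sections: Savitzky-Golay smoothing with window 5 (polynomial order 2),
#' asymmetric least squares baseline correction with smoothness weight
#' `lambda = 1e5` and asymmetry `p = 1e-3`, and porosity masking of pixels
#' whose total baseline-corrected intensity falls below 5% of the median.
#'
#' @param sg_window Odd integer >= 3.
#' @param sg_polyorder Integer < `sg_window`.
#' @param asls_lambda Smoothness weight (> 0).
#' @param asls_p Asymmetry weight in (0, 1).
#' @param asls_iterations Reweighting iterations (>= 1; stops early when
#'   the weights no longer change).
#' @param low_signal_quantile Fraction of the median total intensity below
#'   which a pixel is masked as porosity/gap.
#' @return List of class `"preprocess_config"`.
#' @export
preprocess_config <- function(sg_window = 5L, sg_polyorder = 2L,
                              asls_lambda = 1e5, asls_p = 1e-3,
                              asls_iterations = 10L,
                              low_signal_quantile = 0.05) {
  stopifnot(sg_window >= 3, sg_window %% 2 == 1,
            sg_polyorder >= 0, sg_polyorder < sg_window,
            asls_lambda > 0, asls_p > 0, asls_p < 1,
            asls_iterations >= 1,
            low_signal_quantile > 0, low_signal_quantile < 1)
  structure(list(sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 asls_lambda = asls_lambda, asls_p = asls_p,
                 asls_iterations = as.integer(asls_iterations),
                 low_signal_quantile = low_signal_quantile),
            class = "preprocess_config")
}

#' Unfold a hyperspectral cube into a pixels-by-bands matrix
#'
#' Support pixels are stacked row-major (left to right, top to bottom)
#' into the rows of `D`; non-support pixels are dropped. [refold()] is the
#' exact inverse on support pixels.
#'
#' @param cube A `"hyper_cube"`.
#' @return Object of class `"unfolded_raman"`: `D` (`N_pixels x B`),
#'   `pixel_index` (`N x 2` matrix of (row, col)), `shape`, `axis`,
#'   `step_um`, `support`.
#' @export
unfold <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (!any(cube$support)) stop("cube has empty support: nothing to unfold")
  H <- dim(cube$intensities)[1]; W <- dim(cube$intensities)[2]
  rc <- which(cube$support, arr.ind = TRUE)
  rc <- rc[order(rc[, 1], rc[, 2]), , drop = FALSE]
  lin <- (rc[, 2] - 1L) * H + rc[, 1]
  D <- matrix(cube$intensities, H * W, dim(cube$intensities)[3])[lin, ,
                                                                 drop = FALSE]
  structure(list(D = D, pixel_index = unname(rc), shape = c(H, W),
                 axis = cube$axis, step_um = cube$step_um,
                 support = cube$support),
            class = "unfolded_raman")
}

#' Refold an unfolded matrix back into a cube
#'
#' @param unfolded An `"unfolded_raman"` object.
#' @param values Optional `N_pixels x B` matrix to refold in place of
#'   `unfolded$D`.
#' @return A `"hyper_cube"` equal to the original on support pixels and
#'   zero elsewhere.
#' @export
refold <- function(unfolded, values = unfolded$D) {
  stopifnot(inherits(unfolded, "unfolded_raman"),
            nrow(values) == nrow(unfolded$D))
  H <- unfolded$shape[1]; W <- unfolded$shape[2]
  B <- length(unfolded$axis)
  arr <- matrix(0, H * W, B)
  lin <- (unfolded$pixel_index[, 2] - 1L) * H + unfolded$pixel_index[, 1]
  arr[lin, ] <- values
  hyper_cube(array(arr, dim = c(H, W, B)), unfolded$axis, unfolded$step_um,
             unfolded$support)
}

# interior kernel and one-sided edge weights from the local least-squares
# polynomial fit (normal equations)
sg_weights <- function(window, polyorder) {
  h <- (window - 1L) / 2L
  x <- seq(-h, h)
  X <- outer(x, 0:polyorder, `^`)
  P <- X %*% solve(crossprod(X)) %*% t(X)   # hat matrix over the window
  list(interior = P[h + 1L, ],              # evaluate fit at window centre
       head = P[seq_len(h), , drop = FALSE],
       tail = P[window - seq_len(h) + 1L, , drop = FALSE][h:1, , drop = FALSE])
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Each interior point is replaced by the value at that point of the local
#' least-squares polynomial of degree `polyorder` fitted over the
#' symmetric window; the first and last `(window-1)/2` points are taken
#' from the same-degree polynomial fitted to the one-sided first (last)
#' `window` points.
#'
#' @param y Numeric vector (length >= `window`).
#' @param window Odd window size (default 5).
#' @param polyorder Polynomial degree (default 2), < `window`.
#' @return Smoothed vector of the same length.
#' @export
savgol_smooth <- function(y, window = 5L, polyorder = 2L) {
  if (window %% 2 == 0) stop("Savitzky-Golay window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (length(y) < window) stop("spectrum shorter than the smoothing window")
  drop(savgol_smooth_rows(matrix(y, 1), window, polyorder))
}

# vectorized over rows (pixels x bands)
savgol_smooth_rows <- function(M, window, polyorder) {
  n <- ncol(M)
  h <- (window - 1L) / 2L
  w <- sg_weights(window, polyorder)
  out <- matrix(0, nrow(M), n)
  for (m in seq_len(window))               # interior: shifted-column sums
    out[, (h + 1):(n - h)] <- out[, (h + 1):(n - h)] +
      w$interior[m] * M[, (m):(n - window + m), drop = FALSE]
  out[, seq_len(h)] <- M[, seq_len(window), drop = FALSE] %*% t(w$head)
  out[, (n - h + 1):n] <- M[, (n - window + 1):n, drop = FALSE] %*% t(w$tail)
  out
}

#' Asymmetric least squares (AsLS) baseline estimation
#'
#' Estimates a smooth baseline `z` minimizing
#' `sum_i w_i (y_i - z_i)^2 + lambda * sum_i (d2 z_i)^2` with weights reset
#' each iteration to `p` where `y > z` and `1 - p` elsewhere (starting from
#' all ones), using second-order finite differences. Peaks, lying above the
#' baseline, are nearly ignored (`p` small) while the fluorescence
#' background is tracked.
#'
#' @param y Numeric spectrum (finite).
#' @param lambda Smoothness weight (> 0), default 1e5.
#' @param p Asymmetry in (0, 1), default 1e-3.
#' @param iterations Reweighting iterations, default 10.
#' @return The baseline vector `z`. Subtract and clip at zero to obtain the
#'   corrected spectrum (see [preprocess()]).
#' @export
asls_baseline <- function(y, lambda = 1e5, p = 1e-3, iterations = 10L) {
  if (any(!is.finite(y))) stop("AsLS input must be finite")
  stopifnot(lambda > 0, p > 0, p < 1, iterations >= 1, length(y) >= 3)
  .asls_baseline_cpp(as.numeric(y), lambda, p, as.integer(iterations))
}

#' Mask low-signal (porosity/gap) pixels
#'
#' Porosities and material-free gaps return only a weak spectrum; a pixel
#' is masked when its total baseline-corrected intensity falls below
#' `low_signal_quantile` times the median total intensity.
#'
#' @param D `N_pixels x B` baseline-corrected matrix (or an
#'   `"unfolded_raman"`).
#' @param config A [preprocess_config()].
#' @return Logical vector, `TRUE` for masked (porosity/gap) pixels.
#' @export
mask_low_signal <- function(D, config = preprocess_config()) {
  if (inherits(D, "unfolded_raman")) D <- D$D
  tot <- rowSums(D)
  mask <- tot < config$low_signal_quantile * stats::median(tot)
  if (all(mask))
    stop("all pixels masked as low signal; review low_signal_quantile")
  mask
}

#' Preprocess a hyperspectral cube
#'
#' Fixed-order chain: unfold, Savitzky-Golay smoothing, AsLS baseline
#' subtraction (negative residuals clipped to zero, since the constrained
#' bilinear unmixing model assumes non-negative data), then low-signal
#' porosity masking.
#'
#' @param cube A `"hyper_cube"` (or an `"unfolded_raman"`).
#' @param config A [preprocess_config()].
#' @return Object of class `"preprocessed_raman"`: the unfolded fields plus
#'   `D` (corrected spectra), `mask` (logical, porosity pixels) and
#'   `config`.
#' @export
preprocess <- function(cube, config = preprocess_config()) {
  uf <- if (inherits(cube, "unfolded_raman")) cube else unfold(cube)
  sm <- savgol_smooth_rows(uf$D, config$sg_window, config$sg_polyorder)
  base <- .asls_baseline_mat_cpp(sm, config$asls_lambda, config$asls_p,
                                 config$asls_iterations)
  corr <- sm - base
  corr[corr < 0] <- 0
  uf$D <- corr
  uf$mask <- mask_low_signal(corr, config)
  uf$config <- config
  class(uf) <- c("preprocessed_raman", "unfolded_raman")
  uf
}
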