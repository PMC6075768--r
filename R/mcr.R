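#' Non-negative least squares for many right-hand sides
#'
#' Solves `min ||A X - B||_F` subject to `X >= 0` columnwise, exactly, by
#' enumerating passive (support) sets: for each candidate support the
#' unconstrained normal-equation solution is computed for all columns at
#' once, and each column keeps the feasible candidate with the smallest
#' residual — which is the NNLS optimum, since the optimum coincides with
#' the unconstrained solution on its own passive set. Practical for the
#' small component counts used in curve resolution (`k <= 12`).
#'
#' @param A `m x k` design matrix.
#' @param B `m x n` right-hand sides.
#' @return `k x n` matrix `X >= 0`.
#' @keywords internal
nnls_multi <- function(A, B) {
  k <- ncol(A)
  if (k > 12) stop("passive-set enumeration supports at most 12 components")
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  n <- ncol(B)
  X <- matrix(0, k, n)
  best <- rep(0, n)                      # objective of X = 0 (constant dropped)
  for (code in seq_len(2^k - 1)) {
    s <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    M <- AtA[s, s, drop = FALSE]
    Xs <- tryCatch(solve(M, AtB[s, , drop = FALSE]), error = function(e) NULL)
    if (is.null(Xs)) next
    feas <- colSums(Xs < -1e-10) == 0
    if (!any(feas)) next
    obj <- -2 * colSums(Xs * AtB[s, , drop = FALSE]) +
      colSums(Xs * (M %*% Xs))
    take <- feas & obj < best - 1e-12 * (1 + abs(best))
    if (any(take)) {
      X[, take] <- 0
      X[s, take] <- pmax(Xs[, take, drop = FALSE], 0)
      best[take] <- obj[take]
    }
  }
  X
}

#' Lack of fit of a bilinear reconstruction
#'
#' `LOF(%) = 100 * sqrt(sum((D - C S')^2) / sum(D^2))`; 0 for an exact
#' reconstruction, 100 for the null model `C = 0`.
#'
#' @param D Data matrix (`N x B`).
#' @param C Concentration matrix (`N x k`).
#' @param S Pure-spectra matrix (`B x k`).
#' @return Lack of fit in percent.
#' @export
lack_of_fit <- function(D, C, S) {
  ss <- sum(D^2)
  if (ss == 0) stop("lack of fit undefined for an all-zero data matrix")
  100 * sqrt(sum((D - C %*% t(S))^2) / ss)
}

#' Deterministic purest-variable initialization (SIMPLISMA-style)
#'
#' Selects `k` wavenumber columns of `D` maximizing the purity ratio
#' (column standard deviation over mean, with a noise offset `alpha` equal
#' to 5% of the largest column mean), successively down-weighting columns
#' correlated with those already chosen via the determinant of the
#' normalized correlation-around-the-origin submatrix. Initial pure
#' spectra are then the least-squares spectra of the selected pixel
#' profiles, clipped to be non-negative and unit-max scaled. Fully
#' deterministic.
#'
#' @param D Non-negative `N x B` matrix.
#' @param k Number of components.
#' @param alpha_frac Noise-offset fraction of the maximum column mean.
#' @return `B x k` initial spectra matrix with attribute
#'   `"selected_bands"` (column indices chosen).
#' @export
init_purest_variables <- function(D, k, alpha_frac = 0.05) {
  stopifnot(is.matrix(D), k >= 1, k <= min(dim(D)))
  if (any(D < 0)) stop("D must be non-negative")
  n <- nrow(D)
  mu <- colMeans(D)
  sg <- sqrt(pmax(colSums(D^2) / n - mu^2, 0))
  alpha <- alpha_frac * max(mu)
  purity <- sg / (mu + alpha)
  lam <- sqrt(mu^2 + (sg + alpha)^2)
  COO <- crossprod(D) / n / outer(lam, lam)

  selected <- integer(0)
  for (step in seq_len(k)) {
    w <- vapply(seq_len(ncol(D)), function(j) {
      if (j %in% selected) return(-Inf)
      det(COO[c(j, selected), c(j, selected), drop = FALSE])
    }, numeric(1))
    p <- w * purity
    if (max(p, na.rm = TRUE) <= 1e-12)
      stop("fewer than ", k, " distinguishable columns in D; reduce k")
    selected <- c(selected, which.max(p))
  }

  Ci <- D[, selected, drop = FALSE]
  S <- t(D) %*% Ci %*% solve(crossprod(Ci) +
                               diag(1e-12 * sum(Ci^2), k, k))
  S[S < 0] <- 0
  mx <- apply(S, 2, max)
  if (any(mx == 0)) stop("degenerate initial spectra; reduce k")
  S <- sweep(S, 2, mx, "/")
  attr(S, "selected_bands") <- selected
  S
}

#' Advisory component-count suggestion from the singular spectrum
#'
#' Counts the singular values of `D` (no centering) exceeding a noise
#' floor estimated as `factor` times the median of the trailing half of
#' the singular spectrum. Advisory only: curve resolution is always run
#' with an explicit component count.
#'
#' @param D Data matrix.
#' @param max_k Cap on the suggestion.
#' @param factor Noise-floor multiplier.
#' @return Suggested number of components (integer).
#' @export
select_n_components <- function(D, max_k = 10L, factor = 10) {
  stopifnot(is.matrix(D), length(D) > 0)
  s <- svd(D, nu = 0, nv = 0)$d
  trailing <- s[ceiling(length(s) / 2):length(s)]
  thresh <- max(factor * stats::median(trailing),
                max(s) * length(s) * .Machine$double.eps * 10)
  min(sum(s > thresh), max_k)
}

#' MCR-ALS: multivariate curve resolution by alternating least squares
#'
#' Factorizes the unfolded non-negative data `D ~ C S'` under
#' non-negativity constraints on both the concentration matrix `C` and the
#' pure-spectra matrix `S`. Each half-step is an exact constrained
#' least-squares solve (see [nnls_multi()]), so the lack of fit is
#' non-increasing; after each iteration the columns of `S` are rescaled to
#' unit maximum and the scale absorbed into `C` (resolving the intensity
#' ambiguity; component order remains arbitrary).
#'
#' @param D Non-negative `N_pixels x B` matrix (masked pixels excluded), or
#'   a `"preprocessed_raman"` object (its unmasked rows are used).
#' @param k Number of components (>= 1), or `"auto"` to take the advisory
#'   suggestion of [select_n_components()].
#' @param max_iterations Iteration cap (default 200).
#' @param tol Relative lack-of-fit change threshold (default 1e-4).
#' @param init `"purest_variables"` (default, deterministic) or
#'   `"provided"` (pass `S_init`).
#' @param S_init Optional `B x k` initial spectra when `init = "provided"`.
#' @return Object of class `"mcr_result"`: `C` (`N x k`), `S` (`B x k`,
#'   unit-max columns), `lof_history` (% per iteration),
#'   `explained_variance` (%), `converged`, `n_iterations`, `axis` (when
#'   available).
#' @export
mcr_als <- function(D, k, max_iterations = 200L, tol = 1e-4,
                    init = c("purest_variables", "provided"),
                    S_init = NULL) {
  axis <- NULL
  if (inherits(D, "preprocessed_raman")) {
    axis <- D$axis
    D <- D$D[!D$mask, , drop = FALSE]
  } else if (inherits(D, "unfolded_raman")) {
    axis <- D$axis
    D <- D$D
  }
  stopifnot(is.matrix(D))
  if (any(!is.finite(D))) stop("D must be finite")
  if (any(D < 0)) stop("D must be non-negative")
  init <- match.arg(init)
  if (identical(k, "auto")) {
    k <- select_n_components(D)
    if (k < 1)
      stop("degenerate singular spectrum; specify an explicit k")
  }
  stopifnot(k >= 1, k <= min(dim(D)), tol > 0, max_iterations >= 1)

  S <- if (init == "provided") {
    if (is.null(S_init)) stop("init = 'provided' requires S_init")
    stopifnot(nrow(S_init) == ncol(D), ncol(S_init) == k)
    sweep(S_init, 2, apply(S_init, 2, max), "/")
  } else {
    init_purest_variables(D, k)
  }

  lof_history <- numeric(0)
  lof_prev <- Inf
  converged <- FALSE
  C <- NULL
  for (it in seq_len(max_iterations)) {
    C <- t(nnls_multi(S, t(D)))
    S <- t(nnls_multi(C, D))
    mx <- apply(S, 2, max)
    if (any(mx == 0))
      stop("component ", paste(which(mx == 0), collapse = ", "),
           " collapsed to zero; reduce k")
    S <- sweep(S, 2, mx, "/")
    C <- sweep(C, 2, mx, "*")
    lof <- lack_of_fit(D, C, S)
    if (lof > lof_prev + 1e-6)
      stop("lack of fit increased between iterations (",
           format(lof_prev), " -> ", format(lof),
           "); constrained ALS implementation error")
    lof_history <- c(lof_history, lof)
    # converged when the relative LOF change falls below tol, or at an
    # effectively exact fit (LOF in percent)
    if (lof < 1e-7 ||
        (is.finite(lof_prev) &&
         abs(lof_prev - lof) / max(lof_prev, 1e-12) < tol)) {
      converged <- TRUE
      break
    }
    lof_prev <- lof
  }
  lof <- lof_history[length(lof_history)]
  structure(list(C = C, S = S, lof_history = lof_history,
                 lof = lof,
                 explained_variance = 100 * (1 - (lof / 100)^2),
                 converged = converged,
                 n_iterations = length(lof_history),
                 k = k, axis = axis),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<mcr_result: %d components, %d pixels x %d bands, LOF %.4g%%, ",
    "explained variance %.4g%%, %d iterations%s>\n"),
    x$k, nrow(x$C), nrow(x$S), x$lof, x$explained_variance,
    x$n_iterations, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Tidy / glance methods for MCR fits
#'
#' `tidy()` returns one row per resolved component (its main-peak
#' wavenumber when the axis is known, and its share of total
#' concentration); `glance()` a one-row fit summary.
#'
#' @param x An `"mcr_result"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mcr_result <- function(x, ...) {
  peak <- if (!is.null(x$axis)) x$axis[apply(x$S, 2, which.max)]
          else rep(NA_real_, x$k)
  csum <- colSums(x$C)
  tibble::tibble(component = seq_len(x$k),
                 main_peak_cm1 = as.numeric(peak),
                 concentration_share = csum / sum(csum))
}

#' @rdname tidy.mcr_result
#' @export
glance.mcr_result <- function(x, ...) {
  tibble::tibble(k = x$k, lof = x$lof,
                 explained_variance = x$explained_variance,
                 n_iterations = x$n_iterations, converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot resolved pure spectra
#'
#' @param object An `"mcr_result"` with a known axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcr_result <- function(object, ...) {
  if (is.null(object$axis)) stop("mcr_result carries no wavenumber axis")
  df <- tibble::tibble(
    wavenumber = rep(as.numeric(object$axis), object$k),
    intensity = as.vector(object$S),
    component = factor(rep(seq_len(object$k), each = nrow(object$S))))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "intensity (unit-max)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
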