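# shared fixtures and independent oracles used across the suite

# reduced axis covering the main bands of the phosphate/oxalate species;
# keeps module tests fast while the acceptance suite uses the full axis
test_axis <- function() wavenumber_axis(900, 1600, 2)

# align resolved components to truth spectra by maximum Pearson correlation
# (greedy); returns the permutation perm with resolved[, j] ~ truth[, perm[j]]
align_components <- function(S_res, S_true) {
  R <- stats::cor(S_res, S_true)
  k <- ncol(S_res)
  perm <- rep(NA_integer_, k)
  for (step in seq_len(k)) {
    ij <- which(R == max(R), arr.ind = TRUE)[1, ]
    perm[ij[1]] <- ij[2]
    R[ij[1], ] <- -Inf
    R[, ij[2]] <- -Inf
  }
  perm
}

# independent constrained-ALS oracle: projected gradient on C and S in turn,
# run to tight convergence; no shared code with the package's NNLS solver
pg_als_oracle <- function(D, k, S0, outer_iter = 300, inner_iter = 400) {
  S <- S0
  C <- matrix(stats::runif(nrow(D) * k), nrow(D), k)
  pg_solve <- function(A, B, X) {
    # min ||A X - B||_F, X >= 0 by projected gradient with fixed step
    L <- max(eigen(crossprod(A), only.values = TRUE)$values)
    AtB <- crossprod(A, B)
    AtA <- crossprod(A)
    for (i in seq_len(inner_iter)) {
      X <- pmax(X - (AtA %*% X - AtB) / L, 0)
    }
    X
  }
  for (it in seq_len(outer_iter)) {
    C <- t(pg_solve(S, t(D), t(C)))
    S <- t(pg_solve(C, D, t(S)))
  }
  list(C = C, S = S, lof = lack_of_fit(D, C, S))
}

# penalized weighted least-squares AsLS oracle built on sparse Matrix
# factorizations, iterated until the asymmetric weights are stable
asls_oracle <- function(y, lambda, p, max_iter = 100) {
  n <- length(y)
  D2 <- Matrix::bandSparse(n - 2, n,
                           k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D2)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(max_iter)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(n, w) + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

# Savitzky-Golay oracle: explicit per-window least-squares polynomial fit
savgol_oracle <- function(y, window, polyorder) {
  n <- length(y)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i <= h) { lo <- 1; x0 <- i }
    else if (i > n - h) { lo <- n - window + 1; x0 <- i - lo + 1 }
    else { lo <- i - h; x0 <- h + 1 }
    win <- y[lo:(lo + window - 1)]
    xs <- seq_len(window)
    fit <- stats::lm(win ~ poly(xs, polyorder, raw = TRUE))
    out[i] <- unname(stats::predict(fit, data.frame(xs = x0)))
  }
  out
}

# tiny mixed-composition phantom used by the io and cli tests
small_phantom <- function(seed = 17) {
  spec <- phantom_spec(c(8, 8), 50,
                       list(region_annulus(c(COD = 0.6, apatite = 0.4),
                                           mixture_outer = c(COD = 0.2,
                                                             apatite = 0.8))),
                       seed = seed)
  generate_phantom(spec, axis = wavenumber_axis(900, 1100, 2))
}

# rmse after aligning resolved concentration maps to truth fractions
aligned_c_rmse <- function(C_res, F_true, perm) {
  sqrt(mean((C_res - F_true[, perm, drop = FALSE])^2))
}
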