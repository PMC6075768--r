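test_that("lack of fit behaves as an exact-fit, null-model and homogeneous diagnostic", {
  withr::with_seed(1, {
    C <- matrix(stats::runif(40), 20, 2)
    S <- matrix(stats::runif(30), 15, 2)
  })
  D <- C %*% t(S)
  expect_equal(lack_of_fit(D, C, S), 0)
  expect_equal(lack_of_fit(D, C * 0, S), 100)
  # halving the reconstruction doubles the residual and hence the LOF
  expect_equal(lack_of_fit(D, 0.5 * C, S),
               2 * lack_of_fit(D, 0.75 * C, S))
  expect_error(lack_of_fit(D * 0, C, S), "all-zero")
})

test_that("the enumeration NNLS solver agrees with an independent NNLS oracle", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      A <- matrix(stats::rnorm(30 * 4), 30, 4)
      B <- matrix(stats::rnorm(30 * 3), 30, 3)
    })
    X <- ramanstones:::nnls_multi(A, B)
    expect_true(all(X >= 0))
    for (j in 1:3) {
      ref <- pracma::lsqnonneg(A, B[, j])$x
      expect_equal(unname(X[, j]), ref, tolerance = 1e-6)
    }
  }
})

test_that("purest-variable initialization recovers pure profiles deterministically", {
  ax <- test_axis()
  lib <- default_library()
  sA <- render_spectrum(lib, "apatite", ax)
  sB <- render_spectrum(lib, "COD", ax)

  # rank-1 case
  withr::with_seed(2, c1 <- stats::runif(80, 0.2, 1))
  D1 <- c1 %*% t(sA)
  S1 <- init_purest_variables(D1, 1)
  expect_gt(stats::cor(S1[, 1], sA), 0.99)

  # two species on disjoint pixel sets: assignment is a bijection
  withr::with_seed(3, {
    ca <- stats::runif(40, 0.2, 1)
    cb <- stats::runif(40, 0.2, 1)
  })
  D2 <- rbind(ca %*% t(sA), cb %*% t(sB))
  S2 <- init_purest_variables(D2, 2)
  perm <- align_components(S2, cbind(sA, sB))
  expect_setequal(perm, 1:2)
  expect_gt(min(diag(stats::cor(S2, cbind(sA, sB))[, perm])), 0.95)

  expect_identical(init_purest_variables(D2, 2),
                   init_purest_variables(D2, 2))
  expect_error(init_purest_variables(matrix(1, 10, 5), 3),
               "distinguishable")
})

test_that("MCR-ALS solves the noiseless separable rank-1 problem exactly", {
  ax <- test_axis()
  s <- render_spectrum(default_library(), "struvite", ax)
  withr::with_seed(4, cc <- stats::runif(60, 0.1, 1))
  D <- cc %*% t(s)
  fit <- mcr_als(D, 1)
  expect_lt(fit$lof, 1e-6)
  expect_gt(stats::cor(fit$S[, 1], s), 0.9999)
  expect_gt(stats::cor(fit$C[, 1], cc), 0.9999)
})

test_that("MCR-ALS recovers a noiseless three-component concentric phantom", {
  ax <- wavenumber_axis()
  spec <- phantom_spec(c(24, 24), 50, list(
    region_annulus(c(COD = 1), 0, 0.45),
    region_annulus(c(ammonium_urate = 1), 0.45, 0.75),
    region_annulus(c(n_acetyl_sulfamethoxazole = 1), 0.75, 1)),
    baseline_params = list(amplitude = 0, center = 300, width = 900),
    noise_params = list(sd = 0, prop = 0), seed = 5)
  ph <- generate_phantom(spec, axis = ax)
  uf <- unfold(ph$cube)
  fit <- mcr_als(uf$D, 3)
  S_true <- render_library(default_library(), ax)[, ph$truth$species]
  perm <- align_components(fit$S, S_true)
  expect_setequal(perm, 1:3)
  expect_gt(min(diag(stats::cor(fit$S, S_true)[, perm])), 0.99)
  Fm <- apply(ph$truth$fractions, 3, identity)
  lin <- (uf$pixel_index[, 2] - 1) * 24 + uf$pixel_index[, 1]
  expect_lt(aligned_c_rmse(fit$C, Fm[lin, ], perm), 0.02)
})

test_that("LOF is monotone non-increasing and factors stay non-negative on random instances", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      C0 <- matrix(stats::runif(120 * 3), 120, 3)
      S0 <- matrix(stats::runif(60 * 3)^2, 60, 3)
      E <- matrix(stats::rnorm(120 * 60, sd = 0.02), 120, 60)
    })
    D <- pmax(C0 %*% t(S0) + E, 0)
    fit <- mcr_als(D, 3, tol = 1e-8, max_iterations = 80)
    expect_true(all(diff(fit$lof_history) <= 1e-8))
    expect_true(all(fit$C >= 0))
    expect_true(all(fit$S >= 0))
    expect_equal(fit$explained_variance,
                 100 * (1 - (fit$lof / 100)^2))
  }
})

test_that("final LOF matches an independent projected-gradient constrained ALS oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      k <- sample(2:4, 1)
      n <- sample(60:200, 1)
      b <- sample(40:100, 1)
      C0 <- matrix(stats::runif(n * k), n, k)
      S0 <- matrix(stats::runif(b * k)^2, b, k)
      E <- matrix(stats::rnorm(n * b, sd = 0.05), n, b)
    })
    D <- pmax(C0 %*% t(S0) + E, 0)
    fit <- mcr_als(D, k, tol = 1e-9, max_iterations = 300)
    withr::with_seed(seed + 1000,
      oracle <- pg_als_oracle(D, k, init_purest_variables(D, k)))
    expect_lt(abs(fit$lof - oracle$lof), 0.5)
  }
})

test_that("MCR-ALS recovers spectra and maps from seeded noisy phantoms", {
  ph <- generate_phantom(phantom_minor_inclusion(c(32, 32),
                                                 inclusion_percent = 8,
                                                 seed = 9))
  pp <- preprocess(ph$cube)
  fit <- mcr_als(pp, 4)
  S_true <- render_library(default_library(), ph$cube$axis)[, ph$truth$species]
  perm <- align_components(fit$S, S_true)
  expect_setequal(perm, 1:4)
  cors <- diag(stats::cor(fit$S, S_true)[, perm])
  expect_gte(mean(cors), 0.95)
  Fm <- apply(ph$truth$fractions, 3, identity)
  lin <- (pp$pixel_index[, 2] - 1) * 32 + pp$pixel_index[, 1]
  keep <- !pp$mask
  expect_lte(aligned_c_rmse(fit$C[keep, , drop = FALSE],
                            Fm[lin, , drop = FALSE][keep, , drop = FALSE],
                            perm), 0.05)
})

test_that("the component-count heuristic reads the singular spectrum", {
  ax <- test_axis()
  S3 <- render_library(default_library(), ax)[, c("COD", "apatite",
                                                  "struvite")]
  withr::with_seed(10, C3 <- matrix(stats::runif(150 * 3), 150, 3))
  D3 <- C3 %*% t(S3)
  expect_equal(select_n_components(D3), 3)
  withr::with_seed(11,
    Dn <- pmax(D3 + matrix(stats::rnorm(length(D3), sd = 0.01),
                           nrow(D3)), 0))
  expect_equal(select_n_components(Dn), 3)            # SNR ~ 50
  D1 <- C3[, 1] %*% t(S3[, 1])
  expect_equal(select_n_components(D1), 1)
})

test_that("tidy and glance summarise an MCR fit", {
  ax <- test_axis()
  s <- render_spectrum(default_library(), "COD", ax)
  withr::with_seed(12, cc <- stats::runif(40, 0.1, 1))
  uf <- structure(list(D = cc %*% t(s), axis = ax), class = "unfolded_raman")
  fit <- mcr_als(uf, 1)
  td <- tidy(fit)
  expect_equal(td$main_peak_cm1, main_peak(s, ax))
  expect_equal(td$concentration_share, 1)
  gl <- glance(fit)
  expect_equal(gl$k, 1)
  expect_true(gl$converged)
})

test_that("invalid unmixing inputs are rejected", {
  D <- matrix(stats::runif(60), 10, 6)
  expect_error(mcr_als(D - 1, 2), "non-negative")
  expect_error(mcr_als(D, 20), "k <= ")
  expect_error(mcr_als(D, 2, init = "provided"), "S_init")
})
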