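test_that("exact library spectra are matched perfectly and permutation-invariantly", {
  ax <- test_axis()
  lib <- default_library()
  sp <- c("COD", "apatite", "brushite", "struvite")
  S <- render_library(lib, ax)[, sp]
  asg <- match_to_library(S, lib, ax)
  expect_equal(asg$species, sp)
  expect_equal(asg$correlation, rep(1, 4), tolerance = 1e-12)
  expect_true(all(asg$detected))
  expect_false(any(duplicated(asg$species)))        # injective

  # shuffling component order never changes the detected species set
  perm <- c(3, 1, 4, 2)
  asg2 <- match_to_library(S[, perm], lib, ax)
  expect_setequal(asg2$species, sp)
  expect_equal(asg2$species, sp[perm])
})

test_that("a noise component is reported unidentified", {
  ax <- test_axis()
  lib <- default_library()
  S_true <- render_library(lib, ax)[, c("COD", "apatite")]
  withr::with_seed(31, noise <- abs(stats::rnorm(length(ax))))
  asg <- match_to_library(cbind(S_true, noise / max(noise)), lib, ax)
  expect_true(all(asg$detected[1:2]))
  expect_false(asg$detected[3])
  expect_true(is.na(asg$species[3]))
  expect_lt(asg$correlation[3], 0.5)
})

test_that("resolved COM spectra are assigned to the variant with matching main peak", {
  ax <- wavenumber_axis()
  lib <- default_library()
  sA <- render_spectrum(lib, "COM_typeA", ax)
  asg <- match_to_library(matrix(sA, ncol = 1), lib, ax)
  expect_equal(asg$species, "COM_typeA")
  expect_equal(main_peak(sA, ax), 1487)
  expect_equal(main_peak(render_spectrum(lib, "COM_typeB", ax), ax), 1462)
  expect_error(match_to_library(matrix(sA[-1], ncol = 1), lib, ax),
               "axis mismatch")
})

test_that("main_peak breaks ties toward the lowest wavenumber", {
  ax <- wavenumber_axis(400, 1200, 2)
  y <- numeric(length(ax))
  y[which(ax == 500)] <- 1
  y[which(ax == 1000)] <- 1
  expect_equal(main_peak(y, ax), 500)
  expect_error(main_peak(numeric(length(ax)), ax), "all-zero")
})

test_that("refolded maps place concentrations at their pixels and zero elsewhere", {
  ax <- test_axis()
  spec <- phantom_spec(c(16, 16), 50, list(region_annulus(c(COD = 1))),
                       baseline_params = list(amplitude = 0, center = 300,
                                              width = 900),
                       noise_params = list(sd = 0, prop = 0), seed = 1)
  ph <- generate_phantom(spec, axis = ax)
  uf <- unfold(ph$cube)
  fit <- mcr_als(uf$D, 1)
  maps <- refold_maps(fit$C, uf$pixel_index, uf$shape, 50, ph$cube$support,
                      species = "COD")
  m <- maps$values[, , 1]
  expect_true(all(m[!ph$cube$support] == 0))        # nonzero only on support
  expect_lt(stats::sd(m[ph$cube$support]) / mean(m[ph$cube$support]), 0.01)

  # refolding the truth fractions reproduces the truth maps exactly
  Fm <- apply(ph$truth$fractions, 3, identity)
  lin <- (uf$pixel_index[, 2] - 1) * 16 + uf$pixel_index[, 1]
  maps_t <- refold_maps(Fm[lin, , drop = FALSE], uf$pixel_index, uf$shape,
                        50, ph$cube$support, species = ph$truth$species)
  expect_equal(maps_t$values[, , 1], ph$truth$fractions[, , 1])

  expect_error(refold_maps(fit$C[-1, , drop = FALSE], uf$pixel_index,
                           uf$shape, 50, ph$cube$support), "rows")
})

test_that("pixel fractions sum to 100 and reflect the drawn areas", {
  # single species: 100%
  maps1 <- refold_maps(matrix(1, 9, 1), cbind(rep(1:3, each = 3), 1:3),
                       c(3, 3), 50, matrix(TRUE, 3, 3), species = "COD")
  pf1 <- pixel_fraction(maps1)
  expect_equal(pf1$percent, 100)

  # two species on equal halves: 50/50
  C <- cbind(c(rep(1, 8), rep(0, 8)), c(rep(0, 8), rep(1, 8)))
  idx <- cbind(rep(1:4, each = 4), rep(1:4, 4))
  maps2 <- refold_maps(C, idx, c(4, 4), 50, matrix(TRUE, 4, 4),
                       species = c("a", "b"))
  pf2 <- pixel_fraction(maps2)
  expect_equal(pf2$percent, c(50, 50))
  expect_equal(sum(pf2$percent), 100)

  # a 5% inclusion occupies 5% of the dominant-label area
  ph <- generate_phantom(phantom_minor_inclusion(c(64, 64),
                                                 inclusion_percent = 5,
                                                 seed = 33),
                         axis = test_axis())
  uf <- unfold(ph$cube)
  Fm <- apply(ph$truth$fractions, 3, identity)
  lin <- (uf$pixel_index[, 2] - 1) * 64 + uf$pixel_index[, 1]
  maps3 <- refold_maps(Fm[lin, ], uf$pixel_index, uf$shape, 50,
                       ph$cube$support, species = ph$truth$species)
  pf3 <- pixel_fraction(maps3)
  expect_equal(sum(pf3$percent), 100)
  expect_equal(pf3$percent[pf3$species == "COM_typeA"], 5, tolerance = 0.1)
})

test_that("ray-cast layer thickness measures shells in physical units", {
  # annulus exactly 3 pixels thick at 50 um step: 150 um on axis rays
  H <- 41
  ctr <- (H + 1) / 2
  rr <- sqrt(outer((1:H - ctr)^2, (1:H - ctr)^2, `+`))
  shell <- rr >= 13 & rr < 16
  lt <- layer_thickness(shell, 50, n_rays = 36)
  east <- lt$per_ray_um[1]                          # ray at angle 0
  expect_equal(east, 150, tolerance = 0.1)
  expect_equal(lt$mean_um, 150, tolerance = 0.15)
  expect_true(lt$is_shell)

  # a full disc is not a shell: thickness ~ its radius, flagged
  disc <- rr < 16
  ltd <- layer_thickness(disc, 50, n_rays = 36)
  expect_equal(ltd$mean_um, 16 * 50, tolerance = 0.15)
  expect_false(ltd$is_shell)

  expect_error(layer_thickness(matrix(0, 5, 5), 50), "nowhere")
})

test_that("radial organization score separates sectors, noise and rings", {
  H <- 64
  ctr <- H / 2
  dx <- outer(rep(1, H), 1:H - 0.5) - ctr
  dy <- outer(1:H - 0.5, rep(1, H)) - ctr
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) %% (2 * pi)
  on <- rr <= 28

  # 8 alternating sectors: high score
  sect <- matrix(0L, H, H)
  sect[on] <- 1L + (floor(th[on] / (2 * pi / 8)) %% 2)
  expect_gte(radial_organization_score(sect)$score, 0.9)

  # uniformly random labels: low score across seeds
  for (seed in 1:10) {
    rnd <- matrix(0L, H, H)
    withr::with_seed(seed,
      rnd[on] <- sample(1:2, sum(on), replace = TRUE))
    expect_lte(radial_organization_score(rnd)$score, 0.6)
  }

  # concentric alternating rings (lamellar, not radial): lower than random
  ring <- matrix(0L, H, H)
  ring[on] <- 1L + (floor(rr[on]) %% 2)
  expect_lt(radial_organization_score(ring)$score, 0.3)

  mono <- matrix(0L, H, H); mono[on] <- 1L
  res <- radial_organization_score(mono)
  expect_true(res$monovariant)
  expect_true(is.na(res$score))
})
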