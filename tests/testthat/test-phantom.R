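noiseless <- function(spec) {
  spec$baseline_params$amplitude <- 0
  spec$noise_params$sd <- 0
  spec$noise_params$prop <- 0
  spec
}

test_that("a single-species noiseless phantom reproduces the pure spectrum at every pixel", {
  ax <- test_axis()
  spec <- phantom_spec(c(16, 16), 50, list(region_annulus(c(COD = 1))),
                       baseline_params = list(amplitude = 0, center = 300,
                                              width = 900),
                       noise_params = list(sd = 0, prop = 0), seed = 1)
  ph <- generate_phantom(spec, axis = ax)
  s <- render_spectrum(default_library(), "COD", ax)
  uf <- unfold(ph$cube)
  expect_true(all(apply(uf$D, 1, function(row) identical(row, s))))
})

test_that("the noiseless cube is exactly bilinear in fractions and pure spectra", {
  ax <- test_axis()
  ph <- generate_phantom(noiseless(phantom_core_gap_composite(c(24, 24),
                                                              seed = 2)),
                         axis = ax)
  uf <- unfold(ph$cube)
  Fm <- apply(ph$truth$fractions, 3, identity)     # (H*W) x n_species
  lin <- (uf$pixel_index[, 2] - 1) * 24 + uf$pixel_index[, 1]
  S <- render_library(default_library(), ax)[, ph$truth$species]
  expect_equal(uf$D, Fm[lin, ] %*% t(S), tolerance = 1e-14)
})

test_that("truth fractions are a valid probability field and support is conserved", {
  ph <- generate_phantom(phantom_core_gap_composite(c(32, 32), seed = 3),
                         axis = test_axis())
  fr <- ph$truth$fractions
  tot <- apply(fr, c(1, 2), sum)
  material <- ph$cube$support & !ph$truth$gap_mask
  expect_equal(unname(tot[material]), rep(1, sum(material)), tolerance = 1e-9)
  expect_true(all(tot[!material] == 0))
  expect_true(all(fr >= 0 & fr <= 1))
  # every support pixel belongs to exactly one region
  expect_equal(sum(!is.na(ph$truth$region_id[ph$cube$support])),
               sum(ph$cube$support))
  expect_true(all(is.na(ph$truth$region_id[!ph$cube$support])))
})

test_that("radial sector layout partitions the disc into equal alternating sectors", {
  expect_error(radial_sector_layout(1), ">= 2")
  expect_error(radial_sector_layout(3), "even")
  spec <- phantom_spec(c(64, 64), 50, radial_sector_layout(8), seed = 1)
  ph <- generate_phantom(noiseless(spec), axis = test_axis())
  counts <- table(ph$truth$region_id[ph$cube$support])
  expect_length(counts, 8)
  expect_lt(max(counts) - min(counts), 0.1 * mean(counts))
  # partition: fractions still sum to 1 everywhere on support
  tot <- apply(ph$truth$fractions, c(1, 2), sum)
  expect_equal(unname(tot[ph$cube$support]),
               rep(1, sum(ph$cube$support)))
  # 2 sectors split the disc through the centre into equal halves
  spec2 <- phantom_spec(c(64, 64), 50, radial_sector_layout(2), seed = 1)
  ph2 <- generate_phantom(noiseless(spec2), axis = test_axis())
  counts2 <- table(ph2$truth$region_id[ph2$cube$support])
  expect_lt(abs(counts2[1] - counts2[2]), 0.05 * mean(counts2))
})

test_that("generation is deterministic under a fixed seed and varies across seeds", {
  ax <- test_axis()
  spec <- phantom_minor_inclusion(c(20, 20), seed = 11)
  a <- generate_phantom(spec, axis = ax)
  b <- generate_phantom(spec, axis = ax)
  expect_identical(a$cube$intensities, b$cube$intensities)
  spec2 <- phantom_minor_inclusion(c(20, 20), seed = 12)
  c <- generate_phantom(spec2, axis = ax)
  expect_false(identical(a$cube$intensities, c$cube$intensities))
})

test_that("baseline and noise injection honours its parameters", {
  ax <- test_axis()
  B <- length(ax)
  clean <- array(1, dim = c(50, 50, B))            # constant unit signal
  # amplitude 0, sd 0: exact identity
  same <- add_baseline_and_noise(clean, ax,
                                 list(amplitude = 0, center = 300,
                                      width = 900),
                                 list(sd = 0, prop = 0), seed = 5)
  expect_identical(same, clean)
  # additive-only noise: per-band sample sd over many pixels ~ sigma
  noisy <- add_baseline_and_noise(clean, ax,
                                  list(amplitude = 0, center = 300,
                                       width = 900),
                                  list(sd = 0.05, prop = 0), seed = 5)
  expect_equal(stats::sd(noisy - clean), 0.05, tolerance = 0.05)
  # baseline is positive, smooth and broad
  based <- add_baseline_and_noise(clean * 0, ax,
                                  list(amplitude = 1, center = 300,
                                       width = 900),
                                  list(sd = 0, prop = 0), seed = 5)
  expect_true(all(based >= 0))
  expect_true(all(abs(diff(based[1, 1, ])) < 0.01))
})

test_that("the drug shell of the radial phantom is 20 pixels thick at 5 um step", {
  ph <- generate_phantom(noiseless(phantom_radial_com_drug(seed = 4)),
                         axis = test_axis())
  drug <- match("n_acetyl_sulfamethoxazole", ph$truth$species)
  lab <- ph$truth$labels
  centre <- nrow(lab) / 2
  east <- lab[centre, centre:ncol(lab)]             # axis-aligned ray
  run <- rle(east)
  expect_equal(run$lengths[run$values == drug][1], 20, tolerance = 0.06)
})

test_that("the minor inclusion occupies its requested share of support pixels", {
  for (pct in c(5, 10)) {
    ph <- generate_phantom(noiseless(phantom_minor_inclusion(
      c(64, 64), inclusion_percent = pct, seed = 6)), axis = test_axis())
    com <- match("COM_typeA", ph$truth$species)
    share <- 100 * sum(ph$truth$labels == com) / sum(ph$cube$support)
    expect_equal(share, pct, tolerance = 0.5 / pct)  # within 0.5 pp
  }
})

test_that("invalid phantom specifications are rejected", {
  expect_error(generate_phantom(phantom_spec(
    c(16, 16), 50, list(region_annulus(c(unknownium = 1))))),
    "absent from library")
  expect_error(generate_phantom(phantom_spec(
    c(16, 16), 50,
    list(region_annulus(c(COD = 1)),
         region_disc(c(apatite = 1), cx = 0, cy = 0, radius = 1e-4)))),
    "zero pixel area")
  expect_error(check_region <- phantom_spec(
    c(16, 16), 50, list(region_annulus(c(COD = 0.5)))),
    "sum to 1")
  # uncovered support pixels
  expect_error(generate_phantom(phantom_spec(
    c(16, 16), 50, list(region_annulus(c(COD = 1), 0.5, 1)))),
    "do not tile")
})
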