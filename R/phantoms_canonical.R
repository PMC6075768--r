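#' Canonical stone phantoms
#'
#' Four documented phantom layouts emulating the structural motifs seen in
#' sectioned kidney stones:
#'
#' * `phantom_layered_oxalate()` — a COM core under a COD shell with small
#'   internal apatite deposits (oxalate stone with phase conversion).
#' * `phantom_core_gap_composite()` — a material-free central gap (porous
#'   nucleus giving only weak signal), a whitlockite+apatite body with
#'   spatially varying proportions, a thin COD ring and an external
#'   brushite coat: four mineral species plus a porosity.
#' * `phantom_minor_inclusion()` — a majority apatite/struvite/ammonium-
#'   urate stone carrying a small COM inclusion occupying a chosen
#'   percentage of the support pixels (minor-phase detection limit).
#' * `phantom_radial_com_drug()` — a COM core whose two spectral variants
#'   (main peak 1487 vs 1462 cm^-1) alternate in radial sectors, under a
#'   thin surface layer of N-Acetyl-Sulfamethoxazole (default 100 um) at a
#'   5 um step (drug-layer resolution).
#'
#' Baseline and noise defaults are shared: mean fluorescence amplitude 1
#' (comparable to the unit-max Raman peaks, emulating a strong
#' autofluorescence background), a small additive detector-noise floor
#' (sigma 5e-4) and a dominant signal-proportional (shot-like) noise
#' term (scale 0.03, i.e. peak signal-to-noise about 30).
#'
#' @param shape `c(H, W)` pixels.
#' @param step_um Spatial step (um).
#' @param seed Integer seed.
#' @param baseline_amplitude,noise_sd,noise_prop Baseline/noise levels;
#'   set all to 0 for a noiseless phantom.
#' @return A [phantom_spec()].
#' @name canonical_phantoms
NULL

default_bn <- function(baseline_amplitude, noise_sd, noise_prop) {
  list(baseline = list(amplitude = baseline_amplitude, center = 300,
                       width = 900),
       noise = list(sd = noise_sd, prop = noise_prop))
}

#' @rdname canonical_phantoms
#' @export
phantom_layered_oxalate <- function(shape = c(64, 64), step_um = 50,
                                    seed = 1L, baseline_amplitude = 1,
                                    noise_sd = 5e-4, noise_prop = 0.03) {
  bn <- default_bn(baseline_amplitude, noise_sd, noise_prop)
  regions <- list(
    region_annulus(c(COM_typeA = 1), 0, 0.55),
    region_annulus(c(COD = 1), 0.55, 1),
    region_disc(c(apatite = 1), cx = 0.25, cy = 0.18, radius = 0.12),
    region_disc(c(apatite = 1), cx = -0.3, cy = -0.15, radius = 0.10))
  phantom_spec(shape, step_um, regions, bn$baseline, bn$noise, seed)
}

#' @rdname canonical_phantoms
#' @export
phantom_core_gap_composite <- function(shape = c(64, 64), step_um = 50,
                                       seed = 1L, baseline_amplitude = 1,
                                       noise_sd = 5e-4, noise_prop = 0.03) {
  bn <- default_bn(baseline_amplitude, noise_sd, noise_prop)
  regions <- list(
    # body with radially varying whitlockite/apatite proportions
    region_annulus(c(whitlockite = 0.75, apatite = 0.25), 0.18, 0.78,
                   mixture_outer = c(whitlockite = 0.25, apatite = 0.75)),
    region_annulus(c(COD = 1), 0.78, 0.88),        # thin COD ring
    region_annulus(c(brushite = 1), 0.88, 1),      # external coat
    region_gap(0.18))                              # porous nucleus
  phantom_spec(shape, step_um, regions, bn$baseline, bn$noise, seed)
}

#' @rdname canonical_phantoms
#' @param inclusion_percent Percentage of support pixels occupied by the
#'   COM inclusion (disc area = `inclusion_percent`% of the stone disc).
#' @export
phantom_minor_inclusion <- function(shape = c(64, 64), step_um = 50,
                                    inclusion_percent = 5, seed = 1L,
                                    baseline_amplitude = 1,
                                    noise_sd = 5e-4, noise_prop = 0.03) {
  stopifnot(inclusion_percent > 0, inclusion_percent < 40)
  bn <- default_bn(baseline_amplitude, noise_sd, noise_prop)
  r_inc <- sqrt(inclusion_percent / 100)
  regions <- list(
    region_annulus(c(apatite = 0.80, struvite = 0.20), 0, 0.45,
                   mixture_outer = c(apatite = 0.40, struvite = 0.60)),
    region_annulus(c(struvite = 0.70, ammonium_urate = 0.30), 0.45, 0.75,
                   mixture_outer = c(struvite = 0.30, ammonium_urate = 0.70)),
    region_annulus(c(ammonium_urate = 0.85, apatite = 0.15), 0.75, 1),
    region_disc(c(COM_typeA = 1), cx = 0.45 * cos(0.7),
                cy = 0.45 * sin(0.7), radius = r_inc))
  phantom_spec(shape, step_um, regions, bn$baseline, bn$noise, seed)
}

#' @rdname canonical_phantoms
#' @param n_sectors Even number of alternating COM-variant sectors.
#' @param shell_um Drug-shell thickness (um).
#' @export
phantom_radial_com_drug <- function(shape = c(96, 96), step_um = 5,
                                    n_sectors = 8, shell_um = 100,
                                    seed = 1L, baseline_amplitude = 1,
                                    noise_sd = 5e-4, noise_prop = 0.03) {
  bn <- default_bn(baseline_amplitude, noise_sd, noise_prop)
  r_px <- 0.95 * min(shape) / 2
  shell_frac <- shell_um / (r_px * step_um)
  if (shell_frac >= 0.6)
    stop("shell_um too thick for this frame: increase shape or step_um")
  core <- radial_sector_layout(n_sectors, r_inner = 0,
                               r_outer = 1 - shell_frac)
  shell <- region_annulus(c(n_acetyl_sulfamethoxazole = 1),
                          1 - shell_frac, 1)
  phantom_spec(shape, step_um, c(core, list(shell)),
               bn$baseline, bn$noise, seed)
}
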