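#' Hyperspectral cube container
#'
#' @param intensities `H x W x B` non-negative array of Raman intensities
#'   (arbitrary counts units).
#' @param axis Wavenumber axis of length `B`.
#' @param step_um Spatial step between pixel centres (micrometres).
#' @param support `H x W` logical matrix; `TRUE` where the pixel lies on
#'   stone material (including internal porosities/gaps, which are scanned
#'   but yield only baseline and noise), `FALSE` on the background outside
#'   the stone outline.
#' @return An object of class `"hyper_cube"`.
#' @export
hyper_cube <- function(intensities, axis, step_um, support) {
  axis <- validate_axis(axis)
  stopifnot(length(dim(intensities)) == 3,
            dim(intensities)[3] == length(axis),
            is.matrix(support),
            all(dim(support) == dim(intensities)[1:2]),
            is.numeric(step_um), length(step_um) == 1, step_um > 0)
  if (any(intensities < 0)) stop("cube intensities must be non-negative")
  structure(list(intensities = intensities, axis = axis,
                 step_um = step_um, support = support),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<hyper_cube: %d x %d pixels x %d bands, step %.3g um, %d support pixels>\n",
    d[1], d[2], d[3], x$step_um, sum(x$support)))
  invisible(x)
}

# ---- region geometry -------------------------------------------------------
# Regions are described in normalized stone coordinates: radius as a fraction
# of the stone radius, angles in radians. Painter's rule: later regions
# override earlier ones, so inclusions are simply painted last.

#' Region constructors for phantom layouts
#'
#' `region_annulus()` covers a radial band (optionally an angular sector) of
#' the stone disc; `region_disc()` an off-centre disc (inclusions, deposits);
#' `region_gap()` a central material-free gap that stays inside the scanned
#' support but contributes only baseline and noise.
#'
#' @param mixture Named numeric vector of species fractions (sum 1).
#' @param mixture_outer Optional second mixture; when given, fractions vary
#'   linearly with normalized radial position across the region
#'   (`mixture` at the inner edge, `mixture_outer` at the outer edge),
#'   which gives mixed regions spatially varying composition.
#' @param r_inner,r_outer Radial extent as fractions of the stone radius.
#' @param theta_start,theta_end Angular extent (radians, 0 = +x axis).
#' @param cx,cy Disc centre offset from the stone centre, in stone-radius
#'   units.
#' @param radius Disc radius in stone-radius units.
#' @return A region descriptor (list) consumed by [phantom_spec()].
#' @export
region_annulus <- function(mixture, r_inner = 0, r_outer = 1,
                           theta_start = 0, theta_end = 2 * pi,
                           mixture_outer = NULL) {
  check_mixture(mixture)
  if (!is.null(mixture_outer)) check_mixture(mixture_outer)
  stopifnot(r_inner >= 0, r_outer > r_inner, r_outer <= 1 + 1e-9)
  list(type = "annulus", r_inner = r_inner, r_outer = r_outer,
       theta_start = theta_start, theta_end = theta_end,
       mixture = mixture, mixture_outer = mixture_outer)
}

#' @rdname region_annulus
#' @export
region_disc <- function(mixture, cx, cy, radius) {
  check_mixture(mixture)
  stopifnot(radius > 0)
  list(type = "disc", cx = cx, cy = cy, radius = radius,
       mixture = mixture, mixture_outer = NULL)
}

#' @rdname region_annulus
#' @param emission Residual emission of the gap relative to material
#'   (scattered light reaching the detector from a hole); the gap's
#'   fluorescence baseline is scaled by this factor.
#' @export
region_gap <- function(r_outer, emission = 0.02) {
  stopifnot(r_outer > 0, r_outer < 1, emission >= 0, emission <= 1)
  list(type = "gap", r_inner = 0, r_outer = r_outer, mixture = NULL,
       emission = emission)
}

check_mixture <- function(mixture) {
  if (is.null(names(mixture)) || any(!nzchar(names(mixture))))
    stop("region mixtures must be named numeric vectors of species fractions")
  if (any(mixture < 0)) stop("mixture fractions must be >= 0")
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("mixture fractions must sum to 1 (got ", sum(mixture), ")")
  invisible(mixture)
}

#' Radial sector layout for the two COM spectral variants
#'
#' Splits an annulus into `n_sectors` equal angular sectors, alternating two
#' species, emulating COM stones whose two spectral variants organise in
#' radial lines coming from the stone core.
#'
#' @param n_sectors Even integer >= 2.
#' @param species_a,species_b Species alternated across sectors.
#' @param r_inner,r_outer Radial extent (stone-radius units).
#' @return List of sector regions partitioning the annulus.
#' @export
radial_sector_layout <- function(n_sectors, species_a = "COM_typeA",
                                 species_b = "COM_typeB",
                                 r_inner = 0, r_outer = 1) {
  if (n_sectors < 2) stop("sector count must be >= 2")
  if (n_sectors %% 2 != 0) stop("sector count must be even")
  lapply(seq_len(n_sectors), function(s) {
    sp <- if (s %% 2 == 1) species_a else species_b
    region_annulus(stats::setNames(1, sp), r_inner, r_outer,
                   theta_start = 2 * pi * (s - 1) / n_sectors,
                   theta_end = 2 * pi * s / n_sectors)
  })
}

#' Phantom specification
#'
#' Describes a synthetic stone: frame size, spatial step, region layout,
#' fluorescence-baseline and noise parameters, and the random seed that
#' makes generation fully reproducible.
#'
#' @param shape `c(H, W)` pixels.
#' @param step_um Spatial step in micrometres (5-50 um as acquired).
#' @param regions List of region descriptors (see [region_annulus()]);
#'   painted in order, later regions override earlier ones. Together they
#'   must cover the whole stone disc.
#' @param baseline_params List `amplitude` (mean baseline height relative to
#'   unit-max peaks), `center` and `width` (cm^-1) of the broad fluorescence
#'   curve.
#' @param noise_params List `sd` (additive Gaussian sigma) and `prop`
#'   (signal-proportional Gaussian scale).
#' @param seed Integer seed.
#' @param support_radius Stone radius as a fraction of the half frame.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape, step_um, regions,
                         baseline_params = list(amplitude = 1, center = 300,
                                                width = 900),
                         noise_params = list(sd = 5e-4, prop = 0.03),
                         seed = 1L, support_radius = 0.95) {
  stopifnot(length(shape) == 2, all(shape >= 4),
            step_um >= 5, step_um <= 50,
            baseline_params$amplitude >= 0,
            noise_params$sd >= 0, noise_params$prop >= 0,
            support_radius > 0, support_radius <= 1,
            length(regions) >= 1)
  structure(list(shape = as.integer(shape), step_um = step_um,
                 regions = regions, baseline_params = baseline_params,
                 noise_params = noise_params, seed = as.integer(seed),
                 support_radius = support_radius),
            class = "phantom_spec")
}

# normalized polar coordinates of every pixel centre; row-major, origin
# top-left, pixel centres at (i - 0.5, j - 0.5)
pixel_polar <- function(shape, support_radius) {
  H <- shape[1]; W <- shape[2]
  cx <- W / 2; cy <- H / 2
  r_px <- support_radius * (min(H, W) / 2)
  col <- matrix(rep(seq_len(W), each = H), H, W)
  row <- matrix(rep(seq_len(H), W), H, W)
  dx <- (col - 0.5) - cx
  dy <- (row - 0.5) - cy
  r <- sqrt(dx^2 + dy^2) / r_px
  theta <- atan2(dy, dx) %% (2 * pi)
  list(r = r, theta = theta, dx = dx / r_px, dy = dy / r_px, r_px = r_px)
}

#' Generate a phantom hyperspectral cube and its ground truth
#'
#' Builds the noiseless cube by linear mixing of rendered pure spectra
#' (signal at each material pixel is the fraction-weighted sum of the
#' region's species spectra), then adds the per-pixel fluorescence baseline
#' and noise under the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param library Reference band library.
#' @param axis Wavenumber axis.
#' @return List with elements `cube` (a `"hyper_cube"`) and `truth`
#'   (class `"phantom_truth"`: `fractions` `H x W x n_species` array,
#'   `species`, `labels` `H x W` dominant-species index (0 on gap and
#'   background), `gap_mask`, `layers` tibble of annular layer metadata).
#' @export
generate_phantom <- function(spec, library = default_library(),
                             axis = wavenumber_axis()) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  pol <- pixel_polar(spec$shape, spec$support_radius)
  support <- pol$r <= 1

  species <- unique(unlist(lapply(spec$regions, function(rg)
    names(rg$mixture))))
  missing <- setdiff(species, library_species(library))
  if (length(missing))
    stop("species absent from library: ", paste(missing, collapse = ", "))

  region_id <- matrix(NA_integer_, H, W)
  gap_mask <- matrix(FALSE, H, W)
  emission <- matrix(1, H, W)
  for (i in seq_along(spec$regions)) {
    rg <- spec$regions[[i]]
    memb <- switch(rg$type,
      annulus = support & pol$r >= rg$r_inner & pol$r <= rg$r_outer &
        pol$theta >= rg$theta_start & pol$theta < rg$theta_end,
      disc = support &
        sqrt((pol$dx - rg$cx)^2 + (pol$dy - rg$cy)^2) <= rg$radius,
      gap = support & pol$r <= rg$r_outer,
      stop("unknown region type: ", rg$type))
    if (!any(memb)) stop("region ", i, " has zero pixel area")
    region_id[memb] <- i
    gap_mask[memb] <- identical(rg$type, "gap")
    emission[memb] <- if (identical(rg$type, "gap")) rg$emission else 1
  }
  if (any(support & is.na(region_id)))
    stop("regions do not tile the stone support (",
         sum(support & is.na(region_id)), " uncovered pixels)")

  fractions <- array(0, dim = c(H, W, length(species)),
                     dimnames = list(NULL, NULL, species))
  for (i in seq_along(spec$regions)) {
    rg <- spec$regions[[i]]
    if (identical(rg$type, "gap")) next
    idx <- which(region_id == i)
    if (is.null(rg$mixture_outer)) {
      for (sp in names(rg$mixture))
        fractions[idx + (match(sp, species) - 1) * H * W] <- rg$mixture[[sp]]
    } else {
      tt <- pmin(pmax((pol$r[idx] - rg$r_inner) /
                        (rg$r_outer - rg$r_inner), 0), 1)
      all_sp <- union(names(rg$mixture), names(rg$mixture_outer))
      for (sp in all_sp) {
        fi <- if (sp %in% names(rg$mixture)) rg$mixture[[sp]] else 0
        fo <- if (sp %in% names(rg$mixture_outer)) rg$mixture_outer[[sp]] else 0
        fractions[idx + (match(sp, species) - 1) * H * W] <-
          (1 - tt) * fi + tt * fo
      }
    }
  }

  Smat <- render_library(library, axis)[, species, drop = FALSE]
  Fm <- matrix(fractions, H * W, length(species))
  clean <- Fm %*% t(Smat)                       # (H*W) x B, zero off material
  cube_arr <- array(clean, dim = c(H, W, length(axis)))

  cube_arr <- add_baseline_and_noise(cube_arr, axis, spec$baseline_params,
                                     spec$noise_params, spec$seed,
                                     emission = emission)

  labels <- matrix(0L, H, W)
  mat_px <- which(rowSums(Fm) > 0)
  labels[mat_px] <- max.col(Fm[mat_px, , drop = FALSE], ties.method = "first")

  layers <- dplyr::bind_rows(lapply(seq_along(spec$regions), function(i) {
    rg <- spec$regions[[i]]
    if (!identical(rg$type, "annulus")) return(NULL)
    tibble::tibble(region = i,
                   species = paste(names(rg$mixture), collapse = "+"),
                   r_inner_um = rg$r_inner * pol$r_px * spec$step_um,
                   r_outer_um = rg$r_outer * pol$r_px * spec$step_um)
  }))

  truth <- structure(list(fractions = fractions, species = species,
                          labels = labels, gap_mask = gap_mask,
                          layers = layers, region_id = region_id),
                     class = "phantom_truth")
  list(cube = hyper_cube(cube_arr, axis, spec$step_um, support),
       truth = truth)
}

#' Add fluorescence baseline and noise to a clean cube
#'
#' The baseline is a broad positive curve (wide Gaussian in wavenumber,
#' fixed shape) scaled per pixel by a random amplitude uniform in
#' `[0.5, 1.5] x amplitude`; noise is additive Gaussian plus a
#' signal-proportional Gaussian term (heteroscedastic shot-noise proxy).
#' The result is clipped at zero. Fully deterministic under `seed`.
#'
#' @param arr `H x W x B` clean intensity array (or a `"hyper_cube"`).
#' @param axis Wavenumber axis.
#' @param baseline_params,noise_params See [phantom_spec()].
#' @param seed Integer seed.
#' @param emission Scalar or `H x W` matrix scaling the baseline amplitude
#'   per pixel (porosities/gaps emit only a small fraction of the
#'   material fluorescence).
#' @return Array (or cube) of the same shape.
#' @export
add_baseline_and_noise <- function(arr, axis, baseline_params, noise_params,
                                   seed, emission = 1) {
  is_cube <- inherits(arr, "hyper_cube")
  x <- if (is_cube) arr$intensities else arr
  d <- dim(x)
  n_px <- d[1] * d[2]; B <- d[3]
  stopifnot(B == length(axis),
            baseline_params$amplitude >= 0,
            noise_params$sd >= 0, noise_params$prop >= 0)
  if (any(!is.finite(x))) stop("cube intensities must be finite")
  m <- matrix(x, n_px, B)
  withr::with_seed(seed, {
    if (baseline_params$amplitude > 0) {
      shape <- exp(-((as.numeric(axis) - baseline_params$center) /
                       baseline_params$width)^2)
      amp <- baseline_params$amplitude * stats::runif(n_px, 0.5, 1.5) *
        as.vector(emission)
      m <- m + outer(amp, shape)
    }
    if (noise_params$sd > 0)
      m <- m + stats::rnorm(n_px * B, sd = noise_params$sd)
    if (noise_params$prop > 0)
      m <- m + stats::rnorm(n_px * B) * (noise_params$prop * m)
  })
  m[m < 0] <- 0
  out <- array(m, dim = d)
  if (is_cube) hyper_cube(out, arr$axis, arr$step_um, arr$support) else out
}
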