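#' Match resolved spectra to the reference library
#'
#' Greedy maximum-correlation bipartite assignment: the highest
#' component-species Pearson correlation is assigned first, both are
#' removed, and the process repeats, so no species is claimed twice.
#' Components whose best remaining correlation falls below `threshold`
#' are reported as unidentified.
#'
#' @param S `B x k` matrix of resolved spectra (unit-max columns), or an
#'   `"mcr_result"`.
#' @param library Reference band library.
#' @param axis Wavenumber axis shared by `S` and the library rendering.
#' @param threshold Detection threshold on Pearson correlation
#'   (default 0.9).
#' @return Tibble of class `"component_assignment"`: `component`,
#'   `species` (NA when unidentified), `correlation`, `detected`.
#' @export
match_to_library <- function(S, library = default_library(),
                             axis = wavenumber_axis(), threshold = 0.9) {
  if (inherits(S, "mcr_result")) {
    if (!is.null(S$axis)) axis <- S$axis
    S <- S$S
  }
  axis <- validate_axis(axis)
  if (nrow(S) != length(axis))
    stop("spectra have ", nrow(S), " bands but the axis has ",
         length(axis), " points (axis mismatch)")
  L <- render_library(library, axis)
  R <- suppressWarnings(stats::cor(S, L))
  R[!is.finite(R)] <- -Inf
  k <- ncol(S)
  out <- tibble::tibble(component = seq_len(k),
                        species = NA_character_,
                        correlation = NA_real_,
                        detected = FALSE)
  Rw <- R
  repeat {
    if (all(!is.finite(Rw)) || max(Rw) == -Inf) break
    ij <- which(Rw == max(Rw), arr.ind = TRUE)[1, ]
    comp <- ij[1]; sp <- colnames(R)[ij[2]]
    out$species[comp] <- sp
    out$correlation[comp] <- R[ij[1], ij[2]]
    out$detected[comp] <- R[ij[1], ij[2]] >= threshold
    Rw[comp, ] <- -Inf
    Rw[, ij[2]] <- -Inf
    if (all(!is.na(out$species))) break
  }
  out$species[!out$detected] <- NA_character_
  class(out) <- c("component_assignment", class(out))
  out
}

#' Wavenumber of the main peak of a spectrum
#'
#' Returns the axis value at the global maximum; ties are broken toward
#' the lowest wavenumber. Used to discriminate the two COM spectral
#' variants by their 1487 vs 1462 cm^-1 main peak.
#'
#' @param spectrum Non-negative vector, not all zero.
#' @param axis Wavenumber axis of the same length.
#' @return The main-peak wavenumber (cm^-1).
#' @export
main_peak <- function(spectrum, axis = wavenumber_axis()) {
  axis <- validate_axis(axis)
  stopifnot(length(spectrum) == length(axis))
  if (any(spectrum < 0)) stop("spectrum must be non-negative")
  if (all(spectrum == 0)) stop("main peak undefined for an all-zero spectrum")
  as.numeric(axis[which.max(spectrum)])   # which.max takes the first maximum
}

#' Refold concentration columns into 2-D abundance maps
#'
#' @param C `N x k` concentration matrix whose rows align with
#'   `pixel_index` (pixels excluded by the porosity mask must already be
#'   excluded from both).
#' @param pixel_index `N x 2` matrix of (row, col) positions.
#' @param shape `c(H, W)`.
#' @param step_um Spatial step (um).
#' @param support `H x W` logical support mask of the source cube.
#' @param species Optional character vector naming the k components.
#' @return Object of class `"abundance_maps"`: `values` (`H x W x k`
#'   array, zero on non-support/masked pixels), `species`, `step_um`,
#'   `support`, `included` (`H x W` logical: pixels carried by `C`).
#' @export
refold_maps <- function(C, pixel_index, shape, step_um, support,
                        species = NULL) {
  C <- as.matrix(C)
  if (nrow(C) != nrow(pixel_index))
    stop("C has ", nrow(C), " rows but pixel_index has ", nrow(pixel_index))
  if (any(pixel_index[, 1] > shape[1]) || any(pixel_index[, 2] > shape[2]))
    stop("pixel_index exceeds the map shape")
  k <- ncol(C)
  if (is.null(species)) species <- paste0("component_", seq_len(k))
  H <- shape[1]; W <- shape[2]
  vals <- array(0, dim = c(H, W, k), dimnames = list(NULL, NULL, species))
  included <- matrix(FALSE, H, W)
  lin <- (pixel_index[, 2] - 1L) * H + pixel_index[, 1]
  included[lin] <- TRUE
  for (j in seq_len(k)) vals[lin + (j - 1L) * H * W] <- C[, j]
  structure(list(values = vals, species = species, step_um = step_um,
                 support = support, included = included),
            class = "abundance_maps")
}

#' @export
print.abundance_maps <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<abundance_maps: %d x %d pixels, %d components (%s)>\n",
              d[1], d[2], d[3], paste(x$species, collapse = ", ")))
  invisible(x)
}

# H x W integer matrix of dominant component per included pixel (0 outside)
dominant_labels <- function(maps) {
  d <- dim(maps$values)
  m <- matrix(maps$values, d[1] * d[2], d[3])
  lab <- matrix(0L, d[1], d[2])
  idx <- which(maps$included)
  lab[idx] <- max.col(m[idx, , drop = FALSE], ties.method = "first")
  lab
}

#' Per-species share of the mapped area
#'
#' Fraction (in %) of the unmasked support pixels on which each component
#' has the dominant abundance; shares sum to 100.
#'
#' @param maps An `"abundance_maps"` object.
#' @return Tibble with `species`, `pixels`, `percent`.
#' @export
pixel_fraction <- function(maps) {
  lab <- dominant_labels(maps)
  n <- sum(lab > 0)
  if (n == 0) stop("no included pixels: empty support")
  counts <- tabulate(lab[lab > 0], nbins = length(maps$species))
  tibble::tibble(species = maps$species, pixels = counts,
                 percent = 100 * counts / n)
}

#' Layer thickness by radial ray casting
#'
#' Casts `n_rays` equally spaced rays from the centroid of the layer
#' region and measures, along each ray, the length of the longest
#' contiguous run of pixels belonging to the layer; thickness per ray is
#' that run length times the pixel step. Rays that miss the layer are
#' ignored. A region whose thickness exceeds half the support radius is
#' flagged as not shell-like (a full disc rather than a surface layer).
#'
#' @param map `H x W` numeric abundance map (the layer is where the value
#'   reaches at least `threshold` times its maximum) or a logical
#'   dominance matrix.
#' @param step_um Pixel step (um).
#' @param n_rays Number of rays (>= 8; default 36).
#' @param threshold Dominance threshold for numeric maps (default 0.5).
#' @return List of class `"layer_thickness"`: `mean_um`, `sd_um`,
#'   `per_ray_um`, `n_rays_hit`, `is_shell`.
#' @export
layer_thickness <- function(map, step_um, n_rays = 36L, threshold = 0.5) {
  stopifnot(n_rays >= 8)
  layer <- if (is.logical(map)) map else {
    if (max(map) <= 0) stop("component is nowhere present in the map")
    map >= threshold * max(map)
  }
  if (!any(layer)) stop("component is nowhere dominant in the map")
  H <- nrow(layer); W <- ncol(layer)
  idx <- which(layer, arr.ind = TRUE)
  cy <- mean(idx[, 1] - 0.5); cx <- mean(idx[, 2] - 0.5)
  r_support <- max(sqrt((idx[, 1] - 0.5 - cy)^2 + (idx[, 2] - 0.5 - cx)^2))

  ds <- 0.25                              # ray sampling step, pixels
  r_max <- sqrt(H^2 + W^2)
  rr <- seq(ds / 2, r_max, by = ds)
  per_ray <- rep(NA_real_, n_rays)
  for (a in seq_len(n_rays)) {
    th <- 2 * pi * (a - 1) / n_rays
    px <- floor(cx + rr * cos(th)) + 1L
    py <- floor(cy + rr * sin(th)) + 1L
    ok <- px >= 1 & px <= W & py >= 1 & py <= H
    inside <- rep(FALSE, length(rr))
    inside[ok] <- layer[cbind(py[ok], px[ok])]
    if (!any(inside)) next
    runs <- rle(inside)
    per_ray[a] <- max(runs$lengths[runs$values]) * ds * step_um
  }
  hit <- per_ray[!is.na(per_ray)]
  if (length(hit) == 0) stop("no ray intersects the layer")
  mean_um <- mean(hit)
  structure(list(mean_um = mean_um, sd_um = stats::sd(hit),
                 per_ray_um = per_ray, n_rays_hit = length(hit),
                 is_shell = mean_um <= 0.5 * r_support * step_um),
            class = "layer_thickness")
}

#' @export
print.layer_thickness <- function(x, ...) {
  cat(sprintf("<layer: mean %.1f um, sd %.1f um over %d rays%s>\n",
              x$mean_um, x$sd_um, x$n_rays_hit,
              if (x$is_shell) "" else " [not shell-like]"))
  invisible(x)
}

#' Radial organization score of a two-variant label map
#'
#' Operationalizes the qualitative observation that the two COM spectral
#' variants organise in radial lines from the stone core: rays are cast
#' from the centroid of the labelled pixels and the score is the mean over
#' rays of `1 - transitions / (run length - 1)`, where transitions counts
#' label changes along the ray. Sector-organised maps score near 1;
#' salt-and-pepper label fields score near 0.5; concentric (lamellar)
#' alternating rings score low because every ray crosses every ring
#' boundary. This is a descriptive artifact metric, not a clinical
#' classifier.
#'
#' @param labels `H x W` matrix with values 1/2 for the two variants and
#'   0/NA elsewhere.
#' @param n_rays Number of rays (default 72).
#' @return List: `score` between 0 and 1 (NA when fewer than two variants
#'   are present, with `monovariant = TRUE`).
#' @export
radial_organization_score <- function(labels, n_rays = 72L) {
  lab <- labels
  lab[is.na(lab)] <- 0L
  present <- sort(unique(lab[lab > 0]))
  if (length(present) < 2)
    return(list(score = NA_real_, monovariant = TRUE))
  H <- nrow(lab); W <- ncol(lab)
  idx <- which(lab > 0, arr.ind = TRUE)
  cy <- mean(idx[, 1] - 0.5); cx <- mean(idx[, 2] - 0.5)
  ds <- 0.5
  rr <- seq(ds / 2, sqrt(H^2 + W^2), by = ds)
  scores <- rep(NA_real_, n_rays)
  for (a in seq_len(n_rays)) {
    th <- 2 * pi * (a - 0.5) / n_rays
    px <- floor(cx + rr * cos(th)) + 1L
    py <- floor(cy + rr * sin(th)) + 1L
    ok <- px >= 1 & px <= W & py >= 1 & py <= H
    px <- px[ok]; py <- py[ok]
    pid <- (px - 1L) * H + py
    keep <- c(TRUE, diff(pid) != 0)      # one sample per distinct pixel
    seqlab <- lab[cbind(py[keep], px[keep])]
    seqlab <- seqlab[seqlab > 0]
    if (length(seqlab) < 2) next
    transitions <- sum(diff(seqlab) != 0)
    scores[a] <- 1 - transitions / (length(seqlab) - 1)
  }
  list(score = mean(scores, na.rm = TRUE), monovariant = FALSE)
}

#' Plot abundance maps
#'
#' Facetted raster view of per-component abundances using the low (dark
#' blue) to high (yellow) convention of stone component maps.
#'
#' @param object An `"abundance_maps"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abundance_maps <- function(object, ...) {
  d <- dim(object$values)
  df <- tibble::tibble(
    row = rep(rep(seq_len(d[1]), d[2]), d[3]),
    col = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
    species = rep(object$species, each = d[1] * d[2]),
    abundance = as.vector(object$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$abundance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "#081d58", high = "#ffff33") +
    ggplot2::facet_wrap(~species) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
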