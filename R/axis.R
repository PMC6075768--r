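#' Wavenumber axis for Raman spectra
#'
#' Builds the common spectral grid on which pure spectra are rendered and
#' hyperspectral cubes are simulated and analysed. The default grid spans
#' 464 to 1853 cm^-1 at 1 cm^-1 spacing, which places the two calcium
#' oxalate monohydrate main-peak positions (1487 and 1462 cm^-1) exactly on
#' grid points.
#'
#' @param from First Raman shift (cm^-1).
#' @param to Last Raman shift (cm^-1); must exceed `from`.
#' @param step Grid spacing (cm^-1), > 0.
#' @return Numeric vector of strictly increasing, uniformly spaced Raman
#'   shifts with class `"wn_axis"`.
#' @examples
#' ax <- wavenumber_axis()
#' length(ax)     # 1390 bands
#' range(ax)      # 464 1853
#' @export
wavenumber_axis <- function(from = 464, to = 1853, step = 1) {
  stopifnot(is.numeric(from), is.numeric(to), is.numeric(step),
            length(from) == 1, length(to) == 1, length(step) == 1,
            step > 0, to > from)
  ax <- seq(from, to, by = step)
  structure(ax, class = c("wn_axis", "numeric"))
}

#' Validate a wavenumber axis
#'
#' Checks that an axis is strictly increasing and uniformly spaced
#' (relative tolerance 1e-9). Plain numeric vectors are accepted and
#' returned with the `"wn_axis"` class attached.
#'
#' @param axis Numeric vector of Raman shifts (cm^-1).
#' @return The validated axis (invisibly classed as `"wn_axis"`).
#' @export
validate_axis <- function(axis) {
  if (!is.numeric(axis) || length(axis) < 2)
    stop("wavenumber axis must be a numeric vector with at least 2 points")
  d <- diff(axis)
  if (any(d <= 0))
    stop("wavenumber axis must be strictly increasing")
  if (max(abs(d - d[1])) > 1e-9 * max(abs(axis)))
    stop("wavenumber axis must be uniformly spaced")
  structure(as.numeric(axis), class = c("wn_axis", "numeric"))
}

axis_step <- function(axis) (axis[length(axis)] - axis[1]) / (length(axis) - 1)

#' @export
print.wn_axis <- function(x, ...) {
  cat(sprintf("<wavenumber axis: %d bands, %.6g-%.6g cm^-1, step %.6g cm^-1>\n",
              length(x), x[1], x[length(x)], axis_step(x)))
  invisible(x)
}
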