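#' Reference library of kidney-stone constituent Raman spectra
#'
#' Pure component spectra are modelled as sums of pseudo-Voigt bands
#' (linear Gaussian/Lorentzian blend), one row per band. The shipped
#' default library is synthetic: only the two calcium oxalate monohydrate
#' (COM) variants carry their published main-peak positions (1487 and
#' 1462 cm^-1); all other band positions are fixed, documented constants
#' chosen near literature values and tuned for identifiability (every
#' pair of rendered spectra has Pearson correlation < 0.95 on the default
#' axis). Amplitudes are relative to the strongest band of each species,
#' which is always 1.
#'
#' @param bands A data frame with columns `species`, `center` (cm^-1),
#'   `fwhm` (cm^-1, > 0), `amplitude` (>= 0, max 1 per species) and
#'   `shape_mix` (0 = Gaussian, 1 = Lorentzian).
#' @return A tibble of class `"raman_library"`.
#' @seealso [default_library()], [render_spectrum()]
#' @export
raman_library <- function(bands) {
  bands <- tibble::as_tibble(bands)
  req <- c("species", "center", "fwhm", "amplitude", "shape_mix")
  if (!all(req %in% names(bands)))
    stop("library table must have columns: ", paste(req, collapse = ", "))
  if (any(bands$fwhm <= 0)) stop("band fwhm must be > 0")
  if (any(bands$amplitude < 0)) stop("band amplitude must be >= 0")
  if (any(bands$shape_mix < 0 | bands$shape_mix > 1))
    stop("shape_mix must lie in [0, 1]")
  amax <- tapply(bands$amplitude, bands$species, max)
  if (any(abs(amax - 1) > 1e-9))
    stop("the strongest band of every species must have amplitude 1 ",
         "(unit-max convention); offending species: ",
         paste(names(amax)[abs(amax - 1) > 1e-9], collapse = ", "))
  class(bands) <- c("raman_library", class(bands))
  bands
}

#' Default stone-constituent band library
#'
#' Twelve entries: the two COM spectral variants (`COM_typeA`, strongest
#' band 1487 cm^-1; `COM_typeB`, strongest band 1462 cm^-1), calcium
#' oxalate dihydrate (COD), anhydrous and dihydrate uric acid, apatite,
#' struvite, brushite, whitlockite, ammonium urate, and the two drug
#' phases N-Acetyl-Sulfamethoxazole and atazanavir.
#'
#' @return A `"raman_library"` tibble.
#' @export
default_library <- function() {
  b <- function(species, center, fwhm, amplitude, shape_mix)
    tibble::tibble(species = species, center = center, fwhm = fwhm,
                   amplitude = amplitude, shape_mix = shape_mix)
  raman_library(dplyr::bind_rows(
    b("COM_typeA", c(504, 896, 1462, 1487, 1630),
      c(10, 9, 9, 9, 12), c(0.35, 0.55, 0.35, 1.00, 0.25),
      c(0.4, 0.5, 0.5, 0.5, 0.3)),
    b("COM_typeB", c(504, 896, 1462, 1487, 1630),
      c(10, 9, 9, 9, 12), c(0.35, 0.55, 1.00, 0.35, 0.25),
      c(0.4, 0.5, 0.5, 0.5, 0.3)),
    b("COD", c(506, 910, 1477, 1632),
      c(10, 9, 10, 12), c(0.30, 1.00, 0.75, 0.20), c(0.4, 0.5, 0.5, 0.3)),
    b("uric_acid_anhydrous", c(631, 883, 1037, 1402, 1648),
      c(9, 9, 8, 10, 11), c(0.50, 0.30, 1.00, 0.45, 0.35),
      c(0.5, 0.4, 0.5, 0.5, 0.4)),
    b("uric_acid_dihydrate", c(620, 890, 1020, 1411, 1605),
      c(9, 9, 8, 10, 11), c(0.40, 0.35, 1.00, 0.50, 0.30),
      c(0.5, 0.4, 0.5, 0.5, 0.4)),
    b("apatite", c(591, 961, 1046, 1072),
      c(10, 8, 10, 10), c(0.40, 1.00, 0.35, 0.30), c(0.4, 0.5, 0.4, 0.4)),
    b("struvite", c(567, 946, 1060),
      c(12, 10, 12), c(0.45, 1.00, 0.30), c(0.5, 0.5, 0.4)),
    b("brushite", c(528, 878, 985, 1060, 1118),
      c(11, 10, 9, 12, 10), c(0.35, 0.40, 1.00, 0.25, 0.30),
      c(0.4, 0.4, 0.5, 0.4, 0.4)),
    b("whitlockite", c(550, 612, 970, 1080),
      c(11, 10, 8, 10), c(0.25, 0.35, 1.00, 0.40), c(0.4, 0.4, 0.5, 0.4)),
    b("ammonium_urate", c(629, 1006, 1420, 1665),
      c(10, 9, 11, 12), c(0.40, 1.00, 0.35, 0.30), c(0.5, 0.5, 0.5, 0.4)),
    b("n_acetyl_sulfamethoxazole", c(680, 798, 1150, 1322, 1596),
      c(10, 10, 10, 11, 11), c(0.30, 0.50, 1.00, 0.45, 0.40),
      c(0.5, 0.5, 0.5, 0.5, 0.4)),
    b("atazanavir", c(703, 830, 1245, 1450, 1608),
      c(10, 10, 10, 12, 11), c(0.35, 0.40, 0.50, 0.30, 1.00),
      c(0.5, 0.5, 0.5, 0.4, 0.5))
  ))
}

#' List the species in a library
#' @param library A `"raman_library"`.
#' @return Character vector of species names (in order of first appearance).
#' @export
library_species <- function(library) unique(library$species)

# pseudo-Voigt profile, unit height at center, half maximum at +/- fwhm/2
pseudo_voigt <- function(x, center, fwhm, shape_mix) {
  u <- (x - center) / (fwhm / 2)
  g <- exp(-log(2) * u^2)
  l <- 1 / (1 + u^2)
  (1 - shape_mix) * g + shape_mix * l
}

#' Render a pure component spectrum on a wavenumber axis
#'
#' Sums the species' pseudo-Voigt bands and rescales so the global maximum
#' equals 1 (unit-max normalization).
#'
#' @param library A `"raman_library"`.
#' @param species Species name present in the library.
#' @param axis Wavenumber axis (see [wavenumber_axis()]).
#' @return Non-negative numeric vector of length `length(axis)` with
#'   maximum exactly 1.
#' @examples
#' ax <- wavenumber_axis()
#' s <- render_spectrum(default_library(), "COM_typeA", ax)
#' ax[which.max(s)]  # 1487
#' @export
render_spectrum <- function(library, species, axis) {
  axis <- validate_axis(axis)
  if (!species %in% library$species)
    stop("unknown species '", species, "'; available: ",
         paste(library_species(library), collapse = ", "))
  rows <- library[library$species == species, ]
  y <- rep(0, length(axis))
  for (i in seq_len(nrow(rows)))
    y <- y + rows$amplitude[i] *
      pseudo_voigt(as.numeric(axis), rows$center[i], rows$fwhm[i],
                   rows$shape_mix[i])
  y / max(y)
}

#' Render every library species into a spectra matrix
#'
#' @inheritParams render_spectrum
#' @return `length(axis) x n_species` matrix with species names as columns,
#'   each column unit-max.
#' @export
render_library <- function(library, axis) {
  sp <- library_species(library)
  S <- vapply(sp, function(s) render_spectrum(library, s, axis),
              numeric(length(validate_axis(axis))))
  colnames(S) <- sp
  S
}

#' Pairwise Pearson correlations between rendered pure spectra
#'
#' Identifiability audit: a usable library should have all off-diagonal
#' correlations below 0.95 on the working axis.
#'
#' @inheritParams render_spectrum
#' @return Symmetric correlation matrix with unit diagonal, species names
#'   on both dimensions.
#' @export
pairwise_correlations <- function(library, axis) {
  if (nrow(library) == 0) stop("library is empty")
  stats::cor(render_library(library, axis))
}

#' Read / write a band library as delimited text
#'
#' The on-disk format is a comma-separated table with a single header row
#' `species,center,fwhm,amplitude,shape_mix`; one row per band. Lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @return `read_library()` returns a `"raman_library"`;
#'   `write_library()` returns `path` invisibly.
#' @export
read_library <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  raman_library(tab)
}

#' @rdname read_library
#' @param library A `"raman_library"` to serialize.
#' @export
write_library <- function(library, path) {
  writeLines("# ramanstones band library: one pseudo-Voigt band per row",
             con = path)
  suppressWarnings(utils::write.table(
    as.data.frame(library), path, sep = ",", row.names = FALSE,
    quote = FALSE, append = TRUE))
  invisible(path)
}
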