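#' Read and write hyperspectral cubes
#'
#' Two documented open dialects:
#'
#' * **text** — a header block of `#`-prefixed lines (`shape`, `step_um`,
#'   `n_bands`, `axis`) followed by a comma-separated long table with
#'   columns `row,col,wavenumber,intensity`, one line per support pixel
#'   and band. Pixels absent from the table are non-support. Numbers are
#'   written in shortest round-trip representation, so read(write(cube))
#'   reproduces the cube exactly.
#' * **binary** — magic `RSCUBE01`, then `H, W, B` (int32), `step_um`
#'   (float64), the axis (B float64), the support mask (H*W int32,
#'   column-major) and the full intensity array (H*W*B float64,
#'   column-major).
#'
#' @param path File path.
#' @param format `"auto"` (sniff), `"text"` or `"binary"`.
#' @return `read_cube()` returns a `"hyper_cube"`; `write_cube()` returns
#'   `path` invisibly.
#' @export
read_cube <- function(path, format = c("auto", "text", "binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 8)
    format <- if (identical(rawToChar(magic), "RSCUBE01")) "binary"
              else "text"
  }
  if (format == "binary") return(read_cube_binary(path))
  read_cube_text(path)
}

#' @rdname read_cube
#' @param cube A `"hyper_cube"`.
#' @export
write_cube <- function(cube, path, format = c("text", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(cube, "hyper_cube"))
  if (format == "binary") return(write_cube_binary(cube, path))
  H <- dim(cube$intensities)[1]; W <- dim(cube$intensities)[2]
  hdr <- c("# ramanstones cube v1",
           sprintf("# shape: %d %d", H, W),
           sprintf("# step_um: %.17g", cube$step_um),
           sprintf("# n_bands: %d", length(cube$axis)),
           paste("# axis:", paste(sprintf("%.17g", cube$axis),
                                  collapse = " ")))
  writeLines(hdr, path)
  uf <- unfold(cube)
  n <- nrow(uf$D); B <- ncol(uf$D)
  # %.17g round-trips doubles exactly through text
  dt <- data.table::data.table(
    row = rep(uf$pixel_index[, 1], each = B),
    col = rep(uf$pixel_index[, 2], each = B),
    wavenumber = rep(sprintf("%.17g", as.numeric(cube$axis)), n),
    intensity = sprintf("%.17g", as.vector(t(uf$D))))
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

parse_header_num <- function(lines, key, path) {
  i <- grep(paste0("^# ", key, ":"), lines)
  if (length(i) != 1)
    stop("malformed cube header in '", path, "': missing '# ", key,
         ":' line (header lines 1-", length(lines), ")")
  vals <- suppressWarnings(as.numeric(strsplit(
    sub(paste0("^# ", key, ": *"), "", lines[i]), " +")[[1]]))
  if (any(is.na(vals)))
    stop("malformed cube header in '", path, "' at line ", i,
         ": non-numeric '", key, "'")
  vals
}

read_cube_text <- function(path) {
  all_lines <- readLines(path, n = 200)
  hdr <- all_lines[startsWith(all_lines, "#")]
  if (length(hdr) < 1 || !identical(hdr[1], "# ramanstones cube v1"))
    stop("malformed cube header in '", path,
         "' at line 1: expected '# ramanstones cube v1'")
  shape <- as.integer(parse_header_num(hdr, "shape", path))
  step_um <- parse_header_num(hdr, "step_um", path)
  n_bands <- as.integer(parse_header_num(hdr, "n_bands", path))
  axis <- parse_header_num(hdr, "axis", path)
  if (length(axis) != n_bands)
    stop("malformed cube header in '", path, "': axis has ", length(axis),
         " values but n_bands is ", n_bands)
  axis <- validate_axis(axis)
  dt <- data.table::fread(path, skip = length(hdr), header = TRUE)
  if (!all(c("row", "col", "wavenumber", "intensity") %in% names(dt)))
    stop("cube table in '", path,
         "' must have columns row,col,wavenumber,intensity")
  cnt <- dt[, list(N = .N), by = c("row", "col")]
  if (any(cnt$N != n_bands))
    stop("ragged spectra in '", path, "': pixel (",
         cnt$row[cnt$N != n_bands][1], ",", cnt$col[cnt$N != n_bands][1],
         ") has ", cnt$N[cnt$N != n_bands][1], " bands, expected ", n_bands)
  H <- shape[1]; W <- shape[2]
  arr <- array(0, dim = c(H, W, n_bands))
  support <- matrix(FALSE, H, W)
  support[cbind(cnt$row, cnt$col)] <- TRUE
  bidx <- match(dt$wavenumber, as.numeric(axis))
  if (any(is.na(bidx)))
    stop("cube table in '", path, "' contains wavenumbers not on the axis")
  arr[cbind(dt$row, dt$col, bidx)] <- dt$intensity
  hyper_cube(arr, axis, step_um, support)
}

write_cube_binary <- function(cube, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RSCUBE01", con, eos = NULL)
  d <- dim(cube$intensities)
  writeBin(as.integer(d), con, size = 4)
  writeBin(as.numeric(cube$step_um), con, size = 8)
  writeBin(as.numeric(cube$axis), con, size = 8)
  writeBin(as.integer(cube$support), con, size = 4)
  writeBin(as.numeric(cube$intensities), con, size = 8)
  invisible(path)
}

read_cube_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, "RSCUBE01"))
    stop("'", path, "' is not a ramanstones binary cube")
  d <- readBin(con, "integer", n = 3, size = 4)
  step_um <- readBin(con, "numeric", n = 1, size = 8)
  axis <- validate_axis(readBin(con, "numeric", n = d[3], size = 8))
  support <- matrix(readBin(con, "integer", n = d[1] * d[2], size = 4) > 0,
                    d[1], d[2])
  arr <- array(readBin(con, "numeric", n = prod(d), size = 8), dim = d)
  hyper_cube(arr, axis, step_um, support)
}

#' Export abundance maps as rasters and numeric grids
#'
#' Writes, per component, a PNG raster (dark blue = absent or masked,
#' yellow = high abundance) and a comma-separated numeric grid; filenames
#' embed the matched species name when an assignment is given.
#'
#' @param maps An `"abundance_maps"` object.
#' @param outdir Output directory (created if needed).
#' @param assignment Optional `"component_assignment"` from
#'   [match_to_library()].
#' @return Tibble of written files (invisibly).
#' @export
export_maps <- function(maps, outdir, assignment = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  ramp <- grDevices::colorRamp(c("#081d58", "#ffff33"))
  nm <- maps$species
  if (!is.null(assignment)) {
    lab <- ifelse(assignment$detected, assignment$species,
                  paste0("unidentified_", assignment$component))
    nm <- make.names(lab, unique = TRUE)
  }
  files <- lapply(seq_along(nm), function(j) {
    m <- maps$values[, , j]
    png_path <- file.path(outdir, paste0("map_", nm[j], ".png"))
    grid_path <- file.path(outdir, paste0("map_", nm[j], ".csv"))
    v <- if (max(m) > 0) m / max(m) else m
    rgb <- ramp(as.vector(v)) / 255
    img <- array(rgb, dim = c(nrow(m), ncol(m), 3))
    ok <- tryCatch({
      png::writePNG(img, png_path)
      data.table::fwrite(data.table::as.data.table(m), grid_path,
                         col.names = FALSE)
      TRUE
    }, error = function(e)
      stop("failed writing maps under '", outdir, "': ",
           conditionMessage(e)))
    tibble::tibble(component = j, name = nm[j],
                   png = png_path, grid = grid_path)
  })
  invisible(dplyr::bind_rows(files))
}
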