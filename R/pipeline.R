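#' Run the full Raman chemical-imaging pipeline
#'
#' Executes simulate-or-load, preprocessing (smooth, baseline-correct,
#' porosity-mask), MCR-ALS unmixing, library identification, map
#' refolding and structural reporting in the fixed order of the
#' acquisition-processing chain.
#'
#' @param input A [phantom_spec()] (simulated input), a `"hyper_cube"`, or
#'   a cube file path.
#' @param k Number of MCR components, or `"auto"`.
#' @param config A [preprocess_config()].
#' @param threshold Identification threshold on Pearson correlation.
#' @param library Reference band library.
#' @param axis Wavenumber axis used when simulating (cubes carry their
#'   own).
#' @param seed Optional integer overriding the phantom spec's seed.
#' @param n_rays Rays for layer-thickness measurement.
#' @param outdir Optional directory: report (JSON + text) and maps are
#'   written there.
#' @param verbose Log stage progress and timings.
#' @return Object of class `"structure_report"` (see Details) with fields
#'   `assignment`, `species_detected`, `pixel_fractions`,
#'   `porosity_percent`, `layers`, `com_variants`, `fit` (glance tibble),
#'   `maps`, `mcr`, `provenance`.
#' @export
run_pipeline <- function(input, k = "auto", config = preprocess_config(),
                         threshold = 0.9, library = default_library(),
                         axis = wavenumber_axis(), seed = NULL,
                         n_rays = 36L, outdir = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose)
    message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0), ...)

  truth <- NULL
  if (inherits(input, "phantom_spec")) {
    if (!is.null(seed)) input$seed <- as.integer(seed)
    say("simulating phantom (", input$shape[1], "x", input$shape[2],
        " px, seed ", input$seed, ")")
    ph <- generate_phantom(input, library, axis)
    cube <- ph$cube; truth <- ph$truth
    used_seed <- input$seed
  } else if (inherits(input, "hyper_cube")) {
    cube <- input; used_seed <- seed
  } else if (is.character(input) && length(input) == 1) {
    say("reading cube from ", input)
    cube <- read_cube(input); used_seed <- seed
  } else stop("input must be a phantom_spec, hyper_cube, or file path")

  say("preprocessing (SG window ", config$sg_window, ", AsLS lambda ",
      format(config$asls_lambda), ", p ", format(config$asls_p), ")")
  pp <- preprocess(cube, config)
  porosity_percent <- 100 * mean(pp$mask)
  say(sum(pp$mask), " low-signal pixels masked as porosity/gap")

  say("unmixing by MCR-ALS (k = ", k, ")")
  fit <- mcr_als(pp, k)
  say("LOF ", sprintf("%.4g%%", fit$lof), " after ", fit$n_iterations,
      " iterations")

  assignment <- match_to_library(fit$S, library, cube$axis, threshold)
  detected <- assignment$species[assignment$detected]
  say("identified: ", paste(detected, collapse = ", "))

  map_names <- ifelse(assignment$detected, assignment$species,
                      paste0("unidentified_", assignment$component))
  maps <- refold_maps(fit$C, pp$pixel_index[!pp$mask, , drop = FALSE],
                      pp$shape, cube$step_um, cube$support,
                      species = map_names)
  fractions <- pixel_fraction(maps)

  lab <- dominant_labels(maps)
  layers <- dplyr::bind_rows(lapply(which(assignment$detected), function(j) {
    lt <- tryCatch(layer_thickness(lab == j, cube$step_um, n_rays),
                   error = function(e) NULL)
    if (is.null(lt)) return(NULL)
    tibble::tibble(species = assignment$species[j],
                   mean_um = lt$mean_um, sd_um = lt$sd_um,
                   is_shell = lt$is_shell)
  }))

  com_idx <- match(c("COM_typeA", "COM_typeB"), assignment$species)
  com_variants <- if (all(!is.na(com_idx))) {
    vl <- matrix(0L, pp$shape[1], pp$shape[2])
    vl[lab == com_idx[1]] <- 1L
    vl[lab == com_idx[2]] <- 2L
    c(list(present = TRUE,
           peak_typeA = main_peak(fit$S[, com_idx[1]], cube$axis),
           peak_typeB = main_peak(fit$S[, com_idx[2]], cube$axis)),
      radial_organization_score(vl))
  } else list(present = FALSE)

  report <- structure(list(
    assignment = assignment,
    species_detected = detected,
    pixel_fractions = fractions,
    porosity_percent = porosity_percent,
    layers = layers,
    com_variants = com_variants,
    fit = glance(fit),
    maps = maps,
    mcr = fit,
    truth = truth,
    provenance = list(
      package = "ramanstones",
      version = as.character(utils::packageVersion("ramanstones")),
      seed = used_seed, k = fit$k, threshold = threshold,
      preprocess = unclass(config),
      axis = c(from = cube$axis[1],
               to = cube$axis[length(cube$axis)],
               step = axis_step(cube$axis)),
      step_um = cube$step_um)),
    class = "structure_report")

  if (!is.null(outdir)) {
    say("writing report and maps to ", outdir)
    write_report(report, outdir)
  }
  say("done")
  report
}

#' @export
print.structure_report <- function(x, ...) {
  cat("Raman chemical imaging structure report\n")
  cat("  components detected:",
      if (length(x$species_detected)) paste(x$species_detected,
                                            collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  lack of fit: %.4g%%  explained variance: %.4g%%\n",
              x$fit$lof, x$fit$explained_variance))
  cat(sprintf("  porosity/gap: %.2f%% of support pixels\n",
              x$porosity_percent))
  if (nrow(x$layers))
    for (i in seq_len(nrow(x$layers)))
      cat(sprintf("  layer %s: %.1f um (sd %.1f)%s\n",
                  x$layers$species[i], x$layers$mean_um[i],
                  x$layers$sd_um[i],
                  if (x$layers$is_shell[i]) "" else " [not shell-like]"))
  if (isTRUE(x$com_variants$present))
    cat(sprintf(paste0("  COM variants: peaks %g / %g cm^-1, radial",
                       " organization score %.3f\n"),
                x$com_variants$peak_typeA, x$com_variants$peak_typeB,
                x$com_variants$score))
  invisible(x)
}

#' Serialize a structure report
#'
#' Writes `report.json` (machine-readable, with a provenance block
#' sufficient to regenerate the run), `report.txt` (human-readable) and
#' the per-component map rasters and grids.
#'
#' @param report A `"structure_report"`.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    species_detected = report$species_detected,
    assignment = report$assignment,
    pixel_fractions = report$pixel_fractions,
    porosity_percent = report$porosity_percent,
    layers = report$layers,
    com_variants = report$com_variants[setdiff(names(report$com_variants),
                                               "labels")],
    fit = report$fit,
    provenance = report$provenance)
  jsonlite::write_json(payload, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(outdir, "report.txt"))
  export_maps(report$maps, file.path(outdir, "maps"), report$assignment)
  invisible(outdir)
}

#' Read a pipeline run configuration from YAML
#'
#' Maps the documented keys (`phantom`, `cube`, `k`, `threshold`, `seed`,
#' `outdir`, `n_rays`, and the [preprocess_config()] fields under
#' `preprocess:`) onto [run_pipeline()] arguments. Defaults reproduce the
#' standard processing settings (SG window 5, AsLS lambda 1e5 / p 1e-3,
#' non-negative MCR-ALS).
#'
#' @param path YAML file path.
#' @return Named list of arguments for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) {
    ctor <- switch(y$phantom$layout,
                   layered_oxalate = phantom_layered_oxalate,
                   core_gap_composite = phantom_core_gap_composite,
                   minor_inclusion = phantom_minor_inclusion,
                   radial_com_drug = phantom_radial_com_drug,
                   stop("unknown phantom layout: ", y$phantom$layout))
    args$input <- do.call(ctor, y$phantom[setdiff(names(y$phantom),
                                                  "layout")])
  } else if (!is.null(y$cube)) {
    args$input <- y$cube
  } else stop("config must give either 'phantom:' or 'cube:'")
  if (!is.null(y$preprocess))
    args$config <- do.call(preprocess_config, y$preprocess)
  for (key in c("k", "threshold", "seed", "outdir", "n_rays", "verbose"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  args
}
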