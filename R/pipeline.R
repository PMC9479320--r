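#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the HU window, the
#' filtration backend, truncation and dimension choices, per-group
#' generator configurations, and output/seed control. The defaults are the
#' study conditions: two groups of 8 subjects x 36 patches of 32x32, fat
#' window -190..-30 HU, patches concatenated 6x6 per subject, cubical
#' backend, Betti range in dimension 0 and diagonal statistics in
#' dimension 1.
#'
#' @param hu_window An [hu_window()].
#' @param backend `"cubical"` (sublevel sweep on the patch, the default) or
#'   `"rips"` (Vietoris-Rips on the masked pixel cloud).
#' @param eps_max Rips truncation diameter in pixels (ignored by cubical).
#' @param homology_dim Dimension for the Betti-range contrast (0 counts
#'   components, 1 counts loops).
#' @param concatenate Analyse one concatenated patch per subject (default)
#'   rather than each patch separately.
#' @param grid_cols Tiles per row when concatenating.
#' @param fat,nonfat [generator_config()] objects for the two groups; their
#'   base seeds are overridden by `seed`.
#' @param output_dir Where to write artifacts; `NULL` computes in memory
#'   only.
#' @param seed Master seed for the whole run.
#' @param keep_zero Keep zero-persistence intervals in diagrams.
#' @param write_complexes Also serialise every filtered complex (large TSVs).
#' @param log_level `"info"` for stage messages, `"quiet"` for silence.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(hu_window = fathom::hu_window(),
                            backend = c("cubical", "rips"),
                            eps_max = 10,
                            homology_dim = 0L,
                            concatenate = TRUE,
                            grid_cols = 6L,
                            fat = generator_config("fat"),
                            nonfat = generator_config("nonfat"),
                            output_dir = NULL,
                            seed = 0L,
                            keep_zero = FALSE,
                            write_complexes = TRUE,
                            log_level = c("info", "quiet")) {
  backend <- match.arg(backend)
  log_level <- match.arg(log_level)
  if (!is.finite(eps_max) || eps_max <= 0) {
    abort("eps_max must be positive.", class = "fathom_config_error")
  }
  if (!homology_dim %in% c(0L, 1L)) {
    abort("homology_dim must be 0 or 1.", class = "fathom_config_error")
  }
  fat$seed <- as.integer(seed)
  nonfat$seed <- as.integer(seed)
  validate_generator_config(fat)
  validate_generator_config(nonfat)
  structure(list(hu_window = hu_window, backend = backend, eps_max = eps_max,
                 homology_dim = as.integer(homology_dim),
                 concatenate = isTRUE(concatenate),
                 grid_cols = as.integer(grid_cols),
                 fat = fat, nonfat = nonfat,
                 output_dir = output_dir, seed = as.integer(seed),
                 keep_zero = isTRUE(keep_zero),
                 write_complexes = isTRUE(write_complexes),
                 log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf("[fathom %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) the two-group cohort, masks each analysis unit at
#' the HU window, builds the chosen filtration, computes persistence
#' diagrams and Betti curves, summarises each group, and contrasts the
#' groups. With `concatenate = TRUE` the unit of analysis is one tiled
#' patch per subject; otherwise every patch is analysed separately. All
#' artifacts (manifest, masks, point clouds, complexes, diagrams, curves,
#' plots, report) are written under `output_dir` when it is set, and every
#' artifact is reproducible from `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional precomputed cohort tibble (as from
#'   [generate_cohort()]); by default the cohort is generated from the
#'   config.
#' @return A `topo_comparison` with extra elements `subjects` (per-unit
#'   results), `log` (stage timings and cell counts) and `paths`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
      abort(paste0("output directory not writable: ", out_dir),
            class = "fathom_io_error")
    }
  }
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- withCallingHandlers(
      tryCatch(force(expr), error = function(e) {
        abort(paste0("pipeline stage '", name, "' failed: ",
                     conditionMessage(e)), class = "fathom_stage_error",
              parent = e)
      }))
    log[[length(log) + 1]] <<- tibble::tibble(stage = name,
                                              seconds = tic() - t0)
    res
  }

  cohort <- stage("generate", cohort %||%
                    generate_cohort(config$fat, config$nonfat))
  pipe_log(config, "cohort: %d patches", nrow(cohort))
  if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "patches"))

  units <- stage("assemble", {
    if (config$concatenate) {
      cohort |>
        dplyr::group_by(.data$group, .data$subject) |>
        dplyr::summarise(
          values = list(concatenate_patches(.data$values, config$grid_cols)),
          .groups = "drop") |>
        dplyr::mutate(unit = sprintf("%s_%02d", .data$group, .data$subject))
    } else {
      dplyr::mutate(cohort,
                    unit = sprintf("%s_%02d_%02d", .data$group,
                                   .data$subject, .data$patch))
    }
  })

  analyse_unit <- function(patch, unit) {
    mask <- mask_hu(patch, config$hu_window)
    pts <- points_from_mask(mask)
    fc <- if (config$backend == "rips") {
      vietoris_rips(pts, eps_max = config$eps_max)
    } else {
      lower_star_cubical(patch)
    }
    dg <- persistence(fc, keep_zero = config$keep_zero, source_label = unit,
                      validate = FALSE)
    curve <- betti_curve(dg, config$homology_dim, default_thresholds(fc))
    if (!is.null(out_dir)) {
      write_mask_csv(mask, file.path(out_dir, paste0(unit, "_mask.csv")))
      write_points_tsv(pts, file.path(out_dir, paste0(unit, "_points.tsv")))
      if (config$write_complexes) {
        write_complex_tsv(fc, file.path(out_dir, paste0(unit, "_complex.tsv")))
      }
      write_diagram_tsv(dg, file.path(out_dir, paste0(unit, "_diagram.tsv")))
      write_betti_csv(stats::setNames(list(curve),
                                      paste0("beta", config$homology_dim)),
                      file.path(out_dir, paste0(unit, "_betti.csv")))
    }
    rng <- betti_range(curve)
    list(diagram = dg, curve = curve, n_cells = nrow(fc$cells),
         betti_min = rng[["min"]], betti_max = rng[["max"]])
  }

  results <- stage("persistence", purrr::map2(units$values, units$unit,
                                              analyse_unit))
  units$n_cells <- vapply(results, `[[`, numeric(1), "n_cells")
  units$betti_min <- vapply(results, `[[`, numeric(1), "betti_min")
  units$betti_max <- vapply(results, `[[`, numeric(1), "betti_max")
  pipe_log(config, "persistence done: %d units, %d..%d cells",
           nrow(units), min(units$n_cells), max(units$n_cells))

  comparison <- stage("summarise", {
    summaries <- lapply(unique(units$group), function(g) {
      sel <- which(units$group == g)
      group_summary(g,
                    curves = lapply(results[sel], `[[`, "curve"),
                    diagrams = lapply(results[sel], `[[`, "diagram"))
    })
    compare_groups(summaries)
  })

  if (!is.null(out_dir)) {
    stage("report", {
      write_comparison_json(comparison, file.path(out_dir, "report.json"))
      readr::write_tsv(dplyr::select(units, -"values"),
                       file.path(out_dir, "units.tsv"), progress = FALSE)
      for (g in unique(units$group)) {
        sel <- which(units$group == g)
        pooled <- dplyr::bind_rows(lapply(results[sel],
                                          function(r) tibble::as_tibble(r$diagram)))
        class(pooled) <- c("persistence_diagram", class(tibble::tibble()))
        attr(pooled, "source_label") <- g
        try({
          ggplot2::ggsave(file.path(out_dir, paste0(g, "_diagram.png")),
                          autoplot(pooled), width = 5, height = 4, dpi = 120)
          ggplot2::ggsave(file.path(out_dir, paste0(g, "_betti.png")),
                          autoplot(results[[sel[1]]]$curve),
                          width = 5, height = 4, dpi = 120)
        }, silent = TRUE)
      }
    })
  }

  comparison$subjects <- dplyr::select(units, -"values")
  comparison$log <- dplyr::bind_rows(log)
  comparison$config <- config
  comparison$paths <- if (is.null(out_dir)) character(0) else
    list.files(out_dir, recursive = TRUE, full.names = TRUE)
  comparison
}
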