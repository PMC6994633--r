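#' Load the shipped population presets
#'
#' Reads the preset file of population parameter distributions for the
#' synthetic generator. Only the free lifetime (0.45 ns) and the HSC
#' tau_bound anchor (3.56 ns) are measurement-anchored; all other preset
#' values are plausible defaults encoding the qualitative orderings of the
#' hematopoietic populations.
#'
#' @param path Preset JSON path; default is the file shipped with the
#'   package.
#' @param n_cells Default number of cells attached to each returned spec.
#' @return Named list of [population_spec()] objects.
#' @export
load_population_presets <- function(path = NULL, n_cells = 30L) {
  path <- path %||% system.file("extdata", "presets", "hspc_presets.json",
                                package = "mobflim")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mobflim-presets/1")) {
    stop("not a mobflim preset file: ", path)
  }
  out <- lapply(names(obj$populations), function(nm) {
    p <- obj$populations[[nm]]
    population_spec(nm, n_cells, means = as.list(p$means), sds = as.list(p$sds))
  })
  stats::setNames(out, names(obj$populations))
}

#' Validate a pipeline run configuration
#'
#' Checks structure, types and value ranges of a run configuration (parsed
#' JSON) before any computation; errors carry the offending field name.
#'
#' @param cfg Configuration list (from [jsonlite::read_json()] or built in
#'   code).
#' @return The validated configuration, with defaults filled in, invisibly
#'   usable by [run_pipeline()].
#' @export
validate_run_config <- function(cfg) {
  fail <- function(...) stop("config error: ", ..., call. = FALSE)
  if (!is.list(cfg)) fail("configuration must be a JSON object")
  if (!identical(cfg$format, "mobflim-config/1")) fail("format must be 'mobflim-config/1'")
  acq <- cfg$acquisition %||% list()
  num1 <- function(x, nm, lo = -Inf) {
    if (is.null(x)) return(NULL)
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo) {
      fail(nm, " must be a finite number >= ", lo)
    }
    x
  }
  num1(acq$laser_period_ns, "acquisition.laser_period_ns", 1e-6)
  num1(acq$n_time_bins, "acquisition.n_time_bins", 2)
  num1(acq$harmonic, "acquisition.harmonic", 1)
  num1(acq$irf_sigma_ns, "acquisition.irf_sigma_ns", 0)
  num1(acq$background_rate, "acquisition.background_rate", 0)
  if (!is.null(acq$frame_shape) &&
      (length(acq$frame_shape) != 2 || any(acq$frame_shape < 16))) {
    fail("acquisition.frame_shape must be two integers >= 16")
  }
  if (is.null(cfg$populations) || length(cfg$populations) < 1) {
    fail("at least one population required")
  }
  pops <- cfg$populations
  if (is.data.frame(pops)) pops <- split(pops, seq_len(nrow(pops)))
  for (p in pops) {
    if (is.null(p$preset) && is.null(p$name)) fail("population needs 'preset' or 'name'")
    n <- num1(p$n_cells %||% NULL, "population n_cells", 1)
    if (is.null(n)) fail("population n_cells required")
  }
  ft <- cfg$features %||% list()
  num1(ft$tau_free_ns, "features.tau_free_ns", 1e-3)
  bf <- num1(ft$band_fraction, "features.band_fraction", 0)
  if (!is.null(bf) && bf >= 1) fail("features.band_fraction must be < 1")
  num1(ft$count_threshold, "features.count_threshold", 0)
  if (!is.null(cfg$gate)) {
    if (is.null(cfg$gate$target)) fail("gate.target required when gate is present")
    if (!is.null(cfg$gate$features) &&
        !cfg$gate$features %in% c("all", "single3")) {
      fail("gate.features must be 'all' or 'single3'")
    }
  }
  if (!is.null(cfg$classifier)) {
    tp <- cfg$classifier$train_populations
    if (is.null(tp) || length(tp) != 2) {
      fail("classifier.train_populations must name exactly two populations")
    }
    if (is.null(cfg$classifier$positive)) fail("classifier.positive required")
  }
  num1(cfg$seed, "seed", 0)
  invisible(cfg)
}

#' Run the full synthetic-FLIM analysis pipeline
#'
#' Executes, in order: field simulation per population, phasor transform and
#' MOB extraction, PCA+LDA gating, and (optionally) SVM classification, and
#' writes a report bundle under `out_dir`:
#' `fields/<population>/` (decay TIFF dialect), `phasor/<population>` maps,
#' `cells.csv`, `gate.json` + `gated.csv`, `classifier.json` +
#' `predictions.csv`, `report.json`, plus the frozen resolved configuration
#' (`config.resolved.json`). Outputs are deterministic given the seed; a
#' second invocation with unchanged config reuses cached stage outputs.
#'
#' @param config Path to a run-configuration JSON, or an equivalent list.
#' @param out_dir Output directory.
#' @param seed Optional seed override.
#' @param quiet Suppress progress messages?
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  validate_run_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$seed <- as.integer(cfg$seed %||% 1L)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    if (!quiet) message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }

  resolved_path <- file.path(out_dir, "config.resolved.json")
  resolved_json <- jsonlite::toJSON(cfg, digits = NA, auto_unbox = TRUE,
                                    null = "null", pretty = TRUE)
  cache_valid <- file.exists(resolved_path) &&
    identical(paste(readLines(resolved_path, warn = FALSE), collapse = "\n"),
              as.character(resolved_json))
  writeLines(resolved_json, resolved_path)

  acq_args <- cfg$acquisition %||% list()
  if (!is.null(acq_args$frame_shape)) acq_args$frame_shape <- unlist(acq_args$frame_shape)
  acq_args$seed <- cfg$seed
  acq <- do.call(acquisition_config, acq_args)
  ft <- cfg$features %||% list()
  tau_free <- ft$tau_free_ns %||% 0.45
  band_fraction <- ft$band_fraction %||% 0.3
  count_threshold <- ft$count_threshold %||% 30

  presets <- load_population_presets()
  pops <- cfg$populations
  if (is.data.frame(pops)) pops <- split(pops, seq_len(nrow(pops)))
  specs <- lapply(pops, function(p) {
    if (!is.null(p$preset) && !anyNA(p$preset)) {
      if (!p$preset %in% names(presets)) {
        stop("config error: unknown preset ", p$preset, call. = FALSE)
      }
      sp <- presets[[p$preset]]
      sp$n_cells <- as.integer(p$n_cells)
      sp
    } else {
      population_spec(p$name, p$n_cells,
                      means = as.list(p$means %||% list()),
                      sds = as.list(p$sds %||% list()))
    }
  })

  # stage 1: simulate one field per population
  fields_dir <- file.path(out_dir, "fields")
  cells_path <- file.path(out_dir, "cells.csv")
  tables <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    fdir <- file.path(fields_dir, sp$name)
    pop_seed <- cfg$seed + 1000L * i
    if (cache_valid && file.exists(file.path(fdir, "truth.csv"))) {
      say("simulate: cached field for ", sp$name)
    } else {
      say("simulate: ", sp$n_cells, " ", sp$name, " cells")
      truths <- sample_population(sp, acq$frame_shape, seed = pop_seed,
                                  id_offset = 10000L * i)
      field <- render_field(truths, acq, seed = pop_seed + 1L,
                            band_fraction = band_fraction)
      write_field(field, fdir)
    }
    # stage 2: phasor + MOB extraction
    say("extract: ", sp$name)
    fld <- read_field(fdir)
    phx <- phasor_transform(fld$nadph)
    write_phasor_image(phx, file.path(out_dir, paste0("phasor_", sp$name)))
    tab <- extract_mob_table(fld$nadph, fld$fad, fld$mask,
                             tau_free = tau_free,
                             band_fraction = band_fraction,
                             count_threshold = count_threshold,
                             truth = fld$truth)
    tables[[sp$name]] <- tab
  }
  cells <- do.call(rbind, tables)
  rownames(cells) <- NULL
  write_cell_table(cells, cells_path)

  report <- list(
    package_version = as.character(utils::packageVersion("mobflim")),
    seed = cfg$seed,
    n_cells = nrow(cells),
    populations = lapply(split(cells, cells$population), function(d) {
      list(n = nrow(d),
           orr = mean(d$orr, na.rm = TRUE),
           alpha_bound = mean(d$alpha_bound, na.rm = TRUE),
           tau_bound_ns = mean(d$tau_bound_ns, na.rm = TRUE),
           edge_center_ratio = mean(d$edge_center_ratio, na.rm = TRUE),
           polarity = mean(d$polarity, na.rm = TRUE))
    })
  )

  # stage 3: PCA + LDA gate
  if (!is.null(cfg$gate)) {
    say("gate: LDA plane for ", cfg$gate$target)
    gm <- fit_gate_model(cells, target = cfg$gate$target,
                         features = mob_features(cfg$gate$features %||% "all"),
                         k = cfg$gate$k %||% 3L)
    write_gate_model(gm, file.path(out_dir, "gate.json"))
    gated <- apply_gate(gm, cells)
    utils::write.csv(gated$cells, file.path(out_dir, "gated.csv"),
                     row.names = FALSE)
    report$gate <- list(
      target = cfg$gate$target,
      explained_variance = as.numeric(gm$explained),
      fractions = stats::setNames(as.list(gated$fractions$fraction_target_side),
                                  gated$fractions$population)
    )
  }

  # stage 4: SVM classifier on two populations
  if (!is.null(cfg$classifier)) {
    cl <- cfg$classifier
    tp <- unlist(cl$train_populations)
    say("classify: SVM ", tp[1], " vs ", tp[2])
    sub <- cells[cells$population %in% tp, ]
    model <- train_svm(sub, positive = cl$positive,
                       threshold = cl$threshold %||% 0.5,
                       seed = cfg$seed + 77L)
    write_classifier_model(model, file.path(out_dir, "classifier.json"))
    pred <- predict_hsc(model, sub)
    utils::write.csv(pred, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    ev <- evaluate_against_reporter(pred$predicted_positive,
                                    sub$population == cl$positive)
    report$classifier <- list(
      positive = cl$positive,
      train_populations = as.list(tp),
      cv_accuracy = model$metadata$best_cv_accuracy,
      training_sensitivity = ev$sensitivity,
      training_specificity = ev$specificity
    )
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  say("done: report.json written")
  invisible(report)
}
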