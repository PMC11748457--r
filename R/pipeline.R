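#' Default configuration of the two-scenario analysis
#'
#' One config drives the whole workflow: synthetic landscape, virtual
#' occurrences, thinning, collinearity filtering, repeated fits under a
#' natural-only scenario (scenario 1) and a disturbance scenario
#' (scenario 2, adds the land-use layer), ensembles, habitat
#' classification and accounting, optional future periods and the
#' random-pairing experiment. All randomness derives from `seed`.
#'
#' The synthetic defaults mirror the study conditions at desk scale: a
#' 100 x 100 km landscape of 1-km cells, 82 raw virtual presences
#' thinned at 3 km (the 30-km thinning radius and 50-km rubric buffer
#' of the continental-scale system are rescaled to this 100-km domain:
#' 3 km and 25 km respectively), 500 pseudo-absences, an 80/20 split,
#' |r| <= 0.8 collinearity threshold and 10 repetitions.
#'
#' @param seed master seed.
#' @param n_repetitions fit repetitions per scenario.
#' @param algorithms learner ids to run (default: full registry).
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1, n_repetitions = 10,
                            algorithms = sdm_algorithms()) {
  list(
    seed = seed,
    grid = list(n_rows = 100, n_cols = 100, cell_size_km = 1),
    occurrences = list(n_presences = 82, thinning_radius_km = 3),
    pseudo_absence = list(n = 500, exclusion_km = 0,
                          redraw_per_repetition = TRUE),
    split = c(train = 0.8, valid = 0.2),
    correlation_threshold = 0.8,
    n_repetitions = n_repetitions,
    algorithms = algorithms,
    ensemble = list(k = 5, quality_gate = 0.7),
    jenks = list(n_classes = 4, max_sample = 10000, shared_breaks = FALSE),
    scenario2_enabled = TRUE,
    future_periods = list(
      ssp126_2050s = c(bio12 = 0.5, bio01 = 0.6),
      ssp585_2090s = c(bio12 = 1.2, bio01 = 1.5)
    ),
    pairing = list(enabled = TRUE, n_repetitions = 10, n_top = 20,
                   radius_km = 25, margin = 0.10)
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$split <- unlist(cfg$split)
  cfg$future_periods <- lapply(cfg$future_periods, unlist)
  cfg
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()] list.
#' @export
write_pipeline_config <- function(config, path) {
  # named vectors become YAML maps so names survive the round trip
  config$split <- as.list(config$split)
  config$future_periods <- lapply(config$future_periods, as.list)
  yaml::write_yaml(config, path)
  invisible(path)
}

# additive climate perturbation: shift named layers by k standard deviations
apply_period <- function(stack, shifts_sd) {
  for (v in names(shifts_sd)) {
    lay <- stack$layers[[v]]
    if (is.null(lay)) stop(sprintf("period shift names unknown layer '%s'", v))
    stack$layers[[v]] <- lay + shifts_sd[[v]] * stats::sd(as.vector(lay))
  }
  stack
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full two-scenario analysis
#'
#' Executes every stage from synthetic-landscape generation through the
#' pairing experiment, fully reproducible from `config$seed`. Stage
#' seeds are derived deterministically from the master seed and stored
#' in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return a manifest list: inputs, selected variables, per-fit metrics
#'   table, ensembles, suitability maps, classified maps, area reports,
#'   centroids, change analyses, pairing tallies and G-test.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  seed <- config$seed
  log_stage(quiet, "[simulate] %dx%d landscape, seed %s",
            config$grid$n_rows, config$grid$n_cols, format(seed))
  land <- simulate_landscape(config$grid$n_rows, config$grid$n_cols,
                             config$grid$cell_size_km, seed = seed)
  stack <- land$stack

  occ_raw <- generate_occurrences(stack, land$niche,
                                  config$occurrences$n_presences,
                                  seed = derive_seed(seed, 10))
  occ <- thin_occurrences(occ_raw, config$occurrences$thinning_radius_km,
                          seed = derive_seed(seed, 11))
  log_stage(quiet, "[thin] %d raw -> %d retained", nrow(occ_raw), nrow(occ))

  vars_all <- pearson_filter(stack, config$correlation_threshold)
  vars_s1 <- setdiff(vars_all, names(stack$categorical))
  scenarios <- list(scenario1_natural = vars_s1)
  if (isTRUE(config$scenario2_enabled)) {
    scenarios$scenario2_disturbance <- vars_all
  }

  metrics_rows <- list()
  fits_by_scenario <- list()
  tables_by_scenario <- list()
  for (sc in names(scenarios)) {
    vars <- scenarios[[sc]]
    fits <- list()
    pa_fixed <- NULL
    for (rep_i in seq_len(config$n_repetitions)) {
      pa_seed <- derive_seed(seed, 100 + rep_i)
      if (isTRUE(config$pseudo_absence$redraw_per_repetition) || is.null(pa_fixed)) {
        pa_fixed <- sample_pseudo_absences(stack, occ, config$pseudo_absence$n,
                                           config$pseudo_absence$exclusion_km,
                                           seed = pa_seed)
      }
      tab <- build_model_table(stack, occ, pa_fixed, vars)
      tab <- split_rows(tab, config$split, seed = derive_seed(seed, 200 + rep_i))
      if (rep_i == 1L) tables_by_scenario[[sc]] <- tab
      for (alg in config$algorithms) {
        f <- fit_single_model(alg, tab, repetition = rep_i,
                              seed = derive_seed(seed, 1000 * match(sc, names(scenarios)) +
                                                   10 * rep_i + match(alg, sdm_algorithms())))
        f$table <- tab
        fits[[length(fits) + 1L]] <- f
        metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
          scenario = sc, algorithm = alg, repetition = rep_i,
          TSS = if (f$failed) NA else f$metrics$K_TSS,
          AUC = if (f$failed) NA else f$metrics$K_ROC,
          KAPPA = if (f$failed) NA else f$metrics$K_KAPPA,
          CSI = if (f$failed) NA else f$metrics$K_CSI,
          gamma = f$gamma, failed = f$failed)
      }
    }
    fits_by_scenario[[sc]] <- fits
    log_stage(quiet, "[fit] %s: %d fits (%d failed)", sc, length(fits),
              sum(vapply(fits, function(f) f$failed, TRUE)))
  }
  metrics <- do.call(rbind, metrics_rows)

  ensembles <- list()
  maps <- list()
  classified <- list()
  reports <- list()
  centroids <- list()
  for (sc in names(scenarios)) {
    ok <- Filter(function(f) !f$failed, fits_by_scenario[[sc]])
    tab <- ok[[1L]]$table
    # the TSS-gated committee can legitimately fail when no single model
    # clears the gate; that is recorded, and the ungated AUC committee maps
    ens_tss <- tryCatch(
      select_and_ensemble(ok, tab, metric = "TSS", k = config$ensemble$k,
                          quality_gate = config$ensemble$quality_gate),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "ensemble_failure"))
    ens_auc <- select_and_ensemble(ok, tab, metric = "AUC",
                                   k = config$ensemble$k, quality_gate = NULL)
    best <- if (!inherits(ens_tss, "ensemble_failure") &&
                ens_tss$metrics$K_ROC > ens_auc$metrics$K_ROC) ens_tss else ens_auc
    ensembles[[sc]] <- list(EMmodels_TSS = ens_tss, EMmodels_AUC = ens_auc,
                            mapping = best)
    suit <- predict_suitability(best, stack, scenarios[[sc]])
    maps[[sc]] <- suit
    cmap <- jenks_classify(suit, config$jenks$n_classes,
                           geometry = map_geometry(stack), provenance = sc,
                           max_sample = config$jenks$max_sample)
    classified[[sc]] <- cmap
    reports[[sc]] <- area_report(cmap, stack$cell_size_km^2)
    centroids[[sc]] <- mean_center(cmap)
    log_stage(quiet, "[classify] %s: suitable %.3f x 1e4 km^2", sc,
              total_suitable(reports[[sc]]))
  }

  shared_breaks <- if (isTRUE(config$jenks$shared_breaks)) {
    classified[[1L]]$breaks
  } else NULL

  futures <- list()
  for (p in names(config$future_periods)) {
    pstack <- apply_period(stack, config$future_periods[[p]])
    for (sc in names(scenarios)) {
      key <- paste(sc, p, sep = ".")
      suit <- predict_suitability(ensembles[[sc]]$mapping, pstack, scenarios[[sc]])
      cmap <- jenks_classify(suit, config$jenks$n_classes, breaks = shared_breaks,
                             geometry = map_geometry(stack), provenance = key,
                             max_sample = config$jenks$max_sample)
      rep_f <- area_report(cmap, stack$cell_size_km^2)
      futures[[key]] <- list(
        classified = cmap, report = rep_f, centroid = mean_center(cmap),
        change_vs_current = change_analysis(reports[[sc]], rep_f),
        displacement = centroid_displacement(centroids[[sc]], mean_center(cmap)))
    }
    log_stage(quiet, "[future] period %s done", p)
  }

  pairing <- NULL
  if (isTRUE(config$pairing$enabled) && length(scenarios) == 2L) {
    pairing <- run_pairing_experiment(
      fits_by_scenario, stack, scenarios, occ, config,
      seed = derive_seed(seed, 7000), quiet = quiet)
  }

  structure(list(config = config, stack = stack, niche = land$niche,
                 occurrences_raw = occ_raw, occurrences = occ,
                 selected_variables = scenarios, metrics = metrics,
                 fits = fits_by_scenario, ensembles = ensembles,
                 suitability = maps, classified = classified,
                 reports = reports, centroids = centroids,
                 futures = futures, pairing = pairing),
            class = "sdm_manifest")
}

# Randomized pairing validation: per repetition, draw one model from the
# top-n_top (by composite score) pool of each scenario, map and classify
# both, and score the held-out validation presences with the rubric.
run_pairing_experiment <- function(fits_by_scenario, stack, scenarios, occ,
                                   config, seed, quiet = FALSE) {
  cfg <- rubric_config(radius_km = config$pairing$radius_km,
                       margin = config$pairing$margin)
  ok1 <- Filter(function(f) !f$failed, fits_by_scenario[[1L]])
  ok2 <- Filter(function(f) !f$failed, fits_by_scenario[[2L]])
  outcomes <- list()
  for (r in seq_len(config$pairing$n_repetitions)) {
    i1 <- suppressWarnings(random_pair_selection(ok1, config$pairing$n_top,
                                                 seed = derive_seed(seed, 2 * r)))
    i2 <- suppressWarnings(random_pair_selection(ok2, config$pairing$n_top,
                                                 seed = derive_seed(seed, 2 * r + 1)))
    f1 <- ok1[[i1]]; f2 <- ok2[[i2]]
    m1 <- jenks_classify(predict_suitability(f1, stack, scenarios[[1L]]),
                         config$jenks$n_classes, geometry = map_geometry(stack),
                         max_sample = config$jenks$max_sample)
    m2 <- jenks_classify(predict_suitability(f2, stack, scenarios[[2L]]),
                         config$jenks$n_classes, geometry = map_geometry(stack),
                         max_sample = config$jenks$max_sample)
    va <- f2$table[f2$table$split == "valid" & f2$table$response == 1L, ]
    tr <- score_points(va, m1, m2, cfg)
    tr$repetition <- r
    tr$control_model <- paste0(f1$algorithm, "(", f1$repetition, ")")
    tr$test_model <- paste0(f2$algorithm, "(", f2$repetition, ")")
    outcomes[[r]] <- tr
    log_stage(quiet, "[pairing] rep %d: %s vs %s", r,
              tr$control_model[1L], tr$test_model[1L])
  }
  trace <- do.call(rbind, outcomes)
  tally <- tally_repetitions(trace)
  n_rep <- config$pairing$n_repetitions
  gt <- if (n_rep >= 2L) {
    tab <- tally$table[seq_len(n_rep), c("control", "test")]
    ok_rows <- rowSums(tab) > 0
    if (sum(ok_rows) >= 2L && all(colSums(tab[ok_rows, ]) > 0)) {
      g_test(as.matrix(tab[ok_rows, ]))
    } else NULL
  } else NULL
  list(trace = trace, tally = tally, g_test = gt)
}

#' Write the report bundle of a pipeline run
#'
#' Emits per-fit metrics, composite-score tables, per-map area tables,
#' centroid GeoJSON, pairing tallies and the G-test summary as plain
#' text files under `out_dir`.
#'
#' @param manifest a [run_pipeline()] manifest.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_reports <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  w(manifest$metrics, "model_metrics.csv")
  areas <- do.call(rbind, lapply(names(manifest$reports), function(sc) {
    cbind(map = sc, as.data.frame(manifest$reports[[sc]]))
  }))
  fut <- do.call(rbind, lapply(names(manifest$futures), function(k) {
    cbind(map = k, as.data.frame(manifest$futures[[k]]$report))
  }))
  w(rbind(areas, fut), "habitat_areas.csv")
  writeLines(unlist(lapply(names(manifest$selected_variables), function(sc) {
    c(sc, paste(" ", manifest$selected_variables[[sc]]))
  })), file.path(out_dir, "selected_variables.txt"))
  files <- c(files, file.path(out_dir, "selected_variables.txt"))

  cents <- c(manifest$centroids,
             lapply(manifest$futures, function(f) f$centroid))
  geo <- list(type = "FeatureCollection", features = lapply(names(cents), function(nm) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = as.numeric(cents[[nm]])),
         properties = list(name = nm))
  }))
  gp <- file.path(out_dir, "centroids.geojson")
  jsonlite::write_json(geo, gp, auto_unbox = TRUE, digits = NA)
  files <- c(files, gp)

  if (!is.null(manifest$pairing)) {
    w(manifest$pairing$tally$table, "pairing_tally.csv")
    w(manifest$pairing$trace, "pairing_trace.csv")
    if (!is.null(manifest$pairing$g_test)) {
      gt <- manifest$pairing$g_test
      jp <- file.path(out_dir, "g_test.json")
      jsonlite::write_json(list(G = gt$G, df = gt$df, p_value = gt$p_value),
                           jp, auto_unbox = TRUE, digits = NA)
      files <- c(files, jp)
    }
  }
  yaml::write_yaml(manifest$config, file.path(out_dir, "config.yaml"))
  files <- c(files, file.path(out_dir, "config.yaml"))
  invisible(files)
}
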