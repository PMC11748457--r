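# Seeded parameter-recovery experiment on the full synthetic study
# conditions (100x100 km landscape, known precipitation/slope niche,
# urban+cropland disturbance mask). Shared by the acceptance suite;
# computed once per test run and cached.

recovery_run <- function(seed) {
  land <- simulate_landscape(100, 100, 1, seed = seed)
  stack <- land$stack
  occ <- thin_occurrences(
    generate_occurrences(stack, land$niche, 82, seed = seed + 500), 3,
    seed = seed + 600)
  pa <- sample_pseudo_absences(stack, occ, 500, seed = seed + 700)
  vars2 <- pearson_filter(stack, 0.8)
  vars1 <- setdiff(vars2, names(stack$categorical))

  algs <- c("GLM", "FDA", "RF", "XGBOOST", "MAXENT")
  fit_scenario <- function(vars) {
    tab <- split_rows(build_model_table(stack, occ, pa, vars), c(0.8, 0.2),
                      seed = seed + 800)
    fits <- lapply(algs, fit_single_model, table = tab, seed = seed + 900)
    ens <- select_and_ensemble(Filter(function(f) !f$failed, fits), tab,
                               metric = "AUC", k = 5)
    list(tab = tab, fits = fits, ens = ens)
  }
  s1 <- fit_scenario(vars1)
  s2 <- fit_scenario(vars2)

  imp <- variable_importance(s1$ens, s1$tab, n_permutations = 3,
                             seed = seed + 950)
  top2 <- names(sort(imp, decreasing = TRUE))[1:2]

  geom <- list(origin = stack$origin, cell_size_km = stack$cell_size_km)
  map1 <- jenks_classify(predict_suitability(s1$ens, stack, vars1),
                         geometry = geom, provenance = "scenario1")
  map2 <- jenks_classify(predict_suitability(s2$ens, stack, vars2),
                         geometry = geom, provenance = "scenario2")
  rep1 <- area_report(map1, 1)
  rep2 <- area_report(map2, 1)

  # ground-truth mask effect on the true suitability surface
  suit_unmasked <- true_suitability(stack, niche_params(
    intercept = land$niche$intercept, linear = land$niche$linear,
    quadratic = land$niche$quadratic))
  suit_masked <- true_suitability(stack, land$niche)

  cfg <- rubric_config(radius_km = 25, margin = 0.10)
  va <- s2$tab[s2$tab$split == "valid" & s2$tab$response == 1, ]
  trace <- score_points(va, map1, map2, cfg)

  list(seed = seed,
       ens_auc = s1$ens$metrics$K_ROC,
       top2 = top2,
       suitable_s1 = total_suitable(rep1),
       suitable_s2 = total_suitable(rep2),
       true_mask_reduces = sum(suit_masked) < sum(suit_unmasked),
       pairing_control = sum(trace$outcome == "control"),
       pairing_test = sum(trace$outcome == "test"))
}

recovery_results <- local({
  cache <- NULL
  function(seeds = 1:10) {
    if (is.null(cache)) cache <<- lapply(seeds, recovery_run)
    cache
  }
})
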