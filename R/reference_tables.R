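# Published summary tables from the S. incognitus case study. These are
# the printed inputs for worked examples and arithmetic checks (the
# original rasters and occurrence supplements are not redistributed).

#' Published random-pairing model table (metrics and composite scores)
#'
#' Per scenario and pairing group: the randomly drawn model, its CSI,
#' kappa, AUC and TSS on the held-out validation points, and the printed
#' composite score (3 decimals).
#'
#' @return data.frame with columns `scenario`, `group`, `serial`,
#'   `model`, `repetition`, `CSI`, `KAPPA`, `AUC`, `TSS`,
#'   `gamma_printed`.
#' @export
sincognitus_model_scores <- function() {
  s1 <- data.frame(
    scenario = "scenario1_natural", group = 1:10,
    serial = c(16, 14, 12, 9, 20, 12, 10, 1, 6, 20),
    model = c("GLM", "XGBOOST", "ANN", "GBM", "GLM", "ANN", "ANN",
              "EMmodels", "GLM", "MAXENT"),
    repetition = c(1, 4, 9, 2, 5, 7, 5, 1, 4, 4),
    CSI = c(0.467, 0.583, 0.421, 0.5, 0.467, 0.444, 0.571, 0.837, 0.471, 0.353),
    KAPPA = c(0.597, 0.712, 0.542, 0.632, 0.597, 0.569, 0.698, 0.903, 0.597, 0.468),
    AUC = c(0.956, 0.971, 0.929, 0.96, 0.966, 0.943, 0.972, 0.993, 0.959, 0.917),
    TSS = c(0.85, 0.748, 0.789, 0.799, 0.84, 0.799, 0.94, 0.944, 0.88, 0.78),
    gamma_printed = c(0.359, 0.377, 0.335, 0.361, 0.359, 0.344, 0.398,
                      0.460, 0.363, 0.315))
  s2 <- data.frame(
    scenario = "scenario2_disturbance", group = 1:10,
    serial = c(10, 20, 18, 17, 10, 9, 5, 16, 5, 13),
    model = c("MAXENT", "MAXENT", "GLM", "XGBOOST", "GLM", "MARS", "GLM",
              "FDA", "GBM", "GBM"),
    repetition = c(4, 10, 3, 7, 6, 1, 3, 9, 10, 5),
    CSI = c(0.455, 0.4, 0.417, 0.5, 0.389, 0.533, 0.643, 0.471, 0.583, 0.4),
    KAPPA = c(0.596, 0.517, 0.554, 0.637, 0.508, 0.662, 0.758, 0.597, 0.712, 0.527),
    AUC = c(0.961, 0.951, 0.974, 0.972, 0.943, 0.978, 0.994, 0.969, 0.965, 0.958),
    TSS = c(0.829, 0.81, 0.870, 0.637, 0.749, 0.89, 0.94, 0.809, 0.748, 0.718),
    gamma_printed = c(0.355, 0.335, 0.352, 0.311, 0.324, 0.383, 0.417,
                      0.356, 0.376, 0.325))
  rbind(s1, s2)
}

#' Published random-pairing tallies (10 repetitions)
#'
#' Control/test/equality point counts per pairing repetition, plus the
#' habitat-fragmentation sub-score (a subset of the test points).
#'
#' @return data.frame with columns `repetition`, `control`, `test`,
#'   `equality`, `fragmentation`.
#' @export
sincognitus_pairing_tally <- function() {
  data.frame(
    repetition = 1:10,
    control = c(2, 4, 2, 4, 2, 4, 1, 8, 2, 5),
    test = c(8, 5, 13, 10, 2, 7, 9, 0, 9, 11),
    equality = c(6, 7, 1, 2, 12, 5, 6, 8, 5, 0),
    fragmentation = c(11, 0, 10, 4, 1, 5, 6, 0, 3, 10))
}

#' Published per-grade habitat areas, current climate (10^4 km^2)
#'
#' @return data.frame with columns `scenario`, `class`, `area_1e4_km2`,
#'   `proportion_pct`.
#' @export
sincognitus_current_areas <- function() {
  data.frame(
    scenario = rep(c("scenario1_natural", "scenario2_disturbance"), each = 4),
    class = rep(c("highly", "moderately", "poorly", "unsuitable"), 2),
    area_1e4_km2 = c(61.95, 69.94, 52.35, 773.61,
                     37.19, 30.62, 72.3, 817.74),
    proportion_pct = c(6.47, 7.30, 5.47, 80.77,
                       3.88, 3.20, 7.55, 85.37))
}

#' Published future-period habitat areas (10^4 km^2)
#'
#' Per-grade suitable areas for the two current scenarios and the four
#' future climate/period combinations (disturbance included).
#'
#' @return data.frame with columns `period`, `highly`, `moderately`,
#'   `poorly`, `total_suitable`.
#' @export
sincognitus_future_areas <- function() {
  data.frame(
    period = c("current_scenario1", "current_scenario2",
               "ssp126_2050s", "ssp585_2050s", "ssp126_2090s", "ssp585_2090s"),
    highly = c(61.95, 37.19, 36.82, 40.64, 36.34, 66.16),
    moderately = c(69.94, 30.62, 17.34, 39.04, 37.3, 40.25),
    poorly = c(52.35, 72.3, 75.45, 65.74, 36.89, 60.74),
    total_suitable = c(184.24, 140.11, 129.61, 145.42, 110.53, 167.15))
}

#' Published single-model ensemble shortlist (TSS and AUC blocks)
#'
#' The ten models listed per scenario: the five highest-TSS and five
#' highest-AUC single models that entered the two ensembles.
#'
#' @return data.frame with columns `scenario`, `block`, `model`,
#'   `repetition`, `TSS`, `AUC`.
#' @export
sincognitus_ensemble_shortlist <- function() {
  data.frame(
    scenario = rep(c("scenario1_natural", "scenario2_disturbance"), each = 10),
    block = rep(rep(c("TSS", "AUC"), each = 5), 2),
    model = c("CTA", "ANN", "GLM", "MAXNET", "RF",
              "GLM", "MAXNET", "RF", "GBM", "GLM",
              "CTA", "CTA", "CTA", "GLM", "CTA",
              "FDA", "GBM", "RF", "GLM", "GBM"),
    repetition = c(4, 4, 4, 4, 9, 4, 4, 4, 4, 9,
                   3, 10, 1, 2, 6, 10, 10, 1, 10, 8),
    TSS = c(0.9, 0.9, 0.88, 0.87, 0.847, 0.88, 0.87, 0.563, 0.783, 0.82,
            0.9, 0.9, 0.89, 0.89, 0.89, 0.857, 0.627, 0.543, 0.627, 0.523),
    AUC = c(0.95, 0.95, 0.991, 0.983, 0.964, 0.991, 0.983, 0.98, 0.977, 0.968,
            0.95, 0.95, 0.945, 0.953, 0.945, 0.975, 0.97, 0.968, 0.967, 0.966))
}

#' Area identities printed for the current-climate comparison
#'
#' Convenience accessor mirroring the published contrast: total suitable
#' areas of the two current scenarios and their difference.
#'
#' @return named list: `total_s1`, `total_s2`, `reduction_1e4_km2`,
#'   `reduction_pct`.
#' @export
sincognitus_area_contrast <- function() {
  cur <- sincognitus_current_areas()
  s1 <- sum(cur$area_1e4_km2[cur$scenario == "scenario1_natural" &
                               cur$class != "unsuitable"])
  s2 <- sum(cur$area_1e4_km2[cur$scenario == "scenario2_disturbance" &
                               cur$class != "unsuitable"])
  list(total_s1 = s1, total_s2 = s2,
       reduction_1e4_km2 = s1 - s2,
       reduction_pct = 100 * (s1 - s2) / s1)
}
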