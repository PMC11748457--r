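#' Thin occurrence records to a minimum separation
#'
#' Greedy thinning over a seeded random ordering: points are visited in
#' random order and a point is retained iff it lies at least `radius_km`
#' (great-circle) from every point already retained. Mirrors the common
#' "retain one point per radius" filter used to curb spatial
#' autocorrelation in occurrence data.
#'
#' @param occ an [occurrence_set()].
#' @param radius_km minimum pairwise separation, km (> 0).
#' @param seed RNG seed controlling the visiting order.
#' @return the retained [occurrence_set()]; the visiting order is
#'   attached as attribute `"order"`.
#' @export
thin_occurrences <- function(occ, radius_km, seed = 1) {
  stopifnot_scalar_pos(radius_km, "radius_km")
  n <- nrow(occ)
  if (n == 0L) return(occ)
  ord <- with_seed(seed, sample.int(n))
  pts <- cbind(occ$lon, occ$lat)[ord, , drop = FALSE]
  keep <- logical(n)
  keep[1L] <- TRUE
  for (i in seq_len(n)[-1L]) {
    d <- haversine_km(pts[i, , drop = FALSE], pts[keep, , drop = FALSE])
    keep[i] <- all(d >= radius_km)
  }
  out <- occ[sort(ord[keep]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrence_set", "data.frame")
  attr(out, "order") <- ord
  out
}

#' Greedy collinearity filter on continuous predictors
#'
#' Visits continuous layers in priority order and keeps a variable iff
#' its absolute Pearson correlation (over non-missing cells) with every
#' already-kept variable is at most `threshold`. Categorical layers are
#' not tested and always pass through.
#'
#' @param stack an [env_stack()] with >= 2 continuous layers.
#' @param threshold correlation bound in `(0, 1]` (0.8 for the main
#'   analysis, 0.9 for the pairing experiment).
#' @param priority_order optional character vector; defaults to the
#'   published surviving-variable order when those names exist in the
#'   stack, else to descending variance.
#' @return character vector: kept continuous variables followed by the
#'   categorical layers.
#' @export
pearson_filter <- function(stack, threshold = 0.8, priority_order = NULL) {
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]")
  vars <- names(stack$layers)
  if (length(vars) < 2L) stop("need at least 2 continuous variables")
  if (is.null(priority_order)) {
    canonical <- c("hillshade", "bio15", "alt", "bio08", "bio12", "bio17",
                   "aspect", "bio07", "slope", "bio02")
    if (all(canonical %in% vars)) {
      priority_order <- c(canonical, setdiff(vars, canonical))
    } else {
      v <- vapply(stack$layers, function(m) stats::var(as.vector(m), na.rm = TRUE), 0)
      priority_order <- vars[order(-v)]
    }
  }
  priority_order <- intersect(priority_order, vars)
  vals <- vapply(priority_order, function(v) as.vector(stack$layers[[v]]),
                 numeric(stack$n_rows * stack$n_cols))
  cm <- abs(stats::cor(vals, use = "pairwise.complete.obs"))
  kept <- character()
  for (v in priority_order) {
    if (all(cm[v, kept] <= threshold)) kept <- c(kept, v)
  }
  c(kept, names(stack$categorical))
}

#' Sample pseudo-absence cells uniformly over the eligible domain
#'
#' Eligible cells are non-missing in every continuous layer and at least
#' `exclusion_km` from every presence. Exactly `n` distinct cells are
#' drawn uniformly; their centers are returned.
#'
#' @param stack an [env_stack()].
#' @param presences an [occurrence_set()].
#' @param n number of pseudo-absences (the analysis default is 500).
#' @param exclusion_km presence exclusion buffer, km (default 0).
#' @param seed RNG seed.
#' @return data.frame `lon`, `lat` of the drawn cell centers.
#' @export
sample_pseudo_absences <- function(stack, presences, n, exclusion_km = 0,
                                   seed = 1) {
  stopifnot_scalar_pos(n, "n")
  centers <- cell_centers(stack)
  ok <- rep(TRUE, nrow(centers))
  for (lay in stack$layers) {
    ok <- ok & !is.na(lay[cbind(centers$row, centers$col)])
  }
  pres_cells <- point_to_cell(stack, presences$lon, presences$lat)
  pres_idx <- (pres_cells$col - 1L) * stack$n_rows + pres_cells$row
  cell_idx <- (centers$col - 1L) * stack$n_rows + centers$row
  ok[cell_idx %in% pres_idx] <- FALSE
  if (exclusion_km > 0 && nrow(presences) > 0) {
    d <- haversine_matrix_km(centers[, c("lon", "lat")],
                             presences[, c("lon", "lat")])
    ok <- ok & apply(d, 1L, min) >= exclusion_km
  }
  n_ok <- sum(ok)
  if (n_ok < n) {
    stop(sprintf("only %d eligible cells for %d pseudo-absences (shortfall %d)",
                 n_ok, n, n - n_ok))
  }
  sel <- with_seed(seed, sample(which(ok), n))
  data.frame(lon = centers$lon[sel], lat = centers$lat[sel], row.names = NULL)
}

#' Assemble the modelling table
#'
#' Extracts predictor values at presence and pseudo-absence cells into a
#' flat table with a binary response. Categorical variables are stored as
#' integer codes and flagged via the `"categorical"` attribute.
#'
#' @param stack an [env_stack()].
#' @param presences an [occurrence_set()].
#' @param absences data.frame `lon`, `lat` from
#'   [sample_pseudo_absences()].
#' @param variables character vector of predictor names (default: all).
#' @return data.frame with `lon`, `lat`, `response` and one column per
#'   predictor; attributes `"variables"` and `"categorical"`.
#' @export
build_model_table <- function(stack, presences, absences, variables = NULL) {
  if (is.null(variables)) {
    variables <- c(names(stack$layers), names(stack$categorical))
  }
  pts <- rbind(data.frame(lon = presences$lon, lat = presences$lat, response = 1L),
               data.frame(lon = absences$lon, lat = absences$lat, response = 0L))
  cells <- point_to_cell(stack, pts$lon, pts$lat)
  if (anyNA(cells$row)) stop("some points fall outside the stack extent")
  for (v in variables) {
    pts[[v]] <- layer_at_cells(stack, v, cells$row, cells$col)
  }
  if (anyNA(pts[variables])) stop("missing predictor values in model table")
  attr(pts, "variables") <- variables
  attr(pts, "categorical") <- intersect(variables, names(stack$categorical))
  pts
}

#' Stratified train/validation split
#'
#' Tags each row `train` or `valid`, stratified by response class. Per
#' class, the train count is `round(train_fraction * class size)` unless
#' `forced_counts` pins the presence split exactly (used to reproduce
#' published 45/17 style counts that rounding alone cannot produce).
#'
#' @param table a model table from [build_model_table()].
#' @param fractions numeric `(train, valid)` summing to 1.
#' @param seed RNG seed.
#' @param forced_counts optional integer `(train, valid)` counts for the
#'   presence class; must sum to the number of presences.
#' @return the table with a `split` column added.
#' @export
split_rows <- function(table, fractions = c(0.8, 0.2), seed = 1,
                       forced_counts = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  split <- rep(NA_character_, nrow(table))
  for (cls in unique(table$response)) {
    idx <- which(table$response == cls)
    if (cls == 1L && !is.null(forced_counts)) {
      if (sum(forced_counts) != length(idx)) {
        stop("`forced_counts` must sum to the number of presences")
      }
      n_train <- forced_counts[1L]
    } else {
      n_train <- round(fractions[1L] * length(idx))
    }
    ord <- with_seed(derive_seed(seed, cls), sample(idx))
    split[ord[seq_len(n_train)]] <- "train"
    split[ord[-seq_len(n_train)]] <- "valid"
  }
  if (sum(split == "train" & table$response == 1L) == 0L ||
      sum(split == "valid" & table$response == 1L) == 0L) {
    stop("a split received zero presences")
  }
  table$split <- split
  table
}
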