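#' Presence records with provenance
#'
#' @param lon,lat point coordinates, degrees.
#' @param source per-point provenance labels (recycled).
#' @return data.frame of class `occurrence_set` with columns
#'   `lon`, `lat`, `source`; duplicated coordinate pairs are rejected.
#' @export
occurrence_set <- function(lon, lat, source = "unknown") {
  if (length(lon) != length(lat)) stop("`lon` and `lat` lengths differ")
  df <- data.frame(lon = as.numeric(lon), lat = as.numeric(lat),
                   source = rep_len(as.character(source), length(lon)),
                   row.names = NULL)
  if (anyDuplicated(df[, c("lon", "lat")])) {
    stop("duplicated coordinate pairs in occurrence set")
  }
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Ground-truth niche for a virtual species
#'
#' The true habitat suitability is the inverse-logit of a linear +
#' quadratic form in named stack layers, optionally forced to zero on a
#' set of land-use classes (the human-disturbance mask).
#'
#' @param intercept scalar intercept of the linear predictor.
#' @param linear named numeric vector of linear coefficients per layer.
#' @param quadratic named numeric vector of quadratic coefficients.
#' @param mask_classes integer land-use codes where suitability is 0.
#' @param mask_layer name of the categorical layer carrying the mask.
#' @param standardize if `TRUE` (default) coefficients act on z-scored
#'   layer values, so effect sizes are comparable across layers.
#' @return an object of class `niche_params`.
#' @export
niche_params <- function(intercept = 0, linear = numeric(), quadratic = numeric(),
                         mask_classes = integer(), mask_layer = "lucc",
                         standardize = TRUE) {
  if (length(linear) == 0L && length(quadratic) == 0L) {
    stop("a niche needs at least one nonzero coefficient")
  }
  structure(list(intercept = intercept, linear = linear, quadratic = quadratic,
                 mask_classes = as.integer(mask_classes),
                 mask_layer = mask_layer, standardize = standardize),
            class = "niche_params")
}

#' True suitability surface of a virtual species
#'
#' @param stack an [env_stack()].
#' @param niche a [niche_params()] whose variables exist in the stack.
#' @return matrix of suitabilities in `[0, 1]` (0 on masked cells).
#' @export
true_suitability <- function(stack, niche) {
  vars <- union(names(niche$linear), names(niche$quadratic))
  eta <- matrix(niche$intercept, stack$n_rows, stack$n_cols)
  for (v in vars) {
    lay <- stack$layers[[v]]
    if (is.null(lay)) stop(sprintf("niche variable '%s' not found in stack", v))
    if (niche$standardize) lay <- zscale(lay)
    if (!is.null(niche$linear[v]) && !is.na(niche$linear[v])) {
      eta <- eta + niche$linear[v] * lay
    }
    if (v %in% names(niche$quadratic)) {
      eta <- eta + niche$quadratic[v] * lay^2
    }
  }
  suit <- stats::plogis(eta)
  if (length(niche$mask_classes)) {
    lucc <- stack$categorical[[niche$mask_layer]]
    if (is.null(lucc)) stop(sprintf("mask layer '%s' not found", niche$mask_layer))
    suit[lucc %in% niche$mask_classes] <- 0
  }
  suit
}

#' Sample virtual-species presences from a known niche
#'
#' Cells are drawn without replacement with probability proportional to
#' the true suitability; returned points are cell centers.
#'
#' @param stack an [env_stack()].
#' @param niche a [niche_params()].
#' @param n_presences number of presence points (>= 1).
#' @param seed RNG seed.
#' @return an [occurrence_set()] with `source = "virtual"`.
#' @export
generate_occurrences <- function(stack, niche, n_presences, seed) {
  stopifnot_scalar_pos(n_presences, "n_presences")
  suit <- true_suitability(stack, niche)
  w <- as.vector(suit)
  if (all(w == 0)) stop("degenerate niche: suitability is zero everywhere")
  if (sum(w > 0) < n_presences) {
    stop(sprintf("only %d cells with positive suitability for %d presences",
                 sum(w > 0), n_presences))
  }
  centers <- cell_centers(stack)
  # cell_centers is row-major over (row, col); suit vector is column-major
  idx_map <- (centers$col - 1L) * stack$n_rows + centers$row
  with_seed(seed, {
    drawn <- sample.int(length(w), n_presences, replace = FALSE, prob = w)
    sel <- match(drawn, idx_map)
    occurrence_set(centers$lon[sel], centers$lat[sel], source = "virtual")
  })
}

#' Write / read occurrence CSV (`lon,lat,source`)
#'
#' @param occ an [occurrence_set()].
#' @param path file path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[, c("lon", "lat", "source")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  occurrence_set(df$lon, df$lat, df$source)
}

#' Simulate the default study landscape
#'
#' Builds the synthetic stand-in for the real study system: 19 climate
#' analogues (several pairs correlated above |r| = 0.8, as in WorldClim
#' bioclim layers), a DEM with slope/aspect/hillshade derivatives, a
#' clustered land-use grid dominated by woodland, and a virtual-species
#' niche driven by the precipitation analogue (`bio12`) and terrain
#' slope, with suitability removed on cropland and urban cells.
#'
#' @param n_rows,n_cols grid size (default 100 x 100).
#' @param cell_size_km cell size, km (default 1).
#' @param seed RNG seed.
#' @param n_climate number of climate analogue layers (default 19).
#' @return list with `stack` (24 predictors: `bio01..bio19`, `alt`,
#'   `slope`, `aspect`, `hillshade`, `lucc`), `niche` (the ground-truth
#'   [niche_params()]), and `mask_classes` (cropland/urban codes).
#' @export
simulate_landscape <- function(n_rows = 100, n_cols = 100, cell_size_km = 1,
                               seed = 1, n_climate = 19) {
  clim_names <- sprintf("bio%02d", seq_len(n_climate))
  # collinearity structure typical of bioclim summaries: temperature and
  # precipitation aggregates repeat information across layers
  pairs <- list(c(1, 5, 0.95), c(1, 6, 0.92), c(5, 10, 0.96), c(6, 11, 0.97),
                c(12, 13, 0.90), c(12, 16, 0.93), c(14, 17, 0.95), c(2, 7, 0.85))
  pairs <- Filter(function(p) max(p[1:2]) <= n_climate, pairs)
  stack <- generate_env_stack(n_rows, n_cols, cell_size_km,
                              n_continuous = n_climate,
                              correlated_pairs = pairs,
                              seed = derive_seed(seed, 1),
                              layer_names = clim_names)
  dem <- with_seed(derive_seed(seed, 2), {
    z <- zscale(gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols),
                                       n_rows, n_cols), 8))
    pmax(0.8 + 0.45 * z, 0)  # elevations in km
  })
  terr <- compute_terrain(dem, cell_size_km)
  stack$layers$alt <- dem
  stack$layers$slope <- terr$slope
  stack$layers$aspect <- terr$aspect
  stack$layers$hillshade <- terr$hillshade
  stack$meta <- c(stack$meta,
                  c(alt = "terrain", slope = "terrain",
                    aspect = "terrain", hillshade = "terrain"))
  shares <- c(woodland = 0.45, shrub = 0.10, grassland = 0.10,
              cropland = 0.20, urban = 0.10, water = 0.05)
  stack <- generate_lucc(stack, shares, clustering = 6,
                         seed = derive_seed(seed, 3))
  mask_classes <- stack$class_table$code[stack$class_table$name %in%
                                           c("cropland", "urban")]
  # a sharply discriminating niche: suitability is concentrated where the
  # precipitation analogue and terrain slope are both high, so the
  # suitable fraction of the landscape is small, as in the real system
  niche <- niche_params(
    intercept = -7,
    linear = c(bio12 = 5, slope = 3),
    quadratic = c(bio12 = -0.5, slope = -0.5),
    mask_classes = mask_classes
  )
  list(stack = stack, niche = niche, mask_classes = mask_classes)
}
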