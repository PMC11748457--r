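HABITAT_CLASS_NAMES <- c("unsuitable", "poorly", "moderately", "highly")

#' Fisher-Jenks natural breaks of a value sample
#'
#' Exact dynamic program minimizing total within-class sum of squared
#' deviations on the sorted sample. To bound the quadratic runtime the
#' sample is deterministically decimated (every m-th sorted value) when
#' it exceeds `max_sample`; the full sample is used otherwise.
#'
#' @param values numeric vector (NAs dropped); needs at least `k`
#'   distinct values.
#' @param k number of classes.
#' @param max_sample largest sample the exact DP runs on.
#' @return numeric vector of `k - 1` ascending break values (upper
#'   boundaries of classes 1..k-1); attribute `"wssd"` carries the
#'   optimal within-class sum of squares of the classified sample.
#' @export
jenks_breaks <- function(values, k = 4, max_sample = 10000) {
  v <- sort(values[!is.na(values)])
  if (length(unique(v)) < k) {
    stop(sprintf("need at least %d distinct values for %d classes", k, k))
  }
  if (length(v) > max_sample) {
    idx <- unique(round(seq(1L, length(v), length.out = max_sample)))
    v <- v[idx]
  }
  lim <- fisher_jenks_limits(v, as.integer(k))
  first <- lim[seq_len(k)]
  brk <- v[first[-1L] - 1L]
  attr(brk, "wssd") <- attr(lim, "cost")
  brk
}

#' Classify a suitability surface into habitat grades
#'
#' Cuts the surface at Fisher-Jenks natural breaks into `n_classes`
#' ordered grades, coded `0` (unsuitable) through `n_classes - 1`
#' (highly suitable): a cell gets class 0 iff its value is <= the first
#' break, and so on. Classification is order-preserving by construction.
#'
#' @param suitability numeric matrix in `[0, 1]` (NA = nodata).
#' @param n_classes number of grades (default 4).
#' @param breaks optional externally supplied breaks (ascending), e.g.
#'   to share one classification scale across several maps.
#' @param geometry optional list with `origin`, `cell_size_km` copied
#'   from the source [env_stack()] (needed for centroids).
#' @param provenance free-form tag (scenario / period) carried into
#'   reports.
#' @param max_sample passed to [jenks_breaks()].
#' @return object of class `classified_map`: `classes` (integer matrix),
#'   `breaks`, `geometry`, `provenance`.
#' @export
jenks_classify <- function(suitability, n_classes = 4, breaks = NULL,
                           geometry = NULL, provenance = NULL,
                           max_sample = 10000) {
  if (is.null(breaks)) {
    breaks <- jenks_breaks(as.vector(suitability), k = n_classes,
                           max_sample = max_sample)
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly ascending")
  }
  cls <- matrix(NA_integer_, nrow(suitability), ncol(suitability))
  ok <- !is.na(suitability)
  # class = number of breaks strictly below the value, so a value equal
  # to break_j stays in class j-1
  cls[ok] <- as.integer(rowSums(outer(suitability[ok], breaks, ">")))
  structure(list(classes = cls, breaks = as.numeric(breaks),
                 n_classes = as.integer(n_classes),
                 geometry = geometry, provenance = provenance),
            class = "classified_map")
}

# geometry helper shared with env_stack accessors
map_geometry <- function(stack) {
  list(origin = stack$origin, cell_size_km = stack$cell_size_km,
       n_rows = stack$n_rows, n_cols = stack$n_cols)
}

classified_centers <- function(cmap) {
  g <- cmap$geometry
  if (is.null(g)) stop("classified map carries no geometry")
  fake <- structure(list(n_rows = nrow(cmap$classes), n_cols = ncol(cmap$classes),
                         cell_size_km = g$cell_size_km, origin = g$origin),
                    class = "env_stack")
  cell_centers(fake)
}

#' Per-class habitat area accounting
#'
#' @param cmap a [jenks_classify()] map.
#' @param cell_area_km2 area of one cell, km^2.
#' @return data.frame of class `area_report` with one row per grade:
#'   `class`, `code`, `cells`, `area_1e4_km2` (units of 10^4 km^2) and
#'   `proportion_pct` of all non-nodata cells; attribute
#'   `"total_suitable_1e4_km2"` sums the three suitable grades.
#' @export
area_report <- function(cmap, cell_area_km2 = 1) {
  stopifnot_scalar_pos(cell_area_km2, "cell_area_km2")
  codes <- 0:(cmap$n_classes - 1L)
  counts <- vapply(codes, function(k) sum(cmap$classes == k, na.rm = TRUE), 0L)
  total <- sum(counts)
  nm <- if (cmap$n_classes == 4L) HABITAT_CLASS_NAMES else paste0("class", codes)
  rep <- data.frame(class = nm, code = codes, cells = counts,
                    area_1e4_km2 = counts * cell_area_km2 / 1e4,
                    proportion_pct = 100 * counts / total,
                    row.names = NULL)
  attr(rep, "total_suitable_1e4_km2") <- sum(rep$area_1e4_km2[rep$code > 0L])
  attr(rep, "provenance") <- cmap$provenance
  class(rep) <- c("area_report", "data.frame")
  rep
}

#' Total suitable habitat area of a report, 10^4 km^2
#' @param report an [area_report()].
#' @export
total_suitable <- function(report) {
  sum(report$area_1e4_km2[report$code > 0L])
}

#' Between-map habitat change accounting
#'
#' Per-class and total-suitable deltas (b - a, 10^4 km^2) and the
#' percentage change of the total relative to `report_a`
#' (`100 * (b - a) / a`; a published "decrease of X%" is `-pct_change`).
#'
#' @param report_a,report_b two [area_report()]s on the same study area.
#' @return list with `per_class` (data.frame `class`, `delta_1e4_km2`),
#'   `delta_total_1e4_km2`, `pct_change`.
#' @export
change_analysis <- function(report_a, report_b) {
  tot_a <- sum(report_a$area_1e4_km2)
  tot_b <- sum(report_b$area_1e4_km2)
  if (abs(tot_a - tot_b) > 1e-6 * max(tot_a, tot_b)) {
    stop("reports cover different study areas")
  }
  if (!identical(report_a$class, report_b$class)) {
    stop("reports have different class schemes")
  }
  suit_a <- total_suitable(report_a)
  suit_b <- total_suitable(report_b)
  list(
    per_class = data.frame(class = report_a$class,
                           delta_1e4_km2 = report_b$area_1e4_km2 - report_a$area_1e4_km2,
                           row.names = NULL),
    delta_total_1e4_km2 = suit_b - suit_a,
    pct_change = 100 * (suit_b - suit_a) / suit_a
  )
}

#' Mean center of the suitable habitat
#'
#' Unweighted arithmetic mean of the cell-center coordinates of every
#' cell in the named classes; a suitability-weighted variant is
#' available via `weights`.
#'
#' @param cmap a [jenks_classify()] map with geometry.
#' @param classes class codes counted as suitable (default 1, 2, 3).
#' @param weights optional matrix of cell weights (e.g. the suitability
#'   surface) for a weighted centroid.
#' @return named numeric `(lon, lat)`.
#' @export
mean_center <- function(cmap, classes = c(1L, 2L, 3L), weights = NULL) {
  centers <- classified_centers(cmap)
  cls <- cmap$classes[cbind(centers$row, centers$col)]
  in_cls <- !is.na(cls) & cls %in% classes
  if (!any(in_cls)) stop("no cell in the requested classes")
  w <- if (is.null(weights)) rep(1, sum(in_cls)) else {
    weights[cbind(centers$row, centers$col)][in_cls]
  }
  c(lon = sum(centers$lon[in_cls] * w) / sum(w),
    lat = sum(centers$lat[in_cls] * w) / sum(w))
}

#' Great-circle displacement between two centroids
#'
#' @param c1,c2 `(lon, lat)` coordinates.
#' @return named numeric `distance_km` (haversine) and `bearing_deg`
#'   (initial bearing from `c1` to `c2`, clockwise from north in
#'   `[0, 360)`).
#' @export
centroid_displacement <- function(c1, c2) {
  p1 <- matrix(as.numeric(c1[1:2]), ncol = 2L)
  p2 <- matrix(as.numeric(c2[1:2]), ncol = 2L)
  d <- haversine_km(p1, p2)
  b <- if (d == 0) 0 else bearing_deg(p1, p2)
  c(distance_km = d, bearing_deg = b)
}

#' Land-use profile of occurrence points
#'
#' Tabulates the land-use class of the cell containing each point;
#' points outside the grid are counted under an `outside` bucket.
#'
#' @param occ an [occurrence_set()].
#' @param stack an [env_stack()] carrying the categorical layer.
#' @param layer name of the categorical layer (default `"lucc"`).
#' @return data.frame `class`, `count`, `percentage` (sums to 100).
#' @export
lucc_profile <- function(occ, stack, layer = "lucc") {
  lucc <- stack$categorical[[layer]]
  if (is.null(lucc)) stop(sprintf("categorical layer '%s' not found", layer))
  cells <- point_to_cell(stack, occ$lon, occ$lat)
  inside <- !is.na(cells$row)
  codes <- lucc[cbind(cells$row[inside], cells$col[inside])]
  if (!is.null(stack$class_table)) {
    labels <- stack$class_table$name[match(codes, stack$class_table$code)]
  } else {
    labels <- as.character(codes)
  }
  labels <- c(labels, rep("outside", sum(!inside)))
  tab <- table(labels)
  data.frame(class = names(tab), count = as.integer(tab),
             percentage = 100 * as.integer(tab) / length(labels),
             row.names = NULL)
}
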