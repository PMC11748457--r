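#' Aligned stack of environmental raster layers
#'
#' An `env_stack` bundles named continuous layers (climate, terrain) and
#' categorical layers (land use) on one shared grid. Grids are plain R
#' matrices with row 1 the northernmost row and column 1 the westernmost
#' column; the origin is the north-west corner of the grid. Cell size is
#' given in km and converted to degrees with a fixed scale at the origin
#' latitude, so great-circle distances between nearby cell centers agree
#' with the nominal cell size.
#'
#' @param layers named list of numeric matrices (continuous variables).
#' @param categorical named list of integer matrices (class-coded
#'   variables), all sharing the dimensions of `layers`.
#' @param cell_size_km cell edge length, km.
#' @param origin numeric length-2 `(lon, lat)` of the grid's north-west
#'   corner, degrees.
#' @param class_table optional data.frame with columns `code`, `name`
#'   (and optionally `share`) declaring the categorical class codes.
#' @param meta optional named character vector tagging each variable as
#'   `"climate"`, `"terrain"` or `"human"`.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, categorical = list(), cell_size_km, origin,
                      class_table = NULL, meta = NULL) {
  if (length(layers) == 0L && length(categorical) == 0L) {
    stop("an env_stack needs at least one layer")
  }
  all_layers <- c(layers, categorical)
  if (is.null(names(all_layers)) || any(names(all_layers) == "")) {
    stop("all layers must be named")
  }
  dims <- dim(all_layers[[1L]])
  for (nm in names(all_layers)) {
    if (!is.matrix(all_layers[[nm]]) || !identical(dim(all_layers[[nm]]), dims)) {
      stop(sprintf("layer '%s' does not share the stack dimensions", nm))
    }
  }
  stopifnot_scalar_pos(cell_size_km, "cell_size_km")
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be (lon, lat)")
  }
  structure(list(
    layers = layers,
    categorical = categorical,
    n_rows = dims[1L], n_cols = dims[2L],
    cell_size_km = cell_size_km,
    origin = c(lon = as.numeric(origin[1L]), lat = as.numeric(origin[2L])),
    class_table = class_table,
    meta = meta
  ), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d x %d cells (%.3g km), origin (%.3f, %.3f)\n",
              x$n_rows, x$n_cols, x$cell_size_km, x$origin[1L], x$origin[2L]))
  cat(sprintf("  continuous : %s\n", paste(names(x$layers), collapse = ", ")))
  if (length(x$categorical)) {
    cat(sprintf("  categorical: %s\n", paste(names(x$categorical), collapse = ", ")))
  }
  invisible(x)
}

# degree increments of one cell in latitude / longitude
cell_deg <- function(stack) {
  dlat <- stack$cell_size_km / KM_PER_DEG
  dlon <- stack$cell_size_km / (KM_PER_DEG * cos(stack$origin["lat"] * pi / 180))
  c(dlon = unname(dlon), dlat = unname(dlat))
}

#' Cell-center coordinates of every grid cell
#'
#' @param stack an [env_stack()].
#' @return data.frame with `row`, `col`, `lon`, `lat` in row-major order
#'   (row 1 = northernmost).
#' @export
cell_centers <- function(stack) {
  d <- cell_deg(stack)
  rows <- rep(seq_len(stack$n_rows), times = stack$n_cols)
  cols <- rep(seq_len(stack$n_cols), each = stack$n_rows)
  data.frame(
    row = rows, col = cols,
    lon = stack$origin["lon"] + (cols - 0.5) * d["dlon"],
    lat = stack$origin["lat"] - (rows - 0.5) * d["dlat"],
    row.names = NULL
  )
}

#' Map points to grid cells
#'
#' @param stack an [env_stack()].
#' @param lon,lat point coordinates, degrees.
#' @return data.frame with `row`, `col` (NA for points outside the grid).
#' @export
point_to_cell <- function(stack, lon, lat) {
  d <- cell_deg(stack)
  col <- floor((lon - stack$origin["lon"]) / d["dlon"]) + 1L
  row <- floor((stack$origin["lat"] - lat) / d["dlat"]) + 1L
  bad <- row < 1L | row > stack$n_rows | col < 1L | col > stack$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# value of a named layer at given cells
layer_at_cells <- function(stack, name, rows, cols) {
  lay <- stack$layers[[name]]
  if (is.null(lay)) lay <- stack$categorical[[name]]
  if (is.null(lay)) stop(sprintf("variable '%s' not found in stack", name))
  lay[cbind(rows, cols)]
}

# Gaussian blur of a matrix by two separable 1-D passes; edges use
# renormalized truncated kernels so the field stays stationary.
gaussian_smooth <- function(mat, radius) {
  if (radius <= 0) return(mat)
  half <- max(1L, ceiling(2 * radius))
  kern <- exp(-(seq(-half, half))^2 / (2 * radius^2))
  smooth_1d <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (off in seq(-half, half)) {
      w <- kern[off + half + 1L]
      src <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + w * m[src, , drop = FALSE]
      wsum <- wsum + w
    }
    out / wsum
  }
  t(smooth_1d(t(smooth_1d(mat))))
}

# standardize a matrix to zero mean, unit sd over its cells
zscale <- function(m) {
  s <- stats::sd(as.vector(m))
  if (s == 0) stop("cannot standardize an all-constant layer")
  (m - mean(m)) / s
}

#' Generate a stack of spatially autocorrelated continuous predictors
#'
#' Each layer is smoothed Gaussian white noise (separable Gaussian kernel,
#' `smooth_radius` cells), standardized and then given a per-layer affine
#' scale so layers resemble climate-style variables. Requested pairwise
#' correlations are imposed exactly in the empirical sense: the second
#' member of each pair is rebuilt as `r * z_i + sqrt(1 - r^2) * z_perp`
#' where `z_perp` is a fresh field orthogonalized against `z_i` over the
#' grid cells.
#'
#' @param n_rows,n_cols grid dimensions (>= 3).
#' @param cell_size_km cell size, km.
#' @param n_continuous number of continuous layers (>= 2).
#' @param correlated_pairs list of `c(i, j, target_r)` triples (1-based
#'   layer indices, `|target_r| <= 1`); layer `j` is rebuilt against
#'   layer `i`.
#' @param seed RNG seed; identical calls give bit-identical stacks.
#' @param smooth_radius Gaussian smoothing radius in cells (spatial
#'   autocorrelation range).
#' @param layer_names optional character vector of layer names
#'   (default `env01`, `env02`, ...).
#' @param origin `(lon, lat)` of the north-west corner.
#' @return an [env_stack()] with `n_continuous` layers tagged `climate`.
#' @export
generate_env_stack <- function(n_rows, n_cols, cell_size_km, n_continuous,
                               correlated_pairs = list(), seed,
                               smooth_radius = 5, layer_names = NULL,
                               origin = c(105, 24)) {
  stopifnot_scalar_pos(n_rows, "n_rows")
  stopifnot_scalar_pos(n_cols, "n_cols")
  stopifnot_scalar_pos(cell_size_km, "cell_size_km")
  if (n_continuous < 2L) stop("`n_continuous` must be >= 2")
  for (p in correlated_pairs) {
    if (length(p) != 3L) stop("correlated pairs must be (i, j, target_r) triples")
    if (abs(p[3L]) > 1) stop("target_r must lie in [-1, 1]")
    if (p[1L] < 1 || p[2L] < 1 || p[1L] > n_continuous || p[2L] > n_continuous ||
        p[1L] == p[2L]) {
      stop("correlated pair indices must be distinct layers in the stack")
    }
  }
  if (is.null(layer_names)) {
    layer_names <- sprintf("env%02d", seq_len(n_continuous))
  }
  if (length(layer_names) != n_continuous) {
    stop("`layer_names` must have one name per continuous layer")
  }

  with_seed(seed, {
    fields <- lapply(seq_len(n_continuous), function(i) {
      zscale(gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                             smooth_radius))
    })
    for (p in correlated_pairs) {
      i <- as.integer(p[1L]); j <- as.integer(p[2L]); r <- as.numeric(p[3L])
      zi <- fields[[i]]
      if (abs(r) == 1) {
        fields[[j]] <- sign(r) * zi
        next
      }
      zr <- zscale(gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols),
                                          n_rows, n_cols), smooth_radius))
      # orthogonalize empirically so the achieved correlation is exact
      b <- sum(zr * zi) / sum(zi * zi)
      zperp <- zscale(zr - b * zi)
      fields[[j]] <- zscale(r * zi + sqrt(1 - r^2) * zperp)
    }
    mu <- stats::runif(n_continuous, -5, 25)
    sg <- stats::runif(n_continuous, 0.5, 10)
    layers <- lapply(seq_len(n_continuous), function(i) mu[i] + sg[i] * fields[[i]])
    names(layers) <- layer_names
    env_stack(layers, cell_size_km = cell_size_km, origin = origin,
              meta = stats::setNames(rep("climate", n_continuous), layer_names))
  })
}

#' Terrain derivatives of a digital elevation model
#'
#' Slope and aspect from Horn's 8-neighbour finite differences; border
#' cells use one-sided differences (edge replication). Aspect is the
#' downslope direction in degrees clockwise from north, with flat cells
#' flagged by the sentinel `-1`. Hillshade uses a fixed sun at azimuth
#' 315 deg, altitude 45 deg, scaled to `[0, 1]`.
#'
#' @param dem numeric matrix of elevations in km (>= 3x3 cells).
#' @param cell_size_km cell size, km.
#' @param sun_azimuth,sun_altitude sun position, degrees.
#' @return list of matrices `slope` (deg), `aspect` (deg, -1 when flat),
#'   `hillshade` (`[0, 1]`).
#' @export
compute_terrain <- function(dem, cell_size_km, sun_azimuth = 315,
                            sun_altitude = 45) {
  if (!is.matrix(dem) || nrow(dem) < 3L || ncol(dem) < 3L) {
    stop("`dem` must be a matrix with at least 3x3 cells")
  }
  stopifnot_scalar_pos(cell_size_km, "cell_size_km")
  nr <- nrow(dem); nc <- ncol(dem)
  # pad by edge replication; shifts then give one-sided differences at borders
  pad <- dem[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  sh <- function(dr, dc) pad[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  # row index grows southwards, column index grows eastwards
  gx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
         (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * cell_size_km)
  gy <- ((sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) -
         (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1))) / (8 * cell_size_km)
  slope_rad <- atan(sqrt(gx^2 + gy^2))
  slope <- slope_rad * 180 / pi
  flat <- abs(gx) < 1e-12 & abs(gy) < 1e-12
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[flat] <- -1
  zen <- (90 - sun_altitude) * pi / 180
  az <- sun_azimuth * pi / 180
  asp_rad <- ifelse(flat, 0, aspect * pi / 180)
  hs <- cos(zen) * cos(slope_rad) + sin(zen) * sin(slope_rad) * cos(az - asp_rad)
  hs <- pmin(pmax(hs, 0), 1)
  list(slope = slope, aspect = aspect, hillshade = hs)
}

#' Generate a spatially clustered categorical land-use layer
#'
#' Cuts one smoothed Gaussian field at the empirical quantiles implied by
#' the requested class shares, so classes form contiguous patches and the
#' marginal shares are met up to cell rounding.
#'
#' @param stack an [env_stack()] providing the grid geometry.
#' @param class_table named numeric vector of target shares (must sum to
#'   1; names are class names, codes are assigned 1..K in order).
#' @param clustering smoothing radius in cells controlling patch size.
#' @param seed RNG seed.
#' @return the stack with a `lucc` categorical layer and `class_table`
#'   attached.
#' @export
generate_lucc <- function(stack, class_table, clustering = 6, seed) {
  if (length(class_table) == 0L) stop("`class_table` must be non-empty")
  if (is.null(names(class_table)) || any(names(class_table) == "")) {
    stop("`class_table` shares must be named by class")
  }
  shares <- as.numeric(class_table) / sum(class_table)
  keep <- shares > 0
  codes <- seq_along(class_table)
  grid <- with_seed(seed, {
    if (sum(keep) == 1L) {
      matrix(codes[keep], stack$n_rows, stack$n_cols)
    } else {
      f <- gaussian_smooth(matrix(stats::rnorm(stack$n_rows * stack$n_cols),
                                  stack$n_rows, stack$n_cols), clustering)
      cuts <- stats::quantile(as.vector(f), probs = cumsum(shares[keep]),
                              names = FALSE)
      cuts[length(cuts)] <- Inf
      g <- matrix(codes[keep][findInterval(as.vector(f), c(-Inf, cuts[-length(cuts)]))],
                  stack$n_rows, stack$n_cols)
      storage.mode(g) <- "integer"
      g
    }
  })
  stack$categorical$lucc <- grid
  stack$class_table <- data.frame(code = codes, name = names(class_table),
                                  share = shares, row.names = NULL)
  stack$meta <- c(stack$meta, c(lucc = "human"))
  stack
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster with the grid's geographic georeference
#' (degrees); the companion reader round-trips exactly at the printed
#' precision.
#'
#' @param mat numeric matrix (row 1 = northernmost row).
#' @param path output file.
#' @param stack the [env_stack()] supplying geometry.
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
write_asc <- function(mat, path, stack, nodata = -9999) {
  d <- cell_deg(stack)
  hdr <- c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.10f", stack$origin["lon"]),
    sprintf("yllcorner %.10f", stack$origin["lat"] - nrow(mat) * d["dlat"]),
    sprintf("cellsize %.10f", d["dlat"]),
    sprintf("NODATA_value %s", format(nodata))
  )
  body <- apply(mat, 1L, function(r) {
    r[is.na(r)] <- nodata
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster written by [write_asc()]
#'
#' @param path file path.
#' @return list with `matrix`, `origin` (NW corner lon/lat), `cellsize`
#'   (degrees) and `nodata`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- stats::setNames(vapply(hdr, function(x) as.numeric(x[2L]), 0),
                          tolower(vapply(hdr, `[`, "", 1L)))
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  m[m == vals[["nodata_value"]]] <- NA
  list(matrix = m,
       origin = c(lon = vals[["xllcorner"]],
                  lat = vals[["yllcorner"]] + vals[["nrows"]] * vals[["cellsize"]]),
       cellsize = vals[["cellsize"]],
       nodata = vals[["nodata_value"]])
}
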