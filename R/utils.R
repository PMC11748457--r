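# Internal helpers shared across modules.

# Mean length of one degree of latitude, km (spherical Earth, R = 6371.0088 km).
KM_PER_DEG <- 111.3195

# Earth radius used for all great-circle math, km.
EARTH_RADIUS_KM <- 6371.0088

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so every generator in the package is a pure function of its
#' arguments (seed included) without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Haversine distance in km between two (lon, lat) points or point sets.
haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
}

# Full pairwise haversine distance matrix (km) between rows of two
# two-column (lon, lat) matrices.
haversine_matrix_km <- function(a, b) {
  a <- matrix(as.numeric(unlist(a)), ncol = 2L)
  b <- matrix(as.numeric(unlist(b)), ncol = 2L)
  geosphere::distm(a, b, fun = function(x, y) {
    geosphere::distHaversine(x, y, r = EARTH_RADIUS_KM)
  })
}

# Initial great-circle bearing from p1 to p2, degrees clockwise from
# north in [0, 360).
bearing_deg <- function(p1, p2) {
  geosphere::bearing(p1, p2) %% 360
}

# Derive a bounded per-stage seed from a master seed; keeps results
# reproducible from one config seed while decorrelating stages.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + as.numeric(offset) * 104729) %% 2147483587L) + 1L
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}
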