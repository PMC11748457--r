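#' Configuration of the paired-map scoring rubric
#'
#' @param radius_km buffer radius for the fragmentation check (default
#'   50 km).
#' @param margin minimum drop in buffer suitable-cell fraction (test vs
#'   control) for fragmentation to count, in `[0, 1)` (default 0.10).
#' @param suitable_classes class codes treated as suitable habitat
#'   (default poorly/moderately/highly = 1, 2, 3; a strict variant uses
#'   `c(2, 3)`).
#' @return list of class `rubric_config`.
#' @export
rubric_config <- function(radius_km = 50, margin = 0.10,
                          suitable_classes = c(1L, 2L, 3L)) {
  stopifnot_scalar_pos(radius_km, "radius_km")
  if (margin < 0 || margin >= 1) stop("`margin` must be in [0, 1)")
  structure(list(radius_km = radius_km, margin = margin,
                 suitable_classes = as.integer(suitable_classes)),
            class = "rubric_config")
}

#' Label 8-connected patches of TRUE cells
#'
#' Breadth-first flood fill over the 8-neighbourhood. `NA` cells are
#' treated as background, so labelling can be restricted to an
#' arbitrary region (e.g. a circular buffer) by setting cells outside
#' it to `NA`.
#'
#' @param mask logical matrix.
#' @return list with `n_patches` and `labels` (integer matrix, 0 =
#'   background).
#' @export
label_patches <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- !is.na(mask) & mask
  labels <- matrix(0L, nr, nc)
  offs_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  offs_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  n_patches <- 0L
  todo <- which(m)
  for (start in todo) {
    if (labels[start] != 0L) next
    n_patches <- n_patches + 1L
    queue <- start
    labels[start] <- n_patches
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      nbr_r <- r + offs_r
      nbr_c <- cc + offs_c
      okn <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nidx <- (nbr_c[okn] - 1L) * nr + nbr_r[okn]
      nidx <- nidx[m[nidx] & labels[nidx] == 0L]
      if (length(nidx)) {
        labels[nidx] <- n_patches
        queue <- c(queue, nidx)
      }
    }
  }
  list(n_patches = n_patches, labels = labels)
}

# indices of cells whose centers lie within radius_km of a point
buffer_cells <- function(cmap, lon, lat, radius_km) {
  centers <- classified_centers(cmap)
  d <- haversine_km(cbind(centers$lon, centers$lat), c(lon, lat))
  which_in <- d <= radius_km
  cbind(row = centers$row[which_in], col = centers$col[which_in])
}

#' Is habitat fragmentation evident around a point?
#'
#' Within the circular buffer, suitable cells of each map are labelled
#' into 8-connected patches. Fragmentation is evident iff the test map
#' has strictly more patches than the control map AND its suitable-cell
#' fraction in the buffer is lower by at least the configured margin
#' (patchier and thinner, not merely shrunken).
#'
#' @param control,test two aligned [jenks_classify()] maps.
#' @param point numeric `(lon, lat)`.
#' @param cfg a [rubric_config()].
#' @return logical.
#' @export
fragmentation_evident <- function(control, test, point, cfg = rubric_config()) {
  cells <- buffer_cells(control, point[1L], point[2L], cfg$radius_km)
  if (nrow(cells) == 0L) {
    warning("buffer contains no cells")
    return(FALSE)
  }
  patch_stats <- function(cmap) {
    mask <- matrix(NA, nrow(cmap$classes), ncol(cmap$classes))
    cls <- cmap$classes[cells]
    mask[cells] <- !is.na(cls) & cls %in% cfg$suitable_classes
    list(n = label_patches(mask)$n_patches,
         frac = sum(mask[cells], na.rm = TRUE) / nrow(cells))
  }
  a <- patch_stats(control)
  b <- patch_stats(test)
  b$n > a$n && b$frac <= a$frac - cfg$margin
}

#' Score one validation point against a control/test map pair
#'
#' Applies the five rubric rules in order: (1) suitable only in control
#' -> control scores; (2) suitable only in test -> test scores; (3)
#' suitable in both at different grade -> the higher grade scores; (4)
#' equal grade but fragmentation evident in the test map within the
#' buffer -> test scores, flagged fragmentation; (5) otherwise equal,
#' no score.
#'
#' @param point numeric `(lon, lat)` inside both map extents.
#' @param control,test aligned [jenks_classify()] maps (control =
#'   natural scenario, test = disturbance scenario).
#' @param cfg a [rubric_config()].
#' @return list `outcome` (`"control"`, `"test"` or `"equal"`),
#'   `fragmentation` (logical), `rule` (1-5).
#' @export
score_point <- function(point, control, test, cfg = rubric_config()) {
  class_at <- function(cmap) {
    g <- cmap$geometry
    fake <- structure(list(n_rows = nrow(cmap$classes),
                           n_cols = ncol(cmap$classes),
                           cell_size_km = g$cell_size_km, origin = g$origin),
                      class = "env_stack")
    cell <- point_to_cell(fake, point[1L], point[2L])
    if (is.na(cell$row)) stop("point outside map extent")
    cmap$classes[cell$row, cell$col]
  }
  rc <- class_at(control)
  tc <- class_at(test)
  in_ctrl <- rc %in% cfg$suitable_classes
  in_test <- tc %in% cfg$suitable_classes
  if (in_ctrl && !in_test) {
    list(outcome = "control", fragmentation = FALSE, rule = 1L)
  } else if (in_test && !in_ctrl) {
    list(outcome = "test", fragmentation = FALSE, rule = 2L)
  } else if (in_ctrl && in_test && rc != tc) {
    list(outcome = if (tc > rc) "test" else "control",
         fragmentation = FALSE, rule = 3L)
  } else if (in_ctrl && in_test &&
             fragmentation_evident(control, test, point, cfg)) {
    list(outcome = "test", fragmentation = TRUE, rule = 4L)
  } else {
    list(outcome = "equal", fragmentation = FALSE, rule = 5L)
  }
}

#' Score a set of validation points
#'
#' @param points data.frame with `lon`, `lat`.
#' @param control,test,cfg as in [score_point()].
#' @return data.frame trace: one row per point with `lon`, `lat`,
#'   `outcome`, `fragmentation`, `rule`.
#' @export
score_points <- function(points, control, test, cfg = rubric_config()) {
  res <- lapply(seq_len(nrow(points)), function(i) {
    s <- score_point(c(points$lon[i], points$lat[i]), control, test, cfg)
    data.frame(lon = points$lon[i], lat = points$lat[i],
               outcome = s$outcome, fragmentation = s$fragmentation,
               rule = s$rule)
  })
  do.call(rbind, res)
}

#' Tally rubric outcomes across repetitions
#'
#' @param outcomes data.frame with columns `repetition`, `outcome`
#'   (`control`/`test`/`equal`) and `fragmentation` (logical) — e.g.
#'   row-bound [score_points()] traces.
#' @return list with `table` (one row per repetition plus a summation
#'   row: `control`, `test`, `equality`, `fragmentation`) and `shares`
#'   (each group's share of the grand control+test+equality total, %).
#' @export
tally_repetitions <- function(outcomes) {
  reps <- sort(unique(outcomes$repetition))
  if (length(reps) == 0L) stop("need at least one repetition")
  rows <- lapply(reps, function(r) {
    o <- outcomes[outcomes$repetition == r, , drop = FALSE]
    data.frame(repetition = as.character(r),
               control = sum(o$outcome == "control"),
               test = sum(o$outcome == "test"),
               equality = sum(o$outcome == "equal"),
               fragmentation = sum(o$fragmentation))
  })
  tab <- do.call(rbind, rows)
  sums <- data.frame(repetition = "summation",
                     control = sum(tab$control), test = sum(tab$test),
                     equality = sum(tab$equality),
                     fragmentation = sum(tab$fragmentation))
  grand <- sums$control + sums$test + sums$equality
  list(table = rbind(tab, sums),
       shares = c(control = 100 * sums$control / grand,
                  test = 100 * sums$test / grand,
                  equality = 100 * sums$equality / grand))
}

#' Likelihood-ratio G-test of independence
#'
#' G = 2 * sum O * ln(O / E) with expected counts from the independence
#' model, `0 * ln(0) = 0`, no continuity or Williams correction;
#' df = (r - 1)(c - 1); p from the upper chi-square tail.
#'
#' @param counts matrix of non-negative counts, at least 2x2, with all
#'   row and column sums positive.
#' @return list of class `g_test`: `G`, `df`, `p_value`, `expected`.
#' @export
g_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) stop("table must be at least 2x2")
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column sum")
  expected <- outer(rs, cs) / sum(counts)
  term <- ifelse(counts > 0, counts * log(counts / expected), 0)
  G <- 2 * sum(term)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  structure(list(G = G, df = df,
                 p_value = stats::pchisq(G, df, lower.tail = FALSE),
                 expected = expected),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio G-test: G = %.3f, df = %d, p = %.4g\n",
              x$G, x$df, x$p_value))
  invisible(x)
}

#' Randomly draw one model from the top of a ranked list
#'
#' Ranks fits (or a precomputed score vector) by composite score
#' descending, numbers the best `n_top`, and draws one uniformly.
#'
#' @param gammas numeric vector of composite scores, or a list of
#'   `sdm_fit`s whose `$gamma` is used.
#' @param n_top pool size (default 20); if fewer models are available
#'   the draw is over all of them, with a warning.
#' @param seed RNG seed.
#' @return integer index (into the original vector/list) of the drawn
#'   model.
#' @export
random_pair_selection <- function(gammas, n_top = 20, seed = 1) {
  if (is.list(gammas)) gammas <- vapply(gammas, function(f) f$gamma, 0)
  ord <- order(-gammas)
  if (length(gammas) < n_top) {
    warning(sprintf("only %d models available for a top-%d pool",
                    length(gammas), n_top))
    n_top <- length(gammas)
  }
  pool <- ord[seq_len(n_top)]
  with_seed(seed, pool[sample.int(length(pool), 1L)])
}
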