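test_that("environment stacks are seed-deterministic and validate inputs", {
  a <- generate_env_stack(50, 50, 1, 4, list(), seed = 7)
  b <- generate_env_stack(50, 50, 1, 4, list(), seed = 7)
  expect_identical(a, b)
  c <- generate_env_stack(50, 50, 1, 4, list(), seed = 8)
  expect_false(identical(a$layers[[1]], c$layers[[1]]))

  expect_error(generate_env_stack(0, 50, 1, 4, list(), seed = 1), "n_rows")
  expect_error(generate_env_stack(50, 50, -1, 4, list(), seed = 1),
               "cell_size_km")
  expect_error(generate_env_stack(50, 50, 1, 1, list(), seed = 1), ">= 2")
  expect_error(generate_env_stack(50, 50, 1, 4, list(c(1, 2, 1.2)), seed = 1),
               "target_r")
})

test_that("requested pairwise correlations are achieved", {
  s <- generate_env_stack(50, 50, 1, 2, list(c(1, 2, 1.0)), seed = 1)
  r <- cor(as.vector(s$layers[[1]]), as.vector(s$layers[[2]]))
  expect_gte(r, 0.95)

  s2 <- generate_env_stack(100, 100, 1, 10,
                           list(c(1, 2, 0.9), c(3, 4, 0.85)), seed = 3)
  r12 <- cor(as.vector(s2$layers[[1]]), as.vector(s2$layers[[2]]))
  r34 <- cor(as.vector(s2$layers[[3]]), as.vector(s2$layers[[4]]))
  expect_lt(abs(r12 - 0.9), 0.05)
  expect_lt(abs(r34 - 0.85), 0.05)

  s3 <- generate_env_stack(60, 60, 1, 3, list(c(1, 2, -0.8)), seed = 5)
  rneg <- cor(as.vector(s3$layers[[1]]), as.vector(s3$layers[[2]]))
  expect_lt(abs(rneg - (-0.8)), 0.05)
})

test_that("terrain derivatives match analytic planes", {
  flat <- matrix(1, 10, 10)
  t0 <- compute_terrain(flat, 1)
  expect_true(all(t0$slope == 0))
  expect_true(all(t0$aspect == -1))
  # flat hillshade equals cos(zenith) for 45 deg sun
  expect_equal(unique(as.vector(t0$hillshade)), cos(pi / 4), tolerance = 1e-12)

  # plane rising eastwards: z = 0.1 * x (km), 1-km cells
  east <- outer(rep(1, 20), (1:20) * 0.1)
  t1 <- compute_terrain(east, 1)
  expect_equal(t1$slope[5:15, 5:15],
               matrix(atan(0.1) * 180 / pi, 11, 11), tolerance = 1e-6)
  # downhill is due west
  expect_equal(t1$aspect[5:15, 5:15], matrix(270, 11, 11), tolerance = 1e-6)

  # plane dipping due south: z decreases as row index grows southwards
  south <- outer((20:1) * 0.1, rep(1, 20))
  t2 <- compute_terrain(south, 1)
  expect_equal(t2$aspect[5:15, 5:15], matrix(180, 11, 11), tolerance = 1e-6)
  expect_true(all(t2$hillshade >= 0 & t2$hillshade <= 1))

  expect_error(compute_terrain(matrix(1, 2, 5), 1), "3x3")
})

test_that("land-use generation is clustered, share-accurate and seeded", {
  s <- generate_env_stack(50, 50, 1, 2, list(), seed = 1)
  expect_error(generate_lucc(s, numeric(), seed = 1), "non-empty")

  one <- generate_lucc(s, c(woodland = 1), seed = 1)
  expect_true(all(one$categorical$lucc == 1))

  two <- generate_lucc(s, c(woodland = 0.8, urban = 0.2), seed = 5)
  shares <- prop.table(table(two$categorical$lucc))
  expect_lt(abs(shares[["1"]] - 0.8), 0.05)
  expect_lt(abs(shares[["2"]] - 0.2), 0.05)

  alt <- generate_lucc(s, c(woodland = 0.8, urban = 0.2), seed = 6)
  expect_false(identical(two$categorical$lucc, alt$categorical$lucc))
  shares2 <- prop.table(table(alt$categorical$lucc))
  expect_lt(abs(shares2[["1"]] - 0.8), 0.05)

  # same seed reproduces the grid exactly
  again <- generate_lucc(s, c(woodland = 0.8, urban = 0.2), seed = 5)
  expect_identical(two$categorical$lucc, again$categorical$lucc)
})

test_that("virtual occurrences follow the niche and respect the mask", {
  land <- simulate_landscape(60, 60, 1, seed = 2)
  stack <- land$stack

  # flat niche: suitability ~1 everywhere off-mask, points unique
  flat <- niche_params(intercept = 10, linear = c(bio01 = 1e-9),
                       mask_classes = land$mask_classes)
  occ <- generate_occurrences(stack, flat, 10, seed = 1)
  expect_equal(nrow(occ), 10)
  expect_equal(anyDuplicated(occ[, c("lon", "lat")]), 0L)

  # masked classes never receive a point
  cells <- point_to_cell(stack, occ$lon, occ$lat)
  codes <- stack$categorical$lucc[cbind(cells$row, cells$col)]
  expect_false(any(codes %in% land$mask_classes))

  # strong positive coefficient: presences sit on high values of the driver
  strong <- niche_params(intercept = -2, linear = c(bio12 = 3))
  hits <- vapply(1:10, function(sd) {
    o <- generate_occurrences(stack, strong, 50, seed = sd)
    cl <- point_to_cell(stack, o$lon, o$lat)
    mean(stack$layers$bio12[cbind(cl$row, cl$col)]) >
      mean(stack$layers$bio12)
  }, TRUE)
  expect_true(all(hits))

  # degenerate niche errors
  allmask <- niche_params(intercept = 0, linear = c(bio01 = 1),
                          mask_classes = stack$class_table$code)
  expect_error(generate_occurrences(stack, allmask, 5, seed = 1),
               "degenerate niche")
})

test_that("presence density tracks true suitability", {
  land <- simulate_landscape(50, 50, 1, seed = 4)
  suit <- true_suitability(land$stack, land$niche)
  occ <- generate_occurrences(land$stack, land$niche, 200, seed = 9)
  cells <- point_to_cell(land$stack, occ$lon, occ$lat)
  # aggregate into 5x5-cell blocks: density per block vs mean suitability
  blk <- function(r, c) (ceiling(r / 5) - 1) * 10 + ceiling(c / 5)
  counts <- tabulate(blk(cells$row, cells$col), nbins = 100)
  centers <- cell_centers(land$stack)
  msuit <- tapply(suit[cbind(centers$row, centers$col)],
                  blk(centers$row, centers$col), mean)
  expect_gt(cor(counts, as.numeric(msuit), method = "spearman"), 0.5)
})

test_that("ascii rasters round-trip through the text format", {
  land <- simulate_landscape(20, 20, 1, seed = 3)
  m <- land$stack$layers$bio12
  m[3, 7] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(m, path, land$stack)
  back <- read_asc(path)
  expect_equal(back$matrix, unname(m), tolerance = 1e-8)
  expect_true(is.na(back$matrix[3, 7]))
  expect_equal(unname(back$origin["lat"]), unname(land$stack$origin["lat"]),
               tolerance = 1e-8)
})
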