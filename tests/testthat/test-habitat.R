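test_that("natural breaks separate obvious clusters and handle edge cases", {
  b <- jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)
  expect_equal(as.numeric(b), 3)

  # k equal to the number of distinct values: every value its own class
  b4 <- jenks_breaks(c(5, 1, 9, 3), k = 4)
  expect_equal(as.numeric(b4), c(1, 3, 5))

  expect_error(jenks_breaks(c(1, 1, 2, 2), k = 3), "distinct")
})

test_that("natural breaks achieve the exhaustive-search optimum", {
  for (sd in 1:8) {
    set.seed(sd)
    n <- sample(20:60, 1)
    vals <- round(runif(n, 0, 1), 3)
    if (length(unique(vals)) < 4) next
    b <- jenks_breaks(vals, k = 4)
    expect_equal(attr(b, "wssd"), jenks_bruteforce_wssd(vals, 4),
                 tolerance = 1e-9)
  }
})

test_that("classification is order-preserving and conserves area", {
  set.seed(3)
  suit <- matrix(runif(900), 30, 30)
  cm <- jenks_classify(suit, geometry = list(origin = c(lon = 105, lat = 24),
                                             cell_size_km = 1))
  # order preservation: higher suitability never maps to a lower class
  o <- order(as.vector(suit))
  expect_true(all(diff(as.vector(cm$classes)[o]) >= 0))
  # boundary convention: value equal to a break stays below it
  expect_equal(sum(as.vector(suit) <= cm$breaks[1]),
               sum(cm$classes == 0))

  rep <- area_report(cm, cell_area_km2 = 1)
  expect_equal(sum(rep$cells), 900)
  expect_equal(sum(rep$proportion_pct), 100, tolerance = 1e-9)
  expect_equal(sum(rep$area_1e4_km2), 900 / 1e4, tolerance = 1e-12)
})

test_that("area reports match hand counts", {
  cls <- matrix(0L, 10, 10)
  cm <- make_classified(cls)
  rep <- area_report(cm, 1)
  expect_equal(rep$area_1e4_km2[rep$class == "unsuitable"], 0.01)
  expect_equal(rep$proportion_pct[rep$class == "unsuitable"], 100)

  cls2 <- matrix(rep(0:3, each = 25), 10, 10)
  rep2 <- area_report(make_classified(cls2), 1)
  expect_true(all(rep2$proportion_pct == 25))
  expect_equal(total_suitable(rep2), 75 / 1e4)
})

test_that("change accounting reproduces the published area identities", {
  cur <- sincognitus_current_areas()
  s1 <- cur[cur$scenario == "scenario1_natural", ]
  s2 <- cur[cur$scenario == "scenario2_disturbance", ]
  mk <- function(df) {
    r <- data.frame(class = c("unsuitable", "poorly", "moderately", "highly"),
                    code = 0:3,
                    area_1e4_km2 = df$area_1e4_km2[match(
                      c("unsuitable", "poorly", "moderately", "highly"),
                      df$class)])
    class(r) <- c("area_report", "data.frame")
    r
  }
  ra <- mk(s1); rb <- mk(s2)
  expect_equal(total_suitable(ra), 184.24, tolerance = 1e-9)
  expect_equal(total_suitable(rb), 140.11, tolerance = 1e-9)

  ch <- change_analysis(ra, rb)
  expect_equal(ch$delta_total_1e4_km2, -44.13, tolerance = 1e-9)
  expect_equal(-ch$pct_change, 23.95, tolerance = 5e-3)

  same <- change_analysis(ra, ra)
  expect_equal(same$delta_total_1e4_km2, 0)
  expect_equal(same$pct_change, 0)
  expect_true(all(same$per_class$delta_1e4_km2 == 0))

  bad <- ra; bad$area_1e4_km2 <- bad$area_1e4_km2 * 2
  expect_error(change_analysis(ra, bad), "different study areas")
})

test_that("centroids and displacements follow spherical geometry", {
  cls <- matrix(0L, 9, 9)
  cls[5, 5] <- 3L
  cm <- make_classified(cls)
  cent <- mean_center(cm)
  centers <- cell_centers(make_stack(list(z = matrix(0, 9, 9))))
  exp_c <- centers[centers$row == 5 & centers$col == 5, ]
  expect_equal(unname(cent["lon"]), exp_c$lon)
  expect_equal(unname(cent["lat"]), exp_c$lat)

  # symmetric block centers on the block middle
  cls2 <- matrix(0L, 9, 9); cls2[3:5, 3:5] <- 2L
  c2 <- mean_center(make_classified(cls2))
  exp2 <- centers[centers$row == 4 & centers$col == 4, ]
  expect_equal(unname(c2["lon"]), exp2$lon, tolerance = 1e-12)

  # L-shaped region: direct enumeration oracle
  cls3 <- matrix(0L, 9, 9)
  lcells <- rbind(c(2, 2), c(3, 2), c(4, 2), c(4, 3), c(4, 4))
  cls3[lcells] <- 1L
  c3 <- mean_center(make_classified(cls3))
  sel <- centers[paste(centers$row, centers$col) %in%
                   paste(lcells[, 1], lcells[, 2]), ]
  expect_equal(unname(c3["lon"]), mean(sel$lon), tolerance = 1e-12)
  expect_equal(unname(c3["lat"]), mean(sel$lat), tolerance = 1e-12)

  expect_error(mean_center(make_classified(matrix(0L, 5, 5))), "no cell")

  # displacements
  expect_equal(unname(centroid_displacement(c(105, 24), c(105, 24))["distance_km"]), 0)
  d <- centroid_displacement(c(105, 24), c(105, 25))
  expect_equal(unname(d["distance_km"]), pi / 180 * 6371.0088, tolerance = 1e-6)
  expect_equal(unname(d["bearing_deg"]), 0, tolerance = 1e-9)
  e <- centroid_displacement(c(0, 0), c(1, 0))
  expect_equal(unname(e["bearing_deg"]), 90, tolerance = 1e-9)
})

test_that("occurrence land-use profiles tabulate correctly", {
  land <- simulate_landscape(40, 40, 1, seed = 8)
  stack <- land$stack
  centers <- cell_centers(stack)
  wood_code <- stack$class_table$code[stack$class_table$name == "woodland"]
  wood <- centers[stack$categorical$lucc[cbind(centers$row, centers$col)] ==
                    wood_code, ]
  occ <- occurrence_set(wood$lon[1:4], wood$lat[1:4])
  prof <- lucc_profile(occ, stack)
  expect_equal(prof$percentage[prof$class == "woodland"], 100)

  # 3 woodland + 1 other-class point: 75 / 25
  other <- centers[stack$categorical$lucc[cbind(centers$row, centers$col)] !=
                     wood_code, ][1, ]
  occ2 <- occurrence_set(c(wood$lon[1:3], other$lon),
                         c(wood$lat[1:3], other$lat))
  prof2 <- lucc_profile(occ2, stack)
  expect_equal(prof2$percentage[prof2$class == "woodland"], 75)

  # a point outside the grid lands in the flagged bucket
  occ3 <- occurrence_set(c(wood$lon[1], 150), c(wood$lat[1], 60))
  prof3 <- lucc_profile(occ3, stack)
  expect_true("outside" %in% prof3$class)

  # a woodland-favouring niche over-represents woodland relative to area
  open_codes <- stack$class_table$code[!stack$class_table$name %in%
                                         c("woodland", "shrub")]
  wood_niche <- niche_params(intercept = land$niche$intercept,
                             linear = land$niche$linear,
                             quadratic = land$niche$quadratic,
                             mask_classes = open_codes)
  occ4 <- generate_occurrences(stack, wood_niche, 60, seed = 2)
  prof4 <- lucc_profile(occ4, stack)
  wood_pct <- prof4$percentage[prof4$class == "woodland"]
  areal <- 100 * mean(stack$categorical$lucc == wood_code)
  expect_gt(wood_pct, areal)
})
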