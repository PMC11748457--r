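test_that("patch labelling agrees with an independent graph components oracle", {
  skip_if_not_installed("igraph")
  igraph_patches <- function(mask) {
    idx <- which(mask)
    if (length(idx) == 0) return(0L)
    nr <- nrow(mask)
    coord <- cbind((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
    edges <- c()
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a < b && max(abs(coord[a, ] - coord[b, ])) <= 1) {
          edges <- c(edges, a, b)
        }
      }
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    igraph::components(g)$no
  }
  for (sd in 1:6) {
    set.seed(sd)
    mask <- matrix(runif(100) < 0.4, 10, 10)
    expect_equal(label_patches(mask)$n_patches, igraph_patches(mask))
  }
  # diagonal contact joins patches under 8-connectivity
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(label_patches(diag2)$n_patches, 1)
})

test_that("fragmentation requires both patch increase and habitat loss", {
  # control: one solid suitable block
  ctrl <- matrix(0L, 21, 21)
  ctrl[6:16, 6:16] <- 2L
  cm_ctrl <- make_classified(ctrl)
  pt_centers <- cell_centers(make_stack(list(z = matrix(0, 21, 21))))
  mid <- pt_centers[pt_centers$row == 11 & pt_centers$col == 11, ]
  pt <- c(mid$lon, mid$lat)
  cfg <- rubric_config(radius_km = 8, margin = 0.10)

  # identical maps: no fragmentation
  expect_false(fragmentation_evident(cm_ctrl, cm_ctrl, pt, cfg))

  # a corridor of unsuitable cells splits the block and removes cells
  split <- ctrl
  split[6:16, 10:12] <- 0L
  expect_true(fragmentation_evident(cm_ctrl, make_classified(split), pt, cfg))

  # uniform shrink: still one patch, no fragmentation however large the loss
  shrunk <- matrix(0L, 21, 21)
  shrunk[9:13, 9:13] <- 2L
  expect_false(fragmentation_evident(cm_ctrl, make_classified(shrunk), pt, cfg))

  # patchier but with negligible loss: margin condition blocks it
  nick <- ctrl
  nick[6:16, 11] <- 0L   # removes ~9% of buffer suitable cells
  frac_drop <- (sum(ctrl > 0) - sum(nick > 0)) / sum(!is.na(ctrl))
  expect_lt(frac_drop, 0.10)
  expect_false(fragmentation_evident(cm_ctrl, make_classified(nick), pt,
                                     rubric_config(radius_km = 8, margin = 0.2)))
})

test_that("the rubric fires exactly one rule per point, in order", {
  base <- matrix(0L, 21, 21)
  pt_centers <- cell_centers(make_stack(list(z = matrix(0, 21, 21))))
  mid <- pt_centers[pt_centers$row == 11 & pt_centers$col == 11, ]
  pt <- c(mid$lon, mid$lat)
  cfg <- rubric_config(radius_km = 8)

  suit <- base; suit[8:14, 8:14] <- 2L
  cm_suit <- make_classified(suit)
  cm_none <- make_classified(base)
  high <- base; high[8:14, 8:14] <- 3L
  cm_high <- make_classified(high)
  low <- base; low[8:14, 8:14] <- 1L
  cm_low <- make_classified(low)

  r1 <- score_point(pt, cm_suit, cm_none, cfg)
  expect_equal(r1$outcome, "control"); expect_equal(r1$rule, 1L)

  r2 <- score_point(pt, cm_none, cm_suit, cfg)
  expect_equal(r2$outcome, "test"); expect_equal(r2$rule, 2L)

  r3 <- score_point(pt, cm_low, cm_high, cfg)
  expect_equal(r3$outcome, "test"); expect_equal(r3$rule, 3L)
  r3b <- score_point(pt, cm_high, cm_low, cfg)
  expect_equal(r3b$outcome, "control"); expect_equal(r3b$rule, 3L)

  # equal rank + fragmentation in test
  frag <- suit; frag[8:14, 9:13] <- 0L; frag[11, 11] <- 2L
  r4 <- score_point(pt, cm_suit, make_classified(frag), cfg)
  expect_equal(r4$outcome, "test"); expect_true(r4$fragmentation)
  expect_equal(r4$rule, 4L)

  # equal rank, no fragmentation: no points awarded
  r5 <- score_point(pt, cm_suit, cm_suit, cfg)
  expect_equal(r5$outcome, "equal"); expect_equal(r5$rule, 5L)

  expect_error(score_point(c(0, 0), cm_suit, cm_suit, cfg), "outside")
})

test_that("tallies reproduce the published pairing table", {
  pub <- sincognitus_pairing_tally()
  rows <- lapply(seq_len(nrow(pub)), function(i) {
    data.frame(
      repetition = pub$repetition[i],
      outcome = rep(c("control", "test", "equal"),
                    c(pub$control[i], pub$test[i], pub$equality[i])),
      fragmentation = FALSE)
  })
  tl <- tally_repetitions(do.call(rbind, rows))
  sums <- tl$table[tl$table$repetition == "summation", ]
  expect_equal(sums$control, 34)
  expect_equal(sums$test, 74)
  expect_equal(sums$equality, 52)
  expect_equal(sums$control + sums$test + sums$equality, 160)
  # published fragmentation sub-scores sum to 50 points of the test total
  expect_equal(sum(pub$fragmentation), 50)
  expect_equal(unname(tl$shares["control"]), 21.25)
  expect_equal(unname(tl$shares["test"]), 46.25)

  one <- tally_repetitions(data.frame(repetition = 1,
                                      outcome = c("control", "test", "equal"),
                                      fragmentation = FALSE))
  expect_equal(unname(one$shares), rep(100 / 3, 3), tolerance = 1e-9)
})

test_that("tally conservation holds on random outcome sets", {
  set.seed(5)
  for (i in 1:5) {
    n_rep <- sample(2:6, 1); n_pts <- sample(5:20, 1)
    out <- data.frame(
      repetition = rep(seq_len(n_rep), each = n_pts),
      outcome = sample(c("control", "test", "equal"), n_rep * n_pts, TRUE),
      fragmentation = FALSE)
    out$fragmentation[out$outcome == "test"] <-
      runif(sum(out$outcome == "test")) < 0.5
    tl <- tally_repetitions(out)
    sums <- tl$table[tl$table$repetition == "summation", ]
    expect_equal(sums$control + sums$test + sums$equality, n_rep * n_pts)
    expect_lte(sums$fragmentation, sums$test)
  }
})

test_that("the likelihood-ratio test matches its definition and the published result", {
  # proportional rows: exact independence
  ind <- rbind(c(10, 20), c(5, 10))
  expect_equal(g_test(ind)$G, 0, tolerance = 1e-12)

  pub <- sincognitus_pairing_tally()
  gt <- g_test(as.matrix(pub[, c("control", "test")]))
  expect_equal(gt$G, 26.868, tolerance = 5e-3)
  expect_equal(gt$df, 9)
  expect_lt(gt$p_value, 0.01)

  # independent textbook-formula evaluation on random tables
  set.seed(9)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 8) + 1, 3, 2)
    expect_equal(g_test(tab)$G, g_bruteforce(tab), tolerance = 1e-9)
    # invariant to row permutation
    expect_equal(g_test(tab[c(2, 3, 1), ])$G, g_test(tab)$G, tolerance = 1e-12)
  }

  # agreement with Pearson chi-square when expected counts are large
  set.seed(10)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 60) + 20, 2, 2)
    if (any(chisq.test(tab, correct = FALSE)$expected < 10)) next
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    expect_lt(abs(g_test(tab)$G - chi) / chi, 0.05)
  }

  expect_error(g_test(rbind(c(0, 0), c(1, 2))), "zero row")
  expect_error(g_test(matrix(1:3, 3, 1)), "2x2")
})

test_that("random model drawing is uniform over the ranked pool", {
  gam <- seq(0.5, 0.05, length.out = 25)
  expect_equal(random_pair_selection(gam, n_top = 1, seed = 3), 1L)
  expect_identical(random_pair_selection(gam, n_top = 20, seed = 7),
                   random_pair_selection(gam, n_top = 20, seed = 7))
  expect_warning(random_pair_selection(gam[1:10], n_top = 20, seed = 1),
                 "only 10")

  draws <- vapply(1:10000, function(sd) {
    random_pair_selection(gam, n_top = 20, seed = sd)
  }, 0L)
  freq <- tabulate(draws, nbins = 25) / length(draws)
  expect_true(all(abs(freq[1:20] - 0.05) < 0.01))
  expect_true(all(freq[21:25] == 0))
})
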