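# small shared fixture: a landscape-derived model table
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      land <- simulate_landscape(60, 60, 1, seed = 2)
      occ <- thin_occurrences(
        generate_occurrences(land$stack, land$niche, 82, seed = 3), 3, seed = 4)
      pa <- sample_pseudo_absences(land$stack, occ, 300, seed = 5)
      vars <- pearson_filter(land$stack, 0.8)
      tab <- split_rows(build_model_table(land$stack, occ, pa, vars),
                        c(0.8, 0.2), seed = 6)
      cache <<- list(land = land, tab = tab, vars = vars)
    }
    cache
  }
})

# hand-made fit with a fixed predictor, for contract tests
constant_fit <- function(fun, variables, categorical = character()) {
  structure(list(algorithm = "GLM", repetition = 1L, seed = 1,
                 variables = variables, categorical = categorical,
                 cat_levels = list(), predict_fun = fun, failed = FALSE),
            class = "sdm_fit")
}

test_that("every registered learner yields probabilities and is seeded", {
  fx <- model_fixture()
  for (alg in sdm_algorithms()) {
    f <- fit_single_model(alg, fx$tab, seed = 7)
    expect_false(f$failed)
    p <- predict(f, fx$tab)
    expect_true(all(p >= 0 & p <= 1))
    f2 <- fit_single_model(alg, fx$tab, seed = 7)
    expect_equal(f$metrics$K_ROC, f2$metrics$K_ROC)
    expect_equal(f$gamma, f2$gamma)
  }
  expect_error(fit_single_model("SRE", fx$tab), "arg")
})

test_that("a linear learner separates a strongly separable table", {
  set.seed(1)
  n <- 200
  x <- rnorm(n)
  y <- as.integer(x > 0)
  tab <- data.frame(lon = 105 + seq_len(n) * 1e-4, lat = 24, response = y,
                    x1 = x + rnorm(n, sd = 0.05), x2 = rnorm(n))
  attr(tab, "variables") <- c("x1", "x2")
  attr(tab, "categorical") <- character()
  tab <- split_rows(tab, c(0.8, 0.2), seed = 1)
  f <- fit_single_model("GLM", tab, seed = 1)
  expect_gte(f$metrics$K_ROC, 0.95)
})

test_that("model selection reproduces the published shortlist", {
  sl <- sincognitus_ensemble_shortlist()
  s1 <- unique(sl[sl$scenario == "scenario1_natural",
                  c("model", "repetition", "TSS", "AUC")])
  sel <- select_top_models(s1, metric = "TSS", k = 5, quality_gate = NULL)
  picked <- paste0(s1$model[sel], "(", s1$repetition[sel], ")")
  expect_setequal(picked, c("CTA(4)", "ANN(4)", "GLM(4)", "MAXNET(4)", "RF(9)"))

  # AUC-ranked selection tolerates sub-gate TSS (no floor applied)
  sel_auc <- select_top_models(s1, metric = "AUC", k = 5, quality_gate = NULL)
  expect_true("RF(4)" %in% paste0(s1$model[sel_auc], "(",
                                  s1$repetition[sel_auc], ")") ||
              all(s1$TSS[sel_auc] >= 0.563))
})

test_that("ensembles average member probabilities", {
  vars <- "x1"
  f1 <- constant_fit(function(pf) rep(0.2, nrow(pf)), vars)
  f2 <- constant_fit(function(pf) rep(0.4, nrow(pf)), vars)
  ens <- structure(list(members = list(f1, f2)), class = "sdm_ensemble")
  nd <- data.frame(x1 = 1:3)
  expect_equal(predict(ens, nd), rep(0.3, 3))

  fx <- model_fixture()
  fits <- lapply(c("GLM", "FDA", "XGBOOST"), fit_single_model,
                 table = fx$tab, seed = 7)
  ens2 <- select_and_ensemble(fits, fx$tab, metric = "AUC", k = 3)
  p_members <- sapply(ens2$members, predict, newdata = fx$tab)
  p_ens <- predict(ens2, fx$tab)
  expect_true(all(p_ens >= apply(p_members, 1, min) - 1e-12))
  expect_true(all(p_ens <= apply(p_members, 1, max) + 1e-12))

  # k = 1 collapses to the best single model
  ens1 <- select_and_ensemble(fits, fx$tab, metric = "AUC", k = 1)
  best <- fits[[which.max(vapply(fits, function(f) f$metrics$K_ROC, 0))]]
  expect_equal(predict(ens1, fx$tab), predict(best, fx$tab))
})

test_that("the quality gate rejects uniformly weak candidate sets", {
  df <- data.frame(TSS = c(0.2, 0.5), AUC = c(0.6, 0.7), repetition = 1:2)
  expect_error(select_top_models(df, "TSS", 2, quality_gate = 0.7),
               "best TSS = 0.500")
})

test_that("suitability surfaces respect stack geometry and missing data", {
  fx <- model_fixture()
  f <- fit_single_model("GLM", fx$tab, seed = 7)
  suit <- predict_suitability(f, fx$land$stack, fx$vars)
  expect_equal(dim(suit), c(60, 60))
  expect_true(all(suit >= 0 & suit <= 1, na.rm = TRUE))

  # ranks recover the true niche ordering
  true_s <- true_suitability(fx$land$stack, fx$land$niche)
  expect_gt(cor(as.vector(suit), as.vector(true_s), method = "spearman"), 0.5)

  # constant predictors give a constant surface
  cst <- constant_fit(function(pf) rep(0.7, nrow(pf)), "bio01")
  flat <- predict_suitability(cst, fx$land$stack, "bio01")
  expect_equal(unique(as.vector(flat)), 0.7)

  # nodata propagates
  st2 <- fx$land$stack
  st2$layers$bio01[1, 1] <- NA
  flat2 <- predict_suitability(cst, st2, "bio01")
  expect_true(is.na(flat2[1, 1]))

  expect_error(predict_suitability(f, fx$land$stack, c("nope")), "nope")
})

test_that("permutation importance isolates the driving variables", {
  fx <- model_fixture()
  # predictor that ignores x2 entirely: importance of x2 is exactly 0
  f <- constant_fit(function(pf) plogis(pf$x1), c("x1", "x2"))
  tab <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  imp <- variable_importance(f, tab, n_permutations = 3, seed = 1)
  expect_equal(unname(imp["x2"]), 0)
  expect_gt(imp["x1"], 0.7)

  # constant predictions: all importances defined as 0
  f0 <- constant_fit(function(pf) rep(0.5, nrow(pf)), c("x1", "x2"))
  imp0 <- variable_importance(f0, tab, n_permutations = 2, seed = 1)
  expect_true(all(imp0 == 0))

  # averaging more permutations stabilizes the estimate
  g <- fit_single_model("GLM", fx$tab, seed = 7)
  i1 <- vapply(1:12, function(sd) {
    variable_importance(g, fx$tab, n_permutations = 1, seed = sd)[["bio12"]]
  }, 0)
  i10 <- vapply(1:12, function(sd) {
    variable_importance(g, fx$tab, n_permutations = 10, seed = sd)[["bio12"]]
  }, 0)
  expect_lt(sd(i10), sd(i1))
})
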