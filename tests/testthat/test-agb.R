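toy_composites <- function(nr = 6, nc = 6, px = 100) {
  list(ndvi = make_grid(matrix(seq(0.2, 0.8, length.out = nr * nc), nr, nc),
                        px),
       lst = make_grid(matrix(seq(18, 30, length.out = nr * nc), nr, nc), px),
       precip = make_grid(matrix(seq(150, 350, length.out = nr * nc), nr, nc),
                          px))
}

test_that("predictor sampling reads the containing pixel and logs exclusions", {
  comps <- toy_composites()
  pts <- data.frame(x = c(50, 550, 150, -40), y = c(550, 50, 250, 100))
  comps$ndvi$values[4, 2] <- NA  # row 4, col 2 holds point (150, 250)
  expect_message(tab <- sample_predictors(comps, pts), "excluded")
  expect_equal(nrow(tab), 2L)  # outside point and nodata point dropped
  expect_equal(attr(tab, "n_excluded"), 2L)
  expect_equal(tab$ndvi[1], comps$ndvi$values[1, 1])
  expect_equal(tab$lst[2], comps$lst$values[6, 6])
  all_out <- data.frame(x = c(-10, 1e5), y = c(-10, 1e5))
  expect_error(sample_predictors(comps, all_out), "outside")
})

test_that("exact linear data are recovered to numerical precision", {
  set.seed(41)
  X <- data.frame(ndvi = runif(60, 0, 1), lst = runif(60, 15, 35),
                  precip = runif(60, 100, 400))
  y <- 12 - 40 * X$lst + 300 * X$ndvi + 0.9 * X$precip
  fit <- fit_agb_model(X, y, method = "linear")
  expect_equal(fit$coefficients[["intercept"]], 12, tolerance = 1e-8)
  expect_equal(fit$coefficients[["ndvi"]], 300, tolerance = 1e-8)
  expect_equal(fit$coefficients[["lst"]], -40, tolerance = 1e-8)
  expect_equal(fit$coefficients[["precip"]], 0.9, tolerance = 1e-8)
})

test_that("degenerate fits are refused", {
  X <- data.frame(ndvi = rep(0.5, 20), lst = rep(20, 20),
                  precip = rep(200, 20))
  expect_error(fit_agb_model(X, rnorm(20), method = "linear"),
               "rank-deficient")
  Xok <- data.frame(ndvi = runif(5), lst = runif(5), precip = runif(5))
  expect_error(fit_agb_model(Xok, rnorm(5)), "at least 10")
})

test_that("random-forest fits are reproducible under a fixed seed", {
  set.seed(43)
  X <- data.frame(ndvi = runif(80), lst = runif(80, 15, 35),
                  precip = runif(80, 100, 400))
  y <- 200 * X$ndvi + rnorm(80, 0, 5)
  f1 <- fit_agb_model(X, y, method = "random_forest", seed = 3L)
  f2 <- fit_agb_model(X, y, method = "random_forest", seed = 3L)
  expect_identical(predict(f1, X), predict(f2, X))
})

test_that("AGB maps clip at zero and propagate nodata", {
  comps <- toy_composites()
  set.seed(45)  # break the collinearity of the toy ramps
  comps$precip$values <- matrix(runif(36, 100, 400), 6, 6)
  comps$lst$values <- matrix(runif(36, 15, 35), 6, 6)
  X <- data.frame(ndvi = as.vector(comps$ndvi$values),
                  lst = as.vector(comps$lst$values),
                  precip = as.vector(comps$precip$values))
  y <- -500 + 100 * X$ndvi  # forces negative predictions somewhere
  fit <- fit_agb_model(X, y, method = "linear")
  comps$precip$values[2, 2] <- NA
  map <- predict_agb(fit, comps)
  expect_true(all(map$values >= 0, na.rm = TRUE))
  expect_true(is.na(map$values[2, 2]))
  expect_error(predict_agb(fit, comps[c("ndvi", "lst")]), "must provide")
})

test_that("validation statistics follow their definitions", {
  v <- validate_agb(c(1, 2, 3), c(1, 2, 3))
  expect_equal(v$r, 1)
  expect_equal(v$rmse, 0)
  shifted <- validate_agb(c(11, 12, 13), c(1, 2, 3))
  expect_equal(shifted$r, 1)
  expect_equal(shifted$rmse, 10)
  toy <- validate_agb(c(110, 190, 310), c(100, 200, 300))
  expect_equal(toy$rmse, 10)
  expect_equal(toy$n, 3)
  expect_warning(flat <- validate_agb(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(flat$r))
})

test_that("correlation is scale-invariant but RMSE is not", {
  set.seed(44)
  measured <- runif(50, 100, 300)
  predicted <- measured + rnorm(50, 0, 10)
  v0 <- validate_agb(predicted, measured)
  v1 <- validate_agb(2 * predicted + 5, measured)
  expect_equal(v1$r, v0$r, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(v1$rmse, v0$rmse)))
})

test_that("productivity classes follow the five-class breakpoints", {
  vals <- matrix(c(180, 200, 250, 300, 350, 400, 199.999, 349.999, 50), 3, 3)
  cls <- classify_productivity(make_grid(vals))
  expect_equal(cls$values[1, 1], 1)  # 180 extremely low
  expect_equal(cls$values[2, 1], 2)  # 200 low (left-closed)
  expect_equal(cls$values[3, 1], 3)  # 250 moderate
  expect_equal(cls$values[1, 2], 4)  # 300 high
  expect_equal(cls$values[2, 2], 4)  # 350 still high (top class is > 350)
  expect_equal(cls$values[3, 2], 5)  # 400 extremely high
  expect_equal(cls$values[1, 3], 1)
  expect_equal(cls$values[2, 3], 4)
  expect_equal(cls$values[3, 3], 1)
  expect_error(classify_productivity(make_grid(matrix(-5, 2, 2))),
               "negative")
  # monotone in AGB
  sweep <- matrix(seq(0, 500, length.out = 100), 1, 100)
  codes <- classify_productivity(make_grid(sweep))$values
  expect_true(all(diff(as.vector(codes)) >= 0))
})

test_that("low measurement noise drives validation towards perfection", {
  scn <- scenario(seed = 8L, sample_noise_sd = 0.1, model_noise_sd = 0)
  truth <- gen_agb_truth(scn)
  st <- gen_predictor_stacks(scn, truth)
  comps <- list(ndvi = max_value_composite(st$ndvi),
                lst = temporal_mean(st$lst),
                precip = temporal_sum(st$precip))
  samples <- gen_field_samples(scn, truth)
  X <- sample_predictors(comps, samples)
  fit <- fit_agb_model(X, samples$agb_g_m2, method = "linear")
  v <- validate_agb(predict(fit, X), samples$agb_g_m2)
  expect_gt(v$r, 0.999)
  expect_lt(v$rmse, 1)
})
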