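small_scn <- function(...) {
  args <- utils::modifyList(
    list(nrows = 32L, ncols = 32L, n_regions = 4L, n_samples = 40L,
         n_precip_dates = 10L),
    list(...))
  do.call(scenario, args)
}

test_that("scenario validation rejects inconsistent configurations", {
  expect_error(scenario(n_regions = 10, nrows = 3, ncols = 3),
               "exceeds pixel count")
  expect_error(scenario(class_fractions = c(grassland = 0.5, bare = 0.4)),
               "sum to 1")
  expect_error(scenario(class_fractions = c(bare = 1)), "grassland")
  expect_error(scenario(livestock_growth = -1.5), "-100%")
  expect_error(scenario(agb_noise_sd = -1))
})

test_that("generated regions partition the extent into equal rectangles", {
  scn1 <- small_scn(n_regions = 1L)
  r1 <- gen_regions(scn1)
  expect_length(r1, 1L)

  scn4 <- small_scn()
  r4 <- gen_regions(scn4)
  expect_length(r4, 4L)
  expect_equal(sum(r4$countries == "MNG"), 2L)
  # equal quarters, pairwise disjoint, union covers every pixel
  tmpl <- gen_agb_truth(scn4)
  lab <- rasterize_regions(r4, tmpl)
  counts <- table(lab$values)
  expect_equal(as.numeric(counts), rep(32 * 32 / 4, 4))
  expect_false(anyNA(lab$values))
})

test_that("noise-free AGB truth is exactly the corner-to-corner ramp", {
  scn <- small_scn(agb_noise_sd = 0, agb_gradient = c(sw = 100, ne = 350))
  truth <- gen_agb_truth(scn)
  nr <- scn$nrows; nc <- scn$ncols
  expect_equal(truth$values[nr, 1], 100)  # southwest corner pixel
  expect_equal(truth$values[1, nc], 350)  # northeast corner pixel
  # closed form at every pixel
  for (i in c(1, 7, nr)) for (j in c(1, 13, nc)) {
    t <- ((j - 1) / (nc - 1) + (nr - i) / (nr - 1)) / 2
    expect_equal(truth$values[i, j], 100 + 250 * t)
  }
  # monotone ramp: NE quadrant mean exceeds SW quadrant mean
  regs <- gen_regions(scn)
  zm <- zonal_mean(truth, regs)
  lab <- rasterize_regions(regs, truth)
  ne <- zm$mean[zm$region == "R02"]; sw <- zm$mean[zm$region == "R03"]
  expect_gt(ne, sw)
})

test_that("identical scenarios generate bit-identical outputs", {
  a <- small_scn(seed = 5L); b <- small_scn(seed = 5L)
  expect_identical(gen_agb_truth(a)$values, gen_agb_truth(b)$values)
  ta <- gen_agb_truth(a)
  expect_identical(gen_predictor_stacks(a, ta)$precip$layers[[3]]$values,
                   gen_predictor_stacks(b, ta)$precip$layers[[3]]$values)
  expect_identical(gen_landcover(a)$labels$values,
                   gen_landcover(b)$labels$values)
  expect_identical(gen_field_samples(a, ta), gen_field_samples(b, ta))
  expect_identical(gen_livestock(a), gen_livestock(b))
  # a different seed moves the sample coordinates
  c_scn <- small_scn(seed = 6L)
  expect_false(identical(gen_field_samples(c_scn, ta)$x,
                         gen_field_samples(a, ta)$x))
})

test_that("recompositing the generated stacks returns the intended composites", {
  scn <- small_scn()
  truth <- gen_agb_truth(scn)
  st <- gen_predictor_stacks(scn, truth)
  ndvi_c <- max_value_composite(st$ndvi)
  lst_c <- temporal_mean(st$lst)
  precip_c <- temporal_sum(st$precip)
  # every NDVI layer is <= the composite, equal somewhere on each pixel
  for (lyr in st$ndvi$layers) {
    expect_true(all(lyr$values <= ndvi_c$values + 1e-12))
  }
  # the three composites satisfy the latent link exactly (model noise 0)
  b <- scn$predictor_coefs
  lhs <- b[["intercept"]] + b[["ndvi"]] * ndvi_c$values +
    b[["precip"]] * precip_c$values + b[["lst"]] * lst_c$values
  expect_equal(lhs, truth$values, tolerance = 1e-9)
})

test_that("zero-noise link lets least squares recover the coefficients exactly", {
  scn <- small_scn(agb_noise_sd = 10, sample_noise_sd = 0)
  truth <- gen_agb_truth(scn)
  st <- gen_predictor_stacks(scn, truth)
  X <- data.frame(ndvi = as.vector(max_value_composite(st$ndvi)$values),
                  lst = as.vector(temporal_mean(st$lst)$values),
                  precip = as.vector(temporal_sum(st$precip)$values))
  fit <- fit_agb_model(X, as.vector(truth$values), method = "linear")
  b <- scn$predictor_coefs
  expect_equal(fit$coefficients[["intercept"]], b[["intercept"]],
               tolerance = 1e-6)
  expect_equal(fit$coefficients[["ndvi"]], b[["ndvi"]], tolerance = 1e-6)
  expect_equal(fit$coefficients[["precip"]], b[["precip"]], tolerance = 1e-6)
  expect_equal(fit$coefficients[["lst"]], b[["lst"]], tolerance = 1e-6)
})

test_that("pixel-level residual sd of the true-form fit matches the link noise", {
  scn <- scenario(seed = 2L, model_noise_sd = 10)  # default 128x128 grid
  truth <- gen_agb_truth(scn)
  st <- gen_predictor_stacks(scn, truth)
  d <- data.frame(a = as.vector(truth$values),
                  n = as.vector(max_value_composite(st$ndvi)$values),
                  l = as.vector(temporal_mean(st$lst)$values),
                  p = as.vector(temporal_sum(st$precip)$values))
  resid_sd <- summary(stats::lm(a ~ n + l + p, data = d))$sigma
  expect_lt(abs(resid_sd - 10) / 10, 0.15)
})

test_that("field samples follow the sampling contract", {
  scn <- small_scn(sample_noise_sd = 0)
  truth <- gen_agb_truth(scn)
  lc <- gen_landcover(scn)
  s <- gen_field_samples(scn, truth, labels = lc$labels)
  expect_equal(nrow(s), 40L)
  expect_equal(nrow(gen_field_samples(scenario(), gen_agb_truth(scenario()))),
               327L)  # default sample count
  # zero noise: measured equals truth at the containing pixel
  px <- scn$pixel_size
  col <- floor(s$x / px) + 1L
  row <- scn$nrows - floor(s$y / px)
  expect_equal(s$agb_g_m2, truth$values[cbind(row, col)])
  # samples only fall on grassland pixels
  expect_true(all(lc$labels$values[cbind(row, col)] ==
                    landcover_codebook()[["grassland"]]))
})

test_that("land-cover truth matches configured fractions and separability", {
  scn <- scenario(seed = 3L)  # default 128x128
  lc <- gen_landcover(scn)
  fr <- class_fractions(lc$labels)
  cfg <- scn$class_fractions[match(fr$class, landcover_codebook()[names(scn$class_fractions)])]
  expect_true(all(abs(fr$fraction - cfg) < 0.02))
  expect_equal(length(lc$features), scn$n_features)

  # all-grassland configuration produces a single class
  g1 <- gen_landcover(small_scn(class_fractions = c(grassland = 1)))
  expect_true(all(g1$labels$values == landcover_codebook()[["grassland"]]))

  # zero feature noise: nearest-centroid is perfect
  g0 <- gen_landcover(small_scn(feature_noise_sd = 0))
  np <- length(g0$labels$values)
  feat <- vapply(g0$features$layers, function(g) as.vector(g$values),
                 numeric(np))
  idx <- sample.int(np, 200)
  fit <- train_classifier(feat[idx, ], as.vector(g0$labels$values)[idx],
                          method = "nearest_centroid")
  pred <- predict(fit, feat)
  expect_equal(pred, as.integer(g0$labels$values))
})

test_that("generated livestock follow compound growth by construction", {
  scn <- small_scn(livestock_growth = 0.1)
  inv <- gen_livestock(scn)
  r1 <- inv[inv$region == "R01" & inv$species == "sheep", ]
  base <- r1$headcount[r1$year == 2018]
  expect_equal(r1$headcount[r1$year == 2020], round(base * 1.21))
  # zero growth holds headcounts constant
  inv0 <- gen_livestock(small_scn(livestock_growth = 0))
  counts <- tapply(inv0$headcount, list(inv0$region, inv0$species),
                   function(h) length(unique(h)))
  expect_true(all(counts == 1, na.rm = TRUE))
  # SU growth recovered from the generated table matches the configured rate
  su <- convert_to_su(inv)
  expect_equal(growth_rate(su, "R01", 2018, 2022), 100 * (1.1^4 - 1),
               tolerance = 0.1)
})

test_that("country species books are respected", {
  inv <- gen_livestock(small_scn())
  mng <- unique(inv$species[inv$country == "MNG"])
  imng <- unique(inv$species[inv$country == "IMNG"])
  expect_setequal(mng, c("sheep", "goat", "horse", "cattle", "camel"))
  expect_setequal(imng, c("cattle", "horse", "sheep_goat", "donkey",
                          "mule", "camel"))
})

test_that("target-GCSI inventories hit the analytic capacity ratio", {
  scn <- small_scn(target_gcsi = c(0.5, 1.6, 0.5, 1.6),
                   class_fractions = c(grassland = 1))
  inv <- gen_livestock(scn)
  su <- convert_to_su(inv)
  cap <- analytic_capacity(scn)
  for (k in 1:4) {
    ratio <- su$su[su$region == cap$region[k] & su$year == 2018] /
      cap$gcc_total_su[k]
    expect_equal(ratio, scn$target_gcsi[k], tolerance = 1e-3)
  }
})

test_that("the packaged SU table carries the published values", {
  tab <- table1_fixture()
  expect_s3_class(tab, "su_table")
  expect_equal(su_units(tab), "thousands")
  expect_equal(length(unique(tab$region)), 16L)
  expect_equal(nrow(tab), 80L)
  expect_equal(tab$su[tab$region == "Hovsgol" & tab$year == 2018], 9483.96)
  expect_equal(tab$su[tab$region == "Chifeng" & tab$year == 2022], 17253.57)
  expect_equal(tab$su[tab$region == "Hinggan League" & tab$year == 2022],
               11429.695)
  expect_setequal(unique(tab$country), c("MNG", "IMNG"))
})

test_that("scenario configs round-trip through YAML", {
  scn <- small_scn(seed = 9L, target_gcsi = c(0.5, 1.6, 0.5, 1.6))
  path <- file.path(tempdir(), "scn.yml")
  write_scenario(scn, path)
  back <- read_scenario(path)
  expect_equal(back$seed, scn$seed)
  expect_equal(back$predictor_coefs, scn$predictor_coefs)
  expect_equal(back$class_fractions, scn$class_fractions)
  expect_identical(gen_agb_truth(back)$values, gen_agb_truth(scn)$values)
  writeLines(c("seed: 1", "bogus_key: 2"), path)
  expect_error(read_scenario(path), "unknown scenario keys")
  unlink(path)
})
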