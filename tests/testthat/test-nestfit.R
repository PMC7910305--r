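exact_linear_points <- function(n = 13) {
  evi <- seq(0, 0.3, length.out = n)  # step 0.025, so counts step by -1
  data.frame(evi = evi, nests = as.integer(round(120 - 40 * evi)))
}

test_that("exact relations are interpolated with R-squared 1", {
  evi <- seq(0, 0.3, by = 0.025)
  lin <- data.frame(evi = evi, nests = 10 - 20 * evi)
  f <- suppressWarnings(fit_models(lin))  # lm warns on a perfect fit
  expect_equal(f$linear$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(f$linear$coefficients[2]), -20, tolerance = 1e-10)
  # counts on an exact exponential curve under the +1 transform
  expc <- data.frame(evi = evi, nests = exp(2 - 5 * evi) - 1)
  fe <- suppressWarnings(fit_models(expc))
  expect_equal(fe$exponential$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(fe$exponential$coefficients[2]), -5, tolerance = 1e-10)
})

test_that("selection is argmax R-squared with the declared tie-break", {
  mk <- function(form, r2) structure(list(form = form, r_squared = r2,
                                          coefficients = c(0, -1)),
                                     class = "nest_fit_form")
  fits <- list(mk("linear", 0.52), mk("exponential", 0.31),
               mk("logarithmic", 0.30))
  expect_equal(select_best(fits)$r_squared, 0.52)
  expect_equal(select_best(fits[2])$form, "exponential")
  # exact tie: the simpler form wins
  tie <- list(mk("exponential", 0.4), mk("linear", 0.4))
  expect_equal(select_best(tie)$form, "linear")
  tie2 <- list(mk("exponential", 0.4), mk("logarithmic", 0.4))
  expect_equal(select_best(tie2)$form, "logarithmic")
  expect_error(select_best(list()), "no fits")
  # on real fits the selected R2 dominates every candidate
  pts <- make_decline_points(5)
  fits2 <- fit_models(pts)
  best <- select_best(fits2)
  for (f in fits2) expect_gte(best$r_squared, f$r_squared)
})

test_that("degenerate inputs error; logarithmic is skipped quietly when inadmissible", {
  expect_error(fit_models(data.frame(evi = c(0.1, 0.2), nests = c(1, 2))),
               "at least 3")
  expect_error(fit_models(data.frame(evi = rep(0.1, 5), nests = 1:5)),
               "degenerate")
  # the shifted logarithm handles zero and negative EVI without error
  pts <- data.frame(evi = c(-0.1, 0, 0.1, 0.2), nests = c(9, 6, 4, 1))
  f <- fit_models(pts)
  expect_true("logarithmic" %in% names(f))
  expect_equal(f$logarithmic$log_shift, 0.11)
})

test_that("subsample-averaged p is tiny on exact linear data and reproducible", {
  pts <- exact_linear_points()
  b <- bootstrap_p(pts, "linear", n_boot = 50, seed = 9)
  expect_lt(b$mean_p, 1e-6)
  b2 <- bootstrap_p(pts, "linear", n_boot = 50, seed = 9)
  expect_identical(b, b2)
  b3 <- bootstrap_p(pts, "linear", n_boot = 50, seed = 10)
  expect_false(identical(b$mean_p, b3$mean_p))
})

test_that("a single replicate and a full-fraction subsample equal the full-data p", {
  pts <- make_decline_points(3)
  full_p <- fit_models(pts, forms = "linear")$linear$p_slope
  b1 <- bootstrap_p(pts, "linear", n_boot = 1, subsample_fraction = 1, seed = 2)
  expect_equal(b1$mean_p, full_p, tolerance = 1e-12)
  # every replicate identical at fraction 1, so the mean is the full-data p
  bm <- bootstrap_p(pts, "linear", n_boot = 25, subsample_fraction = 1, seed = 2)
  expect_equal(bm$mean_p, full_p, tolerance = 1e-12)
})

test_that("null data yields large average p-values", {
  set.seed(60)
  means <- replicate(40, {
    pts <- data.frame(evi = seq(0, 0.3, length.out = 20),
                      nests = rpois(20, 8))
    bootstrap_p(pts, "linear", n_boot = 30,
                seed = sample.int(1e6, 1))$mean_p
  })
  expect_gt(mean(means), 0.2)
})

test_that("the fitted-model object supports the standard methods", {
  pts <- make_decline_points(11)
  fit <- nest_evi_fit(pts, n_boot = 40, seed = 4)
  expect_s3_class(fit, "nest_evi_fit")
  expect_length(coef(fit), 2)
  expect_length(predict(fit), nrow(pts))
  expect_equal(predict(fit, data.frame(evi = pts$evi)), predict(fit))
  expect_length(residuals(fit), nrow(pts))
  s <- summary(fit)
  expect_true(all(c("form", "r_squared") %in% names(s$candidates)))
  expect_output(print(fit), "selected")
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(pts), 2))
  # refitting with the same seed is bit-identical
  fit2 <- nest_evi_fit(pts, n_boot = 40, seed = 4)
  expect_identical(fit$bootstrap, fit2$bootstrap)
  expect_identical(coef(fit), coef(fit2))
})
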