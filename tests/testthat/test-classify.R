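test_that("ground-truth plot rules fire woodiest-first", {
  expect_equal(classify_plot(f_water = 0.8, f_sand = 0.2), "water")
  expect_equal(classify_plot(f_tree = 0.12, f_grass = 0.5), "tree")
  expect_equal(classify_plot(f_sand = 1.0), "sand")
  expect_equal(classify_plot(f_shrub = 0.15, f_grass = 0.6), "shrub")
  expect_equal(classify_plot(f_grass = 0.35, f_sand = 0.65), "grass")
  # no rule fires
  expect_equal(classify_plot(f_grass = 0.25, f_sand = 0.5, f_water = 0.25),
               "unclassified")
  expect_error(classify_plot(f_water = 0.8, f_sand = 0.5), "sum")
  expect_error(classify_plot(f_water = -0.1), "within")
})

test_that("five-class EVI thresholds follow the published scheme", {
  expect_equal(classify_evi_5(-0.5), "water")
  expect_equal(classify_evi_5(0.25), "tree")
  # sand/grass overlap resolved at the 0.065 midpoint
  expect_equal(classify_evi_5(0.06), "sand")
  expect_equal(classify_evi_5(0.07), "grass")
  # half-open boundaries
  expect_equal(classify_evi_5(0), "sand")
  expect_equal(classify_evi_5(0.13), "shrub")
  expect_equal(classify_evi_5(0.215), "tree")
  # above the printed tree interval is still tree
  expect_equal(classify_evi_5(0.35), "tree")
  expect_error(classify_evi_5(-1.5), "within")
  expect_error(classify_evi_5(NaN), "finite")
})

test_that("merged three-class boundaries are threshold-exact", {
  expect_equal(classify_evi_3(-0.01), "water")
  expect_equal(classify_evi_3(0.07), "sandy_grassland")
  expect_equal(classify_evi_3(0.2), "woody")
  expect_equal(classify_evi_3(0), "sandy_grassland")
  expect_equal(classify_evi_3(0.13), "woody")
})

test_that("merging five-class labels equals direct three-class labels on a dense grid", {
  g <- seq(-0.9995, 0.9995, by = 0.0005)
  expect_identical(merge_classes(classify_evi_5(g)), classify_evi_3(g))
})

test_that("confusion matrix yields hand-computed accuracy and kappa", {
  truth <- rep(c("a", "b"), each = 50)
  pred <- c(rep("a", 45), rep("b", 5), rep("b", 45), rep("a", 5))
  cm <- validate(truth, pred)
  expect_equal(cm$overall_accuracy, 0.9)
  expect_equal(cm$kappa, 0.8)
  expect_equal(unname(cm$producers_accuracy), c(0.9, 0.9))
  # perfect agreement
  expect_equal(validate(truth, truth)$kappa, 1)
  # single-class degenerate case: kappa undefined, accuracy 1
  cm1 <- validate(rep("water", 5), rep("water", 5))
  expect_true(is.na(cm1$kappa))
  expect_equal(cm1$overall_accuracy, 1)
  expect_error(validate("a", c("a", "b")), "equal length")
})

test_that("kappa is 1 only when all off-diagonal counts vanish", {
  set.seed(42)
  for (i in 1:20) {
    truth <- sample(c("x", "y", "z"), 60, replace = TRUE)
    pred <- truth
    flip <- sample(60, sample(0:5, 1))
    pred[flip] <- sample(c("x", "y", "z"), length(flip), replace = TRUE)
    cm <- validate(truth, pred)
    expect_true(cm$kappa >= -1 && cm$kappa <= 1)
    expect_equal(cm$kappa == 1, all(pred == truth))
  }
})

test_that("coarsening to merged classes never decreases overall accuracy", {
  set.seed(7)
  for (i in 1:50) {
    truth <- sample(c("water", "sand", "grass", "shrub", "tree"),
                    80, replace = TRUE)
    pred <- truth
    flip <- sample(80, 25)
    pred[flip] <- sample(c("water", "sand", "grass", "shrub", "tree"),
                         25, replace = TRUE)
    acc5 <- validate(truth, pred)$overall_accuracy
    acc3 <- validate(merge_classes(truth), merge_classes(pred))$overall_accuracy
    expect_gte(acc3, acc5)
  }
})

test_that("threshold calibration recovers spreads and respects the split", {
  # zero-spread plots at the class centers give degenerate intervals
  cfg <- synthetic_config(seed = 3, class_evi_params = list(
    water = c(-0.5, 0), sand = c(0.04, 0), grass = c(0.10, 0),
    shrub = c(0.17, 0), tree = c(0.27, 0)))
  plots <- generate_habitat_plots(cfg, n_plots = 100)
  cal <- calibrate_thresholds(plots, train_fraction = 1.0, seed = 1)
  centers <- c(-0.5, 0.04, 0.10, 0.17, 0.27)
  for (k in seq_along(centers)) {
    expect_equal(unname(cal$scheme$intervals[[k]]),
                 rep(centers[k], 2), tolerance = 1e-12)
  }
  # and five-class classification recovers every true label, both under the
  # calibrated scheme and under the published one (centers sit strictly
  # inside the printed intervals)
  expect_identical(classify_evi_5(plots$evi, cal$scheme), plots$class)
  expect_identical(classify_evi_5(plots$evi), plots$class)
  # train_fraction 1: every plot's EVI inside its class interval
  cfg2 <- synthetic_config(seed = 5)
  plots2 <- generate_habitat_plots(cfg2, n_plots = 150)
  cal2 <- calibrate_thresholds(plots2, train_fraction = 1.0, seed = 2)
  for (cl in unique(plots2$class)) {
    iv <- cal2$scheme$intervals[[cl]]
    e <- plots2$evi[plots2$class == cl]
    expect_true(all(e >= iv[1] & e <= iv[2]))
  }
})

test_that("calibrated schemes validate positively on held-out plots under either seed", {
  cfg <- synthetic_config(seed = 8)
  plots <- generate_habitat_plots(cfg, n_plots = 250)
  for (seed in c(11, 99)) {
    cal <- calibrate_thresholds(plots, train_fraction = 0.8, seed = seed)
    test_rows <- plots[cal$test, ]
    pred <- classify_evi_5(test_rows$evi, cal$scheme)
    cm <- validate(test_rows$class, pred)
    expect_gt(cm$kappa, 0)
  }
  # split is deterministic under a fixed seed
  c1 <- calibrate_thresholds(plots, seed = 11)
  c2 <- calibrate_thresholds(plots, seed = 11)
  expect_identical(c1$train, c2$train)
  expect_equal(c1$scheme$intervals, c2$scheme$intervals)
})

test_that("calibration errors when a class is missing from training", {
  cfg <- synthetic_config(seed = 3)
  plots <- generate_habitat_plots(cfg, n_plots = 60)
  plots$class[plots$class == "tree"] <- "shrub"
  expect_error(calibrate_thresholds(plots, train_fraction = 1, seed = 1),
               "tree")
})
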