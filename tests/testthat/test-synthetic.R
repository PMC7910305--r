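test_that("noiseless flat configuration emits a constant series", {
  cfg <- synthetic_config(seed = 1, noise_sd = 0, season_amplitude = 0,
                          baseline_mean = 0.05, shift_year = NA)
  s <- generate_evi_series(cfg, 1)
  expect_true(all(s$evi == 0.05))
  expect_length(s, diff(cfg$years) * 12 + 12)
})

test_that("abrupt shift moves the post-shift mean to the woody target", {
  cfg <- synthetic_config(seed = 21, shift_mode = "abrupt",
                          shift_year = 2010, woody_target = 0.25,
                          noise_sd = 0.01, season_amplitude = 0)
  s <- generate_evi_series(cfg, 2)
  yrs <- as.integer(format(s$date, "%Y"))
  post <- s$evi[yrs >= 2010]
  se <- 0.01 / sqrt(length(post))
  expect_lt(abs(mean(post) - 0.25), 3 * se)
  pre <- s$evi[yrs < 2010]
  expect_lt(abs(mean(pre) - cfg$baseline_mean), 3 * 0.01 / sqrt(length(pre)))
  # with the seasonal sinusoid on, the emitted series matches its analytic
  # mean exactly in the noiseless limit
  cfg0 <- synthetic_config(seed = 1, noise_sd = 0, shift_mode = "gradual")
  s0 <- generate_evi_series(cfg0, 1)
  yrs0 <- as.integer(format(s0$date, "%Y"))
  tfrac <- yrs0 + (as.integer(format(s0$date, "%m")) - 0.5) / 12
  expect_equal(s0$evi, synthetic_mean_evi(cfg0, tfrac), tolerance = 1e-12)
})

test_that("via_water mode submerges at the shift year before turning woody", {
  cfg <- synthetic_config(seed = 4, shift_mode = "via_water",
                          noise_sd = 0.01, season_amplitude = 0.02)
  s <- generate_evi_series(cfg, 1)
  yrs <- as.integer(format(s$date, "%Y"))
  plateau <- s$evi[yrs %in% c(2010, 2011)]
  expect_true(all(plateau < 0))
  late <- s$evi[yrs >= 2016]
  expect_gt(mean(late), 0.13)
})

test_that("generators are bit-reproducible under equal configuration", {
  cfg <- synthetic_config(seed = 123)
  expect_identical(generate_evi_series(cfg, 3), generate_evi_series(cfg, 3))
  expect_identical(generate_habitat_plots(cfg), generate_habitat_plots(cfg))
  evi_sy <- data.frame(site = c("S1", "S2"), year = 2017, evi = c(0.05, 0.2))
  expect_identical(generate_nest_table(cfg, evi_sy),
                   generate_nest_table(cfg, evi_sy))
  # different sites draw different noise
  expect_false(identical(generate_evi_series(cfg, 1)$evi,
                         generate_evi_series(cfg, 2)$evi))
  # CSV products round-trip byte-identically
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_csvs(cfg, d1)
  write_synthetic_csvs(cfg, d2)
  for (f in c("evi_series.csv", "plots.csv", "nests.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("every generated plot satisfies the ground-truth rule for its class", {
  cfg <- synthetic_config(seed = 17)
  plots <- generate_habitat_plots(cfg, n_plots = 300)
  relabel <- classify_plot(plots$f_water, plots$f_sand, plots$f_grass,
                           plots$f_shrub, plots$f_tree)
  expect_identical(relabel, plots$class)
  expect_true(all(plots$f_tree[plots$class == "tree"] > 0.10))
  sums <- plots$f_water + plots$f_sand + plots$f_grass + plots$f_shrub +
    plots$f_tree
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("nest counts follow the declining count model", {
  # slope 0, zero dispersion: Poisson with mean exactly exp(intercept)
  cfg <- synthetic_config(seed = 31, nest_model = c(log(5), 0, 0))
  evi_sy <- data.frame(site = sprintf("S%d", 1:8),
                       year = rep(2015:2019, length.out = 8)[1:8],
                       evi = runif(8, 0, 0.3))
  # expectation is 5 regardless of EVI; check on a large emission
  big <- data.frame(site = sprintf("S%d", 1:8)[rep(1:8, 250)],
                    year = 2017, evi = runif(2000, 0, 0.3))
  tab <- generate_nest_table(cfg, big)
  expect_lt(abs(mean(tab$nests) - 5), 3 * sqrt(5 / 2000))
  # zero counts are recorded as entry "0"
  cfg0 <- synthetic_config(seed = 32, nest_model = c(log(0.05), 0, 0))
  tab0 <- generate_nest_table(cfg0, evi_sy)
  expect_true(all(tab0$entry[tab0$nests == 0] == "0"))
  # empty site list gives an empty table
  empty <- generate_nest_table(cfg, data.frame(site = character(0),
                                               year = integer(0),
                                               evi = numeric(0)))
  expect_equal(nrow(empty), 0)
  # negative dispersion is a configuration error
  expect_error(synthetic_config(nest_model = c(1, -1, -0.5)), "dispersion")
})

test_that("steep negative slope yields negative EVI-count correlation", {
  evi <- seq(0, 0.3, length.out = 24)
  neg <- 0L
  for (k in 1:100) {
    cfg <- synthetic_config(seed = 1000 + k)
    tab <- generate_nest_table(cfg, data.frame(site = sprintf("S%d", 1:24),
                                               year = 2017, evi = evi))
    rho <- suppressWarnings(cor(evi, tab$nests, method = "spearman"))
    if (is.finite(rho) && rho < 0) neg <- neg + 1L
  }
  expect_gte(neg, 95)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(years = c(2019, 1988)), "year range")
  expect_error(synthetic_config(shift_year = 1950), "shift_year")
  expect_error(synthetic_config(woody_target = 0.10), "woody_target")
  expect_error(synthetic_config(obs_per_year = 0), "obs_per_year")
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd")
  cfg <- synthetic_config()
  expect_error(generate_evi_series(cfg, 99), "site_index")
})
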