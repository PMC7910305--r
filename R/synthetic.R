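#' Configuration for the synthetic riverscape generator
#'
#' Bundles every knob of the generators: the EVI time-series emitter, the
#' ground-truth habitat-plot emitter, and the nest-count emitter. Defaults
#' describe a riverbank that oscillates seasonally between shallow water
#' (EVI just below 0) and sandy grassland (EVI up to ~0.13), then shifts to
#' woody vegetation (EVI above 0.13) after a disturbance year.
#'
#' @param seed master integer seed; every generator output is a pure
#'   function of (config, arguments).
#' @param n_sites number of nesting sites.
#' @param years inclusive year range, `c(first, last)`.
#' @param obs_per_year scenes per year, spread evenly across months so a
#'   March-April window always contains observations at the default 12.
#' @param season_amplitude half-range of the seasonal EVI sinusoid.
#' @param baseline_mean pre-disturbance mean EVI.
#' @param noise_sd per-scene Gaussian noise SD (EVI units, > 0 unless
#'   exactly 0 for the noiseless limit).
#' @param shift_year disturbance year, or `NA` for no shift.
#' @param shift_mode `"abrupt"` (step), `"gradual"` (linear ramp over
#'   `gradual_ramp_years`), or `"via_water"` (submergence plateau of
#'   `via_water_years`, then ramp).
#' @param woody_target post-shift mean EVI (> 0.13).
#' @param gradual_ramp_years ramp length for gradual / via_water modes.
#' @param via_water_years submergence duration before the ramp.
#' @param via_water_level EVI of the submerged plateau (< 0).
#' @param post_shift_amplitude_factor seasonal amplitude retained after the
#'   shift; woody canopy damps the flood-driven oscillation.
#' @param class_evi_params named list of `c(center, spread)` per habitat
#'   class for plot-EVI emission. Defaults put each center strictly inside
#'   its published threshold interval.
#' @param class_probs sampling probabilities of the five true classes.
#' @param plots_per_site ground plots marked per site (six 1 m^2 plots).
#' @param nest_model `c(intercept, slope, dispersion)` for count emission:
#'   counts have mean `exp(intercept + slope * evi)`; `dispersion` is the
#'   quadratic overdispersion coefficient (variance `mu + dispersion*mu^2`;
#'   0 gives Poisson).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_sites = 8L,
                             years = c(1988L, 2019L),
                             obs_per_year = 12L,
                             season_amplitude = 0.08,
                             baseline_mean = 0.04,
                             noise_sd = 0.02,
                             shift_year = 2010L,
                             shift_mode = c("abrupt", "gradual", "via_water"),
                             woody_target = 0.20,
                             gradual_ramp_years = 3L,
                             via_water_years = 2L,
                             via_water_level = -0.10,
                             post_shift_amplitude_factor = 0.25,
                             class_evi_params = list(
                               water = c(-0.5, 0.02),
                               sand  = c(0.04, 0.02),
                               grass = c(0.10, 0.02),
                               shrub = c(0.17, 0.02),
                               tree  = c(0.27, 0.02)
                             ),
                             class_probs = rep(0.2, 5),
                             plots_per_site = 6L,
                             nest_model = c(intercept = log(20),
                                            slope = -10,
                                            dispersion = 0.2)) {
  shift_mode <- match.arg(shift_mode)
  if (length(years) != 2 || years[2] < years[1])
    stop("configuration error: invalid year range")
  if (!is.na(shift_year) && (shift_year < years[1] || shift_year > years[2]))
    stop("configuration error: shift_year outside year range")
  if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (!is.na(shift_year) && woody_target <= 0.13)
    stop("configuration error: woody_target must exceed 0.13")
  if (obs_per_year < 1) stop("configuration error: obs_per_year must be >= 1")
  if (!is.null(class_evi_params) &&
      !all(HABITAT_CLASSES_5 %in% names(class_evi_params)))
    stop("configuration error: class_evi_params must cover all five classes")
  if (nest_model[[3]] < 0)
    stop("configuration error: negative dispersion")
  structure(list(
    seed = as.integer(seed), n_sites = as.integer(n_sites),
    years = as.integer(years), obs_per_year = as.integer(obs_per_year),
    season_amplitude = season_amplitude, baseline_mean = baseline_mean,
    noise_sd = noise_sd,
    shift_year = if (is.na(shift_year)) NA_integer_ else as.integer(shift_year),
    shift_mode = shift_mode, woody_target = woody_target,
    gradual_ramp_years = as.integer(gradual_ramp_years),
    via_water_years = as.integer(via_water_years),
    via_water_level = via_water_level,
    post_shift_amplitude_factor = post_shift_amplitude_factor,
    class_evi_params = class_evi_params,
    class_probs = class_probs,
    plots_per_site = as.integer(plots_per_site),
    nest_model = c(intercept = unname(nest_model[[1]]),
                   slope = unname(nest_model[[2]]),
                   dispersion = unname(nest_model[[3]]))
  ), class = "synthetic_config")
}

# independent sub-streams per generator and site; stays well below 2^31
.sub_seed <- function(config, stream, site_index = 0L) {
  base <- c(series = 100003L, plots = 200003L, nests = 300007L)[[stream]]
  (config$seed * 7L + base + 1009L * as.integer(site_index)) %% 2147483587L
}

#' Deterministic mean EVI of the synthetic series at given dates
#'
#' The generator's own noiseless equation: seasonal sinusoid around a
#' baseline that moves to `woody_target` after `shift_year` according to
#' `shift_mode`. Exposed so tests and analyses can compare emitted series
#' against their analytic expectation.
#'
#' @param config a [synthetic_config()].
#' @param time numeric time in fractional years (e.g. 2010.5).
#' @return numeric vector of expected EVI.
#' @export
synthetic_mean_evi <- function(config, time) {
  phase <- sin(2 * pi * (time %% 1))
  if (is.na(config$shift_year)) {
    return(config$baseline_mean + config$season_amplitude * phase)
  }
  t0 <- config$shift_year
  ramp <- max(config$gradual_ramp_years, 1L)
  level <- numeric(length(time))
  amp_fac <- numeric(length(time))
  pre <- time < t0
  level[pre] <- config$baseline_mean
  amp_fac[pre] <- 1
  post <- !pre
  if (config$shift_mode == "abrupt") {
    level[post] <- config$woody_target
    amp_fac[post] <- config$post_shift_amplitude_factor
  } else if (config$shift_mode == "gradual") {
    frac <- pmin((time[post] - t0) / ramp, 1)
    level[post] <- config$baseline_mean +
      frac * (config$woody_target - config$baseline_mean)
    amp_fac[post] <- 1 + frac * (config$post_shift_amplitude_factor - 1)
  } else { # via_water: submerged plateau, then ramp to woody
    dt <- time[post] - t0
    plateau <- dt < config$via_water_years
    lv <- numeric(sum(post))
    af <- numeric(sum(post))
    lv[plateau] <- config$via_water_level
    af[plateau] <- config$post_shift_amplitude_factor
    frac <- pmin((dt[!plateau] - config$via_water_years) / ramp, 1)
    lv[!plateau] <- config$via_water_level +
      frac * (config$woody_target - config$via_water_level)
    af[!plateau] <- config$post_shift_amplitude_factor
    level[post] <- lv
    amp_fac[post] <- af
  }
  level + config$season_amplitude * amp_fac * phase
}

#' Generate a synthetic per-site EVI time series
#'
#' Emits `obs_per_year` scenes per year at evenly spaced months, with EVI
#' equal to the analytic mean of [synthetic_mean_evi()] plus Gaussian
#' noise. Identical `(config, site_index)` gives identical output.
#'
#' @param config a [synthetic_config()].
#' @param site_index site number in `1..n_sites`.
#' @return an [evi_series()] named `"S<site_index>"`.
#' @export
generate_evi_series <- function(config, site_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (site_index < 1 || site_index > config$n_sites)
    stop("site_index out of range")
  yrs <- seq(config$years[1], config$years[2])
  k <- config$obs_per_year
  # months evenly spread over the year; k = 12 gives months 1..12
  month_frac <- (seq_len(k) - 0.5) / k
  months <- pmin(12L, floor(month_frac * 12) + 1L)
  time <- rep(yrs, each = k) + rep(month_frac, times = length(yrs))
  dates <- as.Date(sprintf("%d-%02d-15", rep(yrs, each = k),
                           rep(months, times = length(yrs))))
  mu <- synthetic_mean_evi(config, time)
  set.seed(.sub_seed(config, "series", site_index))
  evi <- mu + stats::rnorm(length(mu), 0, config$noise_sd)
  evi <- pmax(pmin(evi, 1), -1)
  evi_series(sprintf("S%d", site_index), dates, evi)
}

# Dirichlet via normalised gamma draws
.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha
  g / sum(g)
}

# cover fractions tilted toward the true class, rejection-sampled until
# the ground-truth rules recover the label
.draw_cover <- function(true_class) {
  # concentration per (water, sand, grass, shrub, tree)
  alpha <- switch(true_class,
    water = c(30, 2, 1, 0.1, 0.1),
    sand  = c(2, 30, 1, 0.1, 0.1),
    grass = c(3, 5, 12, 0.1, 0.1),
    shrub = c(2, 4, 3, 8, 0.1),
    tree  = c(2, 4, 3, 1, 8))
  for (i in 1:200) {
    f <- .rdirichlet1(alpha)
    lab <- classify_plot(f[1], f[2], f[3], f[4], f[5])
    if (lab == true_class) return(f)
  }
  stop("failed to draw cover fractions for class ", true_class)
}

#' Generate synthetic ground-truth habitat plots
#'
#' Draws a true habitat class per plot, cover fractions consistent with
#' that class under the ground-truth rules (Dirichlet tilted toward the
#' class, rejection-sampled until [classify_plot()] recovers the label),
#' and an EVI from the class's `(center, spread)` Gaussian truncated to
#' [-1, 1].
#'
#' @param config a [synthetic_config()].
#' @param n_plots number of plots; defaults to
#'   `n_sites * plots_per_site`.
#' @return data frame with columns `plot`, `site`, `year`, the five cover
#'   fractions, `evi`, and the true `class`.
#' @export
generate_habitat_plots <- function(config, n_plots = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$class_evi_params))
    stop("configuration error: class_evi_params missing")
  if (is.null(n_plots)) n_plots <- config$n_sites * config$plots_per_site
  set.seed(.sub_seed(config, "plots"))
  cls <- sample(HABITAT_CLASSES_5, n_plots, replace = TRUE,
                prob = config$class_probs)
  cover <- t(vapply(cls, .draw_cover, numeric(5)))
  centers <- vapply(config$class_evi_params, `[`, numeric(1), 1)
  spreads <- vapply(config$class_evi_params, `[`, numeric(1), 2)
  evi <- stats::rnorm(n_plots, centers[cls], spreads[cls])
  evi <- pmax(pmin(evi, 1), -1)
  data.frame(
    plot = sprintf("P%04d", seq_len(n_plots)),
    site = sprintf("S%d", ((seq_len(n_plots) - 1L) %% config$n_sites) + 1L),
    year = config$years[2],
    f_water = cover[, 1], f_sand = cover[, 2], f_grass = cover[, 3],
    f_shrub = cover[, 4], f_tree = cover[, 5],
    evi = evi, class = cls,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Generate a synthetic nest table from per-site seasonal EVI
#'
#' Counts are drawn from a negative binomial with mean
#' `exp(intercept + slope * evi)` and variance `mu + dispersion * mu^2`
#' (Poisson when `dispersion = 0`); the declining-nests direction requires
#' `slope < 0`. Zero counts are recorded with entry `"0"`.
#'
#' @param config a [synthetic_config()].
#' @param evi_by_site_year data frame with columns `site`, `year`, `evi`
#'   (nesting-season average EVI per site-year).
#' @return data frame with columns `site`, `bank_type`, `year`, `entry`,
#'   `nests` (integer count backing each entry).
#' @export
generate_nest_table <- function(config, evi_by_site_year) {
  stopifnot(inherits(config, "synthetic_config"))
  nm <- config$nest_model
  if (nm[["dispersion"]] < 0) stop("configuration error: negative dispersion")
  if (nrow(evi_by_site_year) == 0) {
    return(data.frame(site = character(0), bank_type = character(0),
                      year = integer(0), entry = character(0),
                      nests = integer(0), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("site", "year", "evi") %in% names(evi_by_site_year)))
  mu <- exp(nm[["intercept"]] + nm[["slope"]] * evi_by_site_year$evi)
  set.seed(.sub_seed(config, "nests"))
  counts <- if (nm[["dispersion"]] == 0) {
    stats::rpois(length(mu), mu)
  } else {
    # variance mu + d*mu^2  <=>  NB size = 1/d
    stats::rnbinom(length(mu), size = 1 / nm[["dispersion"]], mu = mu)
  }
  sites <- evi_by_site_year$site
  bank <- ifelse((match(sites, unique(sites)) %% 2L) == 1L, "RB", "SB")
  data.frame(
    site = sites, bank_type = bank,
    year = evi_by_site_year$year,
    entry = as.character(counts),
    nests = as.integer(counts),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write the three synthetic CSV products
#'
#' Emits `evi_series.csv` (site, date, evi), `plots.csv` (plot, site,
#' year, cover fractions, evi), and `nests.csv` (site, bank_type, year,
#' entry) into a directory.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_synthetic_csvs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- lapply(seq_len(config$n_sites),
                   function(i) generate_evi_series(config, i))
  evi_df <- do.call(rbind, lapply(series, function(s)
    data.frame(site = s$id, date = format(s$date), evi = s$evi,
               stringsAsFactors = FALSE)))
  plots <- generate_habitat_plots(config)
  nest_years <- seq(max(config$years[1], config$years[2] - 4L),
                    config$years[2])
  evi_sy <- do.call(rbind, lapply(series, function(s) {
    data.frame(site = s$id, year = nest_years,
               evi = vapply(nest_years, function(y)
                 seasonal_average(s, y), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  evi_sy <- evi_sy[is.finite(evi_sy$evi), ]
  nests <- generate_nest_table(config, evi_sy)
  p1 <- file.path(dir, "evi_series.csv")
  p2 <- file.path(dir, "plots.csv")
  p3 <- file.path(dir, "nests.csv")
  utils::write.csv(evi_df, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(plots, p2, row.names = FALSE, quote = FALSE)
  utils::write.csv(nests[, c("site", "bank_type", "year", "entry")], p3,
                   row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3))
}
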