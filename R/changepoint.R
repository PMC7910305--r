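# Gaussian segment costs on cumulative sums.
# mean:    RSS of the segment divided by a pooled variance estimate
#          (-2 log-likelihood up to an additive constant, known variance)
# meanvar: n * (log(2*pi) + log(sigma2_hat) + 1), sigma2_hat floored to keep
#          the cost finite on flat segments
.make_cost <- function(x, statistic, var_floor = 1e-8) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  if (statistic == "mean") {
    # pooled variance from lag-1 differences: robust to mean changes
    sigma2 <- if (n > 1) max(mean(diff(x)^2) / 2, var_floor) else 1
    function(i, j) {
      # cost of segment x[(i+1)..j], i can be vector
      len <- j - i
      rss <- (cs2[j + 1] - cs2[i + 1]) - (cs[j + 1] - cs[i + 1])^2 / len
      pmax(rss, 0) / sigma2
    }
  } else {
    function(i, j) {
      len <- j - i
      rss <- (cs2[j + 1] - cs2[i + 1]) - (cs[j + 1] - cs[i + 1])^2 / len
      s2 <- pmax(rss / len, var_floor)
      len * (log(2 * pi) + log(s2) + 1)
    }
  }
}

.resolve_penalty <- function(penalty, n, statistic) {
  p <- if (statistic == "meanvar") 2 else 1
  if (is.numeric(penalty)) return(list(name = "manual", value = penalty))
  value <- switch(match.arg(penalty, c("mbic", "bic")),
                  mbic = 3 * p * log(n),
                  bic = (p + 1) * log(n))
  list(name = penalty, value = value)
}

# Optimal partitioning with pruning (PELT). Returns 0-based indices of the
# last point of each segment but the final one.
.pelt <- function(cost, n, beta, minseg) {
  F <- rep(Inf, n + 1)
  F[1] <- -beta
  last <- integer(n + 1)
  cand <- 0L
  ptime <- Inf  # time each candidate became prunable
  for (t in seq.int(minseg, n)) {
    # dominance via a later candidate only holds once that candidate is
    # itself eligible, so removal is delayed by minseg
    live <- ptime + minseg > t
    cand <- cand[live]
    ptime <- ptime[live]
    el <- which(t - cand >= minseg)
    vals <- F[cand[el] + 1] + cost(cand[el], t) + beta
    b <- which.min(vals)
    F[t + 1] <- vals[b]
    last[t + 1] <- cand[el][b]
    newly <- el[vals - beta > F[t + 1]]
    ptime[newly] <- pmin(ptime[newly], t)
    cand <- c(cand, t)
    ptime <- c(ptime, Inf)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- last[t + 1]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  list(cps = cps, cost = F[n + 1])
}

# Optimal partitioning without pruning: same global optimum, O(n^2).
.exhaustive <- function(cost, n, beta, minseg) {
  F <- rep(Inf, n + 1)
  F[1] <- -beta
  last <- integer(n + 1)
  for (t in seq.int(minseg, n)) {
    cand <- seq.int(0L, t - minseg)
    cand <- cand[cand == 0L | cand >= minseg]
    vals <- F[cand + 1] + cost(cand, t) + beta
    b <- which.min(vals)
    F[t + 1] <- vals[b]
    last[t + 1] <- cand[b]
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- last[t + 1]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  list(cps = cps, cost = F[n + 1])
}

# Greedy binary segmentation: keep splitting while the best split of any
# current segment lowers the cost by more than the penalty.
.binseg <- function(cost, n, beta, minseg) {
  cps <- integer(0)
  repeat {
    bounds <- c(0L, cps, n)
    best_gain <- 0
    best_cp <- NA_integer_
    for (k in seq_len(length(bounds) - 1)) {
      a <- bounds[k]; b <- bounds[k + 1]
      if (b - a < 2 * minseg) next
      s <- seq.int(a + minseg, b - minseg)
      gain <- cost(a, b) - (cost(a, s) + cost(s, b))
      m <- which.max(gain)
      if (gain[m] - beta > best_gain) {
        best_gain <- gain[m] - beta
        best_cp <- s[m]
      }
    }
    if (is.na(best_cp)) break
    cps <- sort(c(cps, best_cp))
  }
  bounds <- c(0L, cps, n)
  total <- sum(vapply(seq_len(length(bounds) - 1), function(k)
    cost(bounds[k], bounds[k + 1]), numeric(1))) + beta * length(cps)
  list(cps = cps, cost = total)
}

#' Detect changepoints in an EVI series
#'
#' Penalised Gaussian segmentation of a univariate series: changepoints
#' minimise the total segment cost (negative log-likelihood, mean-only at
#' pooled variance or mean-and-variance) plus a per-changepoint penalty.
#' PELT and the exhaustive dynamic program return the global optimum;
#' binary segmentation returns its greedy solution.
#'
#' The default penalty follows the customary modified-BIC family:
#' `3 * p * log(n)` with `p = 1` (mean) or `p = 2` (meanvar) parameters
#' per changepoint; pass a number to override.
#'
#' @param series an [evi_series()] or numeric vector (length >= 4).
#' @param statistic `"meanvar"` (default) or `"mean"` — which moments may
#'   change at a changepoint.
#' @param penalty `"mbic"`, `"bic"`, or a numeric penalty value.
#' @param algorithm `"PELT"`, `"binseg"`, or `"exhaustive"`.
#' @param var_floor variance floor keeping the meanvar cost finite on flat
#'   segments.
#' @return an object of class `changepoint_result`: `id`, `cps` (0-based
#'   index of the last point of each segment except the final one),
#'   `segments` (data frame with start/end indices, mean, variance, and
#'   dates when available), `cost`, `penalty`, `algorithm`, `n`.
#' @examples
#' x <- c(rnorm(30, 0, 0.02), rnorm(30, 0.3, 0.02))
#' detect_changepoints(x, statistic = "mean")
#' @export
detect_changepoints <- function(series,
                                statistic = c("meanvar", "mean"),
                                penalty = "mbic",
                                algorithm = c("PELT", "binseg", "exhaustive"),
                                var_floor = 1e-8) {
  statistic <- match.arg(statistic)
  algorithm <- match.arg(algorithm)
  if (inherits(series, "evi_series")) {
    x <- series$evi
    id <- series$id
    dates <- series$date
  } else {
    x <- as.numeric(series)
    id <- "series"
    dates <- NULL
  }
  n <- length(x)
  if (n < 4) stop("series too short: need at least 4 observations")
  minseg <- if (statistic == "meanvar") 2L else 1L
  cost <- .make_cost(x, statistic, var_floor)
  pen <- .resolve_penalty(penalty, n, statistic)
  fit <- switch(algorithm,
                PELT = .pelt(cost, n, pen$value, minseg),
                exhaustive = .exhaustive(cost, n, pen$value, minseg),
                binseg = .binseg(cost, n, pen$value, minseg))
  bounds <- c(0L, fit$cps, n)
  segs <- data.frame(
    start = bounds[-length(bounds)] + 1L,
    end = bounds[-1],
    mean = NA_real_, var = NA_real_
  )
  for (k in seq_len(nrow(segs))) {
    seg <- x[segs$start[k]:segs$end[k]]
    segs$mean[k] <- mean(seg)
    segs$var[k] <- if (length(seg) > 1) stats::var(seg) else 0
  }
  if (!is.null(dates)) {
    segs$start_date <- dates[segs$start]
    segs$end_date <- dates[segs$end]
  }
  # fit$cost = sum of segment costs + penalty * number of changepoints
  structure(list(id = id, cps = fit$cps, segments = segs,
                 cost = fit$cost,
                 penalty = pen, algorithm = algorithm,
                 statistic = statistic, n = n,
                 dates = dates, x = x),
            class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf("Changepoints for '%s' (%s, %s penalty %.3f): %d found\n",
              x$id, x$algorithm, x$statistic, x$penalty$value,
              length(x$cps)))
  if (length(x$cps)) {
    if (!is.null(x$dates)) {
      cat("  at:", paste(format(x$dates[x$cps]), collapse = ", "), "\n")
    } else {
      cat("  at indices:", paste(x$cps, collapse = ", "), "\n")
    }
  }
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Apply the "no return" criterion to detected changepoints
#'
#' Every observation is mapped to a merged habitat class (water, sandy
#' grassland, woody). Scanning changepoints in time order, the earliest one
#' after which the fraction of later observations still in the
#' pre-changepoint modal class is at most `return_tolerance` marks the
#' regime shift — the point after which the habitat never returns to its
#' prior dynamics. `NA` when no changepoint qualifies.
#'
#' @param series the [evi_series()] the changepoints were computed on.
#' @param cps a [detect_changepoints()] result on `series`.
#' @param return_tolerance maximum tolerated fraction of post-shift
#'   observations in the pre-shift modal class; default 0.05 (a strict
#'   reading with allowance for single noisy scenes; use 0 for the
#'   literal rule).
#' @return an object of class `regime_shift_result`: `id`, `shift_date`
#'   (or `NA`), `shift_index`, `pre_class`, `post_class`,
#'   `return_fraction`, `segment_classes` (modal merged class per
#'   segment).
#' @export
find_regime_shift <- function(series, cps, return_tolerance = 0.05) {
  stopifnot(inherits(cps, "changepoint_result"))
  if (inherits(series, "evi_series")) {
    x <- series$evi
    dates <- series$date
    id <- series$id
  } else {
    x <- as.numeric(series)
    dates <- NULL
    id <- cps$id
  }
  if (length(x) != cps$n) stop("changepoints were not computed on this series")
  lab <- classify_evi_3(x)
  modal <- function(v) names(which.max(table(v)))
  seg_classes <- vapply(seq_len(nrow(cps$segments)), function(k)
    modal(lab[cps$segments$start[k]:cps$segments$end[k]]), character(1))
  shift_index <- NA_integer_
  pre_class <- post_class <- NA_character_
  return_fraction <- NA_real_
  for (cp in cps$cps) {
    post <- lab[(cp + 1):length(lab)]
    if (length(post) == 0) {
      warning("changepoint at index ", cp, " has an empty post-segment; skipped")
      next
    }
    pre <- lab[1:cp]
    pre_modal <- modal(pre)
    frac <- mean(post == pre_modal)
    if (frac <= return_tolerance) {
      shift_index <- cp
      pre_class <- pre_modal
      post_class <- modal(post)
      return_fraction <- frac
      break
    }
  }
  structure(list(
    id = id,
    shift_date = if (!is.na(shift_index) && !is.null(dates))
      dates[shift_index] else as.Date(NA),
    shift_index = shift_index,
    pre_class = pre_class, post_class = post_class,
    return_fraction = return_fraction,
    segment_classes = seg_classes,
    return_tolerance = return_tolerance
  ), class = "regime_shift_result")
}

#' @export
print.regime_shift_result <- function(x, ...) {
  if (is.na(x$shift_index)) {
    cat(sprintf("Site '%s': no regime shift (tolerance %.2f)\n",
                x$id, x$return_tolerance))
  } else {
    cat(sprintf(
      "Site '%s': regime shift at %s (%s -> %s, return fraction %.3f)\n",
      x$id,
      if (is.na(x$shift_date)) paste("index", x$shift_index)
      else format(x$shift_date),
      x$pre_class, x$post_class, x$return_fraction))
  }
  invisible(x)
}

#' Run changepoint and regime-shift detection over many sites
#'
#' Applies [detect_changepoints()] and [find_regime_shift()] to each
#' series; per-site errors become per-site failure records and never abort
#' the batch.
#'
#' @param all_series list of [evi_series()] objects.
#' @param statistic,penalty,algorithm,return_tolerance passed through.
#' @return an object of class `batch_dynamics`: `results` (list of
#'   `regime_shift_result` or failure records), `changepoints` (list of
#'   `changepoint_result`), and `shift_years` (named integer vector,
#'   `NA` for sites without a shift).
#' @export
batch_dynamics <- function(all_series, statistic = "meanvar",
                           penalty = "mbic", algorithm = "PELT",
                           return_tolerance = 0.05) {
  if (length(all_series) < 1) stop("need at least one series")
  results <- vector("list", length(all_series))
  cps_list <- vector("list", length(all_series))
  for (i in seq_along(all_series)) {
    s <- all_series[[i]]
    res <- tryCatch({
      cp <- detect_changepoints(s, statistic = statistic, penalty = penalty,
                                algorithm = algorithm)
      cps_list[[i]] <- cp
      find_regime_shift(s, cp, return_tolerance)
    }, error = function(e) {
      structure(list(id = s$id, error = conditionMessage(e)),
                class = "regime_shift_failure")
    })
    results[[i]] <- res
  }
  ids <- vapply(all_series, function(s) s$id, character(1))
  names(results) <- ids
  names(cps_list) <- ids
  shift_years <- vapply(results, function(r) {
    if (inherits(r, "regime_shift_failure") || is.na(r$shift_index))
      return(NA_integer_)
    if (!is.na(r$shift_date))
      as.integer(format(r$shift_date, "%Y"))
    else NA_integer_
  }, integer(1))
  structure(list(results = results, changepoints = cps_list,
                 shift_years = shift_years),
            class = "batch_dynamics")
}

#' @export
print.batch_dynamics <- function(x, ...) {
  cat(sprintf("Habitat dynamics for %d sites\n", length(x$results)))
  for (r in x$results) print(r)
  yrs <- x$shift_years[!is.na(x$shift_years)]
  if (length(yrs))
    cat("Shift years:", paste(sprintf("%s=%d", names(yrs), yrs),
                              collapse = ", "), "\n")
  invisible(x)
}
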