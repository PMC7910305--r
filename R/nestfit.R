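#' Fit candidate nest-count versus EVI relations
#'
#' Three functional forms relate nesting-season average EVI to the number
#' of nests at a site-year:
#' \itemize{
#'   \item linear: `nests = a + b * evi`, ordinary least squares;
#'   \item exponential: `log(nests + 1) = a + b * evi` by least squares
#'     (the +1 admits zero counts), with R-squared computed on the count
#'     scale from back-transformed predictions;
#'   \item logarithmic: `nests = a + b * log(evi - min(evi) + eps)` — EVI
#'     can be zero or negative, so the argument is shifted by the sample
#'     minimum plus `eps`; the shift is recorded in the result.
#' }
#' All R-squared values are computed on the count scale so the forms are
#' comparable.
#'
#' @param points data frame with columns `evi` and `nests`
#'   (non-negative integer counts); at least 3 rows and 2 distinct EVI
#'   values.
#' @param forms character subset of `c("linear", "exponential",
#'   "logarithmic")`.
#' @param eps positive shift added inside the logarithm.
#' @return list of `nest_fit_form` objects (one per fitted form), each
#'   with `form`, `coefficients`, `r_squared`, `p_slope`, `fit` (the lm),
#'   and `log_shift` for the logarithmic form.
#' @export
fit_models <- function(points,
                       forms = c("linear", "exponential", "logarithmic"),
                       eps = 0.01) {
  stopifnot(all(c("evi", "nests") %in% names(points)))
  points <- points[is.finite(points$evi) & is.finite(points$nests), ]
  if (nrow(points) < 3) stop("need at least 3 points")
  if (length(unique(points$evi)) < 2)
    stop("degenerate EVI spread: need at least 2 distinct values")
  if (any(points$nests < 0)) stop("nest counts must be non-negative")
  forms <- match.arg(forms, several.ok = TRUE)
  y <- points$nests
  sst <- sum((y - mean(y))^2)
  r2 <- function(pred) if (sst == 0) NA_real_ else 1 - sum((y - pred)^2) / sst
  slope_p <- function(fit) {
    cf <- stats::coef(summary(fit))
    if (nrow(cf) < 2 || is.na(cf[2, 4])) NA_real_ else cf[2, 4]
  }
  out <- list()
  if ("linear" %in% forms) {
    fit <- stats::lm(nests ~ evi, data = points)
    out$linear <- structure(list(
      form = "linear", coefficients = stats::coef(fit),
      r_squared = r2(stats::fitted(fit)), p_slope = slope_p(fit),
      fit = fit, log_shift = NA_real_), class = "nest_fit_form")
  }
  if ("exponential" %in% forms) {
    fit <- stats::lm(log(nests + 1) ~ evi, data = points)
    pred <- exp(stats::fitted(fit)) - 1
    out$exponential <- structure(list(
      form = "exponential", coefficients = stats::coef(fit),
      r_squared = r2(pred), p_slope = slope_p(fit),
      fit = fit, log_shift = NA_real_), class = "nest_fit_form")
  }
  if ("logarithmic" %in% forms) {
    shift <- -min(points$evi) + eps
    lx <- log(points$evi + shift)
    if (length(unique(lx)) >= 2) {
      d <- data.frame(nests = y, lx = lx)
      fit <- stats::lm(nests ~ lx, data = d)
      out$logarithmic <- structure(list(
        form = "logarithmic", coefficients = stats::coef(fit),
        r_squared = r2(stats::fitted(fit)), p_slope = slope_p(fit),
        fit = fit, log_shift = shift), class = "nest_fit_form")
    }
    # inadmissible (degenerate transformed spread): skipped, not errored
  }
  out
}

#' Select the best-fitting form
#'
#' Maximum R-squared on the count scale; exact ties go to the simpler
#' form in the preference order linear, logarithmic, exponential.
#'
#' @param fits list from [fit_models()].
#' @return the winning `nest_fit_form`.
#' @export
select_best <- function(fits) {
  if (length(fits) < 1) stop("no fits to select from")
  pref <- c(linear = 1, logarithmic = 2, exponential = 3)
  r2s <- vapply(fits, function(f) f$r_squared, numeric(1))
  ord <- order(-r2s, pref[vapply(fits, function(f) f$form, character(1))])
  fits[[ord[1]]]
}

#' Subsample-averaged p-value of the slope
#'
#' Repeats `n_boot` times: draw `ceiling(subsample_fraction * n)` points
#' without replacement, fit the given form, record the two-sided t-test
#' p-value of the slope coefficient; return the arithmetic mean of the
#' replicate p-values. Replicates with degenerate EVI spread are skipped
#' and counted; more than half skipped is an error. Bit-reproducible under
#' a fixed seed.
#'
#' @param points data frame with `evi`, `nests`.
#' @param form one of `"linear"`, `"exponential"`, `"logarithmic"`.
#' @param n_boot number of replicates (1000 by default).
#' @param subsample_fraction fraction drawn each replicate (0.8 by
#'   default; 1 makes every replicate the full data).
#' @param seed integer seed.
#' @return list with `mean_p`, `n_boot`, `n_skipped`,
#'   `subsample_fraction`, `seed`.
#' @export
bootstrap_p <- function(points, form = "linear", n_boot = 1000L,
                        subsample_fraction = 0.8, seed = 1L) {
  stopifnot(n_boot >= 1, subsample_fraction > 0, subsample_fraction <= 1)
  n <- nrow(points)
  m <- ceiling(subsample_fraction * n)
  if (m < 3) stop("subsample size must be at least 3")
  set.seed(as.integer(seed))
  ps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, m, replace = FALSE)
    sub <- points[idx, , drop = FALSE]
    ps[b] <- tryCatch({
      f <- suppressWarnings(fit_models(sub, forms = form))
      if (length(f) == 0) NA_real_ else f[[1]]$p_slope
    }, error = function(e) NA_real_)
  }
  skipped <- sum(is.na(ps))
  if (skipped > n_boot / 2)
    stop("more than half of the replicates were degenerate")
  list(mean_p = mean(ps, na.rm = TRUE), n_boot = as.integer(n_boot),
       n_skipped = as.integer(skipped),
       subsample_fraction = subsample_fraction, seed = as.integer(seed))
}

#' Fit, select, and assess the nest-count versus EVI relation
#'
#' The headline interface: fits the candidate forms, selects the one with
#' the highest count-scale R-squared, and attaches the subsample-averaged
#' slope p-value of the selected form.
#'
#' @param points data frame with columns `evi` (nesting-season average
#'   EVI) and `nests` (actual nest counts; site-years with uncounted
#'   nesting must be excluded upstream).
#' @param n_boot,subsample_fraction,seed passed to [bootstrap_p()].
#' @param forms candidate forms; see [fit_models()].
#' @return an object of class `nest_evi_fit` with elements `fits`,
#'   `selected`, `bootstrap`, `points`, `call`.
#' @examples
#' pts <- data.frame(evi = seq(0, 0.3, length.out = 12),
#'                   nests = round(pmax(0, 10 - 30 * seq(0, 0.3, length.out = 12))))
#' fit <- nest_evi_fit(pts, n_boot = 50, seed = 7)
#' summary(fit)
#' @export
nest_evi_fit <- function(points, n_boot = 1000L, subsample_fraction = 0.8,
                         seed = 1L,
                         forms = c("linear", "exponential", "logarithmic")) {
  fits <- fit_models(points, forms = forms)
  selected <- select_best(fits)
  boot <- bootstrap_p(points, form = selected$form, n_boot = n_boot,
                      subsample_fraction = subsample_fraction, seed = seed)
  structure(list(fits = fits, selected = selected, bootstrap = boot,
                 points = points, call = match.call()),
            class = "nest_evi_fit")
}

#' @export
print.nest_evi_fit <- function(x, digits = 4, ...) {
  s <- x$selected
  cat(sprintf("Nest-count ~ EVI relation: %s form selected (R2 = %.*f)\n",
              s$form, digits, s$r_squared))
  cat(sprintf("  coefficients: intercept %.*f, slope %.*f\n",
              digits, s$coefficients[1], digits, s$coefficients[2]))
  cat(sprintf("  mean subsample p (n = %d at %.0f%%): %.3g\n",
              x$bootstrap$n_boot, 100 * x$bootstrap$subsample_fraction,
              x$bootstrap$mean_p))
  invisible(x)
}

#' @export
summary.nest_evi_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$fits, function(f)
    data.frame(form = f$form, intercept = unname(f$coefficients[1]),
               slope = unname(f$coefficients[2]), r_squared = f$r_squared,
               p_slope = f$p_slope)))
  rownames(tab) <- NULL
  structure(list(candidates = tab, selected = object$selected$form,
                 bootstrap = object$bootstrap,
                 n = nrow(object$points)),
            class = "summary.nest_evi_fit")
}

#' @export
print.summary.nest_evi_fit <- function(x, ...) {
  cat(sprintf("Candidate fits (n = %d site-years):\n", x$n))
  print(x$candidates, row.names = FALSE, digits = 4)
  cat(sprintf("selected: %s; mean subsample p = %.3g (%d replicates, %d skipped)\n",
              x$selected, x$bootstrap$mean_p, x$bootstrap$n_boot,
              x$bootstrap$n_skipped))
  invisible(x)
}

#' @export
coef.nest_evi_fit <- function(object, ...) object$selected$coefficients

#' @export
predict.nest_evi_fit <- function(object, newdata = NULL, ...) {
  s <- object$selected
  evi <- if (is.null(newdata)) object$points$evi else newdata$evi
  a <- s$coefficients[1]; b <- s$coefficients[2]
  switch(s$form,
         linear = a + b * evi,
         exponential = exp(a + b * evi) - 1,
         logarithmic = a + b * log(evi + s$log_shift))
}

#' @export
residuals.nest_evi_fit <- function(object, ...) {
  object$points$nests - predict(object)
}

#' @export
plot.nest_evi_fit <- function(x, ...) {
  evi <- x$points$evi
  grid <- seq(min(evi), max(evi), length.out = 200)
  plot(evi, x$points$nests, xlab = "nesting-season EVI",
       ylab = "number of nests",
       main = sprintf("Selected form: %s", x$selected$form), ...)
  graphics::lines(grid, predict(x, data.frame(evi = grid)), lwd = 2)
  graphics::abline(v = c(0, 0.13), lty = 3)
  invisible(x)
}

#' @export
simulate.nest_evi_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- pmax(predict(object), 0)
  out <- replicate(nsim, stats::rpois(length(mu), mu))
  as.data.frame(out)
}
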