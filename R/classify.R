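#' @keywords internal
HABITAT_CLASSES_5 <- c("water", "sand", "grass", "shrub", "tree")

#' @keywords internal
HABITAT_CLASSES_3 <- c("water", "sandy_grassland", "woody")

#' Threshold scheme for EVI habitat classification
#'
#' Holds the per-class EVI intervals of the five-class scheme and the merged
#' three-class boundaries. Consecutive class intervals may touch, leave a
#' gap, or overlap; classification resolves each pair at the midpoint of
#' the shared/empty region, i.e. the effective cut between class k and k+1
#' is `(hi_k + lo_{k+1}) / 2`.
#'
#' @param intervals named list of `c(lo, hi)` pairs for
#'   water, sand, grass, shrub, tree, in ascending EVI order.
#' @param b_water,b_woody merged three-class boundaries
#'   (water below `b_water`, woody at or above `b_woody`).
#' @return an object of class `threshold_scheme`.
#' @export
threshold_scheme <- function(intervals, b_water = 0, b_woody = 0.13) {
  stopifnot(identical(names(intervals), HABITAT_CLASSES_5))
  for (cl in HABITAT_CLASSES_5) {
    iv <- intervals[[cl]]
    if (length(iv) != 2 || !all(is.finite(iv)) || iv[1] > iv[2])
      stop("interval for class '", cl, "' must be finite ascending c(lo, hi)")
  }
  if (!(b_water < b_woody)) stop("merged boundaries must satisfy b_water < b_woody")
  los <- vapply(intervals, `[`, numeric(1), 1)
  his <- vapply(intervals, `[`, numeric(1), 2)
  if (is.unsorted(los) || is.unsorted(his))
    stop("class intervals must be in ascending EVI order")
  # effective cuts between consecutive classes (4 cuts for 5 classes)
  cuts <- (his[-5] + los[-1]) / 2
  structure(list(intervals = intervals, cuts = unname(cuts),
                 b_water = b_water, b_woody = b_woody),
            class = "threshold_scheme")
}

#' The published EVI threshold scheme
#'
#' Five-class EVI intervals: water (-1, 0), sand (0, 0.08),
#' grass (0.05, 0.13), shrub (0.13, 0.215), tree (0.215, 0.325).
#' Sand and grass overlap on [0.05, 0.08); the five-class classifier splits
#' the overlap at its midpoint 0.065. Merged boundaries: water below 0,
#' woody vegetation at or above 0.13.
#'
#' @return a [threshold_scheme()].
#' @export
published_scheme <- function() {
  threshold_scheme(list(
    water = c(-1, 0),
    sand  = c(0, 0.08),
    grass = c(0.05, 0.13),
    shrub = c(0.13, 0.215),
    tree  = c(0.215, 0.325)
  ))
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat("EVI threshold scheme\n")
  for (cl in HABITAT_CLASSES_5) {
    iv <- x$intervals[[cl]]
    cat(sprintf("  %-6s [%7.3f, %7.3f)\n", cl, iv[1], iv[2]))
  }
  cat(sprintf("  effective cuts: %s\n",
              paste(format(x$cuts, digits = 4), collapse = ", ")))
  cat(sprintf("  merged: water < %g <= sandy_grassland < %g <= woody\n",
              x$b_water, x$b_woody))
  invisible(x)
}

#' Classify a habitat plot from ground cover fractions
#'
#' Rule-based ground-truth classification of 1 m^2 plots. Rules are
#' evaluated woodiest-first because sparse woody cover dominates a plot
#' (a single tree shading it suppresses grass): tree if tree cover > 10%,
#' else shrub if shrub cover > 10%, else grass if grass cover > 30%, else
#' water if water cover > 75%, else sand if sand cover > 75%, else
#' `"unclassified"`.
#'
#' @param f_water,f_sand,f_grass,f_shrub,f_tree cover fractions in [0, 1]
#'   (vectors are accepted and recycled).
#' @param tol tolerance on the fraction sum exceeding 1.
#' @return character vector of class labels (possibly `"unclassified"`).
#' @examples
#' classify_plot(f_water = 0.8, f_sand = 0.2)   # water
#' classify_plot(f_tree = 0.12, f_grass = 0.5)  # tree
#' @export
classify_plot <- function(f_water = 0, f_sand = 0, f_grass = 0,
                          f_shrub = 0, f_tree = 0, tol = 1e-6) {
  n <- max(length(f_water), length(f_sand), length(f_grass),
           length(f_shrub), length(f_tree))
  f_water <- rep_len(f_water, n); f_sand <- rep_len(f_sand, n)
  f_grass <- rep_len(f_grass, n); f_shrub <- rep_len(f_shrub, n)
  f_tree <- rep_len(f_tree, n)
  fr <- cbind(f_water, f_sand, f_grass, f_shrub, f_tree)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("cover fractions must be finite and within [0, 1]")
  if (any(rowSums(fr) > 1 + tol))
    stop("cover fractions sum to more than 1")
  out <- rep("unclassified", n)
  out[f_sand > 0.75] <- "sand"
  out[f_water > 0.75] <- "water"
  out[f_grass > 0.30] <- "grass"
  out[f_shrub > 0.10] <- "shrub"
  out[f_tree > 0.10] <- "tree"
  out
}

#' Five-class EVI habitat classification
#'
#' Interval membership under the half-open convention [lo, hi): the
#' effective cut between EVI-adjacent classes is the midpoint of their gap
#' or overlap (0.065 for the published sand/grass overlap). Values at or
#' above the tree interval's upper end are still tree; values below -1 are
#' rejected.
#'
#' @param evi numeric EVI values in [-1, 1].
#' @param scheme a [threshold_scheme()]; defaults to [published_scheme()].
#' @return character vector of five-class labels.
#' @export
classify_evi_5 <- function(evi, scheme = published_scheme()) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  if (any(!is.finite(evi))) stop("EVI must be finite")
  if (any(evi < -1 | evi > 1)) stop("EVI must lie within [-1, 1]")
  idx <- findInterval(evi, scheme$cuts, left.open = FALSE) + 1L
  HABITAT_CLASSES_5[idx]
}

#' Merged three-class EVI habitat classification
#'
#' The downstream-canonical scheme: water for EVI below 0, sandy grassland
#' for 0 <= EVI < 0.13, woody vegetation for EVI >= 0.13.
#'
#' @param evi numeric EVI values (finite).
#' @param b_water,b_woody class boundaries.
#' @return character vector of merged labels.
#' @export
classify_evi_3 <- function(evi, b_water = 0, b_woody = 0.13) {
  if (any(!is.finite(evi))) stop("EVI must be finite")
  out <- rep("sandy_grassland", length(evi))
  out[evi < b_water] <- "water"
  out[evi >= b_woody] <- "woody"
  out
}

#' Merge five-class labels into the three-class scheme
#'
#' sand and grass collapse to sandy grassland; shrub and tree collapse to
#' woody vegetation.
#'
#' @param labels character vector of five-class labels.
#' @return character vector of merged labels.
#' @export
merge_classes <- function(labels) {
  map <- c(water = "water", sand = "sandy_grassland",
           grass = "sandy_grassland", shrub = "woody", tree = "woody")
  bad <- !(labels %in% names(map))
  if (any(bad)) stop("unknown class label(s): ",
                     paste(unique(labels[bad]), collapse = ", "))
  unname(map[labels])
}

#' Calibrate an EVI threshold scheme from labelled plots
#'
#' A random training split (default 80%) provides the spread of EVI per
#' ground-truth class; each class interval is the (min, max) of its
#' training EVIs. Overlap between EVI-adjacent classes, when observed, is
#' retained (the classifier resolves it at the overlap midpoint, mirroring
#' how the published sand/grass overlap is handled); disjoint intervals
#' meet at their gap midpoint through the scheme's effective cuts.
#'
#' @param plots data frame with columns `evi` and `class` (five-class
#'   ground-truth labels), e.g. from [generate_habitat_plots()] with
#'   `class = classify_plot(...)`.
#' @param train_fraction fraction of plots used for calibration.
#' @param seed integer seed for the split.
#' @return list with elements `scheme` (a [threshold_scheme()]), `train`
#'   and `test` (row indices of the split).
#' @export
calibrate_thresholds <- function(plots, train_fraction = 0.8, seed = 1L) {
  stopifnot(all(c("evi", "class") %in% names(plots)),
            train_fraction > 0, train_fraction <= 1)
  n <- nrow(plots)
  set.seed(as.integer(seed))
  train <- sort(sample.int(n, size = max(1L, round(train_fraction * n))))
  test <- setdiff(seq_len(n), train)
  tr <- plots[train, , drop = FALSE]
  intervals <- list()
  for (cl in HABITAT_CLASSES_5) {
    e <- tr$evi[tr$class == cl]
    if (length(e) < 2)
      stop("calibration error: class '", cl,
           "' has fewer than 2 training plots")
    intervals[[cl]] <- c(min(e), max(e))
  }
  list(scheme = threshold_scheme(intervals), train = train, test = test)
}

#' Confusion matrix, accuracies, and Cohen's kappa
#'
#' Cross-tabulates ground truth (rows) against predictions (columns) over
#' the union of observed labels, and derives overall accuracy
#' (trace/total), per-class producer's accuracy (recall, diagonal over row
#' total), per-class user's accuracy (precision, diagonal over column
#' total), their unweighted mean, and Cohen's kappa
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with expected agreement from the
#' row-by-column marginals. Kappa is `NA` when chance agreement is 1
#' (a single occupied class).
#'
#' @param truth,predicted equal-length character vectors of class labels.
#' @return an object of class `confusion_matrix` with elements `table`,
#'   `overall_accuracy`, `producers_accuracy`, `users_accuracy`,
#'   `mean_class_accuracy`, `kappa`, `n`.
#' @examples
#' validate(rep(c("a", "b"), each = 50),
#'          c(rep("a", 45), rep("b", 5), rep("b", 45), rep("a", 5)))
#' @export
validate <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (length(truth) < 1) stop("need at least one observation")
  levs <- sort(unique(c(truth, predicted)))
  tab <- table(factor(truth, levels = levs),
               factor(predicted, levels = levs))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps^0.5) NA_real_
           else (p_o - p_e) / (1 - p_e)
  prod_acc <- diag(tab) / rowSums(tab)
  user_acc <- diag(tab) / colSums(tab)
  structure(list(
    table = tab,
    overall_accuracy = p_o,
    producers_accuracy = prod_acc,
    users_accuracy = user_acc,
    mean_class_accuracy = mean(prod_acc, na.rm = TRUE),
    kappa = kappa,
    n = as.integer(n)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted)\n")
  print(x$table)
  cat(sprintf("overall accuracy: %.*f  mean class accuracy: %.*f  kappa: %s\n",
              digits, x$overall_accuracy, digits, x$mean_class_accuracy,
              if (is.na(x$kappa)) "NA" else formatC(x$kappa, digits = digits,
                                                   format = "f")))
  invisible(x)
}
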