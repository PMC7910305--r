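# Independent brute-force changepoint oracle: enumerates every segmentation
# (compositions of n with parts >= minseg) and evaluates the Gaussian cost
# directly from segment moments, without cumulative sums or pruning.

oracle_segment_cost <- function(seg, statistic, sigma2_pooled, var_floor = 1e-8) {
  m <- mean(seg)
  rss <- sum((seg - m)^2)
  if (statistic == "mean") {
    rss / sigma2_pooled
  } else {
    s2 <- max(rss / length(seg), var_floor)
    length(seg) * (log(2 * pi) + log(s2) + 1)
  }
}

# all ways to cut 1..n into contiguous segments of length >= minseg,
# returned as lists of cut positions (last index of each non-final segment)
.cutset_cache <- new.env(parent = emptyenv())
oracle_all_cutsets <- function(n, minseg) {
  key <- paste(n, minseg, sep = "_")
  if (!is.null(.cutset_cache[[key]])) return(.cutset_cache[[key]])
  rec <- function(start) {
    if (n - start + 1 < 2 * minseg) return(list(integer(0)))
    out <- list(integer(0))
    for (cut in seq.int(start + minseg - 1, n - minseg)) {
      for (rest in rec(cut + 1)) out <- c(out, list(c(cut, rest)))
    }
    out
  }
  res <- rec(1L)
  .cutset_cache[[key]] <- res
  res
}

oracle_best_cost <- function(x, statistic, beta, var_floor = 1e-8) {
  n <- length(x)
  minseg <- if (statistic == "meanvar") 2L else 1L
  sigma2 <- if (n > 1) max(mean(diff(x)^2) / 2, var_floor) else 1
  # direct segment-cost table, no cumulative sums
  C <- matrix(Inf, n, n)
  for (i in 1:n) for (j in i:n) {
    if (j - i + 1 >= minseg)
      C[i, j] <- oracle_segment_cost(x[i:j], statistic, sigma2, var_floor)
  }
  best <- Inf
  best_cps <- integer(0)
  for (cps in oracle_all_cutsets(n, minseg)) {
    bounds <- c(0L, cps, n)
    total <- beta * length(cps) +
      sum(C[cbind(bounds[-length(bounds)] + 1L, bounds[-1])])
    if (total < best) {
      best <- total
      best_cps <- cps
    }
  }
  list(cost = best, cps = best_cps)
}

# convenience: synthetic nest-decline dataset at the generator defaults
make_decline_points <- function(seed, n = 24) {
  cfg <- synthetic_config(seed = seed)
  evi <- seq(0, 0.3, length.out = n)
  tab <- generate_nest_table(cfg, data.frame(site = sprintf("S%d", seq_len(n)),
                                             year = 2017L, evi = evi))
  data.frame(evi = evi, nests = tab$nests)
}
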