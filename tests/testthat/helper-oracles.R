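# Independent brute-force oracles and small fixture builders.
# The oracles are deliberately naive re-derivations (explicit loops,
# textbook formulas) kept separate from the package's optimized paths.

# Small genome covering a few chromosomes; lengths are taken from the
# built-in model so truth intervals validate.
tiny_genome <- function(chroms = c("1", "2", "X")) {
  g <- make_genome_model(include_y = TRUE)
  g <- g[g$chrom %in% chroms, ]
  rownames(g) <- NULL
  class(g) <- c("genome_model", "data.frame")
  g
}

# Exhaustive double-loop max-arc enumeration with the pooled two-sample
# t statistic, mirroring the documented admissibility and tie-break
# (smallest i, then smallest j, strict improvement).
naive_max_arc <- function(x, min_width = 2) {
  m <- length(x)
  sstot <- sum((x - mean(x))^2)
  if (!(sstot > 1e-12 * max(sum(x^2), 1e-300))) {
    return(list(i = 2L, j = as.integer(min_width) + 1L, T = 0))
  }
  best <- list(i = NA_integer_, j = NA_integer_, T = -Inf)
  for (i in 2:m) {  # prefix arcs are represented by their suffix complement
    for (j in seq_len(m)) {
      n1 <- j - i + 1
      if (j < i || n1 < min_width || n1 > m - min_width) next
      g1 <- x[i:j]
      g2 <- x[-(i:j)]
      ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
      d <- abs(mean(g1) - mean(g2))
      tval <- if (m - 2 <= 0 || ssw <= sstot * 1e-12) {
        if (d > 0) Inf else 0
      } else {
        d / sqrt(ssw / (m - 2) * (1 / n1 + 1 / length(g2)))
      }
      # same tie margin as the implementation: exact t ties (common on
      # the rank scale) resolve to the earliest arc
      if (tval > best$T * (1 + 1e-9) + 1e-300) {
        best <- list(i = i, j = j, T = tval)
      }
    }
  }
  best
}

# Direct evaluation of the weighted correlation formula: medians of all
# n clones, pairwise two-point medians for the weights, weighted sums
# over observations 1..n-1. Written as explicit loops.
naive_weighted_pearson <- function(x, y) {
  n <- length(x)
  x_ref <- median(x)
  y_ref <- median(y)
  w <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    w[i] <- 0.5 * (median(abs(x[c(i, i + 1)] - x_ref)) +
                   median(abs(y[c(i, i + 1)] - y_ref)))
  }
  xs <- x[seq_len(n - 1)]
  ys <- y[seq_len(n - 1)]
  sw <- sum(w)
  if (sw == 0) return(NA_real_)
  xbar <- sum(w * xs) / sw
  ybar <- sum(w * ys) / sw
  cxy <- sum(w * (xs - xbar) * (ys - ybar)) / sw
  cxx <- sum(w * (xs - xbar)^2) / sw
  cyy <- sum(w * (ys - ybar)^2) / sw
  if (cxx == 0 || cyy == 0) return(NA_real_)
  cxy / sqrt(cxx * cyy)
}

# Exhaustive least-squares two-changepoint fit on a vector: minimizes
# within-piece sum of squares over all (b1, b2) cut positions.
naive_two_changepoints <- function(x, min_len = 2) {
  m <- length(x)
  best <- c(NA, NA)
  best_ss <- Inf
  for (b1 in min_len:(m - 2 * min_len)) {
    for (b2 in (b1 + min_len):(m - min_len)) {
      p1 <- x[1:b1]
      p2 <- x[(b1 + 1):b2]
      p3 <- x[(b2 + 1):m]
      ss <- sum((p1 - mean(p1))^2) + sum((p2 - mean(p2))^2) +
        sum((p3 - mean(p3))^2)
      if (ss < best_ss) {
        best_ss <- ss
        best <- c(b1, b2)
      }
    }
  }
  best
}

# End-to-end run of the pipeline on a simulated truth; returns the
# pieces tests commonly need.
run_pipeline <- function(design, truth, noise, sim_seed, seg_seed,
                         config = segmentation_config(seed = seg_seed)) {
  spots <- simulate_spot_table(design, truth, noise, seed = sim_seed)
  prof <- summarize_replicates(spots, design, sample_id = "s",
                               test_sex = truth$test_sex,
                               reference_sex = truth$reference_sex)
  prof <- drop_chromosome(qc_filter(prof))
  segs <- segment_profile(prof, config)
  calls <- call_segments(segs, test_sex = truth$test_sex,
                         reference_sex = truth$reference_sex)
  list(spots = spots, profile = prof, segments = segs, calls = calls)
}
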