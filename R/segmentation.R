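#' Segmentation configuration
#'
#' Parameters of the rank-based circular binary segmentation: the
#' permutation significance level, permutation count, minimum segment
#' width in clones, whether the rank-robust variant is used, and the
#' merge tolerance below which adjacent segments with similar means are
#' fused after recursion.
#'
#' @param alpha Significance level for accepting a split (default 0.01).
#'   In the rank variant the window is tested on the within-window-rank
#'   scale and on the original scale, each at `alpha/2`, keeping the
#'   overall level at `alpha`.
#' @param n_permutations Permutations per test (default 1000, minimum 100).
#' @param min_width Minimum clones per segment (default 2).
#' @param use_ranks Use the rank variant (default `TRUE`): the arc test
#'   runs on within-window ranks (robust to heavy-tailed noise) and on
#'   the original scale (retains the magnitude of short high-level
#'   amplicons, which rank compression hides), and the more significant
#'   split wins. `FALSE` gives classic original-scale CBS.
#' @param merge_tol Merge adjacent segments whose mean log2 ratios differ
#'   by less than this (default 0.05).
#' @param seed Optional integer seed for the permutation draws.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(alpha = 0.01, n_permutations = 1000,
                                min_width = 2, use_ranks = TRUE,
                                merge_tol = 0.05, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100, min_width >= 1,
            merge_tol >= 0)
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 min_width = as.integer(min_width), use_ranks = use_ranks,
                 merge_tol = merge_tol, seed = seed),
            class = "segmentation_config")
}

#' Maximal circular-arc t statistic
#'
#' Scans every circular arc `[i..j]` of the ordered values whose length
#' and complement both reach `min_width`, computing the pooled two-sample
#' t statistic between arc members and non-members, and returns the arc
#' maximizing `|t|` (ties broken by smallest `i`, then smallest `j`;
#' a candidate must beat the incumbent by a `1e-9` relative margin, so
#' exact ties -- same-length arcs with equal mean difference tie exactly,
#' which is common on the rank scale -- resolve deterministically).
#' Each two-piece partition is enumerated exactly once: a partition
#' touching the window edge is represented by its suffix arc, so prefix
#' arcs (`i = 1`) do not appear. A constant input returns `T = 0` at the
#' first admissible arc; a perfectly separated arc returns `T = Inf`.
#'
#' @param values Ordered numeric vector, length at least `2 * min_width`.
#' @param min_width Minimum arc / complement size (default 2).
#' @return List with elements `i`, `j` (1-based inclusive arc bounds)
#'   and `T`.
#' @export
max_arc_statistic <- function(values, min_width = 2) {
  stopifnot(is.numeric(values), all(is.finite(values)), min_width >= 1)
  if (length(values) < 2 * min_width) {
    stop("need at least 2 * min_width = ", 2 * min_width, " values")
  }
  max_arc_cpp(as.numeric(values), as.integer(min_width))
}

#' Permutation p-value for an observed arc statistic
#'
#' Shuffles the values `n_permutations` times, recomputes the maximal
#' arc statistic of each shuffle, and returns the add-one p-value
#' `(1 + #\{T* >= T_obs\}) / (B + 1)`, which is never exactly zero. If
#' `config$seed` is set the generator is seeded first, making the
#' p-value deterministic.
#'
#' @param values Ordered numeric vector.
#' @param T_obs Observed statistic, e.g. from [max_arc_statistic()].
#' @param config A [segmentation_config()].
#' @return The permutation p-value.
#' @export
permutation_pvalue <- function(values, T_obs, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tstar <- perm_max_arc_cpp(as.numeric(values), config$min_width,
                            config$n_permutations)
  (1 + sum(tstar >= T_obs)) / (config$n_permutations + 1)
}

# One scale's arc test: max arc + permutation p-value (add-one).
test_arc <- function(v, config) {
  st <- max_arc_cpp(v, config$min_width)
  if (st$T <= 0) {
    st$p <- 1
    return(st)
  }
  tstar <- perm_max_arc_cpp(v, config$min_width, config$n_permutations)
  st$p <- (1 + sum(tstar >= st$T)) / (config$n_permutations + 1)
  st
}

# Recursive splitter on a window of clone means. Returns a list of
# c(lo, hi) index pairs (absolute within the chromosome's sequence).
# With use_ranks the window is tested on both the within-window-rank
# scale and the original scale, each at alpha/2 (Bonferroni); ranks
# give robustness to heavy-tailed noise for broad changes, while the
# original scale retains the magnitude information that rank
# compression discards, without which short high-level amplicons
# (a few clones on a long chromosome) are undetectable.
split_window <- function(means, lo, hi, config) {
  n <- hi - lo + 1
  mw <- config$min_width
  if (n < 2 * mw) return(list(c(lo, hi)))
  v <- means[lo:hi]
  if (config$use_ranks) {
    st_rank <- test_arc(rank(v), config)  # average ranks on ties
    st_orig <- test_arc(v, config)
    st <- if (st_rank$p <= st_orig$p) st_rank else st_orig
    if (st$p > config$alpha / 2) return(list(c(lo, hi)))
  } else {
    st <- test_arc(v, config)
    if (st$p > config$alpha) return(list(c(lo, hi)))
  }
  # relative piece bounds from the arc [i..j]; a flank shorter than
  # min_width at the window edge is absorbed into the arc (the true
  # boundary then sits at the window edge)
  i <- st$i
  j <- st$j
  if (i > 1 && i - 1 < mw) i <- 1
  if (j < n && n - j < mw) j <- n
  if (i == 1 && j == n) return(list(c(lo, hi)))  # degenerated to no split
  rel <- list()
  if (i > 1) rel <- c(rel, list(c(1, i - 1)))
  rel <- c(rel, list(c(i, j)))
  if (j < n) rel <- c(rel, list(c(j + 1, n)))
  out <- list()
  for (r in rel) {
    out <- c(out, split_window(means, lo + r[1] - 1, lo + r[2] - 1, config))
  }
  out
}

# Fuse adjacent index ranges whose segment means differ by < merge_tol,
# always merging the closest pair first.
merge_ranges <- function(means, ranges, merge_tol) {
  seg_mean <- function(r) mean(means[r[1]:r[2]])
  repeat {
    if (length(ranges) < 2) break
    mu <- vapply(ranges, seg_mean, 0)
    d <- abs(diff(mu))
    k <- which.min(d)
    if (d[k] >= merge_tol) break
    ranges[[k]] <- c(ranges[[k]][1], ranges[[k + 1]][2])
    ranges[[k + 1]] <- NULL
  }
  ranges
}

#' Segment one chromosome's ordered clone means
#'
#' Recursive circular binary segmentation: the current window is tested
#' with [max_arc_statistic()] and [permutation_pvalue()] (on the
#' within-window-rank and original scales when `use_ranks`, each at
#' `alpha/2`; on the original scale at `alpha` otherwise); if the test
#' is significant and all resulting pieces respect `min_width`, the
#' window splits at the arc boundaries and each piece is re-examined.
#' Adjacent segments with mean difference below `merge_tol` are fused
#' afterwards. Segment means are always computed from the original,
#' unranked clone means. A window shorter than `2 * min_width` is
#' returned as a single segment.
#'
#' @param clones `data.frame` of one chromosome's QC-passing clones in
#'   genome order, with columns `chrom`, `start`, `end`, `mean_log2`.
#' @param config A [segmentation_config()]. If `config$seed` is set the
#'   RNG is seeded once on entry.
#' @return `data.frame` with one row per segment: `chrom`,
#'   `start_index`, `end_index` (positions within the chromosome's
#'   QC-passing clone sequence), `start_bp`, `end_bp`, `n_clones`,
#'   `mean_log2`.
#' @export
segment_chromosome <- function(clones, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  if (nrow(clones) == 0) {
    return(data.frame(chrom = character(), start_index = integer(),
                      end_index = integer(), start_bp = numeric(),
                      end_bp = numeric(), n_clones = integer(),
                      mean_log2 = numeric(), stringsAsFactors = FALSE))
  }
  stopifnot(length(unique(clones$chrom)) == 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  means <- clones$mean_log2
  ranges <- split_window(means, 1, nrow(clones), config)
  ranges <- merge_ranges(means, ranges, config$merge_tol)
  data.frame(
    chrom = as.character(clones$chrom[1]),
    start_index = vapply(ranges, `[`, 0, 1),
    end_index = vapply(ranges, `[`, 0, 2),
    start_bp = clones$start[vapply(ranges, `[`, 0, 1)],
    end_bp = clones$end[vapply(ranges, `[`, 0, 2)],
    n_clones = vapply(ranges, function(r) r[2] - r[1] + 1, 0),
    mean_log2 = vapply(ranges, function(r) mean(means[r[1]:r[2]]), 0),
    stringsAsFactors = FALSE
  )
}

#' Segment a whole profile
#'
#' Runs [segment_chromosome()] over each chromosome of a QC-filtered,
#' Y-free profile (QC-failed clones are skipped) and concatenates the
#' results in genome order. The per-chromosome segments jointly cover
#' every QC-passing clone exactly once.
#'
#' @param profile An `acgh_profile`, QC-filtered and Y-dropped.
#' @param config A [segmentation_config()]. If `config$seed` is set the
#'   RNG is seeded once before the first chromosome, so the whole
#'   segmentation is reproducible.
#' @return Segment `data.frame` as in [segment_chromosome()].
#' @export
segment_profile <- function(profile, config = segmentation_config()) {
  stopifnot(inherits(profile, "acgh_profile"))
  if (any(profile$clones$chrom == "Y")) {
    stop("profile still contains chromosome Y clones; call drop_chromosome()")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL  # chromosomes consume one seeded RNG stream
  cl <- profile$clones[profile$clones$qc_pass, ]
  parts <- lapply(split(cl, chrom_rank(cl$chrom)), segment_chromosome,
                  config = cfg)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
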