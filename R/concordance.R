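#' Spatially informed clone weights
#'
#' Weights for the weighted Pearson concordance between two profiles:
#' an unweighted correlation over clone log2 ratios is dominated by the
#' sheer number of near-normal clones, so each clone pair is weighted by
#' its own and its right neighbor's deviation from "normal" (the sample
#' median). For `i = 1..n-1`,
#' `w_i = 1/2 * (median_{j in {i, i+1}} |x_j - x_ref| +
#'              median_{j in {i, i+1}} |y_j - y_ref|)`,
#' where `x_ref`, `y_ref` are the medians over all `n` clones and the
#' median of two values is their midpoint. Clone `n` carries no weight
#' of its own; the weighted sums downstream run over observations
#' `1..n-1`.
#'
#' @param x,y Equal-length numeric vectors of clone log2 ratios,
#'   `n >= 3`.
#' @return Non-negative numeric vector of length `n - 1`.
#' @export
clone_weights <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  dx <- abs(x - median(x))
  dy <- abs(y - median(y))
  0.5 * ((dx[-n] + dx[-1]) / 2 + (dy[-n] + dy[-1]) / 2)
}

#' Weighted Pearson concordance between two profiles' log2 ratios
#'
#' Computes `r_w = cov(x, y; w) / sqrt(cov(x, x; w) * cov(y, y; w))`
#' over observations `1..n-1` with the [clone_weights()] vector, where
#' `cov(a, b; w) = sum(w * (a - a_w) * (b - b_w)) / sum(w)` and `a_w`
#' is the weighted mean. If every weight is zero (both profiles flat at
#' their medians) or either weighted variance vanishes, the correlation
#' is undefined: `r_w` is `NA`, `weights_degenerate` is set and no
#' category is assigned.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return A list of class `concordance_result` with fields `r_w`,
#'   `category`, `n_clones`, `weights_degenerate`.
#' @export
weighted_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  w <- clone_weights(x, y)
  n <- length(x)
  xs <- x[-n]
  ys <- y[-n]
  sw <- sum(w)
  degenerate <- TRUE
  r_w <- NA_real_
  if (sw > 0) {
    xbar <- sum(w * xs) / sw
    ybar <- sum(w * ys) / sw
    vxx <- sum(w * (xs - xbar)^2) / sw
    vyy <- sum(w * (ys - ybar)^2) / sw
    if (vxx > 0 && vyy > 0) {
      vxy <- sum(w * (xs - xbar) * (ys - ybar)) / sw
      r_w <- vxy / sqrt(vxx * vyy)
      r_w <- max(-1, min(1, r_w))  # clamp Cauchy-Schwarz rounding
      degenerate <- FALSE
    }
  }
  structure(list(
    r_w = r_w,
    category = if (degenerate) NA_character_ else categorize_correlation(r_w),
    n_clones = n,
    weights_degenerate = degenerate
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  if (x$weights_degenerate) {
    cat("weighted Pearson: undefined (degenerate weights), n =",
        x$n_clones, "clones\n")
  } else {
    cat(sprintf("weighted Pearson r_w = %.4f (%s), n = %d clones\n",
                x$r_w, x$category, x$n_clones))
  }
  invisible(x)
}

#' Qualitative correlation category
#'
#' Bins a correlation coefficient into the five-interval scale
#' `[0, 0.2)` uncorrelated, `[0.2, 0.4)` lowly, `[0.4, 0.6)` fairly,
#' `[0.6, 0.8)` moderately and `[0.8, 1]` highly correlated. Negative
#' coefficients fall outside that scale and are labelled
#' `"anticorrelated"`.
#'
#' @param r_w Correlation in `[-1, 1]`.
#' @return Category string.
#' @export
categorize_correlation <- function(r_w) {
  stopifnot(is.finite(r_w), r_w >= -1, r_w <= 1)
  if (r_w < 0) return("anticorrelated")
  if (r_w < 0.2) return("uncorrelated")
  if (r_w < 0.4) return("lowly")
  if (r_w < 0.6) return("fairly")
  if (r_w < 0.8) return("moderately")
  "highly"
}

#' Align two profiles on shared analyzable clones
#'
#' Keeps clones that are autosomal (concordance considers autosomal
#' clones only) and QC-passing in both samples, in genome order.
#'
#' @param a,b `acgh_profile`s from the same array design.
#' @return A list of class `aligned_pair` with fields `clone_id`, `x`,
#'   `y` (the two samples' mean log2 ratios) and `n`.
#' @export
align_profiles <- function(a, b) {
  stopifnot(inherits(a, "acgh_profile"), inherits(b, "acgh_profile"))
  ok_a <- a$clones[a$clones$qc_pass & !(a$clones$chrom %in% c("X", "Y")), ]
  ok_b <- b$clones[b$clones$qc_pass & !(b$clones$chrom %in% c("X", "Y")), ]
  shared <- intersect(ok_a$clone_id, ok_b$clone_id)
  if (length(shared) < 3) {
    stop("fewer than 3 shared autosomal QC-passing clones")
  }
  ok_a <- ok_a[ok_a$clone_id %in% shared, ]
  x <- ok_a$mean_log2
  y <- ok_b$mean_log2[match(ok_a$clone_id, ok_b$clone_id)]
  structure(list(clone_id = ok_a$clone_id, x = x, y = y,
                 n = length(shared)),
            class = "aligned_pair")
}

#' Concordance between two profiles
#'
#' Convenience wrapper: [align_profiles()] then [weighted_pearson()].
#'
#' @inheritParams align_profiles
#' @return A `concordance_result`.
#' @export
profile_concordance <- function(a, b) {
  pair <- align_profiles(a, b)
  weighted_pearson(pair$x, pair$y)
}
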