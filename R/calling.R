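#' Copy-number calling thresholds
#'
#' Log2-ratio thresholds for the five copy-number states: gains and
#' losses at +/-0.2 and high-level gains / homozygous deletions at
#' +/-0.6. With `strict = TRUE` (default) a segment mean must strictly
#' exceed a threshold to change state, so a mean of exactly 0.2 is
#' still neutral.
#'
#' @param gain_thr,loss_thr Low-level gain / loss thresholds
#'   (defaults 0.2, -0.2).
#' @param high_gain_thr,homdel_thr High-level gain / homozygous-deletion
#'   thresholds (defaults 0.6, -0.6).
#' @param strict Exclusive threshold comparison (default `TRUE`).
#' @return A list of class `calling_config`.
#' @export
calling_config <- function(gain_thr = 0.2, loss_thr = -0.2,
                           high_gain_thr = 0.6, homdel_thr = -0.6,
                           strict = TRUE) {
  stopifnot(homdel_thr < loss_thr, loss_thr < 0, gain_thr > 0,
            gain_thr < high_gain_thr)
  structure(list(gain_thr = gain_thr, loss_thr = loss_thr,
                 high_gain_thr = high_gain_thr, homdel_thr = homdel_thr,
                 strict = strict),
            class = "calling_config")
}

# Ordered state labels, loss to gain.
state_levels <- function() {
  c("HOMOZYGOUS_LOSS", "LOSS", "NEUTRAL", "GAIN", "HIGH_GAIN")
}

# Vectorized threshold decision on adjusted means.
threshold_state <- function(adjusted, config) {
  gt <- if (config$strict) `>` else `>=`
  lt <- if (config$strict) `<` else `<=`
  ifelse(gt(adjusted, config$high_gain_thr), "HIGH_GAIN",
  ifelse(gt(adjusted, config$gain_thr), "GAIN",
  ifelse(lt(adjusted, config$homdel_thr), "HOMOZYGOUS_LOSS",
  ifelse(lt(adjusted, config$loss_thr), "LOSS", "NEUTRAL"))))
}

#' Copy-number-neutral X-chromosome baseline
#'
#' The expected log2 ratio of a copy-number-neutral clone on chromosome
#' X given the test and reference sexes: `log2(test X copies /
#' reference X copies)`, i.e. -1 for a male test against a female
#' reference (1 versus 2 copies of X), +1 for the converse, and 0 for
#' matched sexes.
#'
#' @param test_sex,reference_sex `"male"` or `"female"`.
#' @return The baseline log2 ratio.
#' @export
x_baseline <- function(test_sex = c("male", "female"),
                       reference_sex = c("female", "male")) {
  test_sex <- match.arg(test_sex)
  reference_sex <- match.arg(reference_sex)
  log2(germline_copies("X", test_sex) / germline_copies("X", reference_sex))
}

#' Call copy-number states on segments
#'
#' Subtracts the X-chromosome baseline from segment means on X (the
#' equivalent of shifting all four thresholds by the baseline, so a
#' sex-mismatched hybridization does not report the whole X as lost)
#' and thresholds the adjusted means into the five states.
#'
#' @param segments Segment table from [segment_profile()]; must be free
#'   of chromosome Y.
#' @param config A [calling_config()].
#' @param test_sex,reference_sex Sexes of the hybridized samples.
#' @param adjust_x Apply the X baseline adjustment (default `TRUE`;
#'   `FALSE` reproduces the naive analysis in which a male-vs-female
#'   hybridization shows a loss across the whole X).
#' @return The segment table with columns `adjusted_mean` and `state`
#'   appended.
#' @export
call_segments <- function(segments, config = calling_config(),
                          test_sex = c("male", "female"),
                          reference_sex = c("female", "male"),
                          adjust_x = TRUE) {
  test_sex <- match.arg(test_sex)
  reference_sex <- match.arg(reference_sex)
  stopifnot(inherits(config, "calling_config"))
  if (any(segments$chrom == "Y")) {
    stop("chromosome Y segments are not callable; drop Y upstream")
  }
  base <- if (adjust_x) x_baseline(test_sex, reference_sex) else 0
  calls <- segments
  calls$adjusted_mean <- ifelse(calls$chrom == "X",
                                calls$mean_log2 - base, calls$mean_log2)
  calls$state <- threshold_state(calls$adjusted_mean, config)
  calls
}

#' Define a genomic locus query
#'
#' @param name Locus label (e.g. `"AR"`).
#' @param chrom Chromosome label.
#' @param start,end Interval in bp (1-based inclusive).
#' @return A list of class `locus_query`.
#' @export
locus_query <- function(name, chrom, start, end) {
  stopifnot(start >= 1, start <= end)
  chrom_rank(chrom)
  structure(list(name = name, chrom = as.character(chrom),
                 start = start, end = end),
            class = "locus_query")
}

#' The androgen receptor (AR) locus on Xq
#'
#' Convenience query for the AR gene region, whose amplification is
#' associated with castration-resistant prostate cancer.
#'
#' @return A [locus_query()] for X:66,700,000-66,950,000.
#' @export
ar_locus <- function() {
  locus_query("AR", "X", 66700000, 66950000)
}

#' Copy-number state at a locus
#'
#' Returns the state of the call overlapping the query interval. When
#' the query spans several segments the most extreme state wins
#' (HIGH_GAIN / HOMOZYGOUS_LOSS over GAIN / LOSS over NEUTRAL), with the
#' larger `|adjusted_mean|` breaking a gain-versus-loss tie.
#'
#' @param calls Call table from [call_segments()].
#' @param query A [locus_query()].
#' @return A single state string.
#' @export
call_locus <- function(calls, query) {
  stopifnot(inherits(query, "locus_query"))
  hit <- calls$chrom == query$chrom &
    calls$start_bp <= query$end & calls$end_bp >= query$start
  if (!any(hit)) {
    stop("no segment covers locus ", query$name, " (", query$chrom, ":",
         query$start, "-", query$end, ")")
  }
  cand <- calls[hit, ]
  if (nrow(cand) == 1) return(cand$state)
  extremity <- c(NEUTRAL = 0, GAIN = 1, LOSS = 1,
                 HIGH_GAIN = 2, HOMOZYGOUS_LOSS = 2)
  score <- extremity[cand$state]
  top <- cand[score == max(score), ]
  top$state[which.max(abs(top$adjusted_mean))]
}
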