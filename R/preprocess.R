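#' Summarize replicate spots into a per-clone profile
#'
#' Computes the mean and sample standard deviation (n - 1 denominator) of
#' the log2 ratios over each clone's replicate spots, yielding one summary
#' row per clone in genome order. A clone with a single spot gets SD 0.
#'
#' @param spots Spot table with columns `clone_id`, `replicate`,
#'   `log2_ratio` (e.g. from [simulate_spot_table()]).
#' @param design The `array_design` the spots were measured on; every
#'   design clone must have at least one spot.
#' @param sample_id Label stored on the profile.
#' @param test_sex,reference_sex Sexes of the hybridized samples,
#'   needed downstream for the X-chromosome baseline.
#' @return A list of class `acgh_profile` with elements `sample_id`,
#'   `test_sex`, `reference_sex` and `clones`, a `data.frame` with
#'   columns `clone_id`, `chrom`, `start`, `end`, `mean_log2`, `sd_log2`,
#'   `n_spots`, `qc_pass` (initially all `TRUE`; see [qc_filter()]).
#' @export
summarize_replicates <- function(spots, design, sample_id = "sample",
                                 test_sex = c("male", "female"),
                                 reference_sex = c("female", "male")) {
  test_sex <- match.arg(test_sex)
  reference_sex <- match.arg(reference_sex)
  check_design(design)
  stopifnot(all(c("clone_id", "log2_ratio") %in% names(spots)))
  if (!all(is.finite(spots$log2_ratio))) {
    stop("non-finite log2 ratios in spot table")
  }
  unknown <- setdiff(unique(spots$clone_id), design$clone_id)
  if (length(unknown)) {
    stop("spot table contains clone ids absent from the design: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  f <- factor(spots$clone_id, levels = design$clone_id)
  n_spots <- as.integer(tabulate(f, nbins = nrow(design)))
  if (any(n_spots == 0)) {
    stop("no spots for clone(s): ",
         paste(utils::head(design$clone_id[n_spots == 0], 3), collapse = ", "))
  }
  mean_log2 <- as.numeric(tapply(spots$log2_ratio, f, mean))
  sd_log2 <- as.numeric(tapply(spots$log2_ratio, f, stats::sd))
  sd_log2[n_spots == 1] <- 0
  clones <- data.frame(
    clone_id = design$clone_id,
    chrom = as.character(design$chrom),
    start = design$start,
    end = design$end,
    mean_log2 = mean_log2,
    sd_log2 = sd_log2,
    n_spots = n_spots,
    qc_pass = TRUE,
    stringsAsFactors = FALSE
  )
  new_profile(sample_id, test_sex, reference_sex, clones)
}

new_profile <- function(sample_id, test_sex, reference_sex, clones) {
  o <- order(chrom_rank(clones$chrom), clones$start)
  clones <- clones[o, ]
  rownames(clones) <- NULL
  structure(list(sample_id = sample_id, test_sex = test_sex,
                 reference_sex = reference_sex, clones = clones),
            class = "acgh_profile")
}

#' @export
print.acgh_profile <- function(x, ...) {
  cat("aCGH profile '", x$sample_id, "': ", nrow(x$clones), " clones (",
      sum(x$clones$qc_pass), " QC-passing), test ", x$test_sex,
      " vs reference ", x$reference_sex, "\n", sep = "")
  invisible(x)
}

#' Flag clones whose replicate-spot SD exceeds the QC threshold
#'
#' Clones with a replicate-spot standard deviation strictly greater than
#' `sd_max` are flagged as QC failures (`qc_pass = FALSE`); an SD equal
#' to the threshold is retained. Failed clones are flagged, not removed,
#' so that later stages can intersect QC-passing clones across samples.
#' The operation is idempotent.
#'
#' @param profile An `acgh_profile`.
#' @param sd_max Maximum tolerated replicate SD (default 0.2).
#' @return The profile with `qc_pass` recomputed.
#' @export
qc_filter <- function(profile, sd_max = 0.2) {
  stopifnot(inherits(profile, "acgh_profile"), sd_max >= 0)
  profile$clones$qc_pass <- !(profile$clones$sd_log2 > sd_max)
  if (!any(profile$clones$qc_pass)) {
    stop("all clones fail QC at sd_max = ", sd_max)
  }
  profile
}

#' Drop all clones on a chromosome
#'
#' Removes every clone of the named chromosome (default Y, which is not
#' analyzable in a male-versus-female hybridization). A no-op if the
#' chromosome is absent; clone order is preserved.
#'
#' @param profile An `acgh_profile`.
#' @param chrom Chromosome label to drop (default `"Y"`).
#' @return The filtered profile.
#' @export
drop_chromosome <- function(profile, chrom = "Y") {
  stopifnot(inherits(profile, "acgh_profile"))
  keep <- profile$clones$chrom != chrom
  profile$clones <- profile$clones[keep, ]
  rownames(profile$clones) <- NULL
  profile
}
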