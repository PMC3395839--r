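#' Measurement-noise parameters for the spot simulator
#'
#' The measurement model adds, to each clone's expected log2 ratio, a
#' clone-level Gaussian offset shared by its replicate spots (printing /
#' hybridization variation), independent per-spot Gaussian noise, and an
#' occasional additive outlier meant to exercise the SD-based replicate
#' QC filter. `floor_copies` emulates the array's dynamic-range floor so
#' that homozygous deletions in a pure sample do not produce `-Inf`.
#'
#' @param sigma_clone SD of the per-clone offset (log2 units, default 0.08).
#' @param sigma_spot SD of the per-spot noise (default 0.05).
#' @param outlier_prob Probability a spot receives an outlier deviation
#'   (default 0.01).
#' @param outlier_sigma SD of the additive outlier deviation (default 0.6).
#' @param floor_copies Copy number used in place of 0 (default 0.05).
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(sigma_clone = 0.08, sigma_spot = 0.05,
                         outlier_prob = 0.01, outlier_sigma = 0.6,
                         floor_copies = 0.05) {
  stopifnot(sigma_clone >= 0, sigma_spot >= 0, outlier_sigma >= 0,
            outlier_prob >= 0, outlier_prob <= 1, floor_copies > 0)
  structure(list(sigma_clone = sigma_clone, sigma_spot = sigma_spot,
                 outlier_prob = outlier_prob, outlier_sigma = outlier_sigma,
                 floor_copies = floor_copies),
            class = "noise_params")
}

#' Ground-truth copy-number profile
#'
#' Describes the cell population hybridized as the test sample: its sex,
#' the reference sex, a list of integer-copy-number aberrations, and the
#' tumor fraction of the sorted cell pool. Copy number outside any
#' aberration defaults to 2 on autosomes and, for a male test sample, 1
#' on X and Y. Admixed normal (leukocyte) DNA at fraction
#' `1 - tumor_fraction` carries the sex-appropriate germline copy number,
#' which attenuates observed log2 ratios toward 0.
#'
#' @param test_sex,reference_sex `"male"` or `"female"`.
#' @param aberrations `data.frame` with columns `chrom`, `start`, `end`
#'   (bp, 1-based inclusive) and `copies` (non-negative integer tumor
#'   copy number); may have zero rows. Intervals must lie within the
#'   chromosome and must not overlap each other on a chromosome.
#' @param tumor_fraction Fraction of test DNA derived from tumor cells,
#'   in `[0, 1]` (default 1).
#' @return A list of class `truth_profile`.
#' @export
truth_profile <- function(test_sex = c("male", "female"),
                          reference_sex = c("female", "male"),
                          aberrations = NULL,
                          tumor_fraction = 1) {
  test_sex <- match.arg(test_sex)
  reference_sex <- match.arg(reference_sex)
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1)
  if (is.null(aberrations)) {
    aberrations <- data.frame(chrom = character(), start = numeric(),
                              end = numeric(), copies = numeric(),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end", "copies") %in% names(aberrations)))
  if (nrow(aberrations)) {
    aberrations$chrom <- as.character(aberrations$chrom)
    r <- chrom_rank(aberrations$chrom)
    lens <- .chrom_lengths[aberrations$chrom]
    if (any(aberrations$start < 1) || any(aberrations$end > lens) ||
        any(aberrations$start > aberrations$end)) {
      stop("aberration interval outside chromosome bounds")
    }
    if (any(aberrations$copies < 0) ||
        any(aberrations$copies != round(aberrations$copies))) {
      stop("tumor copy numbers must be non-negative integers")
    }
    o <- order(r, aberrations$start)
    ab <- aberrations[o, ]
    same <- ab$chrom[-1] == ab$chrom[-nrow(ab)]
    if (nrow(ab) > 1 && any(same & ab$start[-1] <= ab$end[-nrow(ab)])) {
      stop("aberrations overlap within a chromosome")
    }
    aberrations <- ab
    rownames(aberrations) <- NULL
  }
  structure(list(test_sex = test_sex, reference_sex = reference_sex,
                 aberrations = aberrations, tumor_fraction = tumor_fraction),
            class = "truth_profile")
}

# Germline copy number of a chromosome for a given sex.
germline_copies <- function(chrom, sex) {
  out <- rep(2, length(chrom))
  if (sex == "male") {
    out[chrom %in% c("X", "Y")] <- 1
  } else {
    out[chrom == "Y"] <- 0
  }
  out
}

#' Preset ground-truth profiles
#'
#' Fixed, documented truth profiles emulating samples of the kind the
#' pipeline targets: prostate cancer cell lines with well-characterized
#' aberrations (8p loss, 8q gain, focal AR-region amplification on X for
#' VCaP; PTEN-region homozygous deletion for PC3), a patient-like CTC
#' profile with an 11q13 focal amplification and AR-region high-level
#' gain, and an aberration-free male leukocyte control. All presets are
#' male test versus female reference.
#'
#' @param name One of `"vcap_like"`, `"pc3_like"`, `"lncap_like"`,
#'   `"patient9_like"`, `"normal_male_leukocyte"`.
#' @param tumor_fraction Tumor fraction of the sorted pool (default 1).
#' @return A [truth_profile()].
#' @export
preset_truth <- function(name, tumor_fraction = 1) {
  ab <- function(chrom, start, end, copies) {
    data.frame(chrom = chrom, start = start, end = end, copies = copies,
               stringsAsFactors = FALSE)
  }
  ar_amp <- ab("X", 64500000, 69500000, 8)
  aberrations <- switch(
    name,
    vcap_like = rbind(
      ab("8", 1, 43000000, 1),
      ab("8", 48000000, 146364022, 4),
      ar_amp
    ),
    pc3_like = rbind(
      ab("8", 1, 43000000, 1),
      ab("8", 48000000, 146364022, 4),
      ab("10", 85000000, 95000000, 0),
      ab("13", 45000000, 72000000, 1)
    ),
    lncap_like = rbind(
      ab("6", 75000000, 171115067, 1),
      ab("10", 87000000, 92000000, 0),
      ab("13", 40000000, 80000000, 1)
    ),
    patient9_like = rbind(
      ab("8", 1, 43000000, 1),
      ab("8", 48000000, 146364022, 4),
      ab("11", 66000000, 71000000, 8),
      ar_amp
    ),
    normal_male_leukocyte = NULL,
    stop("unknown preset name: ", name)
  )
  truth_profile("male", "female", aberrations, tumor_fraction)
}

#' Expected log2 ratio under the purity-mixture model
#'
#' For each clone the test-channel copy number is a mixture of tumor and
#' contaminating normal cells,
#' `mix = (1 - f) * g + f * c`, where `f` is the tumor fraction, `g` the
#' normal-cell germline copy number at the clone and `c` the tumor copy
#' number (germline background unless an aberration covers the clone
#' midpoint). The expected ratio is
#' `log2(max(mix, floor) / max(r, floor))` against the reference copy
#' number `r`. On chromosome X a male-versus-female hybridization thus
#' has baseline `log2(1/2) = -1` even without any aberration.
#'
#' @param design An `array_design` (any subset of rows).
#' @param truth A [truth_profile()].
#' @param noise A [noise_params()]; only `floor_copies` is used.
#' @return Numeric vector of expected log2 ratios, one per design row.
#' @export
expected_log2 <- function(design, truth, noise = noise_params()) {
  check_design(design)
  stopifnot(inherits(truth, "truth_profile"))
  chrom <- as.character(design$chrom)
  if (truth$test_sex == "female" && any(chrom == "Y")) {
    stop("Y clones are not defined for a female test sample")
  }
  f <- truth$tumor_fraction
  g <- germline_copies(chrom, truth$test_sex)
  r <- germline_copies(chrom, truth$reference_sex)
  cn <- g  # tumor background equals the test sample's germline
  if (nrow(truth$aberrations)) {
    mid <- (design$start + design$end) / 2
    for (a in seq_len(nrow(truth$aberrations))) {
      hit <- chrom == truth$aberrations$chrom[a] &
        mid >= truth$aberrations$start[a] & mid <= truth$aberrations$end[a]
      cn[hit] <- truth$aberrations$copies[a]
    }
  }
  mix <- (1 - f) * g + f * cn
  log2(pmax(mix, noise$floor_copies) / pmax(r, noise$floor_copies))
}

#' Simulate a spot-level log2-ratio table
#'
#' Draws, for each clone, a shared offset `N(0, sigma_clone^2)`, then for
#' each replicate spot adds `N(0, sigma_spot^2)` noise; each spot is
#' independently hit with probability `outlier_prob` by an additional
#' `N(0, outlier_sigma^2)` outlier deviation. Reproducible under a fixed
#' seed.
#'
#' @param design An `array_design`.
#' @param truth A [truth_profile()].
#' @param noise A [noise_params()].
#' @param seed Integer seed for the random draws (optional).
#' @return A `data.frame` with columns `clone_id`, `replicate`,
#'   `log2_ratio`, one row per spot, in design order.
#' @export
simulate_spot_table <- function(design, truth, noise = noise_params(),
                                seed = NULL) {
  check_design(design)
  if (!is.null(seed)) set.seed(seed)
  mu <- expected_log2(design, truth, noise)
  nrep <- if ("replicates" %in% names(design)) {
    as.integer(design$replicates)
  } else {
    rep(3L, nrow(design))
  }
  stopifnot(all(nrep >= 1))
  offsets <- rnorm(nrow(design), 0, noise$sigma_clone)
  n_spots <- sum(nrep)
  idx <- rep(seq_len(nrow(design)), nrep)
  value <- mu[idx] + offsets[idx] + rnorm(n_spots, 0, noise$sigma_spot)
  hit <- runif(n_spots) < noise$outlier_prob
  if (any(hit)) {
    value[hit] <- value[hit] + rnorm(sum(hit), 0, noise$outlier_sigma)
  }
  data.frame(
    clone_id = design$clone_id[idx],
    replicate = sequence(nrep),
    log2_ratio = value,
    stringsAsFactors = FALSE
  )
}

#' Noiseless per-clone truth states
#'
#' Evaluates the expected log2 ratio of every clone under `truth`,
#' applies the X baseline adjustment implied by the truth's sexes, and
#' thresholds with `config`. This is the simulation ground truth that a
#' correct summarize/segment/call pipeline should reproduce.
#'
#' @inheritParams expected_log2
#' @param config A [calling_config()].
#' @return `data.frame` with columns `clone_id`, `chrom`, `start`, `end`,
#'   `expected_log2`, `adjusted`, `state`.
#' @export
truth_clone_states <- function(design, truth, config = calling_config(),
                               noise = noise_params()) {
  mu <- expected_log2(design, truth, noise)
  base <- x_baseline(truth$test_sex, truth$reference_sex)
  adjusted <- ifelse(as.character(design$chrom) == "X", mu - base, mu)
  data.frame(
    clone_id = design$clone_id,
    chrom = as.character(design$chrom),
    start = design$start,
    end = design$end,
    expected_log2 = mu,
    adjusted = adjusted,
    state = threshold_state(adjusted, config),
    stringsAsFactors = FALSE
  )
}

#' True within-chromosome breakpoints at clone resolution
#'
#' Positions where the noiseless truth state changes between adjacent
#' clones of a chromosome. Breakpoints are reported as the index (within
#' that chromosome's clone sequence, Y excluded) of the last clone of the
#' left-hand state.
#'
#' @inheritParams truth_clone_states
#' @return `data.frame` with columns `chrom`, `after_index`.
#' @export
truth_breakpoints <- function(design, truth, config = calling_config(),
                              noise = noise_params()) {
  st <- truth_clone_states(design, truth, config, noise)
  st <- st[st$chrom != "Y", ]
  out <- lapply(split(st, chrom_rank(st$chrom)), function(d) {
    n <- nrow(d)
    if (n < 2) return(NULL)
    chg <- which(d$state[-n] != d$state[-1])
    if (!length(chg)) return(NULL)
    data.frame(chrom = d$chrom[1], after_index = chg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), after_index = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
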