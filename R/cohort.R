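#' Build a sample-by-clone state matrix for a cohort
#'
#' Each clone inherits the state of the call segment covering its
#' midpoint in each sample. Clones with no covering segment are marked
#' missing (`NA`), as are clones listed as QC failures for a sample via
#' `qc` -- segments span the genomic gaps left by interior QC-failed
#' clones, so the QC record is needed to mark those clones missing
#' rather than silently inheriting a neighbor's state.
#'
#' @param call_sets Named list (names are sample ids) of call tables
#'   from [call_segments()].
#' @param design The shared `array_design`.
#' @param qc Optional named list mapping sample ids to character vectors
#'   of QC-passing clone ids; clones absent from a sample's vector are
#'   marked missing for that sample.
#' @return A list of class `cohort_matrix` with elements `samples`,
#'   `design` (Y clones removed) and `states`, a samples-by-clones
#'   character matrix.
#' @export
build_cohort <- function(call_sets, design, qc = NULL) {
  stopifnot(length(call_sets) >= 1)
  ids <- names(call_sets)
  if (is.null(ids) || any(ids == "")) stop("call_sets must be a named list")
  if (anyDuplicated(ids)) stop("duplicate sample ids in call_sets")
  check_design(design)
  design <- design[design$chrom != "Y", ]
  mid <- (design$start + design$end) / 2
  states <- matrix(NA_character_, nrow = length(ids), ncol = nrow(design),
                   dimnames = list(ids, design$clone_id))
  for (s in ids) {
    calls <- call_sets[[s]]
    for (k in seq_len(nrow(calls))) {
      hit <- design$chrom == calls$chrom[k] &
        mid >= calls$start_bp[k] & mid <= calls$end_bp[k]
      states[s, hit] <- calls$state[k]
    }
    if (!is.null(qc) && !is.null(qc[[s]])) {
      states[s, !(design$clone_id %in% qc[[s]])] <- NA_character_
    }
  }
  structure(list(samples = ids, design = design, states = states),
            class = "cohort_matrix")
}

#' Per-clone gain and loss frequencies across a cohort
#'
#' For every clone, the fraction of non-missing samples whose state is a
#' gain (`GAIN`, `HIGH_GAIN`) or a loss (`LOSS`, `HOMOZYGOUS_LOSS`).
#' Clones missing in every sample are excluded from the track.
#'
#' @param cohort A `cohort_matrix` from [build_cohort()].
#' @return `data.frame` with columns `clone_id`, `chrom`, `start`,
#'   `end`, `gain_freq`, `loss_freq`, `n_informative`.
#' @export
aberration_frequency <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  st <- cohort$states
  n_inf <- colSums(!is.na(st))
  gain <- colSums(st == "GAIN" | st == "HIGH_GAIN", na.rm = TRUE)
  loss <- colSums(st == "LOSS" | st == "HOMOZYGOUS_LOSS", na.rm = TRUE)
  keep <- n_inf > 0
  data.frame(
    clone_id = cohort$design$clone_id[keep],
    chrom = as.character(cohort$design$chrom[keep]),
    start = cohort$design$start[keep],
    end = cohort$design$end[keep],
    gain_freq = gain[keep] / n_inf[keep],
    loss_freq = loss[keep] / n_inf[keep],
    n_informative = n_inf[keep],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Recurrent gain / loss regions
#'
#' Maximal runs of consecutive clones whose gain (or loss) frequency
#' strictly exceeds `threshold` are reported as regions, one direction
#' at a time; region bounds are the first and last member clone's
#' genomic bounds. With the default threshold, an aberration present in
#' 5 of 9 samples (55.6%) is recurrent while one present in exactly half
#' is not.
#'
#' @param track Frequency track from [aberration_frequency()].
#' @param threshold Strict recurrence threshold in `[0, 1)`
#'   (default 0.5).
#' @return `data.frame` with columns `chrom`, `start_bp`, `end_bp`,
#'   `n_clones`, `direction` (`"gain"` or `"loss"`).
#' @export
recurrent_regions <- function(track, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold < 1)
  one_direction <- function(freq, direction) {
    hot <- freq > threshold
    parts <- lapply(split(seq_len(nrow(track)), chrom_rank(track$chrom)),
                    function(idx) {
      r <- rle(hot[idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- which(r$values)
      if (!length(runs)) return(NULL)
      data.frame(
        chrom = track$chrom[idx[1]],
        start_bp = track$start[idx[starts[runs]]],
        end_bp = track$end[idx[ends[runs]]],
        n_clones = r$lengths[runs],
        direction = direction,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, parts)
  }
  out <- rbind(one_direction(track$gain_freq, "gain"),
               one_direction(track$loss_freq, "loss"))
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_clones = integer(),
                      direction = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(chrom_rank(out$chrom), out$start_bp, out$direction), ]
  rownames(out) <- NULL
  out
}
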