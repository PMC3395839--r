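# Tab-separated readers/writers for the pipeline's tabular formats.
# Log2 ratios are written at a fixed 6 decimal places so that a
# write/read round trip reproduces values at the printed precision.

fmt6 <- function(x) sprintf("%.6f", x)

#' Write / read an array design TSV
#'
#' Columns `clone_id`, `chrom`, `start`, `end` (1-based inclusive bp),
#' tab-separated with a header row.
#'
#' @param design An `array_design`.
#' @param path File path.
#' @return `write_design_tsv` returns `path` invisibly;
#'   `read_design_tsv` returns an `array_design`.
#' @export
write_design_tsv <- function(design, path) {
  check_design(design)
  write.table(design[, c("clone_id", "chrom", "start", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @param replicates Replicate spot count attached on read (default 3).
#' @export
read_design_tsv <- function(path, replicates = 3L) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  check_design(d)
  d$replicates <- as.integer(replicates)
  class(d) <- c("array_design", "data.frame")
  d
}

#' Write / read a spot-level log2-ratio TSV
#'
#' Columns `clone_id`, `replicate`, `log2_ratio`.
#'
#' @param spots Spot table.
#' @param path File path.
#' @export
write_spot_tsv <- function(spots, path) {
  out <- data.frame(clone_id = spots$clone_id, replicate = spots$replicate,
                    log2_ratio = fmt6(spots$log2_ratio))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_tsv
#' @export
read_spot_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a per-clone profile TSV
#'
#' An "sproc-like" table: one row per clone with columns `clone_id`,
#' `chrom`, `start`, `end`, `mean_log2`, `sd_log2`, `n_spots`, `qc_pass`.
#' Sample metadata (id and sexes) is stored in `#`-prefixed header lines.
#'
#' @param profile An `acgh_profile`.
#' @param path File path.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "acgh_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sample_id=", profile$sample_id),
    paste0("# test_sex=", profile$test_sex),
    paste0("# reference_sex=", profile$reference_sex)
  ), con)
  cl <- profile$clones
  out <- data.frame(clone_id = cl$clone_id, chrom = cl$chrom,
                    start = cl$start, end = cl$end,
                    mean_log2 = fmt6(cl$mean_log2),
                    sd_log2 = fmt6(cl$sd_log2),
                    n_spots = cl$n_spots, qc_pass = cl$qc_pass)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list(sample_id = "sample", test_sex = "male",
               reference_sex = "female")
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] %in% names(meta)) meta[[kv[1]]] <- kv[2]
  }
  cl <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  cl$qc_pass <- as.logical(cl$qc_pass)
  new_profile(meta$sample_id, meta$test_sex, meta$reference_sex, cl)
}

#' Write / read segments as BED-compatible TSV
#'
#' Columns `chrom`, `start`, `end`, `n_clones`, `mean_log2`; the first
#' three are 0-based half-open on disk (BED convention) and converted
#' back to the package's 1-based inclusive `start_bp`/`end_bp` on read.
#' The header row is `#`-prefixed so the file remains BED-consumable.
#'
#' @param segments Segment table from [segment_profile()].
#' @param path File path.
#' @export
write_segments_bed <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tn_clones\tmean_log2", con)
  out <- data.frame(segments$chrom, segments$start_bp - 1, segments$end_bp,
                    segments$n_clones, fmt6(segments$mean_log2))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
read_segments_bed <- function(path) {
  d <- read.delim(path, comment.char = "#", header = FALSE,
                  stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "n_clones",
                                "mean_log2"),
                  colClasses = c(chrom = "character"))
  data.frame(chrom = d$chrom, start_bp = d$start + 1, end_bp = d$end,
             n_clones = d$n_clones, mean_log2 = d$mean_log2,
             stringsAsFactors = FALSE)
}

#' Write copy-number calls as BED
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `state`,
#' `adjusted_mean`, `n_clones`.
#'
#' @param calls Call table from [call_segments()].
#' @param path File path.
#' @export
write_calls_bed <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tstate\tadjusted_mean\tn_clones", con)
  out <- data.frame(calls$chrom, calls$start_bp - 1, calls$end_bp,
                    calls$state, fmt6(calls$adjusted_mean), calls$n_clones)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a cohort frequency track / recurrent regions
#'
#' @param track Frequency track from [aberration_frequency()].
#' @param regions Region table from [recurrent_regions()].
#' @param path File path.
#' @export
write_frequency_tsv <- function(track, path) {
  out <- track
  out$gain_freq <- fmt6(out$gain_freq)
  out$loss_freq <- fmt6(out$loss_freq)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_tsv
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tn_clones\tdirection", con)
  if (nrow(regions)) {
    out <- data.frame(regions$chrom, regions$start_bp - 1, regions$end_bp,
                      regions$n_clones, regions$direction)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
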