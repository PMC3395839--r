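#' @useDynLib ctcCGH, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm runif sd
#' @importFrom utils read.delim write.table
"_PACKAGE"

# Canonical chromosome ordering used throughout the package.
.chrom_levels <- c(as.character(1:22), "X", "Y")

# Approximate human chromosome lengths (bp). Only relative sizes and
# positions matter for clone placement and segmentation.
.chrom_lengths <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566
)

#' Built-in human genome model
#'
#' Returns the coordinate space used by the simulator and the analysis:
#' 22 autosomes plus X, and optionally Y. Chromosome Y is carried through
#' the simulator so that spot tables resemble real male-versus-female
#' hybridizations, but it is excluded from all downstream analysis by
#' [drop_chromosome()].
#'
#' @param include_y Include chromosome Y in the model (default `TRUE`).
#' @return A `data.frame` with columns `chrom` (character, genome order)
#'   and `length` (bp), of class `genome_model`.
#' @export
#' @examples
#' g <- make_genome_model()
#' nrow(g)  # 24
make_genome_model <- function(include_y = TRUE) {
  chroms <- .chrom_levels
  if (!include_y) chroms <- setdiff(chroms, "Y")
  g <- data.frame(
    chrom = chroms,
    length = unname(.chrom_lengths[chroms]),
    stringsAsFactors = FALSE
  )
  class(g) <- c("genome_model", "data.frame")
  g
}

# Integer rank of chromosome labels in genome order; unknown labels error.
chrom_rank <- function(chrom) {
  r <- match(as.character(chrom), .chrom_levels)
  if (anyNA(r)) {
    stop("unknown chromosome label(s): ",
         paste(unique(chrom[is.na(r)]), collapse = ", "))
  }
  r
}

#' Generate a BAC array design
#'
#' Allocates `n_clones` probes across the chromosomes of `genome`
#' proportionally to chromosome length (largest-remainder rounding, at
#' least one clone per chromosome) and places them at evenly spaced
#' midpoints. The default clone count matches a genome-wide BAC array of
#' 2,464 clones printed in triplicate.
#'
#' @param genome A `genome_model` from [make_genome_model()].
#' @param n_clones Total number of clones (default 2464).
#' @param seed Accepted for interface stability; placement is fully
#'   deterministic, so the seed has no effect.
#' @param replicates Number of printed replicate spots per clone
#'   (default 3).
#' @return A `data.frame` of class `array_design` with columns
#'   `clone_id`, `chrom`, `start`, `end`, `replicates`, sorted by
#'   (chromosome order, start).
#' @export
generate_array_design <- function(genome, n_clones = 2464, seed = NULL,
                                  replicates = 3L) {
  stopifnot(inherits(genome, "data.frame"), all(genome$length > 0))
  k <- nrow(genome)
  if (n_clones < k) {
    stop("n_clones (", n_clones, ") must be at least the chromosome count (",
         k, ")")
  }
  raw <- n_clones * genome$length / sum(genome$length)
  alloc <- floor(raw)
  deficit <- n_clones - sum(alloc)
  if (deficit > 0) {
    take <- order(raw - alloc, decreasing = TRUE)[seq_len(deficit)]
    alloc[take] <- alloc[take] + 1
  }
  # guarantee >= 1 clone per chromosome, stealing from the best-served
  while (any(alloc == 0)) {
    alloc[which.max(alloc)] <- max(alloc) - 1
    alloc[which(alloc == 0)[1]] <- 1
  }
  pieces <- lapply(seq_len(k), function(ci) {
    m <- alloc[ci]
    len <- genome$length[ci]
    spacing <- len / m
    centers <- round((seq_len(m) - 0.5) * spacing)
    half <- min(75000, floor(spacing / 2))
    start <- pmax(1, centers - half)
    end <- pmin(len, centers + half)
    data.frame(
      clone_id = sprintf("BAC_%s_%04d", genome$chrom[ci], seq_len(m)),
      chrom = genome$chrom[ci],
      start = start,
      end = end,
      stringsAsFactors = FALSE
    )
  })
  design <- do.call(rbind, pieces)
  design <- design[order(chrom_rank(design$chrom), design$start), ]
  rownames(design) <- NULL
  design$replicates <- as.integer(replicates)
  stopifnot(!anyDuplicated(design$clone_id), nrow(design) == n_clones)
  class(design) <- c("array_design", "data.frame")
  design
}

# Validate the minimal array-design contract used internally.
check_design <- function(design) {
  need <- c("clone_id", "chrom", "start", "end")
  if (!all(need %in% names(design))) {
    stop("array design must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(design$clone_id)) stop("duplicate clone ids in design")
  if (any(design$start > design$end)) stop("clone start > end in design")
  invisible(design)
}
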