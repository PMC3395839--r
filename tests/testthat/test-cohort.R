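cohort_fixture <- function(n_clones = 60) {
  g <- tiny_genome(c("1", "2"))
  design <- generate_array_design(g, n_clones = n_clones)
  list(genome = g, design = design)
}

test_that("cohort matrix assigns covering-segment states per sample", {
  fx <- cohort_fixture()
  d <- fx$design
  neutral <- data.frame(chrom = c("1", "2"),
                        start_bp = c(1, 1),
                        end_bp = c(249250621, 243199373),
                        n_clones = c(30L, 30L),
                        mean_log2 = c(0, 0),
                        state = "NEUTRAL",
                        adjusted_mean = 0,
                        stringsAsFactors = FALSE)
  cm <- build_cohort(list(a = neutral), d)
  expect_equal(dim(cm$states), c(1, nrow(d)))
  expect_true(all(cm$states == "NEUTRAL"))
  # a QC-failed clone is missing, the rest filled
  drop_id <- d$clone_id[10]
  cm2 <- build_cohort(list(a = neutral), d,
                      qc = list(a = setdiff(d$clone_id, drop_id)))
  expect_true(is.na(cm2$states["a", drop_id]))
  expect_equal(sum(is.na(cm2$states)), 1)
  expect_error(build_cohort(list(neutral), d), "named")
  expect_error(build_cohort(stats::setNames(list(neutral, neutral),
                                            c("a", "a")), d),
               "duplicate")
})

test_that("simulated cohort states match a naive per-clone lookup", {
  fx <- cohort_fixture(80)
  d <- fx$design
  truths <- list(s1 = preset_truth("normal_male_leukocyte"),
                 s2 = preset_truth("pc3_like"),
                 s3 = preset_truth("lncap_like"))
  call_sets <- list()
  qc <- list()
  for (s in names(truths)) {
    out <- run_pipeline(d, truths[[s]], noise_params(0, 0, 0, 0),
                        sim_seed = match(s, names(truths)),
                        seg_seed = 10 + match(s, names(truths)))
    call_sets[[s]] <- out$calls
    qc[[s]] <- out$profile$clones$clone_id[out$profile$clones$qc_pass]
  }
  cm <- build_cohort(call_sets, d, qc = qc)
  # naive oracle: for every sample x clone, scan calls linearly
  for (s in names(call_sets)) {
    calls <- call_sets[[s]]
    for (k in sample(nrow(d), 25)) {
      mid <- (d$start[k] + d$end[k]) / 2
      expect_st <- NA_character_
      for (r in seq_len(nrow(calls))) {
        if (calls$chrom[r] == d$chrom[k] && calls$start_bp[r] <= mid &&
            calls$end_bp[r] >= mid) {
          expect_st <- calls$state[r]
        }
      }
      if (!(d$clone_id[k] %in% qc[[s]])) expect_st <- NA_character_
      expect_identical(unname(cm$states[s, d$clone_id[k]]), expect_st)
    }
  }
})

test_that("aberration frequencies match direct counting", {
  fx <- cohort_fixture(9)
  d <- fx$design[fx$design$chrom != "Y", ]
  # hand-built 9-sample matrix on the first clone: gained in 5 of 9
  states <- matrix("NEUTRAL", nrow = 9, ncol = nrow(d),
                   dimnames = list(paste0("p", 1:9), d$clone_id))
  states[1:5, 1] <- c("GAIN", "GAIN", "HIGH_GAIN", "GAIN", "GAIN")
  states[1:2, 2] <- c("LOSS", "HOMOZYGOUS_LOSS")
  cm <- structure(list(samples = rownames(states), design = d,
                       states = states), class = "cohort_matrix")
  track <- aberration_frequency(cm)
  expect_equal(track$gain_freq[1], 5 / 9)
  expect_equal(track$loss_freq[2], 2 / 9)
  expect_true(all(track$gain_freq + track$loss_freq <= 1))
  # all neutral: zero everywhere
  cm0 <- cm
  cm0$states[] <- "NEUTRAL"
  t0 <- aberration_frequency(cm0)
  expect_true(all(t0$gain_freq == 0) && all(t0$loss_freq == 0))
  # random matrix against a counting loop, with missing entries
  set.seed(9)
  cmr <- cm
  cmr$states[] <- sample(c("NEUTRAL", "GAIN", "LOSS", "HIGH_GAIN",
                           "HOMOZYGOUS_LOSS", NA),
                         length(cmr$states), replace = TRUE)
  tr <- aberration_frequency(cmr)
  for (id in sample(tr$clone_id, 5)) {
    col <- cmr$states[, id]
    col <- col[!is.na(col)]
    k <- match(id, tr$clone_id)
    expect_equal(tr$gain_freq[k],
                 sum(col %in% c("GAIN", "HIGH_GAIN")) / length(col),
                 tolerance = 1e-15)
    expect_equal(tr$loss_freq[k],
                 sum(col %in% c("LOSS", "HOMOZYGOUS_LOSS")) / length(col),
                 tolerance = 1e-15)
  }
  # frequencies are invariant under sample reordering
  cmp <- cmr
  perm <- sample(9)
  cmp$states <- cmp$states[perm, ]
  cmp$samples <- cmp$samples[perm]
  expect_equal(aberration_frequency(cmp), tr)
})

test_that("recurrent regions are maximal runs above the strict threshold", {
  d <- cohort_fixture(20)$design
  d <- d[d$chrom == "1", ][1:10, ]
  track <- data.frame(clone_id = d$clone_id, chrom = d$chrom,
                      start = d$start, end = d$end,
                      gain_freq = c(5/9, 5/9, 0.5, 6/9, 0, 0, 7/9, 7/9,
                                    7/9, 0),
                      loss_freq = rep(0, 10),
                      n_informative = 9,
                      stringsAsFactors = FALSE)
  reg <- recurrent_regions(track, threshold = 0.5)
  expect_equal(nrow(reg), 3)  # clone 3 at exactly 0.5 breaks the first run
  expect_equal(reg$n_clones, c(2, 1, 3))
  expect_equal(reg$direction, rep("gain", 3))
  expect_equal(reg$start_bp[1], d$start[1])
  expect_equal(reg$end_bp[1], d$end[2])
  # no two same-direction regions are adjacent (maximality)
  for (dir in unique(reg$direction)) {
    rr <- reg[reg$direction == dir, ]
    idx_end <- match(rr$end_bp, d$end)
    idx_start <- match(rr$start_bp, d$start)
    expect_true(all(idx_start[-1] - idx_end[-nrow(rr)] > 1))
  }
  # threshold 0 catches every aberrant clone
  reg0 <- recurrent_regions(track, threshold = 0)
  covered <- unlist(mapply(function(s, e) which(d$start >= s & d$end <= e),
                           reg0$start_bp, reg0$end_bp))
  expect_setequal(covered, which(track$gain_freq > 0))
  # empty input gives an empty region table
  t_empty <- track[track$gain_freq > 2, ]
  expect_equal(nrow(recurrent_regions(t_empty)), 0)
})
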