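test_that("genome model has the expected chromosomes and positive lengths", {
  g <- make_genome_model(include_y = TRUE)
  expect_equal(nrow(g), 24)
  expect_true(all(c("X", "Y") %in% g$chrom))
  expect_equal(nrow(make_genome_model(include_y = FALSE)), 23)
  expect_false("Y" %in% make_genome_model(FALSE)$chrom)
  expect_true(all(g$length > 0))
  expect_false(anyDuplicated(g$chrom) > 0)
})

test_that("array design allocates clones proportionally, sorted and unique", {
  g <- make_genome_model()
  d <- generate_array_design(g)
  expect_equal(nrow(d), 2464)
  expect_false(anyDuplicated(d$clone_id) > 0)
  expect_true(all(d$start <= d$end))
  # sorted by genome order then start
  r <- ctcCGH:::chrom_rank(d$chrom)
  expect_true(all(diff(r) >= 0))
  expect_true(all(tapply(d$start, d$chrom, function(s) all(diff(s) > 0))))
  # clones per chromosome roughly proportional to length
  counts <- table(d$chrom)[g$chrom]
  expect_true(cor(as.numeric(counts), g$length) > 0.999)
  # one clone per chromosome at the minimum
  d1 <- generate_array_design(g, n_clones = 24)
  expect_equal(as.numeric(table(d1$chrom)), rep(1, 24))
  expect_error(generate_array_design(g, n_clones = 23), "at least")
  # same seed (placement is deterministic) gives identical designs
  expect_identical(generate_array_design(g, seed = 5),
                   generate_array_design(g, seed = 5))
})

test_that("expected log2 follows the purity-mixture model", {
  g <- tiny_genome(c("1", "X"))
  d <- generate_array_design(g, n_clones = 20)
  nz <- noise_params()
  # neutral autosome is 0 at any tumor fraction
  for (f in c(0, 0.3, 1)) {
    tr <- truth_profile("male", "female", tumor_fraction = f)
    mu <- expected_log2(d, tr, nz)
    expect_equal(mu[d$chrom == "1"], rep(0, sum(d$chrom == "1")))
  }
  # X baseline: male test vs female reference is log2(1/2) = -1
  tr <- truth_profile("male", "female", tumor_fraction = 1)
  expect_equal(expected_log2(d, tr, nz)[d$chrom == "X"],
               rep(-1, sum(d$chrom == "X")))
  # 4 tumor copies at 50% purity: log2((0.5*2 + 0.5*4)/2) = log2(1.5)
  ab <- data.frame(chrom = "1", start = 1, end = 249250621, copies = 4)
  tr4 <- truth_profile("male", "female", ab, tumor_fraction = 0.5)
  expect_equal(expected_log2(d, tr4, nz)[d$chrom == "1"],
               rep(log2(1.5), sum(d$chrom == "1")),
               tolerance = 1e-12)
  # attenuation: |log2| non-increasing as tumor fraction decreases
  for (copies in c(0, 1, 4, 8)) {
    abc <- data.frame(chrom = "1", start = 1, end = 249250621,
                      copies = copies)
    mus <- vapply(seq(1, 0, by = -0.1), function(f) {
      trf <- truth_profile("male", "female", abc, tumor_fraction = f)
      abs(expected_log2(d[d$chrom == "1", ][1, ], trf, nz))
    }, 0)
    expect_true(all(diff(mus) <= 1e-12))
    expect_equal(mus[length(mus)], 0)
  }
  # homozygous deletion in a pure sample hits the dynamic-range floor
  ab0 <- data.frame(chrom = "1", start = 1, end = 249250621, copies = 0)
  tr0 <- truth_profile("male", "female", ab0, tumor_fraction = 1)
  expect_equal(expected_log2(d, tr0, nz)[d$chrom == "1"][1],
               log2(nz$floor_copies / 2))
})

test_that("spot simulation is deterministic and centered on expectations", {
  g <- tiny_genome(c("1", "2"))
  d <- generate_array_design(g, n_clones = 40)
  tr <- truth_profile("male", "female")
  # zero noise reproduces the expected values exactly
  nz0 <- noise_params(0, 0, 0, 0)
  sp0 <- simulate_spot_table(d, tr, nz0, seed = 3)
  mu <- expected_log2(d, tr, nz0)
  expect_equal(sp0$log2_ratio,
               mu[match(sp0$clone_id, d$clone_id)])
  expect_equal(nrow(sp0), 3 * nrow(d))
  # same seed twice gives an identical table
  nz <- noise_params(0.08, 0.05, 0.01, 0.6)
  expect_identical(simulate_spot_table(d, tr, nz, seed = 9),
                   simulate_spot_table(d, tr, nz, seed = 9))
  # law of large numbers at 10,000 neutral clones, spot noise only
  gb <- tiny_genome("1")
  db <- generate_array_design(gb, n_clones = 10000)
  spb <- simulate_spot_table(db, truth_profile("male", "female"),
                             noise_params(0, 0.05, 0, 0), seed = 42)
  expect_lt(abs(mean(spb$log2_ratio)), 0.002)
})

test_that("presets encode the documented aberration profiles", {
  expect_equal(nrow(preset_truth("normal_male_leukocyte")$aberrations), 0)
  v <- preset_truth("vcap_like")
  expect_equal(v$test_sex, "male")
  expect_equal(v$reference_sex, "female")
  ar <- ar_locus()
  hit <- v$aberrations$chrom == "X" &
    v$aberrations$start <= ar$end & v$aberrations$end >= ar$start
  expect_equal(sum(hit), 1)
  # the AR-region amplification reads above the high-gain threshold
  # after the X baseline adjustment at tumor fraction 1
  cfg <- calling_config()
  adj <- log2(v$aberrations$copies[hit] / 2) -
    x_baseline(v$test_sex, v$reference_sex)
  expect_gt(adj, cfg$high_gain_thr)
  p9 <- preset_truth("patient9_like")
  ab11 <- p9$aberrations[p9$aberrations$chrom == "11", ]
  expect_equal(nrow(ab11), 1)
  expect_gt(ab11$start, 5e7)  # q arm
  expect_error(preset_truth("hela_like"), "unknown preset")
})

test_that("truth states and breakpoints mirror the generator's aberrations", {
  g <- make_genome_model()
  d <- generate_array_design(g)
  tr <- preset_truth("vcap_like")
  ts <- truth_clone_states(d, tr)
  ts <- ts[ts$chrom != "Y", ]  # Y is not analyzable and dropped downstream
  expect_equal(sort(unique(ts$chrom[ts$state != "NEUTRAL"])),
               sort(unique(tr$aberrations$chrom)))
  tb <- truth_breakpoints(d, tr)
  # chr8: loss|neutral gap|gain gives two internal boundaries,
  # X: focal amplification gives two
  expect_equal(table(tb$chrom)[["8"]], 2)
  expect_equal(table(tb$chrom)[["X"]], 2)
})
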