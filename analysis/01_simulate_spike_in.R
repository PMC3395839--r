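#!/usr/bin/env Rscript

# Step 1: simulate the spiked-cell validation arrays.
#
# Generates the genome-wide 2,464-clone BAC design and triplicate
# spot-level log2-ratio tables for three prostate cell-line-like truth
# profiles (duplicate isolates each, emulating 20-cell sorted inputs)
# plus an aberration-free male leukocyte control, all hybridized male
# test versus female reference. Writes the design and spot tables under
# results/sim/.

suppressPackageStartupMessages(library(ctcCGH))

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- generate_array_design(make_genome_model(include_y = TRUE))
write_design_tsv(design, file.path(out_dir, "design.tsv"))
cat("array design:", nrow(design), "clones across",
    length(unique(design$chrom)), "chromosomes\n")

# default measurement noise; sorted-cell isolates carry slight
# leukocyte contamination (tumor fraction 0.9)
noise <- noise_params()
presets <- c("lncap_like", "pc3_like", "vcap_like")
seed <- 20120228

for (p in presets) {
  truth <- preset_truth(p, tumor_fraction = 0.9)
  for (r in 1:2) {
    spots <- simulate_spot_table(design, truth, noise,
                                 seed = seed + 10 * match(p, presets) + r)
    f <- file.path(out_dir, sprintf("spots_%s_rep%d.tsv", p, r))
    write_spot_tsv(spots, f)
    cat(sprintf("%-12s replicate %d: %d spots -> %s\n", p, r, nrow(spots), f))
  }
  # pure-DNA positive control: no contamination
  ctrl <- simulate_spot_table(design, preset_truth(p, tumor_fraction = 1),
                              noise, seed = seed + 10 * match(p, presets))
  write_spot_tsv(ctrl, file.path(out_dir, sprintf("spots_%s_control.tsv", p)))
}

leuk <- simulate_spot_table(design, preset_truth("normal_male_leukocyte"),
                            noise, seed = seed + 99)
write_spot_tsv(leuk, file.path(out_dir, "spots_leukocyte.tsv"))
cat("leukocyte control written; simulation complete\n")
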