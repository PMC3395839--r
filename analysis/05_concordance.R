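#!/usr/bin/env Rscript

# Step 5: weighted Pearson concordance between profiles.
#
# Quantifies (a) concordance of duplicate isolates of each cell-line
# truth with their pure-DNA positive control, (b) replicate-replicate
# concordance, (c) cross-line concordance as a negative comparison, and
# (d) the effect of leukocyte dilution (tumor fraction 1 -> 0.2) on
# concordance with a pure partner. Only autosomal, QC-passing-in-both
# clones enter the statistic. Writes results/concordance/summary.json.

suppressPackageStartupMessages({
  library(ctcCGH)
  library(jsonlite)
})

prof_dir <- "results/profiles"
out_dir <- "results/concordance"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

read_prof <- function(id) read_profile_tsv(file.path(prof_dir,
                                                     paste0(id, ".tsv")))
presets <- c("lncap_like", "pc3_like", "vcap_like")
summary <- list()

cat("concordance with pure-DNA positive control:\n")
for (p in presets) {
  ctrl <- read_prof(paste0(p, "_control"))
  for (r in 1:2) {
    res <- profile_concordance(read_prof(sprintf("%s_rep%d", p, r)), ctrl)
    key <- sprintf("%s_rep%d_vs_control", p, r)
    summary[[key]] <- list(r_w = res$r_w, category = res$category,
                           n_clones = res$n_clones)
    cat(sprintf("  %-24s r_w = %.3f (%s)\n", key, res$r_w, res$category))
  }
}

cat("\nreplicate-replicate and cross-line concordance:\n")
for (p in presets) {
  res <- profile_concordance(read_prof(paste0(p, "_rep1")),
                             read_prof(paste0(p, "_rep2")))
  summary[[paste0(p, "_rep1_vs_rep2")]] <-
    list(r_w = res$r_w, category = res$category, n_clones = res$n_clones)
  cat(sprintf("  %-24s r_w = %.3f (%s)\n", paste0(p, "_replicates"),
              res$r_w, res$category))
}
cross <- profile_concordance(read_prof("pc3_like_rep1"),
                             read_prof("lncap_like_rep1"))
summary[["pc3_vs_lncap"]] <- list(r_w = cross$r_w,
                                  category = cross$category,
                                  n_clones = cross$n_clones)
cat(sprintf("  %-24s r_w = %.3f (%s)\n", "pc3_vs_lncap", cross$r_w,
            cross$category))

cat("\nleukocyte dilution of one partner (pc3-like truth):\n")
design <- read_design_tsv("results/sim/design.tsv")
noise <- noise_params()
pure <- read_prof("pc3_like_control")
dil <- list()
for (f in c(1, 0.8, 0.6, 0.4, 0.2)) {
  spots <- simulate_spot_table(design, preset_truth("pc3_like",
                                                    tumor_fraction = f),
                               noise, seed = 7000 + round(100 * f))
  prof <- drop_chromosome(qc_filter(
    summarize_replicates(spots, design, sample_id = sprintf("tf%.1f", f))))
  res <- profile_concordance(prof, pure)
  dil[[sprintf("tumor_fraction_%.1f", f)]] <- res$r_w
  cat(sprintf("  tumor fraction %.1f      r_w = %.3f (%s)\n", f, res$r_w,
              res$category))
}
summary[["dilution_series"]] <- dil

write_json(summary, file.path(out_dir, "summary.json"),
           auto_unbox = TRUE, digits = 6)
cat("\nwrote", file.path(out_dir, "summary.json"), "\n")
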