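#!/usr/bin/env Rscript

# Step 2: summarize triplicate spots and apply clone QC.
#
# For every spot table from step 1: per-clone mean and SD over the
# replicate spots, exclusion of clones with replicate SD > 0.2,
# and removal of chromosome Y (not analyzable in a male-vs-female
# hybridization). Writes per-sample profile TSVs under results/profiles/.

suppressPackageStartupMessages(library(ctcCGH))

sim_dir <- "results/sim"
out_dir <- "results/profiles"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- read_design_tsv(file.path(sim_dir, "design.tsv"))
spot_files <- list.files(sim_dir, pattern = "^spots_.*\\.tsv$",
                         full.names = TRUE)

for (f in spot_files) {
  id <- sub("^spots_", "", sub("\\.tsv$", "", basename(f)))
  prof <- summarize_replicates(read_spot_tsv(f), design, sample_id = id,
                               test_sex = "male", reference_sex = "female")
  prof <- qc_filter(prof, sd_max = 0.2)
  n_fail <- sum(!prof$clones$qc_pass)
  prof <- drop_chromosome(prof, "Y")
  write_profile_tsv(prof, file.path(out_dir, paste0(id, ".tsv")))
  cat(sprintf("%-22s %d clones, %d QC-excluded (SD > 0.2), Y dropped\n",
              id, nrow(prof$clones), n_fail))
}
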