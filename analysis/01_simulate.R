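#!/usr/bin/env Rscript
# Build the study configuration and simulate the synthetic two-cohort
# material: a large truth-level cohort (for the statistical layer) and a
# small rendered imaging cohort (for the image-processing pipeline).
#
# Outputs under results/: config.yaml, cohort_truth.csv, example scene PNGs.

suppressPackageStartupMessages(library(retinavasc))
dir.create("results", showWarnings = FALSE)

cfg <- default_config()
cfg$seed <- 1L
cfg$simulate$n_per_group <- 4L      # rendered imaging cohort (16 eyes)
cfg$simulate$size <- 640L
write_config(cfg, "results/config.yaml")

# truth-level cohort at the emulated study's scale: 100 subjects per group,
# both eyes as rows, published covariate imbalance and highland offsets
spec <- cohort_spec(n_per_group = 100, seed = cfg$seed)
cohort <- generate_cohort(spec)$cohort
write_table_csv(cohort, "results/cohort_truth.csv")
cat(sprintf("truth cohort: %d eye-rows (%d HLC, %d LLC)\n",
            nrow(cohort), sum(cohort$group == "HLC"),
            sum(cohort$group == "LLC")))
cat(sprintf("mean true caliber: HLC %.2f um vs LLC %.2f um\n",
            mean(cohort$vc_um[cohort$group == "HLC"]),
            mean(cohort$vc_um[cohort$group == "LLC"])))

# one example rendered eye for visual QC
sc <- default_scene(seed = cfg$seed, size = 1024)
write_fundus_png(sc$image, "results/example_fundus.png")
write_mask_png(sc$truth$vessel_mask, "results/example_truth_mask.png")
cat("wrote results/example_fundus.png and its truth mask\n")
cat(sprintf("example scene: %.1f%% vessel pixels, %d bifurcations\n",
            100 * mean(sc$truth$vessel_mask),
            nrow(sc$truth$per_branch_truth)))
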