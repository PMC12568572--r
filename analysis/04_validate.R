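#!/usr/bin/env Rscript
# Quality control against ground truth: segmentation recognition rates on
# the gate scene, per-eye recovery of the imaging cohort, and the pooled
# truth-recovery benchmark of the graph/morphometry stages.

suppressPackageStartupMessages(library(retinavasc))

cat("== segmentation gate (default scene) ==\n")
sc <- default_scene(seed = 0, size = 1024)
pre <- preprocess(sc$image)
mask <- segment_vessels(pre)
q <- segmentation_quality(mask, sc$truth$vessel_mask, pre$roi_mask)
cat(sprintf("sensitivity %.4f, specificity %.4f\n",
            q["sensitivity"], q["specificity"]))

cat("\n== per-eye validation of the imaging cohort ==\n")
cfg <- read_config("results/config.yaml")
res <- run_pipeline(cfg)
v <- suppressMessages(validate_against_truth(res$eyes, res$truths))
print(v, digits = 3)
write_table_csv(v, "results/validation_eyes.csv")

cat("\n== pooled truth-recovery benchmark (5 scenes) ==\n")
rb <- recovery_batch(n_scenes = 5, size = 1024, seed = 200)
cat(sprintf(
  "caliber MAE %.3f px | angle err %.2f deg (MAE %.1f) | tortuosity %.3f | density exact: %s\n",
  rb$caliber_mae_px, rb$angle_err_deg, rb$angle_mae_deg,
  rb$tort_rel_err, rb$density_exact))
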