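#!/usr/bin/env Rscript
# Step 4 — Predicted versus in vivo rotation axes.
#
# Converts each joint's averaged peak-inhalation -> peak-exhalation
# rotation to axis-angle form, compares the in vivo axis against the
# anatomical (parapophysis-diapophysis) prediction via body-plane angles,
# and regresses measured on predicted per plane. Because the simulated
# hinges follow the anatomical axes exactly, the regression should sit on
# the identity line up to tracking noise - this is the pipeline
# validation, not a biological result.

library(ribxromm)

SEED <- 20260920
model <- build_ribcage()
script <- default_motion_script(model, seed = SEED, n_breaths = 5,
                                frame_rate = 100, noise_sd_mm = 0.12)
sim <- simulate_breathing(model, script)

bodies <- model$bodies[c(paste0("vcol", 1:3), paste0("rib", 1:8, "_vertebral"))]
joints <- lapply(model$joints[paste0("cv", 1:8)], function(j) {
  j$zero_pose_frame <- NA
  j
})
res <- run_pipeline(sim$trajectories, bodies, joints,
                    predicted_axes = model$predicted_axes)

dir.create("results", showWarnings = FALSE)
write.csv(res$invivo_axes, "results/invivo_axes.csv", row.names = FALSE)
write.csv(res$comparison, "results/axis_comparison.csv", row.names = FALSE)
write.csv(res$regression, "results/axis_regression.csv", row.names = FALSE)

cat("In vivo total rotation per joint:\n")
print(res$invivo_axes[, c("joint_id", "theta_deg", "ternary_x", "ternary_y",
                          "ternary_z")], digits = 3, row.names = FALSE)

err <- vapply(paste0("cv", 1:8), function(j) {
  rec <- as.numeric(res$invivo_axes[res$invivo_axes$joint_id == j,
                                    c("axis_x", "axis_y", "axis_z")])
  tru <- as.numeric(sim$truth$axes[sim$truth$axes$joint_id == j,
                                   c("axis_x", "axis_y", "axis_z")])
  acos(min(1, abs(sum(rec * tru) / sqrt(sum(rec^2) * sum(tru^2))))) * 180 / pi
}, numeric(1))
cat("\nAxis recovery error vs ground truth (deg), with total rotation:\n")
print(data.frame(joint = names(err), error_deg = round(err, 2),
                 theta_deg = round(res$invivo_axes$theta_deg[
                   match(names(err), res$invivo_axes$joint_id)], 1)),
      row.names = FALSE)
cat(sprintf("median %.2f deg, max %.2f deg.\n", median(err), max(err)))
cat("Axis direction is noise-limited at small rotations: the endpoint",
    "angle noise is\nroughly constant (~0.2 deg at 0.12 mm tracking",
    "precision), so the axis error\nscales inversely with the joint's",
    "total rotation - the cranial joints (~8-10 deg\nexcursions) are the",
    "least certain, exactly where error concentrates above.\n")

cat("\nPredicted-vs-measured body-plane-angle regression:\n")
print(res$regression[, c("plane", "slope", "intercept", "r_squared",
                         "p_value")], digits = 3, row.names = FALSE)
cat("\nSlopes near 1 with high R^2 confirm the pipeline recovers the",
    "prescribed hinge\naxes through the complete marker -> pose -> JCS ->",
    "cycle -> axis-angle chain.\nWrote results/invivo_axes.csv,",
    "axis_comparison.csv, axis_regression.csv\n")
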