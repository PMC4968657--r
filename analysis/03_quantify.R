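#!/usr/bin/env Rscript
# Step 3: quantify the phantom studies.
#
# Loads the studies written by 01_simulate.R, runs the quantification chain
# (ROI means -> background correction against the pre-injection frame ->
# proximity ratio A/(A+D) -> calibration inversion) with the calibration
# fitted in 02_calibrate.R, and writes per-replicate and replicate-averaged
# integrity time courses. Also renders pseudocolor ratio images of the
# first healthy replicate.

suppressPackageStartupMessages(library(fretnc))
dir.create("results", showWarnings = FALSE)

cal <- read_calibration_json("results/calibration_fit.json")
seeds <- 1:3

per_rep <- list()
summaries <- list()
for (name in c("healthy", "tumor_bearing")) {
  tcs <- lapply(seeds, function(s) {
    study <- read_study(file.path("scratch/phantoms",
                                  sprintf("%s_s%d", name, s),
                                  "manifest.json"))
    tc <- integrity_timecourse(study, cal)
    tc$scenario <- name
    tc$replicate <- s
    tc
  })
  per_rep <- c(per_rep, tcs)
  s <- summarize_replicates(lapply(tcs, function(tc)
    tc[, c("region", "quantity", "time_h", "value")]))
  s$scenario <- name
  summaries[[name]] <- s
}
write.csv(do.call(rbind, per_rep), "results/integrity_replicates.csv",
          row.names = FALSE)
summary_df <- do.call(rbind, summaries)
write.csv(summary_df, "results/integrity_summary.csv", row.names = FALSE)

# donor-only control: corrected tail-vein donor intensity for clearance
donor_tcs <- lapply(seeds, function(s) {
  study <- read_study(file.path("scratch/phantoms",
                                sprintf("donor_only_s%d", s),
                                "manifest.json"))
  tc <- intensity_timecourse(study, "tail_vein", "donor")
  tc$replicate <- s
  tc
})
write.csv(do.call(rbind, donor_tcs), "results/donor_clearance_intensity.csv",
          row.names = FALSE)

cat("replicate-averaged integrity (mean ± SEM, n = 3):\n")
show <- summary_df[summary_df$time_h %in% c(2, 6) &
                   summary_df$region != "liver" |
                   summary_df$region == "liver" & summary_df$time_h == 6, ]
for (i in seq_len(nrow(show)))
  cat(sprintf("  %-13s %-9s at %2g h: %5.1f ± %.1f %%\n",
              show$scenario[i], show$region[i], show$time_h[i],
              show$value[i], show$sem[i]))

# pseudocolor ratio images of the first healthy replicate
dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)
study <- read_study("scratch/phantoms/healthy_s1/manifest.json")
floor_d <- estimate_intensity_floor(study_frame(study, 0, "donor"))
floor_a <- estimate_intensity_floor(study_frame(study, 0, "acceptor"))
for (t in c(0.25, 6, 24)) {
  d <- study_frame(study, t, "donor")
  a <- study_frame(study, t, "acceptor")
  ri <- compute_ratio_image(a, d, intensity_floor = max(floor_d, floor_a))
  png_path <- sprintf("scratch/figures/healthy_ratio_%gh.png", t)
  write_pseudocolor_png(render_pseudocolor(ri, d, a), png_path)
}
cat("ratio images (red = intact, blue = disintegrated) -> scratch/figures/\n")
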