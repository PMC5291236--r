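#!/usr/bin/env Rscript
# Stage 4: histology quantification.
#
# Scores barrel segregation (wall/hollow cell-density ratio, best optical
# section per animal-equivalent stack), counts axons traversing the
# 100 x 30 um regions of interest in barrel centres and septa, and computes
# the area arithmetic for axon patches within the barrel subfield.

suppressPackageStartupMessages(library(barreldev))
sim_dir <- "results/sim"
stopifnot(dir.exists(sim_dir))

geom <- barrel_annulus(r_hollow = 100, r_wall = 150)
rois <- lapply(1:3, function(i) roi_rect(center_xy = c(400 * i, 0)))
rois_s <- lapply(1:3, function(i) roi_rect(center_xy = c(400 * i, 300),
                                           angle_deg = 90))

rows <- lapply(c("wt", "ko"), function(g) {
  field <- read_points_csv(file.path(sim_dir, sprintf("%s_nuclei.csv", g)))
  seg <- segregation_ratio(field, geom)
  axons <- read_segments_csv(file.path(sim_dir, sprintf("%s_axons.csv", g)))
  cr <- crossing_report(rois, rois_s, axons)
  data.frame(group = g,
             best_ratio = seg$best_ratio,
             best_section = seg$best_section_index,
             centre = cr$centre, septa = cr$septa, total = cr$total)
})
histo <- do.call(rbind, rows)
utils::write.csv(histo, "results/histo_summary.csv", row.names = FALSE)
message("segregation and crossings per group:")
print(histo, digits = 3)

# area arithmetic at the published group means: patch areas summing to
# 0.165 mm^2 inside a 1.21 mm^2 barrel subfield
patch <- polygon_area(rbind(c(0, 0), c(500, 0), c(500, 330), c(0, 330)))
pmbsf <- polygon_area(rbind(c(0, 0), c(1100, 0), c(1100, 1100), c(0, 1100)))
prop <- patch_proportion(list(patch), pmbsf)
message(sprintf(
  "patch area %.3f mm^2 within subfield %.2f mm^2 -> proportion %.4f",
  patch$area_mm2, pmbsf$area_mm2, prop))
utils::write.csv(
  data.frame(patch_mm2 = patch$area_mm2, pmbsf_mm2 = pmbsf$area_mm2,
             proportion = prop),
  "results/area_proportion.csv", row.names = FALSE)
message("wrote results/histo_summary.csv, results/area_proportion.csv")
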