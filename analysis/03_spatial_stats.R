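#!/usr/bin/env Rscript

# Stage 3 -- spatial statistics on synthetic cell-position data.
#
# PCA axes and 200-unit parcellation of a projected cell cloud, Gaussian
# kernel density map with Scott's bandwidth, barrel-wise permutation
# enrichment test (2500 shuffles, alpha 0.001), and assignment of
# visual-space coordinates to parcels through a smooth retinotopy.
# Outputs land in results/spatial/.

suppressMessages(library(tactovis))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/spatial"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cl <- gen_cell_cloud(generator_config(seed = seed, cloud = list(n = 10000L)))
pts <- as.matrix(cl[, c("x", "y")])
ax <- pca_axes(pts)
truth <- attr(cl, "truth")
cat(sprintf("PCA: explained variance (%.0f%%, %.0f%%); generating split (%.0f%%, %.0f%%)\n",
            100 * ax$explained[1], 100 * ax$explained[2],
            100 * truth$split[1], 100 * truth$split[2]))

parc <- parcellate(pts, ax, spacing = 200, cross = TRUE)
write.csv(parc$parcels, file.path(out, "parcels.csv"), row.names = FALSE)
write.csv(parc$section_lines, file.path(out, "section_lines.csv"),
          row.names = FALSE)
cat(sprintf("Parcellation: %d parcels on the PC1 x PC2 grid (200-unit spacing)\n",
            nrow(parc$parcels)))

dm <- density_map(pts)
write.csv(data.frame(x = rep(dm$x, times = length(dm$y)),
                     y = rep(dm$y, each = length(dm$x)),
                     density = as.vector(dm$z)),
          file.path(out, "density_map.csv"), row.names = FALSE)
cat(sprintf("Density map: argmax at (%.0f, %.0f); generating peak (%.0f, %.0f); %d contour lines\n",
            dm$argmax[1], dm$argmax[2], truth$peak[1], truth$peak[2],
            length(dm$contours)))

bg <- gen_barrel_map(generator_config(
  seed = seed, barrel = list(enrichment = c(`7` = 4, `13` = 5))))
pt <- barrel_permutation_test(bg$cells, bg$map, n_shuffles = 2500,
                              alpha = 0.001, seed = seed + 1)
write.csv(data.frame(barrel = rownames(pt$fr_obs),
                     fr = pt$fr_obs, p = pt$p,
                     significant = pt$significant, check.names = FALSE),
          file.path(out, "barrel_enrichment.csv"), row.names = FALSE)
cat("Barrel permutation test (2500 shuffles, alpha 0.001):\n")
print(pt)
cat(sprintf("  enriched barrels by construction: 7 (4x), 13 (5x)\n"))

ret <- gen_retinotopy(generator_config(
  seed = seed, retinotopy = list(type = "smooth",
                                 domain = list(x = range(pts[, 1]) + c(-300, 300),
                                               y = range(pts[, 2]) + c(-300, 300)))))
cov <- parcel_visual_coverage(parc, ret, threshold = 0.05)
sel <- cov$selected
cat(sprintf("Visual-space assignment: %d of %d parcels carry >= 5%% of cells;\n",
            length(sel), nrow(parc$parcels)))
az_el <- do.call(rbind, lapply(Filter(function(p) p$id %in% sel, cov$patches),
                               function(p) p$polygon))
cat(sprintf("  their merged coverage spans azimuth %.0f..%.0f deg, elevation %.0f..%.0f deg\n",
            min(az_el[, 1]), max(az_el[, 1]), min(az_el[, 2]), max(az_el[, 2])))
patches <- do.call(rbind, lapply(cov$patches, function(p)
  data.frame(parcel = p$id, fraction = p$fraction,
             azimuth = p$polygon[, 1], elevation = p$polygon[, 2])))
write.csv(patches, file.path(out, "parcel_visual_patches.csv"),
          row.names = FALSE)
cat(sprintf("Wrote results to %s\n", out))
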