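#!/usr/bin/env Rscript
# Stage 3: nerve-artery inter-centroid distances.
#
# Resumes from results/profiles.csv: all pairwise nerve-artery centroid
# distances within each slice, their per-slice minima, the first-slice
# centroid projection, and the derived perimeter-to-perimeter bound.

suppressMessages(library(cymbamorph))

profiles <- utils::read.csv("results/profiles.csv")

pairs <- pairwise_distances(profiles)
ds <- distance_summaries(pairs)
utils::write.csv(pairs, "results/distances.csv", row.names = FALSE)
utils::write.csv(ds$minima, "results/distance_minima.csv",
                 row.names = FALSE)
utils::write.csv(project_centroids(profiles),
                 "results/projected_centroids.csv", row.names = FALSE)

message(sprintf(
  "All nerve-artery pairs: median %.0f um (IQR %.0f um; %.0f +/- %.0f um)",
  ds$all_pairs$median, ds$all_pairs$iqr, ds$all_pairs$mean,
  ds$all_pairs$sd))
message(sprintf(
  "Per-slice minimum:      median %.0f um (IQR %.0f um; %.0f +/- %.0f um)",
  ds$per_slice_min$median, ds$per_slice_min$iqr, ds$per_slice_min$mean,
  ds$per_slice_min$sd))

# surface-separation bound from the recovered diameter IQRs
dia <- function(cls) summary_stats(
  profiles$equivalent_diameter_um[profiles$element_class == cls])
da <- dia("artery"); dn <- dia("nerve")
b <- perimeter_distance_bounds(ds$per_slice_min$median,
                               c(da$q25, da$q75), c(dn$q25, dn$q75))
message(sprintf(
  "Mean minimum perimeter-to-perimeter distance bounded in %.0f-%.0f um",
  b["lower"], b["upper"]))
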