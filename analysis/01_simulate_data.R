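#!/usr/bin/env Rscript
# Stage 1: generate every input the downstream stages need.
#
# A test chromosome carrying the rearranged AZFc copy vector
# (b=4, t=0, g=5, r=6, y=4, Gr=2, spacer absent) and two reference-structure
# controls are simulated at ~30-40x Poisson depth over the toy-scaled map
# (1/100 coordinates, so the whole pipeline runs in seconds), and a star-shaped
# Y-STR cluster plus its wider clade are simulated under the stepwise mutation
# model. Everything is written under results/.

suppressPackageStartupMessages(library(azfcnahr))

dir.create("results", showWarnings = FALSE)
set.seed(20210416)

toy <- make_toy_map(0.01)
write_reference_map(toy, "results/azfc_map_toy.bed")

rearranged <- copy_vector(b = 4, t = 0, g = 5, r = 6, y = 4, Gr = 2, spacer = 0)
coverages <- c(case = 38.7, ctl1 = 36.4, ctl2 = 41.8)
profiles <- list(
  case = simulate_depth(toy, rearranged, coverages["case"], seed = 1, sample_id = "case"),
  ctl1 = simulate_depth(toy, base_coverage = coverages["ctl1"], seed = 2, sample_id = "ctl1"),
  ctl2 = simulate_depth(toy, base_coverage = coverages["ctl2"], seed = 3, sample_id = "ctl2"))
for (nm in names(profiles))
  write_depth_table(profiles[[nm]], sprintf("results/depth_%s.tsv", nm))
cat("wrote per-base depth tables for", length(profiles), "samples (",
    sum(lengths(profiles$case$depth)), "bases each )\n")

# Y-STR haplotypes: a tight 4-sample cluster (the rearranged lineage) nested
# inside a wider clade, drifting from a common founder
founder <- default_founder()
upstream <- simulate_haplotypes(founder, 3, 90, seed = 4,
                                tip_ids = c("I34-454", "I34-455", "H30-328"))
cluster_founder <- simulate_haplotypes(founder, 1, 70, seed = 5, tip_ids = "cf")
cf <- setNames(as.integer(cluster_founder[1, default_str_panel()]),
               default_str_panel())
cluster <- simulate_haplotypes(cf, 4, 20, seed = 6,
                               tip_ids = c("M4-85", "M4-98", "M4-100", "M4-106"))
haps <- rbind(cluster, upstream)
write_haplotypes(haps, "results/haplotypes_sim.tsv")
writeLines(cluster$sample_id, "results/cluster_ids.txt")
cat("wrote", nrow(haps), "simulated haplotypes over",
    length(default_str_panel()), "loci\n")
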