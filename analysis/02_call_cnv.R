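#!/usr/bin/env Rscript
# Stage 2: amplicon copy-number calling by normalized read depth.
#
# For each simulated sample, the mean depth over every amplicon family is
# divided by the mean depth of the single-copy normalization interval and the
# ratio is converted to an integer copy number by midpoint thresholding.
# The test sample should call (b=4, t=0, g=5, r=6, y=4, Gr=2, spacer=0),
# the controls the reference vector.

suppressPackageStartupMessages(library(azfcnahr))

toy <- load_reference_map("results/azfc_map_toy.bed")
intervals <- rbind(toy$segments[, c("chrom", "start", "end")],
                   toy$norm[, c("chrom", "start", "end")])

for (nm in c("case", "ctl1", "ctl2")) {
  prof <- read_depth_table(sprintf("results/depth_%s.tsv", nm), intervals,
                           sample_id = nm)
  res <- call_all(prof, toy)
  write_calls(res, sprintf("results/calls_%s.tsv", nm),
              sprintf("results/vector_%s.json", nm))
  cat("==", nm, "==\n")
  print(res$calls, digits = 4)
  print(res$vector)
}
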