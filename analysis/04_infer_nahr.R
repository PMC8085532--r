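#!/usr/bin/env Rscript
# Stage 4: reconstruct the NAHR event sequences behind the called vector.
#
# Exhaustive search over ordered NAHR event sequences (up to two events) on
# the full-size reference map, for the copy-number vector called in stage 2.
# Reports each explaining scenario with its per-event genomic spans,
# gene-family dosages and Y-STR copy consequences.

suppressPackageStartupMessages(library(azfcnahr))

map <- azfc_reference_map()
vec <- unlist(jsonlite::read_json("results/vector_case.json"))
cat("observed vector:", paste(names(vec), vec, sep = "=", collapse = " "), "\n\n")

scen <- search_scenarios(map, vec, max_events = 2)
cat(length(scen), "minimal scenario(s) found\n\n")
for (s in scen) print(s)

write_scenarios(scen, "results/scenarios.json")

ref_d <- gene_dosage(reference_copy_vector(map), map)
new_d <- gene_dosage(vec, map)
cat("\ngene dosage (reference -> rearranged):\n")
for (g in names(ref_d))
  cat(sprintf("  %-5s %d -> %d\n", g, ref_d[[g]], new_d[[g]]))
cat("STR copies:", paste(names(str_copy_counts(vec, map)),
                         str_copy_counts(vec, map), sep = "=", collapse = " "), "\n")
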