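# shared fixtures, built in code

full_map <- azfc_reference_map()
toy_map <- make_toy_map(0.01)

# the rearranged chromosome of interest: b2/b4 duplication + b1/b3 deletion
m498_vector <- copy_vector(b = 4, t = 0, g = 5, r = 6, y = 4, Gr = 2, spacer = 0)

# printed normalized depths of the sequenced samples (test sample + controls)
table1_nd <- list(
  "M4-98" = c(b = 0.983, t = 0.076, g = 1.589, r = 1.475, y = 1.962,
              Gr = 0.966, spacer = 0.022),
  "W043" = c(b = 1.023, t = 1.021, g = 1.004, r = 0.965, y = 1.001,
             Gr = 1.024, spacer = 1.010),
  "W005" = c(b = 0.964, t = 0.966, g = 0.940, r = 0.969, y = 0.979,
             Gr = 0.962, spacer = 0.959))

# a bare chromosome structure built directly (bypasses the map)
make_structure <- function(occ, family, orientation) {
  structure(data.frame(occ = occ, source = occ, family = family,
                       orientation = orientation, anchor = occ,
                       stringsAsFactors = FALSE),
            class = c("chrom_structure", "data.frame"))
}

# brute-force scenario oracle: naive exhaustion over all ordered event
# sequences of exactly the minimal explaining length, independent of the
# search's recursion and bookkeeping
oracle_minimal_sequences <- function(map, observed, max_events = 2L) {
  observed <- unname(as.integer(observed[azfcnahr:::copy_vector_names()]))
  vec_of <- function(struct) {
    fams <- names(amplicon_families())
    unname(c(vapply(fams, function(f) sum(struct$family == f), integer(1)),
             sum(struct$family == "spacer")))
  }
  ref <- reference_structure(map)
  if (identical(vec_of(ref), observed)) return(list(list()))
  seqs_at <- function(depth) {
    frontier <- list(list(struct = ref, events = list()))
    for (d in seq_len(depth)) {
      nxt <- list()
      for (st in frontier) {
        for (ev in enumerate_events(st$struct)) {
          nxt[[length(nxt) + 1L]] <- list(struct = apply_event(st$struct, ev),
                                          events = c(st$events, list(ev)))
        }
      }
      frontier <- nxt
    }
    Filter(function(st) identical(vec_of(st$struct), observed), frontier)
  }
  for (L in seq_len(max_events)) {
    hits <- seqs_at(L)
    if (length(hits)) return(lapply(hits, `[[`, "events"))
  }
  list()
}

event_signature <- function(events) {
  paste(vapply(events, function(e)
    paste(e$kind, e$mechanism, e$left, e$right, sep = ":"), character(1)),
    collapse = " -> ")
}
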