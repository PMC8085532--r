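#' Chromosome structure of a reference map
#'
#' Represents the AZFc as an ordered list of segment occurrences. Each
#' occurrence carries its family, orientation (+1/-1), a source label (plain,
#' like `"b2"`, or hybrid, like `"b4/b2"`, recording the pair fused by a
#' NAHR exchange) and a reference anchor: the reference segment whose
#' coordinates stand in for the occurrence when event span lengths are
#' projected back onto the map. Hybrids anchor to the first-named source.
#'
#' @param map An `azfc_map`.
#' @return A `chrom_structure` (data.frame with columns `occ`, `source`,
#'   `family`, `orientation`, `anchor`).
#' @export
reference_structure <- function(map) {
  seg <- map$segments
  structure(data.frame(occ = seg$id,
                       source = seg$id,
                       family = seg$family,
                       orientation = ifelse(seg$strand == "+", 1L, -1L),
                       anchor = seg$id,
                       stringsAsFactors = FALSE),
            class = c("chrom_structure", "data.frame"))
}

as_structure <- function(df) {
  structure(df, class = c("chrom_structure", "data.frame"))
}

#' @export
print.chrom_structure <- function(x, ...) {
  cat("chromosome structure (", nrow(x), " occurrences):\n  ",
      paste(x$occ, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Copy-number vector of a chromosome structure
#'
#' Counts occurrences per amplicon family plus the P3 spacer (hybrid
#' occurrences count as one copy of their family).
#'
#' @param struct A `chrom_structure`.
#' @return A `copy_vector`.
#' @export
structure_vector <- function(struct) {
  fam <- amplicon_families()
  v <- vapply(names(fam), function(f) sum(struct$family == f), integer(1))
  do.call(copy_vector, c(as.list(v), list(spacer = sum(struct$family == "spacer"))))
}

#' Construct a NAHR event
#'
#' An unequal crossover between two same-family, same-orientation (direct
#' repeat) occurrences, the left strictly before the right. Deletions can be
#' intrachromatidic (loop-out within one chromatid) or interchromatidic
#' (unequal sister-chromatid exchange); duplications only arise from the
#' interchromatidic mechanism, whose reciprocal products are a deletion and
#' a duplication chromatid.
#'
#' @param struct The `chrom_structure` the event is defined on.
#' @param kind `"deletion"` or `"duplication"`.
#' @param mechanism `"intrachromatidic"` or `"interchromatidic"`.
#' @param left,right Occurrence ids of the recombining repeats.
#' @return An object of class `nahr_event`.
#' @export
nahr_event <- function(struct, kind = c("deletion", "duplication"),
                       mechanism = c("interchromatidic", "intrachromatidic"),
                       left, right) {
  kind <- match.arg(kind)
  mechanism <- match.arg(mechanism)
  iL <- match(left, struct$occ); iR <- match(right, struct$occ)
  if (is.na(iL) || is.na(iR))
    stop("occurrence ", if (is.na(iL)) left else right,
         " not present in the structure (stale id?)")
  if (iL >= iR) stop("left occurrence must lie strictly before right")
  if (struct$family[iL] != struct$family[iR])
    stop("NAHR requires occurrences of the same amplicon family")
  if (struct$orientation[iL] != struct$orientation[iR])
    stop(left, " and ", right, " are inverted repeats, not direct repeats; ",
         "copy-number-changing NAHR needs direct repeats")
  if (kind == "duplication" && mechanism == "intrachromatidic")
    stop("intrachromatidic NAHR has no duplication product")
  structure(list(kind = kind, mechanism = mechanism,
                 left = left, right = right,
                 family = struct$family[iL]),
            class = "nahr_event")
}

#' @export
print.nahr_event <- function(x, ...) {
  cat(format_event(x), "\n")
  invisible(x)
}

format_event <- function(ev) {
  sprintf("%s %s/%s (%s)", ev$kind, ev$left, ev$right,
          substr(ev$mechanism, 1, 5))
}

#' Enumerate all NAHR events definable on a structure
#'
#' All ordered pairs of same-family, same-orientation occurrences; for each
#' pair a deletion by either mechanism and an interchromatidic duplication.
#'
#' @param struct A `chrom_structure`.
#' @return List of `nahr_event`s (possibly empty).
#' @export
enumerate_events <- function(struct) {
  out <- list()
  for (f in names(amplicon_families())) {
    idx <- which(struct$family == f)
    if (length(idx) < 2) next
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      iL <- idx[a]; iR <- idx[b]
      if (struct$orientation[iL] != struct$orientation[iR]) next
      L <- struct$occ[iL]; R <- struct$occ[iR]
      out <- c(out, list(
        nahr_event(struct, "deletion", "intrachromatidic", L, R),
        nahr_event(struct, "deletion", "interchromatidic", L, R),
        nahr_event(struct, "duplication", "interchromatidic", L, R)))
    }
  }
  out
}

#' Apply a NAHR event to a chromosome structure
#'
#' Deletion: the occurrences strictly between the recombining pair are
#' removed and the pair is fused into one hybrid occurrence `left/right`.
#' Duplication: the intervening span is present twice and the extra family
#' copy appears as the hybrid `right/left` between the two span copies
#' (`... left, span, right/left, span-copy, right ...`).
#'
#' @param struct A `chrom_structure`.
#' @param event A `nahr_event` whose occurrence ids exist in `struct`.
#' @return The rearranged `chrom_structure`.
#' @export
apply_event <- function(struct, event) {
  iL <- match(event$left, struct$occ); iR <- match(event$right, struct$occ)
  if (is.na(iL) || is.na(iR))
    stop("occurrence ", if (is.na(iL)) event$left else event$right,
         " not present in the structure (stale id?)")
  n <- nrow(struct)
  if (event$kind == "deletion") {
    hybrid <- data.frame(occ = paste0(struct$occ[iL], "/", struct$occ[iR]),
                         source = paste0(struct$source[iL], "/", struct$source[iR]),
                         family = struct$family[iL],
                         orientation = struct$orientation[iL],
                         anchor = struct$anchor[iL],
                         stringsAsFactors = FALSE)
    out <- rbind(if (iL > 1) struct[1:(iL - 1), ], hybrid,
                 if (iR < n) struct[(iR + 1):n, ])
  } else {
    between <- if (iR > iL + 1) struct[(iL + 1):(iR - 1), ] else struct[0, ]
    hybrid <- data.frame(occ = paste0(struct$occ[iR], "/", struct$occ[iL]),
                         source = paste0(struct$source[iR], "/", struct$source[iL]),
                         family = struct$family[iR],
                         orientation = struct$orientation[iR],
                         anchor = struct$anchor[iR],
                         stringsAsFactors = FALSE)
    span_copy <- between
    if (nrow(span_copy)) span_copy$occ <- paste0(span_copy$occ, ".c")
    out <- rbind(struct[1:(iR - 1), ], hybrid, span_copy, struct[iR:n, ])
  }
  out$occ <- make.unique(out$occ)
  rownames(out) <- NULL
  as_structure(out)
}

#' Reciprocal products of an interchromatidic exchange
#'
#' Unequal sister-chromatid exchange yields two reciprocal chromatids: one
#' carrying the deletion, the other the duplication. For every family the
#' copy counts of the two products sum to twice the parent's.
#'
#' @param struct A `chrom_structure`.
#' @param event An interchromatidic `nahr_event`.
#' @return List with elements `deletion` and `duplication`.
#' @export
sister_products <- function(struct, event) {
  if (event$mechanism != "interchromatidic")
    stop("only interchromatidic exchange has reciprocal products")
  del <- nahr_event(struct, "deletion", "interchromatidic",
                    event$left, event$right)
  dup <- nahr_event(struct, "duplication", "interchromatidic",
                    event$left, event$right)
  list(deletion = apply_event(struct, del),
       duplication = apply_event(struct, dup))
}

# genomic distance between the recombining repeats, projected on the
# reference map via occurrence anchors (start-to-start)
event_span_bp <- function(struct, event, map) {
  iL <- match(event$left, struct$occ); iR <- match(event$right, struct$occ)
  seg <- map$segments
  sL <- seg$start[match(struct$anchor[iL], seg$id)]
  sR <- seg$start[match(struct$anchor[iR], seg$id)]
  abs(sR - sL)
}

#' Search NAHR event sequences explaining an observed copy-number vector
#'
#' Exhaustive search over ordered sequences of NAHR events starting from the
#' reference structure, regenerating the event catalog at every step (so
#' hybrids are themselves usable repeats). Returns all minimal-length
#' sequences whose final copy-number vector (families plus P3-spacer count)
#' equals the observed vector. Each scenario is annotated with whether its
#' events could also have occurred concurrently, i.e. whether every event is
#' already definable on the reference structure: copy-number data cannot
#' distinguish simultaneous from successive exchanges in that case.
#'
#' @param map An `azfc_map`.
#' @param observed Observed `copy_vector` (or named vector coercible to one).
#' @param max_events Longest event sequence considered (default 2, hard
#'   limit 3: branching grows factorially and the biology of interest needs
#'   only two events).
#' @return List of `nahr_scenario` objects (empty if the vector cannot be
#'   explained within `max_events`).
#' @export
search_scenarios <- function(map, observed, max_events = 2L) {
  if (max_events > 3L) stop("max_events is capped at 3")
  observed <- as_copy_vector(observed)
  ref <- reference_structure(map)
  if (identical(unname(as.integer(structure_vector(ref))),
                unname(as.integer(observed))))
    return(list(new_scenario(list(), ref, map)))
  for (L in seq_len(max_events)) {
    found <- list()
    recurse <- function(struct, events, spans, depth) {
      if (depth == L) {
        if (identical(unname(as.integer(structure_vector(struct))),
                      unname(as.integer(observed))))
          found[[length(found) + 1L]] <<- list(events = events, spans = spans,
                                               struct = struct)
        return()
      }
      for (ev in enumerate_events(struct)) {
        recurse(apply_event(struct, ev),
                c(events, list(ev)),
                c(spans, event_span_bp(struct, ev, map)),
                depth + 1L)
      }
    }
    recurse(ref, list(), numeric(0), 0L)
    if (length(found))
      return(lapply(found, function(f)
        new_scenario(f$events, f$struct, map, spans = f$spans)))
  }
  list()
}

new_scenario <- function(events, final_structure, map, spans = numeric(0)) {
  vec <- structure_vector(final_structure)
  structure(list(events = events,
                 final_structure = final_structure,
                 final_vector = vec,
                 spans_bp = spans,
                 gene_dosage = gene_dosage(vec, map$genes),
                 str_copies = str_copy_counts(final_structure, map),
                 concurrent_capable = concurrent_capable(events, map)),
            class = "nahr_scenario")
}

# every event of the sequence is definable on the reference structure
concurrent_capable <- function(events, map) {
  if (length(events) < 2) return(length(events) > 0)
  ref <- reference_structure(map)
  all(vapply(events, function(ev) {
    ok <- try(nahr_event(ref, ev$kind, ev$mechanism, ev$left, ev$right),
              silent = TRUE)
    !inherits(ok, "try-error")
  }, logical(1)))
}

#' @export
print.nahr_scenario <- function(x, ...) {
  if (!length(x$events)) {
    cat("scenario: reference structure, no events\n")
  } else {
    cat("scenario (", length(x$events), " events",
        if (x$concurrent_capable) ", concurrent-capable", "):\n", sep = "")
    for (i in seq_along(x$events))
      cat(sprintf("  %d. %s  span %.3f Mb\n", i, format_event(x$events[[i]]),
                  x$spans_bp[i] / 1e6))
  }
  cat("  final vector:",
      paste(names(x$final_vector), unname(x$final_vector), sep = "=",
            collapse = " "), "\n")
  cat("  gene dosage:",
      paste(names(x$gene_dosage), unname(x$gene_dosage), sep = "=",
            collapse = " "), "\n")
  cat("  STR copies:",
      paste(names(x$str_copies), unname(x$str_copies), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Per-event genomic span lengths of a scenario
#'
#' Replays the scenario from the reference structure and reports, for each
#' event, the start-to-start distance between its recombining occurrences on
#' reference-projected coordinates (hybrid occurrences anchor to their
#' first-named source segment).
#'
#' @param scenario A `nahr_scenario`.
#' @param map The `azfc_map` the scenario was built on.
#' @return Numeric vector of per-event lengths in bp.
#' @export
scenario_span_lengths <- function(scenario, map) {
  struct <- reference_structure(map)
  spans <- numeric(length(scenario$events))
  for (i in seq_along(scenario$events)) {
    ev <- scenario$events[[i]]
    spans[i] <- event_span_bp(struct, ev, map)
    struct <- apply_event(struct, ev)
  }
  if (!identical(unname(as.integer(structure_vector(struct))),
                 unname(as.integer(scenario$final_vector))))
    stop("scenario replay does not reproduce its recorded final vector")
  spans
}

#' Gene-family dosage implied by a copy-number vector
#'
#' Each AZFc gene family resides in one amplicon family (PRY in blue, RBMY
#' in teal, BPY in green, DAZ in red, CDY in yellow). The dosage is
#' copies-per-host-segment times the host family's copy count, plus any
#' copies outside the modeled region (RBMY has four such copies, so its
#' reference total is six).
#'
#' @param vector A `copy_vector`.
#' @param genes Gene-family map: data.frame with columns `gene_family`,
#'   `host_family`, `copies_per_segment`, `external_copies` (an `azfc_map`
#'   is also accepted).
#' @return Named integer vector of gene-family copy counts.
#' @export
gene_dosage <- function(vector, genes = azfc_reference_map()) {
  if (inherits(genes, "azfc_map")) genes <- genes$genes
  vector <- as_copy_vector(vector)
  if (any(bad <- !genes$host_family %in% names(vector)))
    stop("unknown host amplicon family: ",
         paste(genes$host_family[bad], collapse = ", "))
  setNames(as.integer(genes$copies_per_segment * vector[genes$host_family] +
                        genes$external_copies),
           genes$gene_family)
}

#' Y-STR copy counts implied by a structure or copy-number vector
#'
#' DYS448 resides in the single-copy P3 spacer, so its copy count equals the
#' spacer count; DYF387S1 has one copy in each yellow amplicon, so its count
#' equals the yellow copy number. Given a structure, occurrences are counted
#' through their reference anchors.
#'
#' @param x A `chrom_structure` or a `copy_vector`.
#' @param map An `azfc_map` (supplies the STR anchor table).
#' @return Named integer vector of STR copy counts.
#' @export
str_copy_counts <- function(x, map = azfc_reference_map()) {
  anchors <- map$str_anchors
  strs <- unique(anchors$str)
  if (inherits(x, "chrom_structure")) {
    counts <- vapply(strs, function(s) {
      hosts <- anchors$segment[anchors$str == s]
      sum(x$anchor %in% hosts)
    }, integer(1))
  } else {
    v <- as_copy_vector(x)
    seg <- map$segments
    counts <- vapply(strs, function(s) {
      hosts <- anchors$segment[anchors$str == s]
      fam <- unique(seg$family[match(hosts, seg$id)])
      if (length(fam) != 1)
        stop("STR ", s, " anchors to segments of more than one family")
      if (fam == "spacer") v[["spacer"]] else v[[fam]]
    }, integer(1))
  }
  setNames(as.integer(counts), strs)
}

#' Export scenarios as JSON
#'
#' @param scenarios List of `nahr_scenario`s from [search_scenarios()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  out <- lapply(scenarios, function(s) {
    list(events = lapply(s$events, function(e)
      list(kind = e$kind, mechanism = e$mechanism,
           left = e$left, right = e$right, family = e$family)),
      spans_bp = s$spans_bp,
      final_vector = as.list(setNames(as.integer(s$final_vector),
                                      names(s$final_vector))),
      gene_dosage = as.list(s$gene_dosage),
      str_copies = as.list(s$str_copies),
      concurrent_capable = s$concurrent_capable)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
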