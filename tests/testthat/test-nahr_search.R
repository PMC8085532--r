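test_that("event enumeration respects direct-repeat orientation", {
  ref <- reference_structure(full_map)
  evs <- enumerate_events(ref)
  fams <- vapply(evs, `[[`, character(1), "family")
  # blue: only b1/b3 (+/+) and b2/b4 (-/-) are direct pairs -> 2 pairs x 3
  expect_equal(sum(fams == "b"), 6)
  # teal and yellow are palindrome arms (inverted), gray flanks inverted
  expect_equal(sum(fams %in% c("t", "y", "Gr")), 0)
  # green 3C2 pairs, red 4C2 pairs, all direct
  expect_equal(sum(fams == "g"), 3 * 3)
  expect_equal(sum(fams == "r"), 6 * 3)

  # a hypothetical fully direct 4-copy family: 4C2 = 6 pairs -> 18 events
  direct <- make_structure(c("a1", "u1", "a2", "u2", "a3", "u3", "a4"),
                           c("b", "unique", "b", "unique", "b", "unique", "b"),
                           rep(1L, 7))
  expect_length(enumerate_events(direct), 18)

  single <- make_structure(c("a1"), c("b"), 1L)
  expect_length(enumerate_events(single), 0)

  expect_error(nahr_event(ref, "deletion", "interchromatidic", "t1", "t2"),
               "inverted repeats")
  expect_error(nahr_event(ref, "duplication", "intrachromatidic", "b2", "b4"),
               "no duplication product")
  expect_error(nahr_event(ref, "deletion", "interchromatidic", "b3", "b1"),
               "strictly before")
  expect_error(nahr_event(ref, "deletion", "interchromatidic", "b1", "nope"),
               "stale")
})

test_that("applying the duplication then the deletion yields the observed vector", {
  ref <- reference_structure(full_map)
  dup <- nahr_event(ref, "duplication", "interchromatidic", "b2", "b4")
  after_dup <- apply_event(ref, dup)
  expect_identical(as.integer(structure_vector(after_dup)),
                   c(6L, 2L, 6L, 8L, 4L, 2L, 1L))
  # hybrid recorded as right/left with one copy of the family
  expect_true("b4/b2" %in% after_dup$occ)

  del <- nahr_event(after_dup, "deletion", "interchromatidic", "b1", "b3")
  final <- apply_event(after_dup, del)
  expect_identical(as.integer(structure_vector(final)), as.integer(m498_vector))
  expect_true("b1/b3" %in% final$occ)

  # deleting between adjacent copies only fuses the pair
  adj <- make_structure(c("a1", "a2"), c("r", "r"), c(1L, 1L))
  out <- apply_event(adj, nahr_event(adj, "deletion", "intrachromatidic", "a1", "a2"))
  expect_equal(nrow(out), 1)
  expect_equal(out$occ, "a1/a2")

  # stale ids error after the structure has changed
  expect_error(apply_event(final, dup), "stale")
})

test_that("interchromatidic products obey the conservation law", {
  ref <- reference_structure(full_map)
  prods <- sister_products(ref, nahr_event(ref, "duplication", "interchromatidic",
                                           "b2", "b4"))
  vdel <- as.integer(structure_vector(prods$deletion))
  vdup <- as.integer(structure_vector(prods$duplication))
  expect_identical(vdel + vdup, 2L * as.integer(structure_vector(ref)))
  expect_identical(vdel, c(2L, 2L, 0L, 0L, 0L, 2L, 1L))
  # spacer outside the exchanged span survives in both products
  expect_true(all(c(sum(prods$deletion$family == "spacer"),
                    sum(prods$duplication$family == "spacer")) == 1))

  # property: conservation holds for every enumerable exchange
  for (ev in enumerate_events(ref)) {
    if (ev$mechanism != "interchromatidic") next
    pr <- sister_products(ref, ev)
    expect_identical(as.integer(structure_vector(pr$deletion)) +
                       as.integer(structure_vector(pr$duplication)),
                     2L * as.integer(structure_vector(ref)))
  }
  del_intra <- nahr_event(ref, "deletion", "intrachromatidic", "b1", "b3")
  expect_error(sister_products(ref, del_intra), "interchromatidic")
})

test_that("scenario search reproduces the two-scenario inference", {
  # the reference vector needs no events
  none <- search_scenarios(full_map, reference_copy_vector(full_map))
  expect_length(none, 1)
  expect_length(none[[1]]$events, 0)

  scen <- search_scenarios(full_map, m498_vector, max_events = 2)
  expect_length(scen, 2)
  for (s in scen) {
    expect_length(s$events, 2)
    e1 <- s$events[[1]]; e2 <- s$events[[2]]
    expect_equal(e1$kind, "duplication")
    expect_equal(c(e1$left, e1$right), c("b2", "b4"))
    expect_equal(e1$mechanism, "interchromatidic")
    expect_equal(e2$kind, "deletion")
    expect_equal(c(e2$left, e2$right), c("b1", "b3"))
    # the deletion pair exists on the reference too: events could be concurrent
    expect_true(s$concurrent_capable)
    # replay determinism
    expect_identical(as.integer(s$final_vector), as.integer(m498_vector))
    expect_equal(scenario_span_lengths(s, full_map), s$spans_bp)
  }
  expect_setequal(vapply(scen, function(s) s$events[[2]]$mechanism, character(1)),
                  c("intrachromatidic", "interchromatidic"))
})

test_that("search equals the brute-force oracle over all short sequences", {
  for (obs in list(m498_vector,
                   copy_vector(4, 2, 3, 4, 4, 2, 1),  # only yellow doubled
                   copy_vector(6, 2, 6, 8, 4, 2, 1))) {
    got <- search_scenarios(full_map, obs, max_events = 2)
    want <- oracle_minimal_sequences(full_map, obs, max_events = 2)
    expect_setequal(vapply(got, function(s) event_signature(s$events), character(1)),
                    vapply(want, event_signature, character(1)))
  }
  # doubling yellow alone is unexplainable in two events: every duplication
  # spanning y1..y2 also adds green and red copies
  expect_length(search_scenarios(full_map, copy_vector(4, 2, 3, 4, 4, 2, 1), 2), 0)
  # no deletion-first ordering explains the observed vector: a b1/b3
  # deletion removes b2, leaving no direct blue pair to duplicate
  seqs <- oracle_minimal_sequences(full_map, m498_vector, 2)
  first_kinds <- vapply(seqs, function(ev) ev[[1]]$kind, character(1))
  expect_true(all(first_kinds == "duplication"))
})

test_that("events strictly shrink or grow the structure by their span content", {
  ref <- reference_structure(full_map)
  n0 <- nrow(ref)
  for (ev in enumerate_events(ref)) {
    out <- apply_event(ref, ev)
    if (ev$kind == "deletion") expect_lt(nrow(out), n0)
    else expect_gt(nrow(out), n0)
  }
})

test_that("span lengths project onto the reference coordinates", {
  scen <- search_scenarios(full_map, m498_vector, 2)[[1]]
  spans <- scenario_span_lengths(scen, full_map)
  expect_equal(spans, c(3.5e6, 1.6e6))
  # adjacent zero-gap copies: span equals the left copy's length offset
  ref <- reference_structure(full_map)
  ev <- nahr_event(ref, "deletion", "intrachromatidic", "r3", "r4")
  seg <- full_map$segments
  expect_equal(azfcnahr:::event_span_bp(ref, ev, full_map),
               seg$start[seg$id == "r4"] - seg$start[seg$id == "r3"])
})

test_that("gene dosage and STR copy counts follow the host families", {
  ref_v <- reference_copy_vector(full_map)
  expect_identical(gene_dosage(ref_v, full_map),
                   c(PRY = 4L, RBMY = 6L, BPY = 3L, DAZ = 4L, CDY = 2L))
  expect_identical(gene_dosage(m498_vector, full_map),
                   c(PRY = 4L, RBMY = 4L, BPY = 5L, DAZ = 6L, CDY = 4L))
  expect_identical(gene_dosage(copy_vector(0, 0, 0, 0, 0, 0, 0), full_map),
                   c(PRY = 0L, RBMY = 4L, BPY = 0L, DAZ = 0L, CDY = 0L))
  bad_genes <- data.frame(gene_family = "XYZ", host_family = "q",
                          copies_per_segment = 1, external_copies = 0)
  expect_error(gene_dosage(ref_v, bad_genes), "unknown host")

  expect_identical(str_copy_counts(ref_v, full_map),
                   c(DYS448 = 1L, DYF387S1 = 2L))
  scen <- search_scenarios(full_map, m498_vector, 2)[[1]]
  expect_identical(str_copy_counts(scen$final_structure, full_map),
                   c(DYS448 = 0L, DYF387S1 = 4L))
  expect_identical(str_copy_counts(m498_vector, full_map),
                   c(DYS448 = 0L, DYF387S1 = 4L))

  # fusing t1 and t2 removes the spacer (and DYS448) but keeps both y copies
  ref <- reference_structure(full_map)
  i <- match(c("t1", "t2"), ref$occ)
  fused <- make_structure("t1/t2", "t", 1L)
  fused$source <- "t1/t2"; fused$anchor <- "t1"
  after <- azfcnahr:::as_structure(rbind(ref[1:(i[1] - 1), ], fused,
                                         ref[(i[2] + 1):nrow(ref), ]))
  expect_identical(str_copy_counts(after, full_map),
                   c(DYS448 = 0L, DYF387S1 = 2L))
})

test_that("scenarios serialize to JSON", {
  scen <- search_scenarios(full_map, m498_vector, 2)
  out <- withr::local_tempfile(fileext = ".json")
  write_scenarios(scen, out)
  parsed <- jsonlite::read_json(out)
  expect_length(parsed, 2)
  expect_equal(parsed[[1]]$events[[1]]$kind, "duplication")
  expect_equal(parsed[[1]]$str_copies$DYF387S1, 4)
})
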