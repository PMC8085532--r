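---
title: "Depth-based AZFc rearrangement analysis: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-based AZFc rearrangement analysis: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azfcnahr)
```

## The problem

The AZFc region of the human Y long arm (~4.4 Mb) is built from six families
of nearly identical amplicons (blue *b*, teal *t*, green *g*, red *r*,
yellow *y*, gray *Gr*), mostly arranged in palindromes, with the single-copy
P3 spacer between the teal arms. Because the amplicon copies are almost
sequence-identical, non-allelic homologous recombination (NAHR) between them
repeatedly deletes, duplicates or inverts large blocks, with consequences for
spermatogenesis genes (PRY, RBMY, BPY, DAZ, CDY live in *b*, *t*, *g*, *r*,
*y* respectively) and for forensic Y-STRs: DYS448 sits in the P3 spacer and
the two-copy DYF387S1 in the yellow amplicons, so a null allele at DYS448 or
a tri/tetrallelic DYF387S1 pattern flags a structural rearrangement rather
than a mixture of contributors.

This package implements the full analysis chain for such a case: call
amplicon copy numbers from whole-genome sequencing depth, confirm them with a
smoothed depth profile against controls, enumerate the NAHR event sequences
that can produce the called copy-number vector, and date the carrier lineage
from Y-STR diversity. A synthetic-data layer generates depth and haplotypes
with known truth so that every stage is testable without sequencing data.

## The reference model

The bundled map (`azfc_reference_map()`) lists the ordered segments
Gr1, b1, t1, P3 spacer, t2, b2, IR1, g1, r1, r2, b3, y1, g2, r3, r4, g3, y2,
b4, Gr2 on GRCh37 chrY, plus a 1-Mb single-copy normalization interval in the
X-degenerate portion of Yq, clear of ampliconic sequence. The coordinates are
schematic (the file is labelled synthetic): they honour the published segment
order, the family copy counts (b=4, t=2, g=3, r=4, y=2, Gr=2, one spacer),
and the two span lengths that matter for the inference — b2→b4 start-to-start
exactly 3.5 Mb and b1→b3 exactly 1.6 Mb. Both gray copies are placed outside
the b1–b4 span: a rearranged chromosome carrying the b2/b4 duplication and
b1/b3 deletion shows the gray family unchanged at 2/2, which is only possible
if no gray copy lies inside the rearranged block.

Orientations follow the direct-repeat pairs through which AZFc NAHR is
actually observed: b1/b3 deletions and b2/b4 duplications/deletions occur
between direct repeats, while b2/b3 NAHR needs a prior inversion — so the
blue copies alternate (b1 +, b2 −, b3 +, b4 −), the teal copies are the
inverted arms of the P3 palindrome, yellow and gray are likewise modeled as
inverted pairs, and green/red are direct. This assignment is load-bearing:
with all blue copies direct, a b1/b2 deletion followed by a b3/b4 duplication
would reproduce the observed copy vector with the deletion first, and the
order-infeasibility argument below would not hold.

The gene-dosage table assigns one gene copy per host segment, except RBMY,
which also has four copies outside the modeled region, giving the reference
totals PRY=4, RBMY=6, BPY=3, DAZ=4, CDY=2. The PRY reference total is not
printed anywhere we could verify; one copy per blue segment is the modeling
choice that leaves PRY unaltered under the inferred rearrangement, consistent
with how the rearrangement is described.

## Copy-number calling from depth

For each family the per-base depth is averaged over the union of all its
copies (equivalent to per-copy averaging when copies have equal length, and
well defined when they do not) and divided by the mean depth of the 1-Mb
single-copy interval. A family at the reference copy number then sits at 1,
and a chromosome with $k$ copies at $k/\mathrm{ref}$. Calling is midpoint
thresholding: accept $k$ when the normalized depth lies in
$[(k-0.5)/\mathrm{ref},\,(k+0.5)/\mathrm{ref})$, i.e. for a two-copy family
the one-copy window is $[0.25, 0.75)$ and anything below 0.25 is a zero-copy
call. Intervals are half-open and lower-inclusive; the published description
does not say which side a boundary hit belongs to, and exact hits are
measure-zero on real data, so the choice is a convention, frozen here. The
largest callable copy number defaults to three times the reference per
family; values beyond it clamp with a warning rather than fail, since a
grossly amplified family is still a finding worth reporting.

Depth is consumed from pre-extracted per-base tables (3-column `samtools
depth` style or 4-column bedGraph), not BAM, keeping the pipeline free of
alignment I/O. Positions of a requested interval that are absent from the
file count as depth 0, matching the convention that depth dumps omit zero
rows; a flag keeps them as missing instead for dumps known to be complete.

## The smoothed-profile confirmation

The confirmatory view smooths per-base depth with an exponential moving
average over a 50-kb window stepped 1 bp: smoothing ratio $2/(n+1)$, seeded
with the simple mean of the first $n$ values, burn-in excluded. The test
profile is divided position-wise by the arithmetic mean of the control
profiles (per-control output is available behind a flag; with two controls
the published description does not specify the aggregation, and the mean is
the natural symmetric choice). A ratio near 1 inside an amplicon means
reference copy number; the rearranged chromosome shows ~2 across yellow,
~0 across teal and the spacer, ~5/3 and ~3/2 across green and red. The EMA
lags a window behind structure boundaries, so segment-level comparisons with
the interval-mean method skip one window at each segment entry; within that
tolerance the two methods agree on simulated data, as they did on the real
samples. The EMA is visual confirmation only — no change-point detection or
breakpoint refinement is attempted, since depth cannot localize NAHR
breakpoints inside near-identical repeats anyway.

## NAHR scenario search

The chromosome is an ordered list of segment occurrences. An NAHR event is an
unequal crossover between two same-family, same-orientation occurrences
(direct repeats): a deletion removes everything strictly between them and
fuses the pair into one hybrid occurrence (`b1/b3`), either within one
chromatid (intrachromatidic) or between misaligned sister chromatids
(interchromatidic); a duplication is the reciprocal interchromatidic product,
leaving the intervening span twice plus a hybrid (`b4/b2`) between the two
copies. Hybrids are full-fledged repeats available to later events — this is
what makes order-infeasibility a checkable property rather than an
assumption. Inversions (between inverted repeats) are excluded: they do not
change copy number, so the observable consumed here cannot detect them.

`search_scenarios()` exhaustively enumerates ordered event sequences from the
reference, regenerating the event catalog after each event, and returns all
minimal-length sequences whose family + spacer counts equal the observed
vector. The search is capped at three events (default two): the catalog has
33 events on the reference structure and grows after duplications, so the
sequence space grows factorially, while the inference of interest needs two
events. For the observed vector (b=4, t=0, g=5, r=6, y=4, Gr=2, spacer=0)
the search returns exactly two scenarios — an interchromatidic b2/b4
duplication followed by a b1/b3 deletion, intra- or interchromatidic — and
no deletion-first sequence: the b1/b3 deletion removes b2, leaving no direct
blue pair to duplicate. Both scenarios are flagged concurrent-capable
because the deletion pair already exists on the reference structure, so the
two exchanges could equally have happened in the same meiosis; copy-number
data cannot distinguish simultaneity from succession. A deletion targeting
the post-duplication copy of b3 is *not* returned: replay shows it leaves
only two blue copies, so the apparent ambiguity of two b3-like targets does
not survive the arithmetic.

Span lengths are reported per event as the start-to-start distance between
the recombining occurrences projected onto reference coordinates (hybrids
anchor to their first-named source), giving 3.5 Mb for the duplication and
1.6 Mb for the deletion on the bundled map. Gene dosage follows the host
families: RBMY drops from six to four copies (both teal copies lost, four
external copies remain), BPY/DAZ/CDY each gain two, PRY is unchanged; the
Y-STR consequences are DYS448 = 0 (spacer lost) and DYF387S1 = 4 (yellow
doubled), the null-allele/tetrallelic signature that motivates the analysis.

## ASD dating

Cluster ages are estimated with the average squared distance (ASD) method
over a 16-locus panel: Yfiler Plus minus the multi-copy loci (DYS385a/b,
DYF387S1), the interrupted DYS389II, DYS448 (deleted in the carriers) and
the kit's rapidly mutating loci. The founder is the cluster's modal
haplotype (ties broken by minimizing total squared distance, then by the
smaller allele); a user-supplied founder is accepted. Per locus, ASD is the
mean squared allele difference from the founder; averaged over loci and
divided by the panel-averaged mutation rate it estimates the age in
generations, times 25 years per generation by default. Under the single-step
stepwise mutation model (SMM) the per-locus expectation is $\mu_l G$, so the
estimator is unbiased when the founder is known and very nearly so when the
modal haplotype recovers it, which at realistic time depths it almost always
does.

Three conventions here are implementation choices, stated explicitly because
the source analyses leave them open: the generation interval (25 years;
always printed with the estimate), the founder convention (modal haplotype),
and the standard error (dispersion of the per-locus age estimates across
loci divided by $\sqrt{n_{\mathrm{loci}}}$ — an across-locus convention, not
a coalescent variance). The bundled rate table is a calibrated compilation
of published-magnitude per-locus germline rates whose panel mean is exactly
3.18e-3 per marker per generation, the averaged rate the dating uses; with
it, an ASD of 1/16 (one mutation step across the panel) converts to 19.65
generations ≈ 491 years. Microvariant (non-integer) alleles are rejected
with a clear error: squared distances on partial repeats are undefined.
Median-joining network construction is out of scope — clusters are user
input.

## The synthetic-data layer

`simulate_depth()` emulates the one property of ampliconic sequencing depth
the methods rely on: multi-mapping collapse. Reads from every copy of a
family pile onto the family's reference segments, so expected depth over a
family segment is `base_coverage * copies / reference copies`; the spacer
scales with its own count and single-copy sequence sits at `base_coverage`.
Per-base noise is Poisson (or none, for exact expectations). Real depth is
overdispersed and GC- and mappability-biased; Poisson is deliberate — it is
enough to exercise the thresholds, and the calling margins are so wide at
30–40× over ≥100-kb (or toy-scale ≥1-kb) intervals that miscalls are
vanishingly rare. Passing tests therefore demonstrate the logic of the
calling chain, not robustness to alignment artifacts, reference errors or
partial-span rearrangements, none of which are modeled.

`simulate_haplotypes()` evolves lineages independently from a founder under
the strictly single-step symmetric SMM — the standard model behind these
Y-STR clock calculations; multi-step mutations are excluded. A mutation that
would drive an allele to zero reflects to a +1 step with a warning; founder
alleles sit far from that boundary, so reflection never fires at realistic
time depths.

`make_toy_map()` scales all map coordinates by a factor (default tests use
0.01), preserving order, adjacency, counts and orientations, so simulations
cover ~63 kb instead of ~6.3 Mb and the whole pipeline runs in seconds. The
problem sizes used throughout the tests and the analysis scripts — toy-scale
depth at 30–40×, 500-tip moment checks, 2,000-replicate parameter-recovery
batches of 4-tip clusters — were chosen to make Monte-Carlo error a small
fraction of the assertion tolerances at interactive runtimes.

## Known limitations

* Copy-number observables cannot distinguish structures with identical
  family counts; scenarios are therefore reported at event-pair resolution,
  and breakpoint positions inside repeats are not inferred.
* The published ± values for the real cluster ages (492 ± 74 and
  2,738 ± 410 years) depend on the original haplotype data and on founder,
  generation-interval and SE conventions that are not restated with them;
  this package reproduces the method and its analytic identities, not those
  two printed numbers.
* The bundled map is a constraint-faithful schematic, not a base-accurate
  coordinate list; span lengths are exact on it by construction.
* Depth is taken as given; extraction from BAM, GC correction and
  mappability masking are upstream concerns.
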