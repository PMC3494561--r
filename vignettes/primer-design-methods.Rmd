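---
title: "Evolutionary design of specific PCR primer pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary design of specific PCR primer pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoprimer)
```

## The problem

A PCR experiment succeeds or fails largely on its primer pair.  A good
pair must satisfy many constraints at once: primer lengths in a usable
window, similar lengths and melting temperatures, moderate GC content,
a product of the intended size, no stable primer dimers or hairpins, a
G/C at each 3' end, and — critically for *specific-product* design —
exactly one binding site per primer on the template.  evoprimer treats
this as a combinatorial optimization problem: a candidate pair is a
four-integer chromosome

\[(f_\mathrm{start},\; f_\mathrm{len},\; a_\mathrm{len},\; r_\mathrm{len}),\]

the forward primer's 5' position, both primer lengths, and the
amplicon length.  Decoding reads the forward primer off the plus
strand and the reverse primer as the reverse complement of the
amplicon's last \(r_\mathrm{len}\) bases.  All coordinates are 1-based
and inclusive, so a product bounded by a forward 5' end at 212 and a
reverse 5' end annealing at 707 has length \(707-212+1 = 496\) bp.

## The penalty (fitness) function

Each constraint contributes a non-negative penalty: range constraints
(length, GC%, Tm, product size) contribute their distance outside the
interval; difference constraints (length difference, Tm difference)
the excess over the allowed maximum; dimer and hairpin constraints the
excess of the longest contiguous annealing run over the threshold; a
missing GC clamp costs 1 per primer; and specificity costs 1 per
off-target binding site beyond the single intended one per primer.
The total is a weighted sum, **lower is better**, and a total of 0
means every constraint is met.  Note the orientation: "fitness" in the
GA literature is often higher-is-better; here the ranking sorts
ascending.

Weights are 1 everywhere except specificity, weighted 10, so one
off-target site always outweighs mild property violations.  The
weighted-sum form was chosen because it is transparent, tunable, and
makes "penalty 0" coincide exactly with feasibility; the weights are
exposed (`default_weights()`) rather than hard-coded.  Primers
containing `N` receive an infinite penalty and can never be selected.

## Melting temperature

The default Tm is the nearest-neighbor model with the unified
dinucleotide parameter set (SantaLucia 1998):

\[T_m = \frac{\Delta H}{\Delta S + R\,\ln(C_T/x)} - 273.15
  + 16.6\,\log_{10}[\mathrm{Na^+}],\]

with \(\Delta H, \Delta S\) summed over adjacent dinucleotide stacks
plus terminal initiation terms, the symmetry entropy correction
(−1.4 cal mol⁻¹ K⁻¹) for self-complementary sequences, \(x = 4\) for
non-self-complementary duplexes and 1 otherwise, and \(R\) the gas
constant.  Defaults are 0.05 M Na⁺ and 250 nM total strand — common
design defaults, both configurable via `thermo_conditions()`.  The
classic empirical formula \(81.5 + 16.6\log_{10}[\mathrm{Na^+}] +
0.41\,\mathrm{GC\%} - 675/\mathrm{length}\) is available as
`tm_gc_salt()` and selectable with `tm_method = "gc_salt"`.

A practical consequence of the NN model at 50 mM Na⁺ is that random
18–21-mers with 40–60% GC rarely reach 50 °C; under the default Tm
window (50–62 °C) feasible pairs are dominated by 22–24-mers.  This is
physically sensible, not a defect, but it is why the small-template
study below lowers the Tm floor to 45 °C for 18–20-mers.

## Secondary-structure markers

Five markers are computed per pair: cross-dimer, two self-dimers, two
hairpins, GC clamps, and internal specificity.

* **Dimers** are scored by an ungapped sliding alignment of one primer
  against the reverse of the other, counting Watson-Crick pairs at
  every offset (no G·T wobble, `N` never pairs).  The report keeps the
  offset maximizing total matches, with ties broken toward the larger
  contiguous run and then the smaller offset.  The *constraint* is
  applied to the contiguous run — contiguous 3'-stable stretches are
  what dimer screens flag — while the total is retained for reporting.
* **Hairpins** evaluate every stem1/loop/stem2 partition with loop
  ≥ 3 nt (the sterically minimal loop), zipping the stems antiparallel
  outward from the loop.
* **Specificity** scans the supplied template(s) only (an "internal"
  check): each primer must have exactly one binding site, on the
  correct strand, within the allowed mismatch count (default 0).
  Genome-scale external screening (e.g. BLAST) is deliberately out of
  scope.

All three scanners are validated against independent exhaustive
brute-force implementations in the test-suite.

## The search: GA and MA

The engine is a generational GA over the 4-gene chromosome:
tournament selection of size 2, two-point crossover with probability
0.8, per-gene uniform re-sampling mutation with probability 0.05,
repair by clamping into the valid index space, and elitist
replacement (the best individual always survives, so the best penalty
is non-increasing across generations).  The memetic variant (default)
additionally applies steepest-descent local search — best strictly
improving ±1 neighbor over the four genes, iterated to a local
minimum — to the initial population and to every offspring.

Defaults are a population of 50 and five independent runs (run *i*
seeded with `seed + i`), with 100 generations per run; a run stops
early once it reaches penalty 0, which is the global lower bound.
Each run returns its best individual; candidates are de-duplicated
and ranked.  Everything is deterministic given the seed, and the
caller's RNG state is restored on exit.

The operator variants (tournament of 2, two-point crossover, clamping
repair, textbook per-offspring local search) were genuinely open
design choices; they were picked as the simplest standard forms that
keep the engine easy to reason about and test.  Repair-by-clamping
was preferred over rejection because it keeps the population size
constant and the search smooth.

## Ranking and reporting

Candidates are sorted lexicographically by (total penalty, Tm
difference, forward start); rank 1 is best.  The combination of
penalty and ΔTm could also be arithmetic — a weighted sum is exposed
via `rank_pairs(score = "weighted")` — but the lexicographic order is
the minimal reading of "rank by fitness and Tm difference" and is the
default.  The plain-text report echoes every constraint and algorithm
parameter, then per pair: sequences (5'→3'), lengths, positions
(from–to, the reverse primer given as the plus-strand coordinates of
its binding site), GC count and GC%, Tm and Tm difference, product
size, and a structure-marker line.  Reports are byte-deterministic
(no timestamp unless `stamp = TRUE`), which the test-suite exploits.

## In-silico PCR and the virtual gel

`simulate_pcr()` pairs every plus-strand site of the forward-acting
primer with every downstream minus-strand site of the reverse-acting
primer on the same template (both primer orientations are tried, as
real PCR would; `strict_orientation` disables this), capping products
at 4000 bp by default.  With mismatches allowed, the 3'-terminal base
must still match exactly — a terminal mismatch blocks extension.
Amplicons can be turned back into design templates
(`amplicon_as_template()`), supporting iterative redesign; the record
id encodes the origin coordinates.

The virtual gel uses the standard log-linear agarose mobility model:
distance from the well is proportional to
\(\log_{10}(\text{size}_{\max}) - \log_{10}(\text{size})\), anchored
to a 100–1500 bp window matching the default 100-bp ladder, clipped at
the lane ends.  The real migration behavior of any particular gel rig
is not published for this class of tools; this model is a documented,
monotone stand-in that preserves band ordering and approximate
spacing.  Bands closer than one render unit in a lane are flagged as
co-migrating.  Renderers emit deterministic ASCII or SVG;
`compare_bands()` reports expected-vs-observed deltas in bp and in
distance.

## The fixture generator

`make_fixture()` builds the synthetic study material: a random
background of configurable GC content with `n_feasible`
non-overlapping planted amplicons whose primer pairs are
rejection-sampled to satisfy *every* constraint, then verified with
`evaluate_pair()` on the finished template (penalty 0) and rebuilt in
the rare case of a cross-slot specificity collision.  It is fully
deterministic per seed.  What it emulates: templates that contain at
least one (or exactly zero, for GC-poor backgrounds) fully feasible
pair under known coordinates, so search results can be checked against
ground truth.  What it does not emulate: repeat structure,
low-complexity runs, ambiguity codes, and base-composition biases of
real genomic sequence — so passing the recovery study shows the
search works on its index space, not that real templates always admit
feasible primers.

## Problem sizes and numerical choices

The optimum-recovery study uses 50 independently seeded 120-bp
fixtures with primer lengths 18–20, products 60–100 bp and a Tm
window of 45–62 °C — a space of ~15 000 chromosomes per template,
small enough for exhaustive enumeration to provide the certified
global optimum while leaving the evolutionary search a real job.  The
memetic search with default budgets recovers the enumerated optimum
in ≥95% of trials, and its mean best penalty is never worse than the
GA's at paired seeds — the measurable form of "local search improves
results".  GC% is rounded half-up to two decimals (matching how such
tables are printed); Tm is reported to two decimals but compared at
full precision internally.  Ties in the dimer scan are resolved
deterministically (larger run, then smaller offset), so identical
inputs always give identical reports.

## Known limitations

* Dimer/hairpin scoring is combinatorial (match counting), not
  thermodynamic (ΔG); gapped annealing alignments are not considered.
* Specificity is internal to the supplied templates; no genome-wide
  screen.
* Printed Tm values in legacy primer tables often mix formulas and
  ionic conditions; this package's two formulas are documented and
  reproducible, but they will not in general reproduce numbers whose
  generating conditions are unknown.
* The amplicon model ignores primer efficiency and yield; the gel
  model ignores band intensity and gel-to-gel curvature.
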