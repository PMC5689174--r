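---
title: "retroburst: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retroburst: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Related fungal species can differ several-fold in genome size while sharing
most of their gene content.  In Boletales and other basidiomycetes the
dominant driver of such expansion is the amplification of LTR
retrotransposons — mobile elements bounded by two long terminal repeats
(LTRs) that are sequence-identical at the moment of insertion.  Because the
two repeats subsequently diverge independently under the neutral clock,
each full-length element carries its own timestamp: align its two LTRs,
correct the observed divergence for multiple substitutions, divide by twice
the substitution rate, and you have its insertion age.  A histogram of ages
across all elements ("burst profile") reveals when a genome went through
amplification episodes — recent bursts (0–5 million years) indicate
currently active elements, old peaks (25–30 MY) indicate ancient expansions
whose copies have been decaying since.

`retroburst` implements this analysis chain end to end at desk scale —
simulation with known ground truth, structural detection, superfamily
classification, Kimura-2P dating, census, reverse-transcriptase phylogeny —
plus the accompanying secretome GO-term enrichment statistic.  Every stage
is testable against the synthetic generator, which is first-class code, not
a fixture.

## The dating model

For one element with trimmed LTR alignment of `n` usable columns, `P` is
the proportion of transitions (A↔G, C↔T) and `Q` the proportion of
transversions.  The Kimura two-parameter distance is

    K = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]

and the insertion age is `T = K / (2r)` with `r = 1.05e-9`
substitutions/site/year, the fungal rate used throughout; the factor 2
reflects that *both* LTRs accumulate substitutions.  When `1 - 2P - Q <= 0`
or `1 - 2Q <= 0` the distance is undefined (saturated divergence); such
elements are flagged undatable and excluded from burst profiles rather than
clamped to a maximum age, which would fabricate a bin.

Numerical notes:

* `kimura2p(0.1, 0.05)` evaluates to `0.1701812`; the two algebraic forms
  `-½ln[(1-2P-Q)√(1-2Q)]` and `-½ln(1-2P-Q) - ¼ln(1-2Q)` agree to 1e-12 and
  both are tested.
* In the small-divergence limit `K → P + Q` (relative error < 2% for
  `P + Q <= 0.01`); `K` is strictly increasing in both `P` and `Q` on the
  valid domain.
* Burst profiles use half-open 5-MY bins `[i·5, (i+1)·5)` MY by default;
  ages at or beyond `max_age` (default 50 MY) pool into the last bin.

A cohort simulated *exactly at* a bin edge (e.g. all elements 5 MY old)
splits its estimated ages ~50/50 between the two adjacent bins — the modal
bin of such a cohort is a coin flip, not a property of the method.  The
package's bin-level recovery tests therefore use bin-centre cohorts (2.5
and 27.5 MY), while mean-age recovery is asserted at 5 and 25 MY, where it
is well-posed (±15% at n = 100 elements with 500-bp LTRs).

## What the simulator states (and does not)

The generator (`simulate_background`, `family_template`, `age_ltr_pair`,
`insert_elements`) emulates:

* a random i.i.d. background genome with configurable GC (no real genome
  structure: no isochores, genes, or pre-existing repeats);
* full-length elements `[LTR5][internal][LTR3]` whose internal region
  carries reverse-translated copies of the bundled reference peptides in
  the canonical order — GAG, protease, RT, RNase H, integrase for Gypsy
  (plus a chromodomain after the integrase for the Chromoviridae layout);
  GAG, protease, integrase, RT, RNase H for Copia;
* insertion with a 4–6 bp target-site duplication (TSD), uniform over
  {4,5,6} — the typical LTR-element range;
* LTR divergence: per site a Poisson(`r·T`) number of substitutions applied
  sequentially, each a transition with probability `transition_fraction`
  (default 0.5, i.e. α = 2β, exactly the process the K2P estimator
  corrects) and otherwise one of the two transversions uniformly.  Both
  copies evolve independently, so expected pair divergence ≈ `2rT` minus
  multiple-hit saturation.  Tests verify the mean pair mismatch against the
  analytic jump-chain expectation (matrix exponential) out to 50 MY;
* optional degenerate copies: 5′- or 3′-truncations removing a uniform
  20–80% of the element, and solo LTRs (one aged repeat plus TSD), planted
  rather than evolved;
* indels default off, and when enabled touch only internal regions, so
  LTR-pair dating stays exact and alignment trimming is tested separately.

Two deliberate restrictions make truth well-defined:

* **No nested insertions** and no recombination between LTRs (solo LTRs are
  planted, not generated by ectopic recombination).
* **Boundary-unambiguous planting**: if the background base adjacent to the
  target site coincided with the element's terminal base, a shifted element
  reading with a different TSD would be *equally valid* — no detector could
  recover "the" truth.  The simulator nudges the insertion point (≤ 8 bp)
  until the planted boundary is unique.  Real genomes contain such
  ambiguous insertions; for them, single-base boundary uncertainty is
  irreducible.

A green test against this world therefore establishes correctness of the
algorithms under the stated model — not performance on real assemblies with
nesting, segmental duplications, assembly gaps, or non-LTR repeats.

## Structural detection

Detection is LTRharvest-style: exact 20-mer seed pairs on the same strand
with start spacing 1–15 kb, grouped into collinear chains (offset tolerance
`band_width`), extended outward by ungapped X-drop extension (+2/−3, drop
25), boundaries snapped to the best flanking TSD, then filtered on LTR
length (100–1500 bp), spacing, pair identity (≥ 0.80 over all aligned
columns, N counting as mismatch) and optionally TSD presence.  All
parameters are config-exposed; the defaults mirror common LTRharvest
settings because no specific values are canonical.

Design choices worth knowing:

* **Ungapped extension.** The simulated LTR pairs are indel-free by
  construction, so banded *gapped* extension buys nothing; `band_width`
  survives as the chain offset tolerance.
* **TSD-guided boundary refinement.** Score-argmax extension overshoots by
  1–3 bp whenever a flanking base matches by chance (~25% per side).
  Candidate boundary shifts within ±6 bp (total) are scored by
  `TSD length − total shift`: a true TSD viewed from a boundary overshot by
  `d` appears truncated to `L − d`, so the true reading always outscores
  its truncated shadows, while unrelated duplications at large shifts are
  penalised away.  Pure longest-first and pure nearest-first rules each
  misplace a meaningful fraction of boundaries.
* **Exact overlap resolution.** Adjacent copies of one family generate
  chimeric cross-element pairings (ltr3 of copy A with ltr5 of copy B)
  whose scores tie with the true candidates.  Greedy selection can pick the
  chimera and suppress both neighbours; weighted interval scheduling
  maximises total score and provably prefers the two true candidates.  A
  containment filter additionally drops any candidate strictly spanning
  another accepted candidate — impossible for genuine elements in a world
  without nesting.
* **Degenerate copies.** Solo LTRs and truncated copies still create
  chimeras that are *structurally indistinguishable* from full elements
  (two similar repeats, legal spacing, occasionally a chance TSD).  In
  repeat-dense simulations the recommended profile is `require_tsd = TRUE`
  plus domain confirmation (keep `superfamily != "unknown"`), mirroring the
  practice of confirming structural candidates with coding evidence.

## Classification

Candidates are translated in six frames and scanned (Smith–Waterman,
BLOSUM62, gap 10/0.5) against a bundled peptide library.  The library is
**synthetic** — seeded random peptides standing in for references that
cannot be redistributed; files are suffixed `_synthetic` and regenerated by
`data-raw/make_domain_library.R`.  Per-domain score thresholds are frozen
at the scan-level 99% no-hit quantile of a 500-replicate Monte-Carlo null
(random 3-kb sequences, best score over a domain's references and all six
frames, per-domain quantile `0.99^(1/6)` so the whole-library false-hit
rate is ~1%).

Classification is by domain order on the coding strand (the strand of the
best RT hit): RT before integrase ⇒ Gypsy; integrase before RT ⇒ Copia;
either missing ⇒ unknown.  Chromoviridae = Gypsy with a chromodomain
starting after the integrase.  The invariant *chromoviridae ⇒ Gypsy* is
enforced structurally.  Frameshift tolerance: hits of one element may come
from different frames; ordering uses nucleotide start coordinates only.

## Census

Families are single-linkage clusters at the 80/80 convention (pairwise
identity ≥ 0.80 over ≥ 0.80 of both lengths; a 12-mer Jaccard prefilter
skips alignments between unrelated sequences).  Consensus building is a
star alignment to the longest member with per-column majority vote, ties
resolving to the longest member's base.  Copy annotation is seed-and-extend
per consensus against both strands; each chain is extended along its
diagonal and trimmed to the maximum-scoring segment (+2/−3 Kadane), which
stops honestly at a truncated copy's boundary.  Overlapping hits of one
family merge; `fraction_of_consensus` is the merged genome span over the
consensus length (equal to consensus coverage in the indel-free world, and
immune to a solo LTR matching both terminal repeats of its consensus).
"Full-length copy" means fraction ≥ 0.95 — the strictest round threshold
compatible with curating a library to families that retain at least one
full copy; it is config-exposed.  Coverage percentages are unions of
annotated intervals over assembly length (never sums), including N runs in
the denominator; per-order and TOTAL rows are unions too.  "Copies" counts
merged chains, not raw hits.

## Phylogeny

RT peptides (best RT hit per family, internal stops kept as `*` but scored
as `X`) are aligned by an authored progressive aligner: 3-mer Jaccard guide
tree (average linkage), profile–profile Needleman–Wunsch with affine gaps
under BLOSUM62 (gap of length L costs `open + L·extend`), then columns with
> 50% gaps dropped.  With two sequences this reduces exactly to optimal
pairwise global alignment, which the tests verify against an independent
implementation.  Distances are Poisson-corrected p-distances
(`d = −ln(1 − p)` over mutually ungapped columns; raw p-distance is the
config-exposed alternative); saturated pairs (`p ≥ 1`) raise an error
advising taxon removal.  Tree inference is canonical neighbor joining
(ape's Saitou–Nei implementation; negative branch lengths clamped to 0) —
a deliberate replacement of approximate maximum likelihood with SH
supports: deterministic, dependency-free, and consistent (exact topology
recovery on additive matrices, which the tests check against brute-force
quartet oracles).  Supports are nonparametric bootstrap proportions over
column resampling, deterministic given the seed.  Outgroup rooting places
the root at the midpoint of the outgroup's pendant edge; the bundled
outgroup is synthetic.  What is preserved from the original analysis is
the *acceptance surface* — clade recovery on synthetic families — not any
particular support values.

## Enrichment

For each GO term, a 2×2 table contrasts the secretome subset with the
genome: `a` subset genes with the term, `b` without, `c` non-subset genes
with the term, `d` the rest.  The genome column *includes* the subset
(`a + c` is the genome-wide count), matching published tables where the
genome count is always ≥ the subset count; a disjoint background is
config-exposed.  The test is the one-sided (enrichment-only) Fisher exact
test: the upper hypergeometric tail `P(X ≥ a)` summed exactly in log space
(`lchoose` + log-sum-exp), verified against plain enumeration to 1e-12 for
populations ≤ 30.  Bonferroni correction uses `m` = the number of terms
actually tested after the `min_genome_count` filter; published corrected
values are therefore reproduced as *bounds* (raw p ≤ corrected p), not
equalities, since the original `m` is unknown.  Annotations are taken as
given — no GO-graph propagation.

## Determinism and seeds

One global seed is fanned out per stage by hashing the stage label
(`derive_seed`), so toggling one stage never shifts another's random
stream.  All stochastic operations accept explicit seeds; identical
config + seed yields byte-identical FASTA/GFF3/TSV outputs (hash-compared
in the tests).  All derived seeds stay below 2^31.

## Known limitations

* Detection assumes co-oriented, indel-free LTR pairs; inverted or
  internally rearranged elements are invisible by construction.
* The synthetic domain library supports algorithm testing only; real
  annotation requires real reference peptides (Repbase/Pfam), supplied via
  `load_domain_library()`.
* Single-element ages carry large stochastic error (a 350-bp LTR pair at
  2.5 MY yields zero differences ~16% of the time); only cohort-level
  statements are supported.
* Coverage figures quantify the consensus library's footprint, not total
  repeat content: non-LTR repeat classes are out of scope.
* The enrichment stage tests the table as given; terms are not propagated
  up the GO hierarchy.
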