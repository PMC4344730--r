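---
title: "Detecting a conserved non-autonomous Helitron and screening it for horizontal transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a conserved non-autonomous Helitron and screening it for horizontal transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helhunt)
```

## The problem

Helitrons are class II DNA transposons that propagate by rolling-circle
replication. Non-autonomous family members carry no coding capacity, so the
only reliable handles for finding them are primary-sequence and structural
diagnostics: a 5'-TC (often TCC) terminus, a 3'-CTRR terminus (R = A/G,
typically CTAG), a GC-stabilised stem-loop just upstream of the 3' terminus,
a 5' inverted repeat (5'-IR), base pairing between 5' and 3' subterminal
regions (SIR), and — in the lepidopteran Hel-2 family this package is built
around — a variable-length tetranucleotide microsatellite such as (CTGT)n.
New copies insert between AT or TT dinucleotides and leave no target-site
duplication.

Because Hel-2 copies are strikingly similar across moth and butterfly
species whose genomes diverged long ago, they are candidates for horizontal
transposon transfer (HTT): movement of the element between species other
than by descent, plausibly shuttled by insect viruses. The comparative
signature of HTT is that TE-to-TE identity between two species *exceeds*
the identity of an orthologous housekeeping marker (here RpS5 by default),
and that the TE phylogeny disagrees with the species phylogeny.

`helhunt` implements that whole chain — homology scan, structural
annotation, alignment and identity matrices, the comparative-divergence HTT
screen, and distance/likelihood phylogenetics — together with a simulator
that generates genomes with planted elements under vertical or horizontal
inheritance, so every stage can be verified against known ground truth
without downloading anything.

## Homology scanning

`local_align()` is an affine-gap Smith–Waterman search on both strands with
blastn-like scoring (+2/−3, gap open 5, extend 2; a gap of length L costs
`open + L * ext`). Suboptimal hits are extracted by greedily masking the
subject span of each reported hit and re-aligning, down to a score floor
set to the score a 50 bp, 65 %-identity gapless alignment would achieve —
the same quantity that anchors the retention filter, so nothing the filter
could keep is ever discarded early. Significance uses the Karlin–Altschul
form `E = K m n exp(-lambda S)`; `karlin_lambda = 0.634` solves the
ungapped stationarity equation for +2/−3 at uniform base frequencies and
`karlin_K = 0.41` is a conventional value. Both are documented constants,
not estimates: the package is meant to be reproducible, not to re-derive
database statistics.

`filter_hits()` keeps a hit when identity ≥ 65 %, E ≤ 1e−5, and the
alignment either spans the whole query (with a 5 bp end slack, so terminal
motif erosion does not demote complete copies) or anchors at least 50 bp at
the query 5' or 3' end — the partial classes capture copies whose other
terminus has been obscured by later insertions or substitutions. Identity
counts gap columns in the denominator (BLAST-style); the ungapped variant
is available wherever identities are computed.

## Structural annotation

`find_termini()` takes the leftmost TC in the first 30 bases and the
rightmost CTRR ending in the last 30; flanking bases are read from host
context when available and checked against the A/T integration-site rule.

`fold_hairpin()` minimises a DNA nearest-neighbour free energy over
contiguous-stem hairpins (stem ≥ 4 pairs, ≤ 2 internal mismatches,
terminal pairs required to close the stem, loop 3–30 nt). Stacking uses
the unified duplex parameters (37 °C, 1 M NaCl); the loop penalty is
linear (3.5 kcal/mol at the minimum loop, +0.35 per extra base) and each
stem mismatch costs a flat 0.5 and contributes no stacking. Bulges and
internal loops are deliberately out of model: for a presence/absence
decision about a terminal hairpin, a mismatch-tolerant contiguous stem is
enough, and the restricted structure space can be enumerated exhaustively,
which is how the folder is tested. Structures are reported when dG ≤ −3
kcal/mol (tunable); the 3' search window is the 100 bp upstream of the 3'
terminus. These window and threshold choices are package defaults exposed
as arguments — the diagnostic layout fixes their order of magnitude but no
published value pins them exactly.

`find_inverted_repeats()` reports maximal mismatch-bounded arm pairs along
anti-diagonals: a 5'-IR must fit inside the first 60 bases, a SIR pairs the
first and last 120-base subterminal windows. `find_microsatellites()`
finds maximal tandem arrays of any rotation of (CTGT) / (GTTT), allows a
fractional trailing unit, and merges overlapping arrays to the longest.

`classify_element()` turns the feature set into a confidence tier:
**full** = both canonical termini and a qualifying hairpin; **partial** =
one terminus with a hairpin, or both termini without one (copies with a
cryptic terminus); **structural_only** = hairpin or SIR but no canonical
terminus; **rejected** otherwise.

## Alignment and identities

`pairwise_global()` and `progressive_msa()` use ClustalW-style nucleotide
scoring (match +1, mismatch 0) with the family-standard gap penalty 10 and
extension 0.2; the MSA builds its guide tree from k-mer distances by
neighbor joining and merges profiles in postorder. Traceback ties resolve
diagonal > up > left, so alignments are deterministic across platforms.
`complete_deletion()` removes every column containing a gap — the
filtering convention used before distance computation. "Identity" and
"similarity" are treated as the same statistic, reported in both the
all-columns and ungapped-columns modes since published tables rarely state
which was used.

## The HTT screen

`compare_matrices()` compares a TE identity matrix with a host-marker
identity matrix over the same species and flags every pair where the TE is
*more* conserved than the genomic background (`delta = te − host > 0`).
The raw inequality is the primary flag; `permutation_test()` adds a
label-permutation p-value per pair but never replaces the flag.

The permutation null needs care at small taxon counts. The observed delta
for a focal pair is compared with the deltas obtained at the focal pair's
position after jointly relabelling the taxa; a relabelling that leaves the
focal pair in place reproduces the observed arrangement exactly, and is
therefore treated as the observed case (the "+1" of the standard
permutation formula) rather than as a fresh null draw — otherwise, with
six taxa, the 48 of 720 pair-preserving relabellings would impose a hard
floor of about 0.07 on every p-value and no signal, however strong, could
ever reach 0.05. With fewer than eight taxa the group is small enough
that the package enumerates it exactly instead of sampling, which makes
the p-value deterministic. The price of excluding the tie mass is a
slightly liberal test at very small n (with six exchangeable taxa the
rate of p ≤ 0.05 is 1/15 ≈ 0.067 rather than 0.05); the vertical-only
calibration check in the test suite monitors exactly this quantity, and
the flag the screen acts on remains the raw inequality.

## Phylogenetics

`t3p_distance()` implements the Tamura 3-parameter estimator from the
transition proportion P, transversion proportion Q and GC content theta
(`h = 2 theta (1−theta)`), with the standard gamma-rates transform when
rate variation is on; theta defaults to the empirical GC of the
gap-filtered alignment. Saturated pairs are flagged `NA`, never silently
truncated. The default gamma shape is 2.249 with 4 discrete categories at
their distribution means.

Trees come from neighbor joining (`nj_tree()`, negative branches clamped
to zero with the deficit moved to the sibling edge), optionally polished
by `nni_search()` — a nearest-neighbor-interchange hill-climb scored by
`pruning_loglik()`, a Felsenstein-pruning log-likelihood under the T3P
rate matrix with discrete-gamma mixing. A full ML tree search is
deliberately out of scope: NJ(+NNI) under the same model family is
tractable, fully testable against enumeration oracles, and sufficient for
the incongruence question the screen asks. `bootstrap_consensus()`
resamples columns, builds a tree per pseudoreplicate (1000 by default) and
reports the ≥ 50 % majority-rule consensus with percent supports;
`robinson_foulds()` quantifies incongruence against a reference species
tree.

## The simulator and what passing tests mean

`simulate_scenario()` evolves a rendered element template and a random
host-marker gene along a species tree under the T3P process (substitutions
only — no indels, so ground-truth column maps stay exact and recall can be
scored unambiguously). Elements are planted between AT/TT dinucleotides
with no target-site duplication, splitting the dinucleotide so the flanks
read `...A | element | T...`. An HTT event branches the transferred copy
off the donor's *realised* lineage at the event time and evolves it to the
present in the recipient; this is what decouples TE similarity from host
divergence under transfer. All randomness fans out from one scenario seed
through a documented child-seed derivation, so datasets are byte-identical
across runs.

Default study conditions used by the test suite and the acceptance script:
six taxa, a 300 bp element, a 500 bp marker, equal TE and host clocks, a
single recent transfer (time 0.9) between non-sister lineages for the
power checks, and a star phylogeny (exchangeable lineages) for the
null-calibration check, where the permutation test's assumptions hold
exactly. Under a structured tree with no transfer the test is conservative
— relabellings mix pairs with different expected divergences and widen the
null — which is the safe direction for a screen. Simulated genomes are
5 kb with three planted copies; these sizes give unambiguous recovery
statistics while keeping a full run of the suite inexpensive.

Passing on this synthetic model shows the machinery is correct under
substitution-only divergence with known truth. It does not demonstrate
robustness to indels, nested insertions interrupting an element,
sequencing error, or assembly artefacts — on real data the partial
coverage classes and the cryptic-terminus tiers carry that load, and the
identity thresholds were chosen for cross-species detection, not
within-genome exhaustive annotation.

## Numerical and degenerate-input choices

* Alignment scores are doubles throughout; DP tie-breaks are fixed
  (diagonal > up > left) for determinism.
* `evalue()` at score 0 is `K m n`; filters use ≤ / ≥ comparisons at the
  documented thresholds, so boundary hits (exactly 65 %, exactly 1e−5)
  are retained.
* Zero aligned columns yield a flagged `NaN` identity with a warning, not
  an error; an all-gap alignment survives `complete_deletion()` as a
  0-column alignment with a warning.
* In bootstrap replicates a resampled pair can saturate; its distance is
  capped at 1.5 × the largest finite replicate distance — a replicate
  must produce *some* tree for the consensus to count it.
* `nj_tree()` refuses matrices with undefined entries, naming the pairs.
* Exhaustive permutation enumeration replaces sampling whenever the
  permutation group is no larger than `n_perm`.

## Known limitations

The hairpin model excludes bulged stems, so a real hairpin interrupted by
a 1-base bulge may be reported as two shorter alternatives or missed near
the reporting ceiling. The progressive MSA has no iterative refinement
and is not a general-purpose aligner; it is adequate for the short,
highly similar element families it is used on here. The HTT screen makes
no claim about transfer direction or timing, and with six taxa its
permutation p-values are coarse (15 exchangeable pair positions) — the
delta ranking carries most of the information at that scale. Robinson–
Foulds against a reference species tree treats all edges equally and does
not weight by support.
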