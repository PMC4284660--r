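---
title: "Models and methods behind chordevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chordevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

chordevo quantifies how fast two related genomes evolve: in gene order,
in protein sequence, in exon arrangement, in domain combinations, in
conserved non-coding sequence, and in within-species polymorphism.
This vignette explains the models behind each estimator, the parameters
that matter, the numerical conventions, and what the bundled simulator
does and does not emulate.

## Coordinates and data model

All internal coordinates are 0-based, half-open, on the forward strand.
GFF3 (1-based closed) and axt inputs are converted at the I/O boundary
only; BED passes through unchanged. Readers validate rather than clamp:
features outside their declared sequence, ragged alignment texts, or
BED intervals with `end < start` are errors. Amino-acid intervals in
domain tables follow the same half-open convention.

## DCJ rearrangement distance

A genome is a set of linear or circular chromosomes over signed
markers. Marker *m* has a tail and a head extremity; consecutive
markers define adjacencies, chromosome ends are telomeres. The DCJ
(double-cut-and-join) distance between genomes with equal marker
content is

  d = N − (C + I/2),

where the adjacency graph connects the adjacency/telomere vertices of
the two genomes through their shared extremities, `C` counts its
cycles and `I` its odd-length paths (each shared extremity contributes
exactly one edge, so a path is odd iff it holds an odd number of
extremities). Markers missing from either genome are dropped before
the computation and the dropped counts are reported, so rates can be
recomputed under other conventions. Duplicated markers are rejected
and redirected to the aliquoting operations.

The implementation is validated against `dcj_distance_bfs()`, an
exhaustive breadth-first search over the full DCJ move set (including
circular intermediates); the test suite checks equality for *every*
one-chromosome signed genome on up to 5 markers, and recovery of
planted operation counts on 200-marker genomes.

Rates: the per-marker rate is ρ = d/N (so a 120-operation distance
over 269 shared markers is 0.45); the relative rate divides ρ by the
protein divergence of the same pair, making rearrangement comparable
across pairs of different ages; the per-time rate divides by the
divergence time in Myr instead.

## Genome aliquoting

For a genome whose markers all occur twice (for example after
whole-genome duplication), `aliquot_distance()` estimates the minimal
DCJ distance to a *perfectly duplicated* ancestor and reconstructs that
ancestor's gene order.

- **Exact mode** enumerates every ancestor genome (all adjacency
  matchings over the marker extremities, linear or circular, any
  number of chromosomes) and every copy assignment, taking the
  minimum. Enumeration is factorial, so it is capped at 6 distinct
  markers; it serves as the correctness anchor for the heuristic.
- **Greedy mode** selects ancestor adjacencies by walking the natural
  graph (input adjacencies/telomeres connected through duplicated
  extremity classes) and taking alternate vertices along each
  component — the pairing that maximizes short cycles — then assigns
  copy labels by propagating along ancestor-consistent runs, and
  refines both by hill climbing (single-marker and run-block label
  flips, ancestor re-derivation from the current labels, and, on
  small instances, 2-swaps of suspect adjacencies). Every reported
  distance is realized by a concrete ancestor and labeling, so the
  greedy estimate is always an upper bound on the exact distance. A
  parity argument (a perfectly duplicated genome has even class
  multiplicities everywhere; one DCJ operation flips at most four
  parities) supplies the reported lower bound.

On a doubled 200-marker genome scrambled by ten random DCJ operations
the greedy estimate typically equals the planted count; in a minority
of random replicates it exceeds it by one or two operations. This is a
property of any polynomial heuristic for this problem (the published
exact formulation is an integer linear program, out of scope here);
the bracketing invariants — greedy ≥ exact, greedy ≥ lower bound —
hold always and are tested.

## Orthology and protein distances

Gene-level reciprocal best hits: for each directed gene pair, the best
protein-variant pair (by summed bitscore) represents the genes;
its alignment segments are concatenated with query-overlaps resolved
best-bitscore-first. The gene-level identity is the length-weighted
mean of segment identities; coverage is the concatenated aligned
length over the query protein length. A pair is accepted when each
gene is the other's best gene-level hit and both directions pass the
identity (60%) and coverage (40%) cutoffs; ties break by bitscore then
lexicographic subject id. These defaults and the weighting rule are
package choices where the underlying procedure leaves them open.

Protein distance uses gap-free columns only (an external
conserved-column mask can be supplied via `site_mask`), with the
Poisson correction d = −ln(1 − p). Sequence diversity is measured as
in Blastclust: single-linkage components over edges that pass identity
and coverage in both orientations; the number of clusters is the
diversity.

## Exon phases and shuffling

The phase at an exon boundary is the cumulative CDS length modulo 3 in
translation order; minus-strand genes are reversed first, so a gene's
phases are strand-invariant. Genes whose CDS is not a multiple of 3
are excluded (with a warning when they claim to be complete): their
frame is not defined. Phase spectra count internal exons above a
length cutoff (100 bp by default) over the nine phase combinations,
with binomial 95% CIs on the symmetric classes.

Shuffled exons: in RBH mode an exon is shuffled when its
reciprocal-best exon (nucleotide-level hits on CDS exons, ≥60%
identity over ≥50% of the shorter exon by default — exon-level
thresholds are package defaults, configurable) lies in a gene that is
not its own gene's orthologue. In chainnet mode an exon is flagged
when its aligned counterpart falls outside its orthologue's span;
exons without alignment evidence are not flagged, which is why
chainnet reports fewer, higher-confidence calls — an inequality the
tests assert on simulated data.

Subgenic rates: DCJ distance over matched exon markers minus the
distance over gene markers, floored at zero (the two marker sets can
differ; the raw value is also reported). A single exon
excision/insertion costs at most two DCJ operations, so k planted
shuffles yield a contribution in [k, 2k].

Domain exons: a domain interval is projected codon-exactly from
protein to CDS coordinates; one overlapping base pair marks the exon
as domain-encoding (the smallest defensible overlap rule; the
threshold is a parameter).

## Domain combinations

Architectures are cleaned greedily by e-value (overlapping hits drop).
Pairs default to *adjacent* unordered type pairs — the stricter,
shuffling-relevant reading of "two-domain combination"; co-occurring
mode is provided for sensitivity analysis, and adjacent ⊆ cooccur is
asserted. Self-pairs are excluded by default (tandem expansions are a
different phenomenon).

Dollo parsimony assigns each pair one gain on the branch above the
MRCA of the species that carry it, and losses on the maximal pair-free
subtrees below; the suite verifies gains + losses equals the
brute-force minimum over all single-gain scenarios on every presence
pattern of 4- and 5-leaf trees. Gains per branch divided by branch
durations give pairs-per-Myr rates. Presence/absence trees use Jaccard
distances and neighbor joining.

## Conserved non-coding elements

Coarse candidates: alignment columns overlapping reference CDS (or all
exons — both masks exist because annotations differ in whether UTRs
are present, and the choice changes the totals) are removed; gap runs
of ≥10 bp split candidates; candidates closer than 10 bp on both
genomes merge; identity counts gap columns as mismatches. The merge
and gap-break defaults are package choices.

Refinement applies filters in a fixed order — short (<75 bp), adjacent
to CDS (within 20 bp; the adjacency distance is a package default),
homologous (hit at e ≤ 1e−5 against known proteins/structural RNAs),
then identity < 70% — attributing each removal to the first applicable
class so that class lengths are additive: coarse length = refined
length + the per-class removals, an identity the tests check exactly
on an engineered fixture. Only the listed homology classes are
removed, so unannotated conserved sequence (candidate regulatory
elements, microRNAs, lncRNAs) stays in.

## Polymorphism and population size

Variant calling walks haplotype alignment blocks: SNPs are single
mismatch columns (never merged), indels are maximal gap runs classed
small (≤300 bp) or large (>300 bp), minus-strand blocks are
inversions, and blocks whose query sequence differs from their
reference sequence's dominant counterpart are translocations. SNP and
indel *event* rates use aligned (gap-free) columns as denominator;
indel *length* fractions use the genome length — the two conventions
these quantities are reported in.

Inter-variant spacings are fitted to a geometric law (zero-based
support by default: a gap of zero between adjacent variant sites is
allowed; the one-based convention is also implemented). The MLE is
n/(n + Σg); the chi-square goodness of fit pools bins to expected
counts ≥5 and has n−2 degrees of freedom. Random placement passes;
clustered placement is rejected with high power — both are tested.

dN/dS follows Nei–Gojobori (1986): fractional synonymous site counts
per codon (changes to stops count as nonsynonymous), differences
averaged over all mutational pathways with equal weights (pathways
through stop codons are skipped), Jukes–Cantor correction
d = −(3/4) ln(1 − 4p/3). This counting estimator is a deliberate,
reproducible approximation to likelihood methods; on neutral
simulations it is consistent with dN/dS = 1 within sampling error.

Effective population size uses the neutral identity θ = 4·Ne·μ:
Ne = π/(4 μ g). With π taken as the sum of the SNP (4.39%) and
small-indel event (0.98%) rates and μ = 10⁻⁸–10⁻⁹ per year at a 1-year
generation time, Ne spans 1.3–13 million — the reconstruction of the
printed range from its printed inputs; which π the original estimate
used is not stated, so this identification is flagged as such.

## Region profiles

The genome partition assigns every base exactly one class with
precedence CDS > intron > upstream/downstream > intergenic; flanks
default to 1000 bp (the flank length is a parameter, as "up/downstream
region" has no canonical width) and flank-flank overlaps split at the
midpoint. Exactness (disjoint cover, length conservation) is asserted,
not assumed. Reads are assigned by majority overlap; per-site
methylation is methylated/total reads, class levels are unweighted
means over sites (the coverage-weighted mean is reported alongside,
since the convention is ambiguous), and the ≥80% high-methylation
fraction is reported per class.

## The simulator: what it emulates, and what it does not

`build_ancestor()` creates chromosomes of alternating intergenic
blocks, planted CNEs and multi-exon genes (truncated-geometric exon
counts, lognormal exon/intron/intergenic lengths, CDS padded to full
codons so phases are realized by construction) plus per-protein domain
architectures. `evolve_lineage()` applies, in order: optional WGD
(exact doubling), inversions, translocations, exon shuffles, domain
pair gains/losses, CNE decay, and substitutions, recording every event
so that `replay_events()` reproduces the descendant byte for byte — an
identity the suite asserts.

Key emulation choices:

- **Substitutions** are i.i.d. per site with a uniform alternative
  base (Jukes–Cantor), at the neutral rate in intergenic and intronic
  sequence and at that rate × 0.1 in exons and CNEs. The default
  neutral rate (0.35 per lineage) puts neutral sequence below
  whole-genome alignability while exons and CNEs stay alignable — the
  regime in which CNE detection is meaningful for anciently diverged
  species pairs, where orthologous introns retain virtually no
  similarity.
- **Alignability**: `derive_alignment()` emits a block for an
  ancestrally shared unit only when its pairwise identity reaches a
  threshold (60% by default), emulating the sensitivity limit of a
  reciprocal-best whole-genome aligner. It aligns atomic units
  (intergenic blocks, CNEs, exons), not arbitrary breakpoints.
- **Structural breakpoints** fall in neutral sequence: inverted or
  translocated segments start and end on gene/CNE features and
  translocations land inside an intergenic block, which is split. Real
  breakpoints can of course disrupt genes; the simulator trades that
  realism for exact, assertable ground truth.
- **Exon shuffles** excise one internal exon with flanking intron
  halves and reinsert it into another gene's intron (split at its
  midpoint). With probability β the donor exon is drawn from the 1–1
  phase class; otherwise a phase class is drawn uniformly from the
  nine and a donor from that class, so the expected 1–1 share among
  shuffled exons is β + (1−β)/9. Insertions are allowed to break the
  recipient's frame — selection, not mechanism, is what biases real
  shuffling toward symmetric exons — and such genes are subsequently
  excluded from phase annotation by the frame check.
- **Small indels** (diploid simulation) are geometric with mean 8 bp
  truncated at 300 bp; only the ≤300 bp class boundary and the
  dominance of ≤50 bp events are anchored externally, so the mean is a
  package default, configurable. Large indels are 301–10,000 bp.
  The default planted SNP (4.39%) and indel-event (0.98%) densities
  are the study conditions for the polymorphism estimators.

Not emulated: transposable-element sequence evolution, selection,
recombination, alignment errors, annotation errors, and
assembly artifacts. Passing recovery tests therefore shows the
estimators are correct on clean inputs at planted rates; it does not
certify behavior on noisy real annotations.

## Problem sizes and determinism

The test suite and the acceptance script run simulations at desk
scale: ancestors of 40–200 genes over a few hundred kb, 50–200 planted
events, 10⁴ codons or spacing observations for the statistical checks,
and exhaustive enumeration up to 5 markers (DCJ) / 6 markers
(aliquoting exact mode) / 5-leaf trees (Dollo). These sizes give the
oracles full coverage and the stochastic checks 3-standard-error
resolution. All randomness flows from explicit seeds; identical seeds
give byte-identical bundles and reports.
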