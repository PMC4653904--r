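---
title: "Methods: building a unified coordinate system for HTH-DNA complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a unified coordinate system for HTH-DNA complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hthatlas)
```

## The problem

Helix-turn-helix (HTH) proteins are the most widespread family of
DNA-binding domains: a bundle of three alpha-helices whose third
("recognition") helix docks into the DNA major groove and reads out
sequence. Because this binding modality is highly conserved, the
protein-DNA interfaces of different HTH complexes can be superimposed
and compared residue by residue and basepair by basepair — provided one
can (i) curate clean double-stranded complexes, (ii) locate the
recognition helix reliably, (iii) align complex pairs in a way that is
anchored on the DNA rather than the protein, and (iv) merge all pairwise
alignments into one exemplar-anchored multiple alignment. `hthatlas`
implements that pipeline end to end, together with position weight
matrix (PWM) construction from curated binding sites and atomic
contact-frequency statistics expressed in the shared coordinate system.

All residue and basepair indices in the package are 0-based with
half-open ranges; PDB serial numbers exist only at the I/O boundary.

## Curation

`read_structure()` parses ATOM/HETATM records (via bio3d), keeps the
first alternate location of each atom, strips waters and non-polymer
heteroatoms, and partitions chains into protein and nucleic by residue
identity. `screen_pathologies()` flags the three conditions under which
a structure is rejected: single-stranded DNA, missing backbone atoms
(C-alpha for protein; C1'-C5' for DNA), and non-standard amino acids.

`standardize_duplex()` brings the DNA into a canonical form: both
strands 5'→3', basepairs matched, overhangs removed. "Physically
matched" is made precise geometrically: two nucleotides pair when their
bases are Watson-Crick complementary and their C1'-C1' distance falls in
9-12 Å (idealized B-form pairs sit near 10.5 Å); candidate pairs are
accepted greedily by increasing distance and the result must be an
antiparallel monotone matching. Greedy matching rather than an optimal
assignment is sufficient here because admissible pairings of a genuine
duplex are geometrically unambiguous; inconsistent inputs raise an
error rather than a guess. Standardization never moves an atom — it
only reorders and removes records — and it is idempotent.

`split_domains()` cuts annotated HTH domains out of their chains, merges
multi-chain domains into one contiguously renumbered chain (N→C in the
order supplied), and attaches the standardized duplex; a domain whose
atoms never come within 10 Å of the DNA is excluded as having no
cognate DNA. Domain discovery itself is an input: annotations come from
detection runs or from generator ground truth.

## Detecting the HTH domain

Detection applies three distance criteria in order, short-circuiting at
the first failure. All residue-DNA distances are minima over all atoms
of the residue and all atoms of the DNA.

1. **Candidacy.** Some alpha-helix must have a contiguous window of
   five residues whose mean distance to the DNA is *strictly below*
   5 Å. The window minimizing the mean is chosen; among qualifying
   helices the one with the smallest mean wins.
2. **Orientation.** Each of those five residues must individually lie
   within 6.5 Å of the DNA (inclusive).
3. **Tri-helical bundle.** At least three helices must be present, and
   the central residue must have a C-alpha within 18 Å (inclusive) of
   at least one residue in each of two helices other than the
   recognition helix.

The *central residue* is the recognition-helix residue whose C-alpha is
closest to the DNA major axis, defined as the least-squares line through
the DNA backbone carbons along their direction of maximal variance, with
its sign canonicalized toward increasing forward-strand index. A finite
discrete helix has a small intrinsic tilt between this principal axis
and the geometric helical axis (about 6° at 16 bp, vanishing as the
duplex grows); the synthetic generator therefore places the central
residue with a ~3 Å margin so the identification is insensitive to it.

Boundary semantics follow the wording of each criterion: candidacy is
strict ("less than"), orientation and the tri-helical test are
inclusive. Helix assignment honors explicit helix annotations (e.g.
HELIX records) when given; otherwise a geometric C-alpha rule is used:
position *i* starts a helical turn when |CA(i)-CA(i+3)| ∈ [4.5, 6.5] Å
and |CA(i)-CA(i+4)| ∈ [5.5, 7.5] Å, residues covered by a turn are
merged, and maximal runs of at least four residues become segments. All
ties anywhere in the pipeline break toward the lowest index, for
determinism.

## Redundancy elimination

Two complexes are redundant when their recognition helices carry the
same sequence. Each complex contributes a 41-symbol window centered on
its central residue (20 residues each side; positions beyond the chain
are GAP). The distance between two windows is the minimum number of
mismatched overlap positions over all shifts with |shift| ≤ 15 — the
largest shift that keeps an 11-residue window around both central
residues inside the overlap. A GAP aligned against an amino acid counts
as a mismatch; GAP-GAP columns match, so a sequence always has distance
zero to itself. Mismatches are counted over the full overlap, not only
the central window.

Zero-distance pairs become edges of a redundancy graph. Every isolated
node is kept; from each connected component one representative is kept:
highest degree, then best (lowest Å) resolution, then lexicographic
id. Treating components (rather than only cliques) makes the procedure
well-defined for every topology, with the degree criterion resolving
non-clique components through centrality. Unknown resolutions sort
last.

## Pairwise alignment

The alignment of two complexes minimizes the recognition-helix C-alpha
RMSD subject to the DNA backbone RMSD being below a gate δ = 2 Å
(strict). DNA near the binding site is structurally the most uniform
part of these complexes, so candidates are generated from *canonical
matching regions*: with *n* the basepair whose C1' is closest to the
central residue's C-alpha, the five 5-bp windows starting at n−4
through n each contain n. A duplex that cannot host all five regions
(fewer than 4 bp on either side of n) makes the complex unalignable
rather than shrinking the candidate set — this keeps the candidate
count invariant. Five regions per complex and two duplex orientations
(the mirror symmetry of double-stranded DNA: forward↔forward, or
forward↔reverse with basepair order reversed, both preserving 5'→3'
directionality) give exactly 5 × 5 × 2 = 50 candidates per pair.

Because the correspondence within a candidate is fully constrained
(same atom name, same basepair offset, orientation fixed), the
iterative closest-points superposition collapses to a single
closed-form least-squares step (SVD, proper rotations only), which
`superpose()` implements. Candidates with DNA RMSD ≥ δ are discarded.
For each survivor the recognition-helix RMSD is evaluated **in the
DNA-derived frame, without re-fitting** — this is what makes the DNA
constraint meaningful — minimizing over all residue mappings: every
shift of one helix along the other with at least m = 8 residues
overlapping, in both N→C orientations. The candidate with the smallest
helix RMSD wins; its 5-bp register is extended arithmetically across
the full overlap of both duplexes to produce the base-by-base map, and
the winning helix mapping is the residue-by-residue map.

## Clustering and the unified coordinate system

Pairwise helix RMSDs form a distance matrix (unalignable pairs are
+∞). Affinity propagation (AP) clusters the complexes on similarities
s = −d, chosen because it returns an *exemplar* per cluster — the
member closest to all others — and takes a single soft preference
parameter instead of a cluster count. The implementation is the
standard responsibility/availability message passing (damping 0.9, up
to 1000 iterations, convergence when the exemplar set is stable for 50
iterations), followed by a refinement pass that moves each exemplar to
the member minimizing summed intra-cluster distance. Two degeneracies
are handled deterministically: exact ties are broken by a sub-numerical
deterministic jitter, and when all alignable distances are numerically
identical — a regime where the exemplar objective is provably
indifferent between partition sizes — the trivial clustering
(connected components of alignability) is returned directly.

`tune_preference()` scans a fixed grid — the 5%…95% quantiles of the
off-diagonal similarities plus their median, anchored by one coarse
point at minus the configured distance bound (default 3.5 Å) so that a
one-big-cluster configuration is always explored — and keeps the
preference maximizing the largest cluster's size subject to that
cluster's internal median distance staying below the bound. The bound's
default reflects the scale at which HTH complexes still share a binding
modality; complexes farther than that from every cluster (bent DNA,
residual false positives) end up in singleton clusters.

The largest cluster's exemplar anchors the unified coordinate system:
every member is aligned pairwise to the exemplar, affine-transformed
into its frame, and its residue/basepair maps stored. Universal indices
are simply the exemplar's own indices — no renumbering — so a
correspondence between any two members is obtained by composing
member→exemplar→member maps. Complexes outside the main cluster, or
unalignable to the exemplar, are retained as outliers with reasons.

## PWMs and contact statistics

Binding sites are deduplicated by (provenance id, sequence) — the same
experiment reported by several repositories collapses to one record,
while distinct experiments reporting the same site are kept. Sites are
placed ungapped on the complex's forward-strand duplex sequence at the
offset and strand maximizing matches (a deterministic stand-in for
curation-time manual alignment; ties prefer forward strand, then the
smallest offset; over-long sites are trimmed with a warning). Column
probabilities use Laplace smoothing, (c + α)/(N + 4α) with α = 1 by
default; a column with no data is the uniform prior, which is also the
α-smoothing limit at N = 0. Columns map onto basepairs
order-preservingly given the orientation, with reverse-orientation maps
complement-swapping the columns; unmapped basepairs report the uniform
prior.

Contacts are all protein-atom/DNA-atom pairs within a cutoff (default
5 Å), annotated with universal positions; pairs at unmapped positions
are skipped and counted. A spatial cell grid restricts the search but
is exactly equivalent to the full scan (and is tested against it). The
database-wide frequency of a position pair is the fraction of
structures showing at least one contact there — a per-structure
normalization, so duplicating a complex does not change frequencies.
Per-pair atom-type heatmaps use a fixed dictionary (20 amino acids ×
emitted atom names; 4 bases × 5 backbone carbons, in documented order);
unknown atom names are binned as OTHER with a warning.

## The synthetic generator

`make_hth_complex()` builds complexes with known ground truth so every
stage is testable without downloading structures. The DNA is an
idealized straight B-form duplex: the five backbone carbons of each
nucleotide on helical cylinders (3.4 Å rise, 36° twist, C1' radius
9.4 Å, paired C1' atoms 68° apart, giving the ~10.5 Å C1'-C1' pair
distance), with the antiparallel complementary strand generated
automatically. The protein is a C-alpha trace plus one CB pseudo
side-chain atom per residue — every distance the pipeline defines uses
only C-alpha, the backbone carbons, or minima over atoms, so this
reduced representation exercises all of them. The tri-helical bundle
places the recognition helix tangentially against the duplex at the
middle basepair, its axis midway in angle between the two backbone
strands flanking that height, with the two support helices 8 Å further
out; at the default dock distance of 12 Å the closest window residues
sit 2-4.5 Å from the DNA, so all three detection criteria pass with
margin. The middle recognition-helix residue's helical phase points
straight at the DNA axis, making it the unambiguous central residue.

Decoy modes violate exactly one criterion each: inflating the dock
distance by 5 Å fails candidacy; radially displacing the central
residue of a 5-residue recognition helix by 8 Å fails orientation while
keeping the window mean under 5 Å; emitting only two helices fails the
tri-helical test. `bend_angle` produces atlas outliers: a V-shaped kink
through the dock basepair in which each duplex arm deflects by the
given angle away from the protein. Because the kink basepair remains
the one closest to the central residue, every canonical matching region
straddles the kink and no clean 5-bp window survives; at 60° per arm
the best candidate's DNA RMSD (~2.4 Å) exceeds the δ = 2 Å gate, so the
bent complex is excluded from the atlas as unalignable. Milder bends,
or bends placed away from the binding site, are *absorbed* by the
DNA-anchored candidate scheme — that robustness to distal DNA
deformation is a design feature of the alignment, and the generator's
kink is deliberately placed where it cannot be absorbed.

What the generator does **not** emulate: full side chains and their
rotamers, base atoms (distances are to backbone carbons only),
sequence-dependent DNA shape, crystallographic noise beyond isotropic
Gaussian jitter, and multi-domain or multi-chain architectures (those
are assembled in tests by splicing generator output). Passing tests
therefore demonstrate the correctness of the algorithms under the
stated geometric model, not the empirical distributions of cutoff
statistics in real crystal structures.

## Numerical choices and limitations

* Rotations are proper throughout (reflections rejected); superposition
  uses the SVD closed form with a determinant correction, and errors on
  collinear point sets.
* Every tie (window choice, shift, candidate order, representative
  selection) breaks toward the lowest index / smallest |shift| /
  negative shift / lexicographic id, making all outputs deterministic.
* Generated randomness (sequences, jitter, rotations) is seeded
  explicitly, and generator functions restore the caller's RNG state.
* The test and acceptance problem sizes — 16-20 bp duplexes, bundles
  of 8-16 residue helices, atlases of 11 complexes, 10^4 sampled
  binding sites, 1000-pair oracle sweeps — were chosen so the full
  suite completes in about a minute while still exercising every
  combinatorial invariant (50 candidates, 25 pairings, 41-symbol
  windows, 5 regions).
* Limitations: mmCIF and NMR multi-model inputs are out of scope;
  modified nucleotides are rejected rather than remapped; protonation
  is not performed; detection assumes a contiguously indexed protein
  chain (which standardization guarantees).
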