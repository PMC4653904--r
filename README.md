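# hthatlas

A structural atlas pipeline for helix-turn-helix (HTH) protein-DNA
complexes. The HTH motif — a tri-helical bundle whose third
("recognition") helix docks into the DNA major groove — binds DNA with
a highly conserved modality, which makes it possible to superimpose the
interfaces of different HTH-DNA complexes and compare them residue by
residue and basepair by basepair. `hthatlas` implements the full
computational pipeline for building such an atlas:

* **Curation** — PDB reading/writing, screening for the three
  structural pathologies (single-stranded DNA, missing backbone atoms,
  non-standard residues), duplex standardization (strands 5'→3',
  geometric basepair matching, overhang removal), and per-domain
  splitting.
* **Detection** — heuristic identification of the recognition helix and
  central residue via three distance criteria: a contiguous 5-residue
  window with mean residue-DNA distance < 5 Å, each window residue
  within 6.5 Å, and a tri-helical bundle check at 18 Å around the
  central residue.
* **Redundancy elimination** — 41-residue recognition sequences
  compared under constrained shifts (|shift| ≤ 15, preserving an
  11-residue central overlap); zero-mismatch pairs form a graph from
  which one representative per connected component is retained (degree,
  then resolution, then id).
* **Alignment** — the DNA-anchored constrained superposition: five 5-bp
  canonical matching regions around the basepair nearest the central
  residue, two duplex orientations (mirror symmetry), hence
  5 × 5 × 2 = 50 candidates per pair; each is superposed under a fully
  constrained atom correspondence (closed-form least squares), gated at
  DNA RMSD < δ = 2 Å, and the survivor minimizing the recognition-helix
  C-alpha RMSD over all residue mappings (shifts × flips, overlap
  ≥ m = 8) wins:
  minimize RMSD_HTH subject to RMSD_DNA < δ.
* **Atlas** — affinity propagation on the pairwise helix-RMSD matrix
  (similarity −d, tunable preference), exemplar selection, and a
  unified coordinate system: every member is affine-transformed onto
  the exemplar and indexed by the exemplar's residue/basepair numbers,
  so any two members correspond by composing member→exemplar→member
  maps.
* **PWMs** — binding-site deduplication, ungapped best-match alignment
  to the crystal duplex sequence, Laplace-smoothed position weight
  matrices ((c + α)/(N + 4α), α = 1), mapped onto structure basepairs.
* **Contacts** — atomic contact records and per-position contact
  frequencies across the database, in universal coordinates, with
  atom-type heatmaps.
* **Synthetic generator** — idealized B-DNA plus a C-alpha-trace
  tri-helical bundle with known ground truth (recognition helix,
  central residue, anchor basepair), including single-criterion decoys
  and bent-DNA atlas outliers, so the whole pipeline is testable
  without downloading structures.

## Worked example

```r
library(hthatlas)

# a synthetic complex with ground truth
g <- make_hth_complex(synth_params(seed = 42))
g$complex
#> <hth_complex synth/A: 32 residues, 16 bp, recognition helix [19,32) central 25>

# detection: candidacy -> orientation -> tri-helical
a <- detect_hth(g$complex)
a
#> <hth_assessment: pass (helix [19,32), central 25)>
round(a$window_distances, 2)
#> [1] 1.48 2.92 4.90 3.49 1.15     # five closest residues, mean 2.79 A

# align the complex to a rigidly moved copy of itself
moved <- perturb(g$complex, random_rotation(seed = 7), c(8, -3, 12))$complex
align_pair(g$complex, moved)
#> <pairwise_alignment: DNA RMSD 0.000 A, helix RMSD 0.000 A, FORWARD,
#>   13 residue pairs, 16 basepair pairs>

# the 41-symbol recognition sequence used for redundancy tests
paste(extract_recognition_sequence(g$complex), collapse = "")
#> [1] "HDCMCVRGNAILPGDDWMCDRWNTWQQ--------------"
```

The detection report shows the five window residues all within the
6.5 Å orientation cutoff and a window mean of 2.79 Å, well under the
5 Å candidacy cutoff. The alignment of the moved copy recovers the
rigid transform exactly (both RMSDs at numerical zero), maps all 13
recognition-helix residues, and registers all 16 basepairs in FORWARD
orientation. Trailing `-` symbols in the recognition sequence are GAP
padding where the 41-residue window extends past the chain.

An atlas is built the same way at any scale:

```r
cxs <- ...                             # named list of detected complexes
D   <- pairwise_distance_matrix(cxs)   # helix RMSD, Inf if unalignable
tp  <- tune_preference(D)              # affinity-propagation preference scan
ucs <- build_unified_coordinates(cxs, tp$result)
universal_position(ucs, "some_complex", 7, "bp")
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hthatlas.R", package="hthatlas"))')" \
    synth --seed 42 --out fixture.pdb --truth truth.json
# also: standardize, detect, align, dedupe, pwm
```

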