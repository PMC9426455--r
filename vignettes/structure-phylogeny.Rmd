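---
title: "Structure-based phylogenetics of capsid folds: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based phylogenetics of capsid folds: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldphylo)
```

## Why compare structures instead of sequences

Viral capsid proteins keep their three-dimensional fold long after their
sequences have diverged beyond recognition. The jelly-roll fold — an
eight-stranded antiparallel β-sandwich — is shared by capsid proteins of
viruses with completely different genome chemistries, and the leading
explanation for some of these sharings is horizontal transfer of the capsid
gene between lineages. At that evolutionary depth, sequence alignment is
uninformative and the phylogenetic signal lives in geometry: how far apart,
in ångströms, two folds are after the best possible rigid superposition.

`foldphylo` implements that style of analysis as a reusable pipeline:

1. read Cα traces from coordinate files (`load_structure`);
2. cut out the conserved fold core using a residue-range table
   (`extract_core`), or keep the full modeled chain;
3. superpose every pair of cores without using sequence information
   (`find_correspondence`, `pairwise_core_rmsd`), and progressively map all
   structures onto a common core (`multiple_superpose`);
4. collect the all-vs-all optimal-superposition RMSDs into a distance
   matrix (`build_distance_matrix`);
5. build a neighbor-joining tree (`neighbor_joining`) and test clade
   claims (`is_monophyletic`, `clade_report`).

A companion module quantifies virion geometry (icosahedral lattice
accounting and a parametric model of a spooled genome layer), and a
synthetic-data module generates inputs with known ground truth so every
stage of the pipeline can be validated without downloading anything.

## Rigid superposition

For two point sets in fixed correspondence, `kabsch()` minimises the RMSD
over proper rigid motions via the SVD of the cross-covariance matrix, with
the usual determinant correction so a reflection is never returned. The
closed-form quaternion (Horn) method gives the same optimum by an
independent route; the test suite keeps the two within $10^{-8}$ Å of each
other on a thousand random instances. Collinear or coincident point sets
still return a minimiser but are flagged `degenerate`, since the optimal
rotation is then not unique.

Under a fixed 1:1 correspondence the optimal-superposition RMSD is a
Procrustes distance and satisfies the triangle inequality; the suite
checks this property on random triples. Once the correspondence itself is
estimated per pair (the realistic case) metricity is no longer guaranteed —
one reason neighbor joining, which tolerates moderately non-metric input,
is the right tree method here.

## Finding the correspondence

The paper-scale question — which residue of structure A sits on which
residue of structure B — is answered without sequence, by an iterative
superpose/re-align loop in the tradition of progressive multiple
structure aligners:

* **Seeding.** All gapless windows of `seed_window` residues (default 30,
  stride 4) of A are exhaustively superposed against all such windows of
  B. The best window pair *per diagonal-offset band* becomes a candidate
  seed, and candidates compete on how many residues a single refinement
  round brings within the pair cutoff.
* **Refinement.** Superpose on the current pair set; score every residue
  pair $s_{ij} = 1/(1 + (d_{ij}/d_0)^2)$ with $d_0 = 3$ Å on
  post-superposition distances; run global sequential dynamic programming
  with a linear gap penalty of $0.6\,s_{\max}$ per skipped interior
  position, end gaps free; keep aligned pairs closer than 6 Å. Iterate (at
  most 20 rounds) until the pair set is stable.

Three choices here deserve their rationale spelled out, because the naive
variants fail in instructive ways:

* **End gaps are free.** With a strictly global alignment and per-position
  gap costs, two cores that sit at different offsets within their chains
  are unreachable: the end gaps cost more than the matched core gains, and
  the optimal path degenerates to a distance-ignoring diagonal.
  Semi-global alignment is the standard remedy and is what the DP uses.
* **Seeds compete per offset band, not globally.** In a repetitive
  all-β fold every strand window resembles every other, and at realistic
  noise levels wrong-register window pairs routinely out-score the true
  register *locally*. Keeping only the single best-RMSD window therefore
  mis-registers whole structures. Taking the best window in each band of
  diagonal offsets guarantees the true register is always among the
  candidates, and the refinement-coverage criterion reliably selects it.
* **Windows span several strands.** Fifteen-residue windows fit inside a
  single strand and overfit coordinate noise; thirty-residue windows
  bridge two to three strands, so their superposition reflects the global
  register. The default `seed_window = 30` follows.

All parameters live in `align_params()` and the procedure is fully
deterministic: same inputs, same output. `pairwise_core_rmsd` additionally
orders its two inputs by label before aligning, making the reported value
exactly symmetric. Alignments with fewer than 30 accepted pairs are
flagged low-confidence rather than silently trusted.

## From alignment to tree

`multiple_superpose` picks as reference the trace with the lowest mean
pairwise RMSD, maps every other structure onto it, and keeps the reference
residues matched by *all* structures as the common core; a consensus is
then refined by iterating mean-coordinate superposition to $10^{-6}$ Å.
The distance matrix holds, for each pair, the optimal-superposition RMSD
restricted to that common core. Whether such matrices should be
consensus-restricted or use per-pair cores is a genuine free choice in
this kind of analysis; common-core restriction is used because it makes
every entry measure the *same* residues, at the cost of values that can
differ by a few tenths of an ångström from per-pair-core numbers.

`neighbor_joining` is the Saitou–Nei agglomeration with the standard
$Q$-criterion and branch-length formulas, plus two conventions chosen for
reproducibility: ties in $Q$ are broken toward the lexicographically
smallest pair of cluster labels, and negative branch lengths are clamped
to zero (not redistributed — the matrices here are small and
near-additive). On additive matrices the algorithm is exact: topology and
every edge length are recovered to floating-point precision, which the
acceptance suite verifies on 500 random trees of 4–12 leaves. No
bootstrap support is computed: resampling is not defined for structural
coordinates in this setting.

Trees are unrooted (trifurcating root) in Newick with 6-significant-digit
branch lengths; matrices are exchanged as relaxed square PHYLIP (full
labels, count on the first line) and CSV. Monophyly is tested in the
unrooted sense: a taxon set is a clade exactly when some edge bipartitions
the leaves into that set and the rest.

## The synthetic evolution model

`simulate_backbone` builds a deterministic, self-avoiding Cα trace shaped
like a β-meander: extended strands (3.3 Å axial advance per residue,
zig-zag amplitude 0.95 Å, sheets stacked 4.8 Å apart) joined by
circular-arc loops, with consecutive Cα distances held in the canonical
3.8 ± 0.1 Å window. Strand and loop lengths follow a fixed irregular
pattern (9, 12, 8, 11, 10, 13 / 3, 5, 4, …): real sandwiches have unequal
strands, and a perfectly periodic meander would be a pathological decoy
landscape in which any sequence-independent aligner can mis-register by a
whole strand.

`evolve_along_tree` then walks a given tree: along each branch of length
$b$ every coordinate receives independent Gaussian noise of standard
deviation $\sigma\sqrt{b}$ (Brownian-on-coordinates divergence), loop
residues suffer indels at rate $r\,b$ (half deletions, half duplications —
loops only, so the strand core persists, mirroring how real divergence
concentrates in surface loops), and the whole structure receives an
arbitrary proper rigid motion. Everything is reproducible from the seed.

Two properties of this model matter when interpreting results:

* The expected squared deviation between two leaves grows linearly with
  their patristic distance $L$, so the *RMSD* grows like
  $\sigma\sqrt{3L}$ — a concave transform of the additive distance.
  Neighbor joining handles this well in practice (the pipeline recovers
  20/20 topologies at $\sigma = 0.3$ Å/√unit under the default
  conditions), but branch lengths of RMSD trees compress deep divergences
  and should be read qualitatively. Real fold divergence saturates
  similarly.
* At $\sigma = 0$ leaves differ by rigid motions only: the pipeline
  correctly returns an identically zero matrix, which carries no
  topological information at all. Exactness of tree *reconstruction* in
  the noiseless regime is therefore a statement about additive matrices
  (where it holds, perfectly), not about zero matrices. Even for
  arbitrarily small positive $\sigma$, finite traces put sampling noise
  on the matrix entries, and a generating tree whose internal edges are
  very short relative to that noise can fail to be recovered — that is a
  property of the estimation problem, not of the implementation.

What the generator does **not** emulate: side chains, sequence evolution,
fold-level rearrangements, domain insertions of realistic geometry, or
crystallographic artefacts. Passing the synthetic suite shows the
pipeline's machinery is correct and robust to coordinate noise and loop
indels; it does not certify any particular biological conclusion drawn
from real structures, where model quality and core-definition choices
dominate.

## Virion geometry

`capsid_lattice(T)` enforces membership of the icosahedral series
$T = h^2 + hk + k^2$; a $T$-lattice capsid has $60T$ subunits in $T$
quasi-equivalent positions per asymmetric unit ($T=3$: 180 subunits,
positions A, B, C).

The spooled genome layer is modeled as a single continuous solenoid of
constant radius $r$, pitch $p$ (axial separation of adjacent turns) and
$n$ turns, filled with base pairs at 3.4 Å of contour length each (ideal
B-form DNA). Its capacity is
$\lfloor n \sqrt{(2\pi r)^2 + p^2} / 3.4 \rfloor$ base pairs, with a
closed-form inverse (`radius_for_capacity`). Whether observed "parallel
turns" are one helix or stacked closed rings is usually not resolvable at
the relevant map resolutions; the helix with $p$ equal to the observed
inter-turn spacing is this package's declared convention, and
`measure_turn_spacing` works on either arrangement (it follows the
azimuth around the axis, interpolates the axial coordinate at whole-turn
crossings of eight fixed azimuths, and averages). A three-turn, 28 Å-pitch
spool holding 630 bp requires $r \approx 113.5$ Å; against a genome with
a 669 bp double-stranded region that model covers 94.2% — a consistency
statement about the parametric model, not evidence that the spool *is*
the double-stranded region.

Numerical details: trace points are spaced so the *chord* between
consecutive base-pair centers equals the rise exactly (the angular step is
solved by root finding; at capsid-scale radii chord and arc differ by well
under $10^{-3}$ Å); capacity uses floor (complete base pairs only);
pseudo-atom export writes one Cα-style record per center.

## Problem sizes and reproducibility

The validation suite runs entirely from synthesised data: 500 random
additive matrices for tree exactness, 1000 random point-set pairs for the
superposition oracle, 1000 random spool specifications for the geometry
closed forms, and 20 evolved datasets of 6–10 leaves at 150 residues for
the end-to-end recovery rate. These sizes give the property checks enough
replicates to be meaningful while keeping a full run of the suite within
a few minutes on a single CPU. `scripts/acceptance.R` recomputes the
headline numbers from scratch under a caller-supplied seed; all
randomness in the package flows through explicit seeds, and the pipeline
proper (alignment through tree) is deterministic.

## Known limitations

* The aligner is a deliberately simple iterative-DP method: adequate for
  globally similar folds (the regime of fold-core phylogenies), but not a
  substitute for flexible or hinge-aware aligners when domains move.
* RMSD trees have compressed deep branches (see above); only topology and
  clade membership should be interpreted.
* Core residue ranges must be curated by the user for real structure
  sets; the package validates but cannot invent them.
* No density-map handling: the spool model is parametric geometry, fitted
  by the user's reading of a reconstruction, not by map correlation.
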