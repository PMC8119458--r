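---
title: "An orientation-dependent statistical energy function and fold-tree sampler for RNA refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An orientation-dependent statistical energy function and fold-tree sampler for RNA refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`rnarefine` scores an RNA conformation as a sum of six knowledge-based
terms,

    E = E_bb + E_bo + E_oo + E_rot + E_internal + E_clash,

and refines near-native models by Metropolis Monte Carlo simulated
annealing on a nucleobase-centric fold tree.  Every statistical table
behind these terms is harvested from a user-supplied corpus of RNA
structures; the package ships deterministic synthetic fixtures (ideal
duplexes and hairpin toys) so the whole pipeline runs and is tested
without any external data.

## Base-base term

Each base is a rigid body with a local coordinate system: origin at
C1', x-axis along the glycosidic bond (C1'-N9 for purines, C1'-N1 for
pyrimidines), z-axis normal to the base plane.  The relative placement
of two bases has six degrees of freedom: the origin-origin distance r
(0-15 Å in 0.3 Å bins), the twist omega about the inter-origin axis
(8° bins), and the inter-origin direction expressed in each local
frame, quantized by a sphere codebook of near-uniform unit vectors
obtained by Monte Carlo annealing of points with 1/d² repulsion.

Similarity between two placements is measured without superposition:
four fixed pseudo-atoms per base (T1-T4, identical for all base types)
yield a 4×4 cross-distance matrix per placement, and the metric (DDM)
is the RMS of the element-wise differences between two such matrices.
It is rotation- and translation-invariant, zero for congruent
placements, and correlates with superposition RMSD at r ≈ 0.97-0.99
over the deviation range the kernels operate in.  Note the defining
sum is over *differences* of corresponding cross-distances; a literal
sum of the cross-distances themselves would not vanish at identity and
could not support the "same orientation below 0.15 Å" reading used by
the density estimate.

The orientation density is a kernel sum f(x) = Σᵢ h(DDM(x, xᵢ)) with a
flat-top kernel: h = 1 below 0.15 Å, Gaussian with width 0.1 Å beyond.
For non-local pairs (sequence separation > 2) the density is
reweighted so that orientations that are merely frequent (e.g. induced
by neighbouring interactions) do not masquerade as strong direct
interactions: each observation inherits a weight
w = exp(-E_QM(c)/4.32)/f(c) from its nearest orientation-cluster
center c, where E_QM is a tabulated quantum-chemical pair energy and
4.32 kcal/mol the conversion between quantum and statistical energy
scales.  The energy is E₀ = −ln f'(x)/f_ref with f_ref fixed per class
so the table minimum is exactly −8.0 (non-local) or −4.0 (separations
1 and 2), and positive values are clipped to zero; only negative cells
are stored.  Lookup interpolates linearly along r and omega (omega
periodic) and resolves the two directions to their nearest codebook
vectors; interpolation across codebook cells is not attempted because
the cells are irregular, so the lookup is continuous in r and omega
with (small) jumps only across direction-cell boundaries.

Because the package consumes quantum energies as a table, the repo
ships only a synthetic stand-in generator (`toy_qm_table()`): a stated
analytic rule assigns each cluster center an energy that deepens with
pseudo-atom contact (range ≈ 0 to −30 kcal/mol).  It reproduces the
*scale and monotonicity* of ab initio pair energies, not their values.

## Base-oxygen and oxygen-oxygen terms

A base-oxygen contact is represented by the four distances from the
oxygen to the base's pseudo-atoms (kernel width 0.16 Å).  The energy
is E_bo = −w_bo·s(θ)·ln f/f_ref: a logistic gate
w_bo = 1 − 1/(1+exp((3.7−d_min)/0.08)) on the minimum base-oxygen
distance, and a quadratic angular score s(θ) that is 1 at the median
hydrogen-bond angle and 0 outside the corpus range trimmed by 3% per
tail.  The angular gate applies to the hydroxyl and phosphate oxygens
(O2', OP); ether/ester oxygens (O3', O4', O5') are not gated.  Unlike
the base-base term, the repulsive part is kept (attenuated by the
gates, not clipped).  f_ref scales the deepest log-ratio to −3.0,
about one third of a canonical G-C pair.

Oxygen-oxygen hydrogen bonds cover the O2'-O2', O2'-OP and OP-OP
classes.  A contact is the four defining atoms (the two oxygens plus
their bonded C or P) reduced to the six pairwise distances; the RMS
difference of those six distances is the metric (kernel width 0.1 Å),
which encodes the angular dependence implicitly and needs no
superposition.  Gate midpoint 3.3 Å, rate 0.07; minima scaled to
−3.0/−2.0/−1.5 per class.

## Clash, rotamer, internal terms

E_clash is zero beyond a statistical minimum-approach radius r₀,
rises to a constant plateau (k·0.4)⁴ with k = 3 in the 0.4 Å shell
inside r₀, and grows linearly below that.  As printed, the plateau
ends in a step at r₀ itself; the function is continuous at r₀ − 0.4.
r₀ is the 5th percentile of observed sub-5 Å distances per atom-type
pair (atoms within three covalent bonds excluded), resolved on a 1 Å
grid in the base-local frame for pairs involving a base (sp²) atom.
Two adaptations make this estimator usable on small corpora: backbone
atoms keep their individual atom names as types (so the routinely
short intra-backbone 1-5 contacts set their own radii), and every
radius is capped by a hydrogen-bond-aware hard-sphere ceiling per
element pair (e.g. O–O 2.60 Å, N–N 2.75 Å, C–C 3.10 Å).  On a large
corpus the percentile itself approaches those ceilings and the cap is
inert; on a desk-scale corpus the percentile of a narrow distance
distribution would otherwise land far above any physical contact
limit and penalize ordinary stacking.

E_rot treats the ribose as a main-chain rotamer: the eight sugar
atoms expressed in the base-local frame, kernel density with width
0.15 Å over the RMS atom deviation, energy −ln f/f_max (zero at the
densest conformer).  E_internal covers the phosphate closure: a
softened harmonic (quadratic core, linear wings, C¹ at |u| = 1) on
the deliberately flexible O5'-C5' bond (mean 1.422 Å, k = 5) and on
the P-O5'-C5' and O5'-C5'-C4' angles (120.7°, 111.1°, k = 0.1), plus
three conditional backbone-torsion energies
−ln P(ε,ζ|ν) − ln P(α|ζ,β) − ln P(β,γ|ν) from corpus statistics
(10° bins, the pucker improper ν reduced to its two regions, add-one
smoothing so no lookup is ever infinite).

## Fold-tree sampling

A conformation is a spanning tree over residues: nodes carry a base
frame and a ribose conformer, edges a rigid transform, typed by
pairing context (canonical pair, non-canonical pair, helix neighbour
5'→3'/3'→5', non-canonical-region neighbour, loop neighbour, jump).
Candidate edges are ranked pairs-first (canonical > non-canonical >
helix neighbours > loop neighbours); surplus connections are scored
but carry no tree edge, and the root is the first residue of the
longest canonical helix.  Nested and pseudoknotted pairings both
work because the tree does not require nesting.

Node moves select a ribose rotamer or perturb one base frame by less
than 0.2 Å / 2°; they touch nothing else except the two flanking
phosphates.  Edge moves transform the whole downstream subtree
rigidly — internal geometry is preserved exactly — either by a small
local wiggle or by drawing from the edge type's move set: the
observed relative placements of that context clustered in two levels
of 60, giving 3600 representative transforms.  On corpora smaller
than the move-set size the sub-cluster level samples with
replacement (the leaf count stays 3600).  Phosphates bridging
residues whose relative placement changed are rebuilt by a
hierarchical search over the ε-ζ torus: 50 coarse representatives,
50 refinements around the best, then a 5×5 grid in 1° steps — 125
internal-energy evaluations per closure.

The energy change of a move recomputes only terms with a changed
participant (the cached-pair bookkeeping is tested against full
recomputation to 1e-6).  Annealing uses Metropolis acceptance with
geometric cooling: refinement starts at T = 0.5 with factor 0.9,
prediction-style runs at T = 2.5 with factor 0.95, both ending at
0.01.  Steps per round follow the 400/2000/4000 rule per canonical /
non-canonical / other edge.  The clash and internal terms are ramped
from weight 0.05 at the initial temperature to 1 after 60% of the
rounds so early rounds can escape steric lock-in; the best-so-far
conformation is tracked at full weights and returned.  Refinement
mode ends the ramp after 20% of the rounds instead: a near-native
start needs no escape phase, and at desk-scale step budgets a long
soft-sterics phase lets trajectories drift into collapsed states they
cannot anneal out of once the weights harden (`ramp_end` on
`anneal_schedule()` exposes the choice).

# Design choices where the design was open

- **Twist convention.**  Omega is the signed angle (right-hand rule
  about the i→j axis) between the projections of the two x-axes onto
  the plane normal to the inter-origin axis.  Like any dihedral-type
  angle this quantity is invariant under exchanging the two frames
  (the axis flips together with the order of the projections), so the
  library stores it once per unordered pair; any fixed convention
  works as long as table building and lookup share it.
- **Separation classes.**  Inter-chain pairs are non-local ("2+") by
  construction.  f_ref(1) and f_ref(2) are normalized independently,
  each to −4.0.
- **Sparse table build.**  The kernel density is evaluated only at
  grid cells containing an observation plus their ±1 radial/twist
  neighbours.  Cells farther than ~0.6 Å in DDM from every
  observation carry relative density below e⁻¹⁰ and would be clipped
  to zero anyway, so the sparse build is exact for the stored table.
- **Density floor.**  The denominator of the reweighting factor is
  floored at 1e-6 so sparsely populated cluster centers cannot
  produce unbounded weights.
- **Move mixing.**  Node vs edge moves are chosen proportionally to
  their counts; within edge moves, local wiggles and move-set draws
  are 50/50.
- **Pucker regions.**  The improper ν splits at 0° into the C3'-endo
  and C2'-endo regions for the torsion conditioning.
- **Chain breaks.**  P-O3' beyond 2.5 Å terminates torsion triples
  and phosphate bookkeeping; insertion codes are rejected (the tree
  needs a simple linear order); altloc keeps 'A'/blank; hydrogens are
  ignored throughout.

# What the fixtures emulate

`ideal_helix()` builds duplexes from idealized planar base templates
(regular-polygon rings with mean bond lengths) and a C3'-endo ribose
attached in the base frame.  Starting from textbook A-form values,
the pair placement (displacement along the pseudo-dyad, two tilt
angles), glycosidic torsion, twist (27.4°/step) and rise (2.72 Å)
were re-calibrated once against these idealized templates by
minimizing phosphate-closure strain under steric and stacking
constraints; the result is a right-handed, sterically clean duplex
with canonical hydrogen bonding (N1-N3 2.8-3.0 Å) whose backbone
closes with near-zero internal energy.  `hairpin_toy()` adds a 4-nt
loop whose four base frames were calibrated the same way (closure +
sterics + a loop-closing non-canonical pair).  `perturb_structure()`
jitters every residue rigidly and re-closes all phosphates, so decoys
are chemically sensible refinement inputs with RMSD ≈ the requested
sigma.

The fixture corpus (five 10-bp duplexes covering all sixteen
dinucleotide steps, plus two hairpins) populates every statistics
class the tables need.  What it does *not* emulate: experimental
coordinate noise, modified nucleotides, multi-loop and junction
topologies, tertiary contacts, loop diversity, or the contact-distance
tails a 2000-structure corpus would provide.  Tests passing on these
fixtures demonstrate the machinery (table construction, scaling,
sampling, bookkeeping) — they do not certify accuracy on experimental
RNA, for which the statistics should be rebuilt from a curated PDB
corpus via `build_all_tables()` at full problem size.

# Problem sizes and numerical choices

The full-scale protocol (2000-vector codebook, 80 cluster centers,
1500 rotamers, step rule at scale 1) is the default interface, but the
shipped tests and the acceptance script run the study conditions at
desk scale, stated here as the package's own choices: a 200-vector
codebook, 16 orientation clusters per pair type, the fixture corpus
above, and an annealing step scale of 0.0025 (about 1,200 proposals
per trajectory for the 8-nt hairpin, whose full-protocol step count
would be 13,200 per temperature round).  The refinement
self-consistency study perturbs the hairpin by sigma = 1.0 Å and
refines 20 independent seeds in `refine` mode; besides the early
steric ramp discussed above, refinement mode draws only 10% of its
edge moves from the orientation-library move sets and keeps the rest
local, since library transforms behave as catapults when the start
point is already near-native.  Degenerate geometry
(vectors under 1e-6 Å, coincident origins) raises errors in the
geometry layer and is treated as a zero-energy/maximum-repulsion case
inside the samplers' guarded paths; rotations accumulated over long
trajectories are re-orthonormalized by polar decomposition whenever
round-off exceeds 1e-12.  Ties in nearest-codebook and
nearest-center lookups break to the lowest index.

# Known limitations

- The statistical radii and all densities are only as good as the
  corpus; the shipped fixtures are a functional stand-in, not a
  substitute for real structures.
- The clash plateau steps to zero exactly at r₀ (as the defining
  piecewise form is printed); forces in the shell are zero, which is
  physically odd but inert for Metropolis sampling.
- Base-pair breaking/formation is outside the sampler's move sets;
  the method refines near-native models and keeps the pairing fixed.
- Multi-chain systems are connected by jump edges with local moves
  only.
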