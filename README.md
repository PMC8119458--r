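# rnarefine

Knowledge-based refinement of near-native RNA 3D models in R.

RNA structure predictors routinely produce models that are close to the
native fold (1–3 Å) but chemically sloppy: clashing atoms, strained
backbones, imperfect base pairing. `rnarefine` implements an
orientation-dependent statistical energy function together with a Monte
Carlo simulated-annealing sampler that pulls such models toward cleaner,
lower-energy conformations while keeping their pairing fixed.

## The model

Each nucleobase is a rigid body carrying a local coordinate frame
(origin at C1′). The energy of a conformation sums:

- **Base–base term** — a six-dimensional table over the relative
  placement of two base frames (distance, twist, and the inter-origin
  direction expressed in each frame, quantized by a repulsion-optimized
  sphere codebook), estimated from a structure corpus by kernel density
  estimation on a four-pseudo-atom distance-matrix metric and
  optionally reweighted by per-cluster quantum-chemistry pair energies.
  Tables are normalized so the deepest cell is exactly −8 (non-local
  pairs) or −4 (sequence neighbors).
- **Base–oxygen and oxygen–oxygen terms** — hydrogen-bond-like
  contact densities for backbone oxygens against base planes and
  against each other, with distance gates and angular scores; minima
  −3.0, and −3.0/−2.0/−1.5 per oxygen-pair class.
- **Clash term** — a piecewise plateau/linear repulsion below
  statistically estimated per-atom-class contact radii.
- **Ribose rotamer and backbone torsion terms** — densities over an
  8-atom local sugar representation and over coupled
  (ε,ζ)/(α)/(β,γ) torsion tables conditioned on sugar pucker.

Sampling runs on a nucleobase-centric fold tree: a spanning tree over
bases whose edges prefer Watson–Crick pairs, then non-canonical pairs,
then stacked neighbors. Node moves perturb one base; edge moves move a
whole subtree rigidly, drawing either small local wiggles or
orientation-library transforms from a 3600-member hierarchical move
set. Phosphates crossing a moved boundary are rebuilt by a hierarchical
ε–ζ torus search costing exactly 125 internal-energy evaluations.
Energies update incrementally (the delta of a move equals a full
recomputation to numerical precision), wrapped in Metropolis
acceptance under a geometric cooling schedule with a ramped clash
weight.

Everything — including the corpus the statistics are estimated from —
can be built offline: the package ships deterministic generators for
ideal A-form duplexes, a calibrated 8-nt hairpin, perturbed decoys and
planted-mode observation libraries. See the methods vignette
(`vignettes/methods.Rmd`) for the science, the design decisions and
the limitations of the synthetic fixtures.

## Worked example

Build the energy tables from the synthetic corpus, perturb the hairpin
fixture, and refine the decoy back toward it (about half a minute on
one CPU):

```r
library(rnarefine)

corpus  <- fixture_corpus(seed = 1)          # 5 duplexes + 2 hairpins
tables  <- build_all_tables(corpus, seed = 1)

native  <- hairpin_toy("GCGCAAGC")
pairing <- pairing_annotation("GCGCAAGC", "((....))", rbind(c(3L, 6L)))
total_energy(native, tables)
#> E_bb          -48.4458
#> E_bo           -0.4718
#> E_oo            2.8911
#> E_rot           0.0000
#> E_internal     91.2021
#> E_clash        12.4416
#> total          57.6172

decoy <- perturb_structure(native, sigma = 1.0, seed = 7,
                           tables = tables$torsion)
structure_rmsd(native, decoy)                   # 1.03 A from native
total_energy(decoy, tables)$total               # 270.6

out <- refine(decoy, pairing, tables, n_models = 1, seed = 1,
              step_scale = 0.0025)              # desk-scale step budget
structure_rmsd(native, out$models[[1]])         # 0.85 A
out$energies[1]                                 # 113.3
```

Real structures enter through `read_rna("model.pdb")` and leave through
`write_rna()`; `inst/cli/rnarefine.R` exposes the same pipeline as a
command line (`build-tables`, `score`, `refine`, `make-fixtures`).

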