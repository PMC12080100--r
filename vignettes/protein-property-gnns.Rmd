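---
title: "Predicting protein properties with graph neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein properties with graph neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgnn)
```

## The problem and the models

Physics-based calculators for solvation free energy, hydrodynamic
properties or residue pKa values are accurate but slow — minutes to hours
per protein. `pgnn` implements two graph neural networks that regress such
properties directly from 3D structure, fast enough for screening whole
structure collections, plus the transfer-learning machinery to adapt a
pretrained encoder to new targets with little data.

**The global residue-graph model (GSnet).** A protein becomes a graph with
one node per residue. Node features are E(3)-invariant: a learned 64-d
embedding of the amino-acid type, sine/cosine/mask triples for φ, ψ and
χ₁–χ₃ (15 values — the mask bit is 0 when an angle does not exist, in which
case its sine and cosine are zeroed), and the distance from the residue's
Cα to the protein's center of mass, which locates the residue within the
fold. Residues whose Cα atoms are within 15 Å are connected; each scalar
distance is smeared onto K = 300 Gaussians with centers linearly spaced on
[0, 15] Å and width equal to the spacing (≈ 0.05017 Å), giving edge
features that are smooth in geometry. Six transformer message-passing
layers with a single attention head update the 150-d node states; each
layer applies attention over in-neighbors with edge-augmented keys and
values, adds a learned root transform of the receiver, and finishes with a
residual connection and LayerNorm. A mean over all node embeddings feeds a
4-linear-layer MLP (1024 hidden channels, shifted-softplus activations)
that outputs the six global targets simultaneously, or one value for
transfer targets.

**The local atom-graph model (aLCnet).** pKa shifts are governed by the
local electrostatic environment, so this variant builds one small graph per
ionizable residue: all C, H, N, O and S atoms within 10 Å of the Cα
(metals and other elements excluded), with partial charges as an explicit
node feature next to residue-type and atom-type embeddings. Edges connect
atoms within 5 Å, smeared on [0, 5] Å with the same K = 300; when an atom
has more than 150 in-neighbors only the 150 nearest are kept (ties broken
by serial number for determinism). Three message-passing layers with three
attention heads act on 75-d nodes. The pKa readout concatenates the
selection mean **μ**, the Cα embedding, and the mean over the atoms of the
residue of interest (225 values). The GSnet-based pKa readout instead
concatenates [**μ**, h_i, μ₆, μ₈, μ₁₀, μ₁₂, μ₁₅] (1050 values), where μ_r
averages embeddings of residues within r Å of the residue of interest
(always including it, so the pooled set is never empty). The pKa heads are
deeper (6 linear layers, 20% dropout) because the task is
low-data.

Predicted pKa values are reported as `null + shift`: the network is trained
in shift space relative to a reference (model-compound) pKa table, which
keeps the null model as the exact zero function and makes the baseline
comparison trivial. Training in absolute space is available
(`model$target_space <- "absolute"`); the prediction report always carries
`shift`, `null` and `pka` columns so the convention is unambiguous.

## Training

Targets are z-scored with mean and standard deviation computed on the
training split only; validation data reuse those statistics. Solvation free
energies are typically available for only part of a corpus, so the loss is
a masked MSE: masked-out entries contribute exactly zero to the loss, to
every parameter gradient, and to the averaging denominator. The optimizer
is Adam at 1e-4, switched to 1e-5 after epoch 50 (optimizer moments are
kept across the switch — the simpler choice, documented here because it is
a genuine degree of freedom), batch size 64, early stopping when validation
loss fails to improve (strict inequality, no minimum delta) for ten
consecutive epochs; residue-level SASA and pKa regimes instead run a fixed
10 or 100 epochs. `train_repeats()` trains several models from independent
seeds and selects by validation loss (ties resolved toward the lowest
repeat index); `top_k_summary()` implements the top-10-of-20 reporting
convention.

Transfer learning has two modes. In `transfer_frozen`, every GNN parameter
(embeddings, encoders, message-passing layers) is excluded from the
optimizer and is bit-identical before and after training — only the output
MLP trains, and since the readout features are then constant they are
precomputed once per sample. In `transfer_finetune` the whole network
trains from the checkpoint. The four pKa training variants (original or
SASA-fine-tuned encoder × frozen or optimized) are expressible as
checkpoint + mode combinations.

The networks, reverse-mode differentiation and Adam are implemented in this
package over base-R matrices. Gradients are exact (unit tests check them
against central finite differences at ~1e-12 absolute agreement), and
backward passes prune branches that lead only to constants, which matters
because the 300-wide edge features are fixed inputs.

## The synthetic-structure generator

Real training corpora (AlphaFold-scale structure sets, curated pKa
databases) are external; the generator provides deterministic all-atom
chains so that every stage — parsing, featurization, training, transfer,
splitting, prediction — runs and is tested fully offline. Backbones are
built from ideal internal coordinates (helix φ = −57°, ψ = −47°; extended
φ = ψ = 180°; coil draws both uniformly), with minimal side chains (Cβ
plus one χ₁-bearing γ atom where the type allows, so the dihedral-mask
machinery is exercised), optional backbone hydrogens, and Gaussian
coordinate jitter (default 0.3 Å in datasets). Default dataset lengths are
12–32 residues: large enough for non-trivial graphs (~20 neighbors per
residue in a helix), small enough that the full acceptance suite runs in
minutes on one CPU.

Five of the six targets are documented closed-form proxies chosen to land
in realistic ranges so normalization behaves like it would on real data:
Rg is exact (mass-weighted); Rh = 1.29·Rg; Dt = 2450/Rh nm²/µs and
Dr = 1.84·10⁵/Rh³ µs⁻¹ (Stokes–Einstein-like constants for water at 298 K,
with Rh in Å); V is the sum of atomic sphere volumes; ΔG_sol is a Born-like
proxy −685.6·Σq²/Rh kJ/mol. Twenty percent of generated records drop
ΔG_sol to mirror partial solvation coverage and keep the masking path hot.
These proxies are rotation/translation invariant and obey known scaling
laws (doubling coordinates doubles Rg, halves Dt, shrinks Dr eight-fold),
which the tests assert. What passing tests on synthetic data do **not**
show: accuracy on real proteins, realistic side-chain packing or rotamer
statistics, or the physics of real hydrodynamics and electrostatics — the
generator validates the machinery, not the science of any particular
trained model.

A learnability surrogate closes the loop: a full-size global model trained
from scratch on 200 synthetic structures with Rg as the single target
reaches validation Pearson r > 0.95. Rg is computable from node geometry,
so the architecture must be able to learn it; the surrogate uses a larger
step (1e-3) and smaller batches (16) than the default schedule because at
200 samples an epoch is ~13 optimizer steps rather than the thousands per
epoch the 1e-4 default is tuned for, and 15 epochs, which keeps the run
inside a few minutes on one CPU (convergence is typically reached by epoch
5).

## The leakage-aware splitter

Residue-level pKa data are riddled with near-duplicates (the same residue
measured in homologous structures under different identifiers), which
inflates naive test performance. The splitter clusters parent sequences
greedily, longest first, at identity > 0.5 — each sequence joins the first
cluster whose representative it matches, else founds one — and aligns each
member to its cluster representative to obtain alignment-column maps.
Identity comes from ends-free pairwise alignment (match +1, mismatch 0,
affine gaps open 10 / extend 0.5) with the denominator equal to the
alignment length including gap and overhang columns; this is an in-repo
analogue of the usual external clustering tools, and behavioral parity with
them is explicitly not claimed — what matters, and what is tested, is the
similarity predicate. Two records are similar iff they are in the same
cluster **and** the same alignment column **and** of the same residue type.
A record whose residue falls in a gap relative to the representative gets
no column and is conservatively treated as dissimilar, with a warning.
Training keeps internal duplicates (harmless there); validation is
deduplicated and purged against training; a disjoint test source is
deduplicated and purged against both, and a final exhaustive train × test
predicate scan must come back empty — the audit trail (every pair found at
every stage) is returned to the caller.

## Numerical choices and degenerate inputs

- Cutoffs are inclusive (≤) at 15, 10 and 5 Å; boundary behavior is fixed
  for determinism.
- Chain breaks (residue-numbering gaps or Cα–Cα > 4.5 Å) end φ/ψ
  continuity; both flanking residues are treated as termini for the broken
  angle. Missing side-chain atoms mask the corresponding χ rather than
  being rebuilt.
- Altloc records other than `' '`/`'A'` are dropped; insertion codes are
  appended to the residue identity in file order; blank element columns
  fall back to the first non-digit character of the atom name; masses come
  from a fixed element table (H 1.008, C 12.011, N 14.007, O 15.999,
  S 32.06).
- LayerNorm uses ε = 1e-5 with a learned affine; attention includes a
  learned root/self term by default (`root_term = FALSE` reverts to the
  pure residual); encoder widths (64-d embeddings, two-layer continuous
  encoders, one 2×node_dim hidden reduction layer) are config-exposed.
- Edgeless graphs (e.g. a single residue) skip attention and reduce each
  layer to LayerNorm(h + root(h)).
- Shrake–Rupley SASA uses deterministic golden-spiral sphere points
  (default 960; no RNG). Radii: PQR values when present, else C 1.70,
  N 1.55, O 1.52, S 1.80, H 1.20 Å; probe 1.4 Å. Per-residue values sum to
  the molecular value exactly. Because the point grid is fixed in the
  global frame, rotation invariance holds only to the quadrature error of
  the point count (~0.2% at 480 points); translations are exact.
- The null pKa table (ASP 3.65, GLU 4.25, HIS 6.54, LYS 10.40, TYR 9.84,
  CYS 8.55) is the package's configurable choice of the common experimental
  reference scale.
- All computation is in double precision (R has no 32-bit float storage);
  distances are computed in double and the invariance contracts are
  asserted at the single-precision tolerance 1e-4, which the
  implementation passes with orders of magnitude to spare.
- Checkpoints are single-container files with a format version and a
  configuration echo, and refuse to load into a mismatched configuration.

## Known limitations

Training at realistic corpus scale (10⁵ structures) and reproducing
published accuracy on real proteins requires external data and GPU-class
compute; this package validates the architecture, training mechanics and
data hygiene at desk scale. mmCIF input, hydrogen placement/optimization,
structure repair, multi-model NMR expansion (only the first model is read)
and periodic boundaries are out of scope. The greedy clusterer and
representative-based column maps may differ from external
clustering/multiple-alignment tools in gappy regions; the audit report
makes the resulting decisions inspectable.
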