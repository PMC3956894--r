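---
title: "Folding globular proteins with predicted contacts: models and methods"
author: "contactfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding globular proteins with predicted contacts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`contactfold` implements coarse-grained de novo structure prediction of small
globular proteins by fragment assembly, guided jointly by knowledge-based
statistical potentials and a pseudo-energy term built from predicted
residue-residue contacts. Contact predictions of the kind produced by sparse
inverse-covariance methods on large multiple sequence alignments arrive as a
list of residue pairs `(i, j)` with a probability-like confidence (PPV); the
package consumes such lists in the CASP RR dialect, embeds them into a
seven-term objective, samples conformations with replica-exchange simulated
annealing over fragment-replacement moves, and assesses the resulting decoy
ensembles with scores built from long-range contact satisfaction and
structural consensus.

Everything is testable without external data: a synthetic generator produces
idealized toy proteins, their true contact maps, noisy "predictions" at a
controlled precision, and labelled decoy sets.

# Chain representation

A conformation is a chain of per-residue backbone torsions (phi, psi, omega,
degrees). Cartesian coordinates for N, CA, C, O and an ideal C-beta are
rebuilt deterministically from torsions with fixed ideal bond geometry
(N-CA 1.458 Å, CA-C 1.525 Å, C-N 1.329 Å; standard angles), omega defaulting
to 180° (trans). Side chains are not modelled: the fidelity target of the
package is topology, which C-beta-level geometry supports. All contact
distances are CB-CB, with CA substituted for glycine.

# The energy function

The objective is a weighted sum of seven terms,
`E = sum_k W_k * E_k`, with terms:

* **SR, LR** — distance-binned residue-pair potentials from the inverse
  Boltzmann relation `E = -ln((observed + pc)/(expected + pc))`, trained on
  reference structures, in two sequence-separation classes (SR: 5-10, LR:
  >10). Residues are collapsed to seven classes (hydrophobic, aromatic,
  polar, positive, negative, glycine, proline) so that desk-scale training
  sets give stable statistics; bins are 0-15 Å in 0.5 Å steps with
  pseudocount 1 per bin, energies in kT = 1 units.
* **SOLV** — a burial potential over the count of CB neighbours within
  10 Å (capped at 20), trained the same way.
* **HB** — a secondary-structure reward: minus the number of residues whose
  backbone torsions realize their predicted H/E state (helix: phi in
  (-120,-30), psi in (-80,-5); strand: phi in (-180,-90), psi > 90 or
  < -150).
* **COMPACT** — `(Rg - 2.2 L^0.38)^2` on the CA radius of gyration; the
  coefficient and exponent are the standard globular scaling, and the
  quadratic form penalizes both collapse and over-expansion.
* **STERIC** — soft-sphere repulsion `sum max(0, r_i + r_j - d)^2` over
  atom pairs of residues at least two apart in sequence (radii N 1.45,
  CA/C/CB 1.6, O 1.35 Å).
* **RR** — the predicted-contact pseudo-energy described next.

The SR/LR/SOLV stand-ins are deliberately simple, fully specified forms so
that every term is exactly testable against a brute-force loop; each sits
behind its own function so a richer potential can replace it.

## The contact term

Each predicted contact contributes a square well with exponentially decaying
flanks:

* `E(d) = -P` for `d <= d_con` (default 8 Å),
* `E(d) = P (1 - 2 exp(-(d - d_con)/lambda))` beyond, with decay length
  `lambda = 4` Å.

The form is continuous at the well edge, attraction fades exponentially with
distance, and an unsatisfied contact is eventually penalized by `+P` — the
penalty is proportional to the prediction confidence, which suppresses the
influence of weak false positives. The decay length of 4 Å brings the term
within ~95% of its asymptote by d of roughly 20 Å, keeping gradients local.
The functional form is configurable; the implementation treats it as a
pluggable component behind `rrcon_energy()`.

All contacts with positive probability are used (no truncation of the list);
the minimum sequence separation is 5, matching the shortest "short-range"
contact class (5-9; mid-range 10-23; long-range >23 — separation 23 itself
is classed as mid-range).

## Weight calibration

Weights are not hand-set. For a given target, an ensemble of random-torsion
conformations is generated (default 200; torsions drawn from a mixture of
the helical and extended basins plus a uniform fraction, mimicking
fragment-assembled chains), each term is evaluated across the ensemble, and
`W_k = f_k * sd(SR) / sd(term_k)`, so that each weighted term fluctuates as
much as the short-range pair term, times the user factor `f_k`. Factors
default to 1 except STERIC (3) and RR (5): clashes must stay prohibitive and
the contact information is deliberately weighted to rival the sum of the
statistical terms.

# Fragment assembly

The fragment library is mined from source structures: all 9-residue torsion
windows ("fixed" fragments — 9 spans a helical turn plus flanks) plus
supersecondary fragments covering two secondary-structure elements (H or E
runs of at least 4 residues, assigned geometrically from torsions rather
than via an external assignment program) joined by a loop of at most 8. To
keep benchmark folding blind, windows with >= 35% sequence identity to any
equal-length target window are removed.

At each target position a shortlist is built: fragments must agree with the
predicted secondary structure at >= 70% of positions (confidence-weighted),
and survivors are ranked by a threading score — the SR/LR pair energy of the
target residues mounted on the fragment's own geometry — keeping the best 25.
The threading score uses only the pair tables (no solvation), which is cheap
and sufficient to order candidates.

# Sampling

Search is Metropolis Monte Carlo over two move types: replacement of the
torsions at a random position by a random shortlist fragment (probability
0.8) and a single-residue Gaussian torsion perturbation of 10° (0.2),
starting from the extended chain. Eight replicas run on a geometric
temperature ladder between 0.5 and 10 kT with neighbour exchanges attempted
every 500 moves per replica under the standard Metropolis exchange
criterion; the whole ladder is annealed linearly over the run. The run's
step budget is quoted as a single total over all replicas (so `steps =
50000` with 8 replicas runs 6250 moves per replica); replica count,
temperatures and the move mixture are not prescribed by the underlying
approach and are exposed in `anneal_config()`. The returned model is the
lowest-energy conformation visited by the coldest replica, with its energy
recomputed from the returned coordinates (so decoys are self-contained).

Contacts can enter the objective three ways: all at once (`all`), or
`sequential` — only short-range contacts (separation <= 9) at the start,
the active separation bound growing linearly with each annealing cycle
until the full range `L - 1` is reached (a "cycle" is one temperature step
of the annealing schedule; 50 cycles per run by default), or not at all
(`no_contacts`); `contacts_only` zeroes every statistical weight instead.
The `combined` ensemble mode pools equal numbers of `all` and `sequential`
runs and lets model selection choose across both.

# Model selection and quality assessment

Within an ensemble, models are selected by energy (top-1, top-5) or by
greedy TM-score clustering: the decoy with the most neighbours at TM >= 0.5
becomes a representative and is removed with its neighbours, repeatedly;
representatives of the five largest clusters are reported.

Three ensemble-level quality scores are computed:

* **MQA_LR** — among the top-L predicted contacts (L = chain length), count
  the long-range ones (`N_LR`, separation > 23) and the fraction satisfied
  in the assessed model at CB-CB <= 8 Å (`CON_LR`); the score is
  `CON_LR * ln(1 + N_LR)`, monotone in both the satisfied fraction and the
  amount of long-range information. It is evaluated on the final
  (lowest-energy) model.
* **mean pairwise TM** — the mean TM-score over all unordered decoy pairs
  (both orientations scored, larger kept); structural consensus of the
  ensemble.
* **CS** — the combined score `7 * TM + 1 * MQA_LR`. A model is called a
  correct fold when CS > 3.4 (thresholds 3.0 and 6.0 pair with the TM >=
  0.4 and 0.7 claims and are configurable).

The TM-score itself is computed with the standard length-dependent scale
`d0 = 1.24 (L - 15)^{1/3} - 1.8` (clamped at 0.5 Å) and a deterministic
superposition search: seeds from contiguous windows of lengths L, L/2, L/4
(and 4 for short chains), each refined by iterative distance-cutoff residue
reselection and a final score-weighted superposition ascent; short chains
additionally get a fixed set of deterministic rotation and random-subset
seeds so that the search is exhaustive where exhaustiveness is affordable.
DME (superposition-free RMS difference of intramolecular CA distances) and
the classical Kabsch superposition complete the metric set. Fragment-fit
quality lists use the upper-fence outlier rule `>= Q3 + 1.5 IQR` with
type-7 quartiles; constant lists have no outliers by convention.

# The synthetic generator

`make_toy()` builds toy natives from four topologies (helix hairpin,
three-helix bundle, beta hairpin, mixed sheet+helix) as ideal-torsion
elements joined by fixed loop motifs; the motifs were selected once, by
seeded search over loop torsion space, for clash-free element packing that
survives the generator's 5° loop jitter. A candidate native is accepted only
if clash-free and packed (at least `0.5 L` native contacts at separation >=
5); loop jitter is resampled otherwise, up to 100 attempts. Sequences are
hydrophobic-patterned but aperiodic — the buried helix face and alternating
strand positions draw from a hydrophobic pool, the rest from polar/charged
pools, using the seeded RNG — so that different toys are distinguishable to
the sequence-based fragment decontamination.

`simulate_predictions()` emulates a contact predictor at a chosen precision
p: `round(n p)` true native contacts plus false pairs required to be > 12 Å
in the native, so "false" remains unambiguous under model jitter. PPVs are
drawn truth-independently (uniform — any top-k prefix then has expected
precision p) or truth-correlated (Beta(4,2) vs Beta(2,4)) to mimic an
informative ranking. `make_decoy_set()` produces labelled near-native decoys
(loop-torsion jitter, optionally plus a global backbone jitter emulating
harder targets) and far decoys (9-residue block shuffles with 30% of
torsions re-drawn from broad basins, which destroys topology while keeping
the chain locally protein-like).

What the toys do *not* emulate: real side-chain packing, irregular loop
conformations, long-range beta sheets between distant strands, domain
boundaries, alignment-derived contact bias, or native Ramachandran
diversity. Passing the package's tests therefore demonstrates internal
correctness and the qualitative physics of contact-guided assembly at desk
scale, not performance on real proteins.

# Benchmark experiments and problem sizes

Two standard experiments are packaged so that results are reproducible with
one call each (`run_fold_benchmark()`, `run_qa_benchmark()`):

* the contact-benefit comparison folds the 60-residue helix hairpin 20
  times with its true contacts (ppv 1) and 20 times with no contacts at
  50,000 total MC moves per run, and compares the TM-scores of the returned
  models (one-sided Welch test);
* the QA discrimination experiment builds 10 targets of graded difficulty
  (near-decoy loop jitter 4-60°, global jitter 0-12°, contact precision
  0.95 down to 0.3), each with a 10-near + 10-far labelled ensemble scored
  by a calibrated model, and measures how well CS separates ensembles whose
  selected model is a correct fold (TM >= 0.5) from those where it is not
  (rank AUC), plus precision/recall of the CS > 3.4 call.

These sizes — 60-residue targets, ensembles of 20, 50,000-move runs — are
the package's chosen desk-scale study conditions: large enough for the
helix hairpin to fold reproducibly under contact guidance, small enough
that the complete test suite and both benchmarks run on a laptop core.

# Numerical and design notes

* Residue indexing is 1-based everywhere in files and user-facing objects;
  0-based indices exist only at the C++ boundary.
* RR files: the d_low/d_high columns are ignored; the well bound is the
  model's `d_con`, not the file's. Duplicate `(i, j)` records keep the
  highest PPV; ordering ties break lexicographically by `(i, j)` for
  determinism. `min_ppv` filtering is strict (`>`), so the default keeps
  exactly the positive-probability contacts.
* ss2 confidence triplets that do not sum to 1 (PSIPRED rounds to three
  decimals) are renormalized with a warning.
* MSA filtering order: duplicate rows first, then deletion of query-gap
  columns, then the identity filter (matches over non-gap query columns;
  the denominator choice matters and is documented in `filter_msa()`).
* The sequential schedule rounds half-up; at cycle 0 the bound is 9 (end
  of the short-range class), at the final cycle `L - 1`.
* Fold runs are bit-reproducible from an integer seed: the sampler uses its
  own Mersenne-Twister-derived generator rather than R's global RNG, with
  uniform and normal variates generated from explicit bit arithmetic so
  results do not depend on library-specific distribution implementations.
* Tiny chains: `d0` is clamped at 0.5 Å; TM-score requires L >= 3;
  degenerate (collinear) point sets are rejected by `superpose()`.
* `calibrate_weights()` guards against zero-spread terms (weight falls back
  to the user factor with a warning).

# Limitations

The statistical potentials are desk-scale stand-ins trained on synthetic
toys; they are not transferable to real proteins without retraining on a
curated structure set. The supersecondary pattern inventory (H-loop-H and
friends with elements >= 4, loops <= 8) is an interpretation, as is the
linear sequential schedule anchored at separation 9. Replica counts,
temperatures, and move mixtures are pragmatic defaults, all exposed in
configuration. The TM-score search is deterministic and strong at the sizes
used here but is not a certified global optimizer for arbitrary inputs.
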