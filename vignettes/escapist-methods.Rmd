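---
title: "Electrostatic pair potentials for protein model quality assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic pair potentials for protein model quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Structure-prediction pipelines emit many closely ranked candidate models,
and a model quality assessment program (MQAP) must pick the one closest to
the native fold. `escapist` implements a knowledge-based MQAP built on a
single physical feature: the **electrostatic potential difference (EPD)**
between the Cβ atoms of sequence-consecutive residues, expressed in the
dimensionless unit kT/e (k Boltzmann's constant, T = 298 K, e the
elementary charge; 1 kT/e ≈ 25.7 mV).

The Cβ atom is the first sidechain atom — present in every standard residue
except glycine — and serves as a one-atom proxy for the chemically diverse
sidechain. Backbone-only features carry no sequence information: the EPD
across the C–N peptide bond, or between consecutive Cα atoms, has
essentially the same distribution for every amino-acid pair, because the
geometry of those atoms is fixed by the backbone. The Cβ–Cβ EPD, in
contrast, reflects the charge and polarity of the two sidechains and takes
well-separated mean values for different residue-type pairs, with a
comparatively small spread in native structures. That contrast is exactly
what the package's backbone-control modes (`mode = "cn"`, `mode = "ca"`)
versus the default Cβ mode (`mode = "cb"`) reproduce on synthetic fixtures.

### Learning phase

Given a set of native structures, for every chain and every consecutive
residue pair (n, n+1) — skipping `ignore_nterm` and `ignore_cterm` residues
at the termini, where unmodeled terminal charges perturb the potential —
the signed feature is

    EPD = φ(atomP of residue n) − φ(atomQ of residue n+1)

Pair types are order-independent. The key is the two one-letter codes
sorted alphabetically; in the symmetric atom modes (Cβ–Cβ, Cα–Cα) swapping
the residue order negates the difference exactly, so the observation enters
with its sign reversed (`multfactor = −1`) and "AC" statistics pool both
A→C and C→A occurrences. In the asymmetric C–N mode the feature belongs to
the peptide bond itself and is already order-independent; applying the sign
flip there would split each pair type into an artificial ± mixture, so the
raw sign is kept. This asymmetric-mode convention is the package's own
resolution of an ambiguity in the original algorithm statement, chosen so
that the backbone control reproduces its expected single-population
behaviour.

Per pair key the mean ("mean learnt value") and standard deviation are
computed, and a pair type is retained only if

* its SD is at most `sd_thresh` (default 50 kT/e), and
* it has at least `min_samples` observations (default 30).

The SD filter is what removes uninformative features mechanically:
cysteine-containing pairs, whose EPDs are broad and erratic (the CC pair,
with its narrow distribution, survives), would be excluded by spread alone.
An explicit `exclude_cysteine` flag additionally drops *all* C-containing
pairs for users who prefer the conservative choice. The retained `(pair,
mean, sd, n)` table is the **template**, written as a TSV with provenance
comments; `reference_template()` loads the packaged 16-pair Cβ sample
learned from a nonredundant high-resolution crystal-structure set with the
reference APBS electrostatics.

Two pooling conventions exist and differ when structures contribute
unequal pair counts: pooling all observations (every occurrence weighs
equally; the default, matching the per-observation accumulation of the
learning algorithm) and per-protein averaging (each structure's mean weighs
equally; `pooling = "per_protein"`). Both are implemented; the retention
filter always uses the pooled-observation SD.

### Quality assessment: the PDscore

Scoring a candidate structure repeats the feature extraction and compares
each canonical pair EPD with its template mean:

    PDscore = (1/NumberCompared) * Σ |EPD_observed − template mean|

Only pairs whose type is present in the template increment
`NumberCompared`; glycine-containing pairs (no Cβ) and filtered pair types
are skipped, never averaged in as zeros. A structure with *no* comparable
pair is an error (`escapist_unscorable`), deliberately distinct from a
perfect score of 0. The original formulation's fixed denominator (N−x−y−2)
disagrees by one with its own summation bounds; the algorithmic
`NumberCompared` normalization is taken as normative, which also handles
skipped pairs correctly.

The ranking hypothesis is Boltzmann/Anfinsen reasoning: native structures
are minimum-free-energy states, statistical features harvested from native
structures are sampled near their ensemble means, hence the native should
deviate least — the minimum PDscore — among a set of candidates.
**Specificity** for one target is the fraction of decoys whose PDscore is
strictly greater than the native's; a decoy tying the native counts against
the native (the conservative reading, consistent with the published binary
misfold column). Aggregate specificity is the unweighted mean over targets.
Unscorable or unparsable decoys are excluded from the denominator with a
warning.

## Electrostatics backends

The reference electrostatics is the PDB2PQR(PARSE) + APBS toolchain at the
standard continuum settings: solute dielectric 2, solvent dielectric 78,
probe radius 1.4 Å, 298 K, zero ionic strength. `run_external_backend()`
writes the control file with exactly those parameters, runs `apbs`, reads
the OpenDX grid and interpolates at atom centers; it raises a
`escapist_missing_executable` condition when the binaries are absent.
Absolute potentials (and therefore template means) depend on the grid and
charge setup, so templates record their backend provenance and should only
be compared within one backend.

For self-contained, deterministic work the package carries its own solver
stack:

* **Direct Coulomb** (default): pairwise sums in a homogeneous dielectric,
  exact and fast. The potential at an atom excludes that atom's own charge.
  The homogeneous constant defaults to the solute dielectric (2), an
  effective protein-interior value that puts Cβ-mode EPDs on the same
  ~10–100 kT/e scale as the reference electrostatics.
* **Finite-difference Poisson** (`solve_potential()`): vectorized red-black
  successive over-relaxation on a regular grid; charges spread trilinearly
  to the eight surrounding nodes; dielectric equal to the solute value
  inside the probe-inflated van der Waals envelope and the solvent value
  outside (face values are arithmetic node means, no surface smoothing);
  Dirichlet boundary from the analytic Coulomb sum in the outer medium. At
  zero ionic strength the linearized Poisson–Boltzmann equation *is* the
  Poisson equation, so no salt term is carried. Convergence is declared
  when the largest per-sweep update falls below `tol` (default 1e-5)
  relative to the field magnitude; non-convergence within `max_iter` sweeps
  is a classed error reporting the residual.
* **Trilinear readout** (`potential_at()`): the standard 8-node
  interpolation, exact on affine fields — which is what the unit tests
  assert to machine precision.

Grid defaults: 0.5 Å spacing, box = 1.7 × the molecular extent with a 16 Å
floor so that small test systems stay away from the boundary. The
charge/radius assignment bundled for the built-in backends is a heavy-atom
table in the spirit of PARSE with hydrogen charges collapsed onto their
bonded heavy atoms; every residue sums exactly to its integer formal charge
at neutral pH (Asp/Glu −1, Lys/Arg +1, His 0), and when the atoms carrying
a formal charge are absent — e.g. structures truncated at Cβ — the missing
charge is restored onto Cβ so integrality survives truncation.

## What the synthetic fixtures emulate — and what they do not

`generate_peptide()` builds idealized peptides from frozen Engh/Huber-style
bond lengths and angles (trans peptide bonds, tetrahedral Cβ), at
configurable backbone dihedrals (default extended), with seeded isotropic
Gaussian coordinate jitter standing in for coordinate uncertainty.
`generate_decoy_family()` writes a native plus noise-perturbed copies in
the directory layout `evaluate_decoy_set()` consumes; per-coordinate noise
of SD σ yields decoys at mean all-atom RMSD σ√3. All generators are pure
functions of their arguments and seed.

The default study conditions used throughout the tests and the acceptance
script are: learning sets of 50 peptides of 30 residues over the
six-residue alphabet {A, D, F, K, S, T} (chosen to mix charge signs and
polarities so all pair types collect ≥ 30 samples), native jitter 0.05 Å,
and benchmarks of 5 targets with 10 decoys each at 2 Å noise. These sizes
keep a full run in seconds while leaving every pair-type statistic
well-populated.

Passing on these fixtures demonstrates the machinery — canonicalization,
filtering, normalization, ranking — and the self-consistency of the method
under its own generative model. It does *not* demonstrate discrimination on
real decoy sets: idealized peptides have no packing, no solvent structure,
no torsional decoy modes, and Gaussian coordinate noise is a much cruder
error model than fragment-assembly decoys. Reproducing the published
benchmark specificities requires the external structure databases and the
APBS toolchain, which the package's optional integration path supports but
its test suite deliberately does not depend on. The published per-target
score and specificity tables ship as data files and are reconstructed
through the package's ranking/aggregation path as in-paper checks.

## Numerical and design choices

* Termini: `ignore_nterm = ignore_cterm = 3` by default (values are
  configurable; the original work excludes terminals without stating the
  count).
* Chain breaks: pairs spanning an author-numbering gap > 1 are skipped;
  pairs never cross chains. Multi-chain files are scored over all chains
  with a flag to restrict to the first chain.
* Altlocs: highest occupancy wins; ties prefer altloc "A", then
  lexicographic order. Nonstandard residues (MSE etc.) are dropped, not
  remapped — the template has keys only for the 20 standard types.
* Sample SD uses the n−1 denominator; a single observation gets SD 0 and
  is left to the `min_samples` filter.
* `min_samples = 30` is applied uniformly (the source material uses a
  ">30" rule only for its sequence-distance bins).
* Ties between native and decoy count against the native; the
  native's rank reports 1 + the number of decoys scoring ≤ it.
* Scoring with the built-in backend is bit-reproducible, and rigid-body
  motion changes a PDscore only at floating-point noise level in direct
  mode (pairwise distances are invariant).

## Known limitations

* The built-in direct-Coulomb mode has no dielectric boundary; it is a
  deliberately simple, exactly testable stand-in whose absolute EPD values
  differ from APBS output. Templates are backend-specific by construction.
* The finite-difference solver uses a hard, unsmoothed dielectric boundary
  and arithmetic face averaging — adequate for the few-percent agreement
  the validation targets, not for publication-grade solvation energetics.
* Physically non-viable decoys (atom clashes, impossible charge
  geometries) still yield finite potentials and scores; electrostatic
  deviation alone cannot flag them, which is why combining features is
  advisable before trusting a ranking on such sets.
* The sequence-distance SD profile on idealized fixtures with i.i.d.
  synthetic potentials is flat by construction; the rising profile seen in
  native structures is a property of real conformational correlation that
  the generator does not emulate.

## A worked session

```{r example}
library(escapist)

# learn a template from synthetic natives
set.seed(1)
seqs <- replicate(50, paste(sample(c("A","D","F","K","S","T"), 30,
                                   replace = TRUE), collapse = ""))
natives <- lapply(seq_along(seqs), function(i)
  generate_peptide(seqs[i], jitter = 0.05, id = sprintf("n%02d", i)))
tpl <- learn_features(natives, feature_config())
summary(tpl)

# score a native against a 2-Angstrom decoy of itself
native <- natives[[1]]
decoy <- perturb_structure(native, 2, seed = 99)
pd_score(native, tpl)
pd_score(decoy, tpl)

# full decoy-set evaluation
root <- tempfile()
synthetic_decoy_benchmark(root, n_targets = 5, n_residues = 30,
                          noise_levels = 2, count_per_level = 10, seed = 11)
evaluate_decoy_set(root, tpl)
```
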