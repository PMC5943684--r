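---
title: "Methods: comparative structural and flexibility analysis with thermadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative structural and flexibility analysis with thermadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thermadapt` compares a family of homologous enzymes adapted to different
habitat temperatures: a reference structure with solved coordinates, a
set of homolog models, and conformer ensembles sampled at temperatures
around each enzyme's catalytic optimum. This vignette documents the
models and procedures, the parameters that matter, the synthetic-data
generators the test suite is built on, and the numerical choices made
where the design was genuinely open.

## Coordinate model and conventions

All geometry operates on a flat atom table parsed from PDB records
(`read_structure()`, backed by bio3d). **Author residue numbering is the
canonical coordinate system**: residues are addressed as
`chain:resseq[icode]` keys everywhere, and sequential 1..N indices are
derived views. This matters because catalytic residues of real enzymes
are cited in author numbering (e.g. a nucleophile at position 155 whose
chain starts at 1 but has gaps), and any analysis that silently renumbers
breaks cross-referencing.

Alternate locations are resolved by highest occupancy with an
alphabetical tie-break (so 'A' wins a 50/50 tie) — a deterministic rule
chosen because upstream conventions differ and silent nondeterminism in
an input parser poisons everything downstream. Waters are dropped; other
hetero groups are kept but flagged and excluded from all protein-internal
censuses. Units are Angstrom throughout; report writers emit RMSF in both
Å and nm because plotting conventions in the molecular-dynamics
literature vary.

## Interaction criteria

`detect_interactions()` implements four geometric contact classes with
every cutoff held in a `criteria_set`, so a user reconciling against
another interaction calculator can tune rather than re-code:

| kind        | default criterion | counting unit |
|-------------|-------------------|---------------|
| hydrophobic | side-chain C of Ala/Val/Leu/Ile/Met/Phe/Trp/Pro/Tyr within 5.0 Å, sequence separation ≥ 2 | residue pair |
| aromatic    | ring centroids of Phe/Tyr/Trp/His within 4.5–7.0 Å | residue pair |
| ionic       | side-chain N of Arg/Lys/His within 6.0 Å of side-chain O of Asp/Glu | residue pair |
| hbond       | heavy-atom N/O donor–acceptor ≤ 3.5 Å, donor–acceptor–antecedent angle ≥ 90°, separation ≥ 1 (side chain) or ≥ 2 (backbone–backbone) | donor–acceptor atom pair |

Two conventions deserve justification. First, His counts as a potential
cation in ionic detection (switchable via `ionic_include_his`); this
follows residue-level interaction calculators and means a His–Asp triad
contact legitimately appears in the ionic census. Second, hydrophobic,
aromatic and ionic contacts are counted once per residue pair while
hydrogen bonds are counted per atom pair: published census tables for
~300-residue proteins show tens of ionic contacts but hundreds of
hydrogen bonds, magnitudes only consistent with exactly this mixed
counting.

The census partition calls an interaction "in loops" if at least one
partner residue is loop-class and "surface-exposed" if at least one
partner has relative solvent accessibility ≥ 0.20 — the standard
exposure threshold; it is `criteria`-exposed.

## Secondary structure

`assign_sse()` is a self-contained Kabsch–Sander implementation rather
than a wrapper around an external DSSP binary, so the package and its
tests carry no system dependency. Amide hydrogens are rebuilt from
backbone geometry (1 Å from N, opposite the preceding carbonyl); the
electrostatic H-bond energy is

E = 0.084 · 332 · (1/d(O,N) + 1/d(C,H) − 1/d(O,H) − 1/d(C,N)) kcal/mol,

with a bond when E < −0.5 kcal/mol. N-turn patterns give G/H/I helices,
bridge patterns give E/B strands, and turns give T. Bends (S) are not
computed — they require only a Cα curvature test and would in any case
map to loop. The 3-state collapse is H,G,I → helix; E,B → strand;
everything else → loop. Counting turns and bends as loop is deliberate:
it is the convention under which loop fractions of α/β-hydrolases come
out near 46%, matching how such fractions are reported.

Loops are maximal loop-class runs of length ≥ `min_len` (default 2,
termini included), numbered L1…Ln from the N-terminus per structure. The
numbering is per-structure; reconciling it with an externally published
loop scheme is a configuration concern, not something the package
guesses at.

`sse_fractions()` rounds to integer percentages by largest remainder, so
the three classes always sum to exactly 100.

## Superposition and per-class RMSD

`kabsch_superpose()` is the closed-form SVD solution with the reflection
guard: when the determinant of the raw solution is negative, the axis of
the smallest singular value is negated, so a proper rotation (det +1) is
always returned. Residue pairing for cross-homolog superposition comes
from global sequence alignment (Needleman–Wunsch via Biostrings,
BLOSUM62, gap open 10 / extend 0.5) — appropriate for homologs built on
a common template; a spatial nearest-Cα mode exists for validation.
Per-class RMSD restricts the fitted deviations to pairs whose
**reference** residue is helix, strand or loop; using the reference's
labels (rather than each homolog's) keeps the three class masks
identical across a family and is recorded in the report.

Catalytic triad geometry is fixed to the canonical charge-relay contacts:
Ser OG – His NE2, and His ND1 to the nearest of the acid's two
carboxylate oxygens. Figure captions in the literature rarely name the
atoms; these are the hydrogen-bonding pairs of the mechanism.

## Flexibility and thermal-region classification

`rmsf_profile()` computes per-residue RMSF over a trailing window
(default the last 30% of frames, generalizing "the last 30 ns of 100 ns"
to frame fractions since the package sees frames, not times). Frames are
Kabsch-fitted on the full Cα selection to their running mean in two
passes; loop-excluded fitting was considered and rejected because
whole-selection fitting is what trajectory tools do by default, and the
fitted/unfitted difference is itself a diagnostic the tests cover (rigid
jitter must change RMSF by < 3%).

`delta_rmsf()` subtracts the T_opt profile from a comparison profile and
applies a centered moving average (default window 3, edges truncated;
window 1 is the exact difference). `classify_thermal_regions()` then
votes per residue:

- **stability**: ΔRMSF(T_high) > +θ **and** ΔRMSF(T_low) < −θ — the
  region softens when heated past the optimum and rigidifies when
  cooled, the signature expected of stability-determining surface loops;
- **activity**: ΔRMSF(T_low) > +θ — the region gains mobility when
  cooled below the optimum, the signature of regions that must stay
  flexible for catalysis;
- otherwise neutral.

The two votes cannot collide (ΔRMSF(T_low) cannot be both > +θ and
< −θ). Votes are merged into maximal runs and runs shorter than
`min_run` dissolve to neutral. θ = 0.2 Å and `min_run` = 3 are package
choices — the qualitative sources say only "significant" — and both are
parameters precisely because of that; sensitivity to θ belongs in any
report built on this classification.

`flexibility_ratio()` reports mean RMSF over all residues divided by
mean RMSF over loop residues; values near 0.75 indicate loops roughly
one-third more flexible than the structure-wide average. The ratio is
scale-invariant.

## Synthetic generators and what they do (not) emulate

The generators exist so that every pipeline stage has an oracle:

- `synth_structure()` builds a continuous backbone from ideal φ/ψ blocks
  (PPII-like loops with seeded jitter, ideal α-helices) and plants
  features with *pseudo side chains carrying only the atoms the criteria
  need*: a Ser-His-Asp triad at exact target distances, Arg–Asp bridges,
  Leu–Leu contacts. Non-planted residues are glycine, so the planted
  census is the whole census, and cross-feature clearance (> 6.5 Å,
  beyond the largest residue-pair cutoff) keeps it exact.
- `synth_sheet()` places a rigid copy of an ideal strand by minimizing
  the summed Kabsch–Sander energies of the intended antiparallel ladder
  bonds under a clash penalty — the one construction where ideal
  dihedrals alone do not produce the hydrogen-bond registry.
- `synth_homolog()` applies substitutions, bridge-breaking mutations
  (Asp → Ala, carboxylate removed), deletions, a rigid transform and
  isotropic coordinate noise, and emits the true correspondence and
  per-bridge fates.
- `synth_ensemble()` draws frames as base + independent per-residue
  isotropic Gaussian displacements (region- and temperature-dependent σ),
  optionally followed by rigid-body jitter. The expected RMSF is exactly
  σ√3.

Independence is the point and the limitation: real trajectories have
correlated collective modes, anisotropic fluctuations, and
non-Gaussian jumps between substates; an elastic-network mode would be a
natural extension but would destroy the closed-form σ√3 oracle the tests
rest on. Passing these tests therefore demonstrates that the statistics
and the classification logic are computed correctly — not that the
biological conclusions drawn from any particular real trajectory are
right.

## Numerical choices and degenerate inputs

- Kabsch requires ≥ 3 non-collinear pairs (second singular value
  ≥ 10⁻⁸); collinear input is a hard error, not a silent fit.
- SASA uses Shrake–Rupley with a deterministic Fibonacci sphere lattice
  (960 points, probe 1.4 Å) and Gly-X-Gly theoretical maxima for
  relative accessibility. Binary point counting leaves a per-residue
  quantization jitter of a few percent at the default point count; the
  profile as a whole is converged below 1% on doubling, which is the
  convergence contract the tests assert.
- Alignment identity is computed over aligned columns excluding dual
  gaps; "similarity" means a positive BLOSUM62 score.
- Equilibration is flagged by the slope of a linear fit to the trailing
  30% of the RMSD series (tolerance 10⁻³ Å per frame index); slope noise
  shrinks with frame count, so short noisy series legitimately fail it.
- Chains shorter than 4 residues cannot carry any H-bond pattern and are
  labeled loop with a warning; residues with incomplete backbones are
  labeled loop and flagged.
- All generators restore the caller's RNG state; identical seeds give
  byte-identical PDB output.

## Problem sizes

The test suite and the acceptance script run on deliberately modest
sizes chosen to make their statistical tolerances meaningful: 44–120
residue synthetic structures, ensembles of 2 000–5 000 frames (RMSF
recovery within 2% needs ≥ 100 residues at 5 000 frames, since Kabsch
fitting absorbs six degrees of freedom and biases RMSF down by a factor
of about 1 − 1/n_res), 50 seeded structures for census monotonicity, and
10 seeds for region-recovery and bridge-conservation checks. Exhaustive
alignment enumeration covers all sequence pairs up to length 2 over a
4-letter alphabet plus a seeded sample of longer pairs; full enumeration
to length 6 would be ~10⁷ pairs against an exponential-time oracle and
adds nothing to the check.

## The study orchestrator

`run_study()` validates a `study_config` (per-enzyme structure,
ensembles keyed by temperature with T_opt/T_high/T_low roles, host
temperature), then produces: the pairwise superposition table with
per-class RMSD against the reference; per-enzyme interaction censuses
with loop/surface partitions; the bridge-conservation matrix; amino-acid
composition trends versus host temperature (Spearman ρ, direction
threshold |ρ| ≥ 0.5, deliberately descriptive — four enzymes support no
inference); per-residue flexibility tables and thermal-region
classifications; and a manifest recording package version, seed,
parameters and every default that filled an unset key. Stage failures
abort with the stage name; nothing is written unless the whole study
succeeds, and reruns with the same config and seed are byte-identical.

## Known limitations

- Interaction criteria approximate, but do not bit-reproduce, any
  specific external interaction calculator; hydrogen-bond counts are the
  most sensitive to convention and should be compared only under
  matched criteria.
- The Kabsch–Sander implementation omits bends (S) and π-helix
  refinements beyond the standard 5-turn pattern; both map to classes
  that do not affect the 3-state fractions this package reports.
- Sequence-based residue pairing assumes homologs alignable end to end;
  for low-identity pairs the spatial pairing mode is the safer check.
- The classification treats residues independently before run-merging;
  it has no spatial smoothing across sequence-distant but
  space-adjacent regions.
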