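# thermadapt

Comparative structural and flexibility analysis of thermally adapted
enzyme homologs.

## The problem

Homologous enzymes isolated from psychrophilic (~10 °C), psychrotrophic
(~20 °C), mesophilic (~37 °C) and thermophilic (~70 °C) bacteria share a
fold and a catalytic machinery, yet their stability and activity optima
track their hosts' habitat temperatures. For α/β-hydrolases of the
hormone-sensitive-lipase family — a Ser-His-Asp catalytic triad, the
GXSXG nucleophile elbow, an HGGG oxyanion hole — the structural signal of
that adaptation is subtle: it hides in the census of atomic interactions,
in the conservation of surface salt bridges, and in how the flexibility of
a handful of surface-exposed loops responds to temperature. `thermadapt`
packages the analyses needed to expose that signal, for people comparing a
reference crystal structure against a ladder of homologs and their
conformational ensembles:

- **Interaction census** — geometric detection of hydrophobic contacts
  (side-chain carbons ≤ 5 Å), aromatic pairs (ring centroids 4.5–7 Å),
  hydrogen bonds (heavy-atom donor–acceptor ≤ 3.5 Å with an angular gate)
  and ion pairs (side-chain N/O ≤ 6 Å), partitioned into loop and
  surface-exposed fractions.
- **Salt-bridge conservation** — a reference bridge is *conserved* in a
  homolog only if both partners map through the residue correspondence
  **and** the mapped pair still satisfies the ionic criteria there.
- **Secondary structure and loops** — a self-contained Kabsch–Sander
  implementation (backbone H-bond energy
  `E = 0.084·332·(1/d_ON + 1/d_CH − 1/d_OH − 1/d_CN)` kcal/mol, bond iff
  `E < −0.5`), 8-state labels collapsed to helix/strand/loop, maximal
  loop runs numbered L1…Ln, and largest-remainder composition percentages.
- **Superposition** — closed-form Kabsch least squares (proper rotations
  only) with RMSD split by the reference's secondary-structure classes,
  plus catalytic-triad geometry (Ser OG–His NE2; His ND1 to the nearest
  carboxylate oxygen).
- **Flexibility** — per-residue RMSF over a trailing window of a
  conformer ensemble, `RMSF_i = sqrt(mean_t ‖r_i(t) − r̄_i‖²)` after
  two-pass Kabsch fitting; ΔRMSF between a comparison temperature and
  T_opt; and the sign rule that classifies residue runs as
  **stability-associated** (ΔRMSF(T_high) > +θ and ΔRMSF(T_low) < −θ) or
  **activity-associated** (ΔRMSF(T_low) > +θ).
- **Synthetic generators** — seeded structures with planted triads,
  bridges and hydrophobic pairs at exact distances; homolog families with
  known bridge fates; Gaussian conformer ensembles whose true RMSF is
  σ√3 — so every stage is testable end to end without external data.

## Worked example

```r
library(thermadapt)

ref <- synth_structure(helix_lengths = c(14, 14), loop_lengths = c(5, 6, 5),
                       n_bridges = 3, triad = TRUE, seed = 11)
ref$model
#> structure_model 'synth_s11': 190 atoms, 44 residues (44 standard), chains: A

triad_distances(ref$model, ref$truth$triad$keys)
#> triad A:4/A:8/A:5: Ser(OG)-His(NE2) 3.0 A, His(ND1)-acid(ODx) 2.8 A

sse <- assign_sse(ref$model)
sse_fractions(sse)
#>  helix_pct strand_pct   loop_pct
#>         64          0         36

hom <- synth_homolog(ref, break_bridges = 2, coord_noise_sigma = 0.3,
                     rigid_rotation = c(20, 5, -10), seed = 2)
sup <- classwise_rmsd(superpose_models(ref$model, hom$model,
                                       hom$correspondence), sse_a = sse)
sup
#> superposition: 44 pairs, RMSD 0.545 A
#>   helix  0.498 A (28)
#>   loop   0.619 A (16)

bc <- map_bridge_conservation(detect_interactions(ref$model, "ionic"),
                              hom$model, hom$correspondence)
table(bc$status)
#> conserved      lost
#>         3         1
```

The superposition RMSD (0.545 Å) sits at the planted per-axis noise times
√3 (0.52 Å), loops a little above helices; of the four ionic contacts in
the reference (three planted Arg–Asp bridges plus the triad's His–Asp
pair), exactly the mutated bridge is reported lost. Ensemble statistics
land on their analytic values the same way:

```r
se <- synth_ensemble(ref, temperatures = c(15, 35, 50), sigma = 0.5,
                     n_frames = 2000, seed = 5)
prof <- rmsf_profile(se$ensembles[["35"]], window = c(0.7, 1))
mean(prof$rmsf)
#> 0.847  # planted sigma * sqrt(3) = 0.866 A
```

`run_study()` orchestrates all of the above over a configured enzyme
family and writes a TSV/JSON report bundle with a reproducibility
manifest; see the methods vignette (`vignettes/thermadapt-methods.Rmd`).

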