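# msmflux

Markov state models (MSMs) and transition-path-theory (TPT) flux
analysis for molecular dynamics trajectories, in R.

## The problem

Long MD simulations of proteins such as the BRD4 bromodomain visit a
handful of metastable conformational states connected by rare
transitions. Questions like *"by which routes does the protein travel
from its initial conformation to its final one, and how much of the
transition traffic does each route carry?"* are answered by building a
Markov state model from the trajectories and decomposing its reactive
flux into pathways. `msmflux` implements that full pipeline:

1. **Featurization** — backbone φ/ψ torsions from multi-model PDB
   ensembles (or any numeric feature matrix), with sin/cos embedding
   of periodic angles.
2. **TICA** — time-lagged independent component analysis; solves the
   generalized eigenproblem `C_τ v = λ C_0 v` on symmetrized
   covariances to extract the slowest collective coordinates.
3. **Microstates** — restarted k-means (k-means++ seeding, Lloyd
   refinement, best of 10 restarts), with the number of clusters
   selected by cross-validated VAMP-2 scoring.
4. **MSM** — transition counting at lag τ, largest strongly connected
   set, reversible maximum-likelihood transition matrix `T(τ)`
   (detailed balance `ρ_i T_ij = ρ_j T_ji`), implied timescales
   `t_i = −τ / ln λ_i(τ)`, and the Chapman–Kolmogorov test
   `P(kτ) ≈ P(τ)^k`.
5. **Macrostates** — PCCA+ spectral coarse-graining into metastable
   sets, named SA (source), S1…S3, SB (sink).
6. **Flux** — forward committors `q⁺` from
   `q⁺_i = Σ_{j∈B} T_ij + Σ_{j∉A∪B} T_ij q⁺_j` (with `q⁻ = 1 − q⁺`
   under detailed balance), reactive flux
   `f_ij = ρ_i q⁻_i T_ij q⁺_j`, net flux
   `f⁺_ij = max(f_ij − f_ji, 0)`, iterative maximum-bottleneck pathway
   decomposition, and path probabilities `P_i = f_i / Σ_j f_j`.

Standard trajectory observables (RMSD, RMSF, radius of gyration,
DCCM, B-factors, Shrake–Rupley SASA, inter-loop distances) and
synthetic generators with planted ground truth (exact Markov chains,
overdamped Langevin dynamics on multi-well potentials, dihedral-like
hidden-state datasets) round out the package, so every estimator can
be validated against analytic oracles without external data.

## Worked example

Generate a small synthetic dihedral dataset with three planted
metastable states and run the pipeline:

```r
library(msmflux)

ds  <- emulate_dihedral_dataset(n_traj = 4, n_frames = 2000,
                                n_features = 20, n_metastable = 3,
                                p_hop = 0.01, start_state = 0L,
                                end_state = 2L, seed = 7)
cfg <- pipeline_config(tica_dim = 4, k = 8, pcca_m = 3, ck_kmax = 3,
                       seed = 1)
res <- run_pipeline(ds, cfg)
res$table
```

```
   pathway path_flux percentage
1    SA→SB  7.87e-03      50.99
2 SA→S1→SB  7.57e-03      49.01
3    Total  1.54e-02        100
```

Half the reactive flux flows directly from the source macrostate SA
to the sink SB, and half detours through the intermediate S1: the
`path_flux` column is the probability flux each route carries per lag
step, and `percentage` is its share of the decomposed total. The run
log also reports the forward committor of each macrostate
(`SA=0.000  S1=0.654  SB=1.000` here: a trajectory in S1 is 65% likely
to reach SB before returning to SA) and the Chapman–Kolmogorov
deviation of the macrostate model.

A thin command-line wrapper is included at
`inst/cli/msmflux-pipeline.R`:

```sh
Rscript inst/cli/msmflux-pipeline.R --synth 10 --seed 42 --out rundir
```

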