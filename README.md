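# confenum

Exhaustive enumeration of disordered-linker conformations and ensemble
population fitting.

## The problem

Partially disordered proteins — for example tandem-domain scaffolds whose
folded domains are joined by a flexible linker — exist in solution as
ensembles of conformations. NMR chemical shifts constrain each residue's
backbone torsions (φ, ψ) to one or a few regions of the Ramachandran map,
but local optimization cannot guarantee that every conformation compatible
with those constraints has been found. `confenum` implements a systematic
alternative for structural biologists working on such systems:

1. **Torsion boxes.** Per-residue likelihood maps over the 324-voxel
   (20° × 20°) Ramachandran grid are normalized to probabilities; all voxels
   above a threshold (default 0.01) are grouped into 8-connected components
   (periodic across ±180°) and each component's bounding rectangle becomes a
   φ×ψ *box*.
2. **Interval branch-and-prune enumeration.** Within each combination of
   boxes, linker fragments are built atom by atom. Each backbone torsion is
   equivalent to a 1–4 interatomic distance — φ(i) to C(i−1)···C(i), ψ(i) to
   N(i)···N(i+1) — so a torsion box becomes a distance interval. Atoms are
   placed by trilateration from three references (two exact distances, one
   interval); the interval is discretized into at most 4 branch samples
   (minimum step 0.1 Å, bounds widened by 0.05 Å) and every branch that
   violates scaled van der Waals contacts (factor 0.7) or improper-angle
   targets (CA chirality, peptide planarity) is pruned with its subtree.
   Leaves are saved when their Cα RMSD to the previous save exceeds 2 Å,
   up to 10⁹ per run.
3. **Self-organizing-map reduction.** Sets larger than 1000 conformers are
   encoded by the four largest eigenvalues and eigenvectors of the Cα–Cα
   distance-row covariance C_ij = (1/n) Σ_k (d_ik − d̄_i)(d_jk − d̄_j)
   (vector length 4(n+1)), quantized on a periodic 2D Kohonen map, and
   reduced to one representative per occupied local minimum of the U-matrix
   U(μ) = (1/8) Σ_{ν∈N(μ)} d(ν, μ).
4. **Assembly and domain attachment.** Overlapping fragments are merged by
   superposing their 3 shared residues (switch at the closest backbone atom
   pair; merges with Cα pairs under 1 Å rejected); rigid folded domains are
   attached by a grid search with anchor-vector alignment and clash/distance
   acceptance rules.
5. **Populations.** Conformer populations are determined by
   maximum-entropy reweighting: minimize χ²/2 − θS with
   S = −Σ w_i ln(w_i/w⁰_i) on the simplex, with the two-round protocol
   (10 random-start fits, keep conformers whose summed population exceeds
   0.01, refit, report mean ± sd). Profile agreement is quantified by RMS,
   Pearson R and Q = rms(calc − obs)/rms(obs).

A synthetic-data module generates torus-Gaussian likelihood maps and
known-weight conformer ensembles with noisy observables, so the whole
pipeline is testable without any experimental input.

## Worked example

Enumerate a 12-residue synthetic linker, cluster, assemble, and report the
bookkeeping:

```r
library(confenum)

sc   <- synthetic_scenario(strrep("A", 12), start_resid = 101,
                           modes = data.frame(phi = -65, psi = -45,
                                              sd = 8, weight = 1),
                           seed = 2)
maps <- make_synthetic_maps(sc)
cfg  <- pipeline_config(sc$sequence, 101,
                        fragments = list(101:106, 104:109, 107:112),
                        maps = maps,
                        settings = enumeration_settings(max_branches = 2,
                                                        save_rmsd_gate = 1.0),
                        cluster_threshold = 60, som_rows = 8, som_cols = 8)
report <- run_pipeline(cfg)
report$fragment_tables
#>   fragment from  to N_iBPrun N_iBPconf N_clustiBP
#> 1        1  101 106        1        63          4
#> 2        2  104 109        1        63          4
#> 3        3  107 112        1        63          4
report$assembly[[2]]
#>  N_trials N_clashes   N_saved   N_clust
#>        64         0        64         3
```

Each fragment's single box combination (`N_iBPrun`) produced 63 clash-free
conformations (`N_iBPconf`), reduced to 4 representatives (`N_clustiBP`);
the second assembly step tried all 16 × 4 = 64 pairs, none clashed, and the
SOM kept 3 full-length chains. Counters always obey
`N_saved = N_trials − N_clashes`.

Population fitting on a synthetic known-weight ensemble:

```r
sc  <- synthetic_scenario(strrep("A", 15), weights = c(0.6, 0.3, 0.1),
                          noise = 0.01, seed = 3)
ens <- make_synthetic_ensemble(sc)
fit <- maxent_reweight(ens$predicted, ens$observed, theta = 0.01)
round(fit$weights, 3)
#> [1] 0.604 0.295 0.100
```

A command-line front end is installed at `exec/confenum` inside the
package (`system.file("exec", "confenum", package = "confenum")`) with
subcommands `boxes`, `enumerate`, `assemble`, `fit` and `synth`.

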