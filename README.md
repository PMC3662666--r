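# ringcsp

Detecting subtle protein conformational change upon fragment binding from
backbone-amide NMR observables.

In fragment-based drug discovery, a bound fragment perturbs the amide
proton chemical shifts of its target. When the protein does **not**
rearrange, the dominant predictable contribution to those perturbations is
the ring-current effect of the fragment's aromatic rings — which can be
simulated from docked ligand poses. Residues whose *experimental* chemical
shift perturbation (CSP) exceeds the *simulated* value for **every**
plausible pose are therefore evidence that the protein itself moved.
ringcsp implements that comparison, and corroborates it with residual
dipolar couplings (RDCs), which report N–H bond orientations directly.

## The models

**Ring-current shift (Haigh–Mallion).** For an amide proton and an
aromatic ring, summing over the ring bonds (j, k):

    δ = −i · B · Σ_(j,k) S_jk · (1/r_j³ + 1/r_k³)

where `S_jk` is the signed area of the triangle formed by the proton and
bond atoms after projection onto the ring plane, `r_j`, `r_k` are the 3D
distances from the ring atoms to the proton, `i` is the ring-type
intensity factor (1.00 for a benzene-type carbocycle) and `B` the
amide-proton target factor (configurable; SHIFTX-lineage default). The
sign convention puts the shielding cone above/below the ring plane at
negative δ.

**Pose agreement (P factor).** Per docked pose k, with N the protein's
residue count:

    P_k = (1/N) · Σ_res |CSP_H^exp − CSP_H^sim,k|        (mad mode)

with an RMSD-normalised variant selectable. Low P = good agreement.
Residues whose experimental CSP exceeds the per-residue maximum simulated
CSP by more than 0.2 ppm (strong) or 0.06 ppm (moderate) are flagged as
conformational-change candidates.

**RDC alignment tensor.** `D_i = u_iᵀ S u_i` with S the symmetric
traceless Saupe order matrix (Hz scale, 5 free parameters), fitted from
≥ 5 couplings by SVD least squares; agreement is summarised by the Pearson
correlation r and quality factor `Q = rms(D_exp − D_calc)/rms(D_exp)`,
with residues deviating by more than 6.5 Hz flagged as outliers.

## Worked example

Everything below is synthetic and self-contained: an ideal helix, a
biphenyl-like two-ring fragment docked 4 Å from residue 30, peak lists
forward-modelled from pose 1 with an artificial 0.3 ppm conformational
change injected at residues 10 and 45, and RDCs generated from a known
alignment tensor.

```r
library(ringcsp)

spec <- fixture_spec(n_residues = 60, target_residue = 30,
                     perturbed_residues = c(10, 45), inject_ppm = 0.3, seed = 7)
protein <- make_helix_protein(spec)
poses   <- make_pose_ensemble(spec, protein, n_poses = 20)
peaks   <- make_synthetic_peaklists(protein, poses[[1]], spec)

sim    <- simulate_ensemble(protein, poses)
csp    <- compute_experimental_csp(peaks$free, peaks$bound)
scores <- p_factor(csp, sim, n_residues = 60)
aggregate_clusters(scores)
#> P factor over 3 cluster(s); global range [0.01, 0.02982]
#>   cluster_id n_poses     mean_p      min_p      max_p
#> 1          1       7 0.01751178 0.01000000 0.02410759
#> 2          2       7 0.02227506 0.01472901 0.02982097
#> 3          3       6 0.02144445 0.01724059 0.02607875

flag_disagreement(csp, sim)
#> CSP disagreement over 59 residues: 2 strong (> 0.20 ppm), 0 moderate (> 0.06 ppm)
#>      chain resno csp_h_exp max_csp_h_sim     delta   tier
#> A:10     A    10 0.3013635   0.001594438 0.2997690 strong
#> A:45     A    45 0.3035895   0.004770754 0.2988187 strong
```

The two injected residues — and only those — are recovered as `strong`:
their experimental CSPs cannot be explained by the ring current of any
pose. The per-cluster P values quantify how well each docking cluster
explains the observed CSP pattern overall.

```r
rdcs <- make_synthetic_rdcs(protein, random_alignment_tensor(10, seed = 7), spec)
fit  <- fit_alignment_tensor(rdcs, nh_vectors(protein))
summary(fit)
#> Alignment tensor fit (SVD least squares)
#>   residues used: 59
#>   Pearson r: 1.0000   Q factor: 0.0000
#>   Saupe eigenvalues (Hz): 15.093, 0.720, -15.813
#>   Da: -7.907 Hz   rhombicity: -0.606
#>   no outliers
#>   residual rms: 0.000 Hz
```

`fit` is a classic fitted-model object with `coef()`, `predict()`,
`residuals()`, `simulate()` and `plot()` (observed vs back-calculated
couplings with outliers labelled). `compare_structures()` refits the
tensor against several candidate structures and ranks them by r — the way
one asks which known conformer a bound-state RDC set resembles most.

## Command line

A thin script over the same functions is installed at
`inst/cli/ringcsp` (subcommands `simulate-csp`, `flag`, `fit-rdc`,
`isoshield`, `make-fixtures`; flags `--config`, `--out-dir`, `--seed`,
`--log-level`). `make-fixtures` emits a complete worked example from a
seed; every command echoes all resolved constants into
`run_metadata.txt` and is byte-reproducible from its config.

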