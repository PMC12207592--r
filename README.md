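# shapecv

Iterative, data-driven collective variables (CVs) for biased sampling of
conformational transitions between two metastable states of a particle
system.

Sampling a rare transition with metadynamics-style methods is only as good
as the CV being biased.  `shapecv` implements a refinement loop that uses
the biased data itself to improve the CV:

1. **Cluster** configurations with a shape-based Gaussian mixture model: each
   component has weight φ_j, mean structure μ_j (N×3) and Kronecker
   covariance Σ_N ⊗ I₃, with every frame rotated to its
   Mahalanobis-optimal pose, and per-frame statistical weights w_i undoing
   any sampling bias (weighted EM: γ_ij = w_i φ_j N_j(x_i) / Σ_k φ_k N_k(x_i)).
2. **Discriminate**: a frame-weighted linear discriminant between two
   labeled states on aligned positions gives a linear coordinate
   l(x) = v·(R(x−ξ) − μ) that can be evaluated — with its analytic
   gradient — on any frame on the fly.
3. **Bias** along l with well-tempered metadynamics
   (V(s,t) = Σ_τ h e^{−V/((γ−1)kT)} e^{−(s−s_τ)²/2σ²}) or OPES
   (V(s) = kT(γ−1)/γ · log(P(s)/Z + ε), capped at ΔE), with quadratic
   walls; estimate the free energy surface either from the bias,
   F(s) = −γ/(γ−1)·V(s), or by reweighting with w_i ∝ e^{+V(s_i)/kT}.
4. **Re-cluster** the biased frames with their weights, **match** the new
   clusters to the original states by Gaussian Bhattacharyya distance
   D_B = ⅛Δμᵀ Σ̄⁻¹ Δμ + ½ ln(det Σ̄/√(det Σ_a det Σ_b)), and fit the next
   weighted discriminant between the matched clusters.  Repeat until the
   FES converges (mean absolute error under a 7.5 kcal/mol reference cut).

A built-in synthetic module (`make_two_state_system()`,
`run_biased_langevin()`) provides two-state Gaussian-mixture particle
systems with exactly known Boltzmann statistics and an overdamped Langevin
engine (C++), so every estimator in the pipeline is tested against
closed-form or brute-force oracles.  It is a desk-scale stand-in for
molecular-dynamics data; no external dataset is needed.

## A worked example

```r
library(shapecv)

# a mirror-symmetric two-state system: 6 particles, ~6 kT barrier,
# states are chirality partners with exactly equal free energy
sys <- make_two_state_system(N = 6, seed = 1)
sys
#> <toy_two_state: 6 particles, separation 2.2 A, spread 0.3 A,
#>  barrier 6.03 kT, mirror-symmetric>

# two cycles of the refinement loop: initial LDA from short unbiased runs,
# WT-MetaD biasing, weighted re-clustering, Bhattacharyya matching,
# weighted re-LDA
cfg <- protocol_config(K = 2, seeds = 1:2, scheme = "wtmetad", gamma = 8,
                       steps = 60000, max_iterations = 2, tol_mae = 0.01)
res <- iterate_cv(sys, cfg, seed = 1)
tidy_history(res)
#>   iteration transit_count mae_vs_previous
#> 1         0            NA              NA
#> 2         1            21              NA
#> 3         2            16       0.2983576
```

Each iteration records the refit mixture model, the cluster-to-reference
match, the number of round trips between the states, and the reweighted
free energy profile along the system's fixed inter-state axis; with a
symmetric system the two FES minima must agree, and here they do to a few
tenths of a kcal/mol.  `autoplot(res$history[[3]]$fes)` draws the profile,
and `export_coefficients(res$coordinate, out_dir = "coord")` writes the
coefficient vector (one `particle_index cx cy cz` row per particle, unit
norm, state A negative), the reference mean as PDB, the alignment
covariance factor as delimited text, and a YAML manifest — the layout an
external biased-MD engine consumes.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/shapecv` (subcommands `generate`, `simulate`, `fit-gmm`,
`scan-k`, `wlda`, `fes`, `iterate`, `export`, each driven by a YAML
config).

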