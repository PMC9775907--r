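# motifResilience

Tools for asking how much of a regulatory motif's canonical behavior
survives when the motif is wired into a larger, random gene regulatory
network.

The motifs are the **toggle switch** (TS; two genes A and B mutually
inhibiting each other, canonically bistable with the two "single-positive"
states 10 and 01) and the **toggle triad** (TT; three genes with all six
pairwise inhibitions, canonically tristable with three single-positive
states), plus variants with self-activation (`-SA`) or self-inhibition
(`-SI`) loops on every motif node. These circuits drive binary and ternary
cell-fate decisions (PU.1/GATA1 in hematopoiesis, GATA3/RORγT/T-bet in
CD4⁺ T-cell differentiation) and are standard building blocks in synthetic
biology — where they are always embedded in a larger network, not
isolated.

## The model

Each node follows one ODE with shifted-Hill regulation per incoming edge:

    dT/dt = G_T · Π_i H^S(P_i) · Π_j H^S(N_j) − k_T · T
    H^S(B; B⁰, n, λ) = (B⁰)ⁿ/((B⁰)ⁿ+Bⁿ) + λ · Bⁿ/((B⁰)ⁿ+Bⁿ)

Instead of one parameter fit, the pipeline follows the random circuit
perturbation (RACIPE) formalism: thousands of parameter sets are sampled
from fixed ranges (G ∈ [1,100], k ∈ [0.1,1], integer n ∈ 1..6, activating
λ ∈ [1,100], inhibitory λ = 1/U(1,100), thresholds by the half-functional
rule), each is integrated from many random initial conditions, and the
pooled stable steady states are binarized (log2, z-score, threshold at 0)
into ON/OFF state strings. Per-network resilience metrics: Sarle's
bimodality coefficient (BiC) per node, pairwise Spearman correlations
(and MaxCC/MinCC for triads), single-/double-positive state fractions
F1/F2/F3, the bistable:monostable ratio B:M (switch), and a multiple
linear regression of C on A and B (triad). Meta-analyses correlate these
metrics with the motif's in-degree across ensembles of random networks.

## Worked example

```r
library(motifResilience)

# the isolated toggle switch at full sampling depth (~5 s)
ens <- simulate_ensemble(motif_topology("TS"), n_models = 10000,
                         n_init = 100, seed = 101)
motif_metrics(ens)
#>       BiC_A     BiC_B      CC_AB        F1        f00         f11   B_to_M
#> 1 0.8126068 0.8084864 -0.8288531 0.9569951 0.03491718 0.008087721 1.004847
```

Both nodes are strongly bimodal (BiC ≈ 0.81, far above the 5/9 bimodality
threshold), the two nodes are strongly anticorrelated (Spearman CC ≈
−0.83), 96% of all stable states are single-positive, and bistable
parameter sets retain the canonical {01, 10} pair slightly more reliably
than monostable ones retain a single-positive state (B:M > 1) — the
fingerprint of a healthy switch. Embedding the same motif in increasingly
dense random networks erodes all of these numbers:

```r
net <- generate_embedded_network("TS", order_N = 5, connectivity_x = 4,
                                 seed = 1)   # 7 nodes, 22 edges
plan <- experiment_plan("TT", preset = "scaled_down", seed = 1)
records <- run_experiment(plan)              # one metric row per network
indegree_metric_correlations(records, normalized = TRUE)$rho
```

For embedded triads, the maximum pairwise correlation (MaxCC) rises and
the single-positive fraction falls as the motif's total in-degree grows;
the in-degree of the motif — not the order or global density of the host
network — is the best predictor of the decay.

The methods vignette (`vignettes/motif-resilience.Rmd`) documents the
sampling rules, numerical tolerances, scale conventions and the design
choices behind every metric.

## Command line

A thin dispatcher over the same functions lives at
`inst/scripts/motifnet.R`:

```sh
Rscript inst/scripts/motifnet.R generate --motif TS --order 5 \
    --connectivity 4 --count 100 --seed 1 --outdir topo/
Rscript inst/scripts/motifnet.R simulate --motif TS --topo 'topo/*.topo' \
    --n-models 1000 --n-init 20 --outdir sim/
Rscript inst/scripts/motifnet.R analyze --motif TT --preset scaled_down \
    --outdir analysis/
```

Topologies use the RACIPE `.topo` text format (`Source Target Type`, 1 =
activation, 2 = inhibition); simulations write RACIPE-style per-multiplicity
solution tables and a parameter table; every stage writes a manifest with
content hashes of its outputs.

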