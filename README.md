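# psokm

Hybrid particle-swarm + K-means clustering for screening tibial rotation
pathologies from physical characteristics.

## The problem

Tibial rotation — rotation of the shin about its long axis relative to the
femur — is measured as four angles per subject (right/left ×
external/internal: RTER, RTIR, LTER, LTIR). Angles of at most 20° (Type 1)
or above 65° (Type 3) are pathological; the 20–65° band (Type 2) is normal.
This package is for biostatisticians and clinical researchers asking whether
routinely available physical parameters — age, weight, height — carry enough
structure to recover, by unsupervised clustering, the subject groups within
which these pathology types distribute.

Subjects are referenced against a deterministic anthropometric rule: age
above 30 years → Cluster 1; otherwise weight ≤ 60 kg → Cluster 2, else
Cluster 3. A clustering of the raw features is scored by how well it
rediscovers these rule clusters and their pathology-type composition.

## The method

Plain K-means minimizes the within-cluster sum of squared errors

    SSE = Σ_k Σ_{x ∈ C_k} ‖x − μ_k‖²

but is only locally convergent. The hybrid (PSO-KM) searches centroid space
globally with a particle swarm — each particle is a flattened K × d centroid
set, its fitness the SSE — moving by the canonical rules

    V(t+1) = w·V(t) + c1·r1·(Pbest − X(t)) + c2·r2·(Gbest − X(t))
    X(t+1) = X(t) + V(t+1)

with w = 0.73, c1 = c2 = 1.49, 30 particles, 30 iterations, and then
refines the swarm-best centroids with one K-means run (refinement never
increases the SSE). The package also implements the full evaluation
arithmetic — per-cluster success rates (100·min/max of subject counts),
per-type rates, general accuracies, and the Rand index — plus a seeded
synthetic cohort generator standing in for the non-deposited 484-subject
reference cohort. See `vignettes/pso-kmeans-methods.Rmd` for the full
account.

## Worked example

```r
library(psokm)

coh <- simulate_cohort(cohort_config(), seed = 1)   # 484 subjects, 52/249/183
fit <- pso_kmeans(subject_features(coh$subjects), k = 3, seed = 1)
summary(fit)
#> Hybrid PSO + K-means clustering, k = 3, n = 484
#> SSE (standardized features): 439.8
#> Cluster sizes: 183, 45, 256
#> ...
#> Swarm stage: 30 particles, 30 iterations; best fitness 639.256 -> 440.82
#> K-means refinement: SSE 440.82 -> 439.832

evaluate_partition(coh$subjects, fitted(fit), "ltir")
#> Per-cluster success rates (%):
#>     C1     C2     C3
#>  86.54  97.27 100.00
#> ...
#> Rand index vs rule clusters: 0.9729
```

The swarm reduces the clustering SSE from 639.3 (best random particle) to
440.8, K-means refinement polishes it to 439.8. The fitted clusters match
the anthropometric rule clusters with success rates 86.5–100% per cluster
and a Rand index of 0.97: on this synthetic cohort, age/weight/height
recover the rule grouping almost exactly, and the per-type general
accuracies show the Type 2 (normal) composition is recovered best —
exactly the pattern the method is designed to surface.

The published type-by-cluster counts of the reference cohort ship with the
package, so the canonical comparison figures are recomputable from raw
counts:

```r
cc <- rotation_reference_counts("ltir")
report_from_counts(cc$real, cc$psokm)$success_rates
#>    C1    C2    C3
#> 88.46 95.98 91.96
```

`run_pipeline(out_dir, seed = 1)` orchestrates the whole comparison
(simulate → cluster with PSO-KM and KM → evaluate all four rotations →
comparison table + JSON reports + manifest), and
`inst/scripts/psokm-cli.R` exposes it as a command line
(`simulate`/`cluster`/`evaluate`/`run`/`compare`).

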