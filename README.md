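# lesionpatterns

Two-tier spatio-temporal classification of enhancing multiple-sclerosis
lesions from longitudinal, co-registered lesion masks under two contrast
agents (gadolinium, Gd, marking blood-brain-barrier breakdown; ultrasmall
superparamagnetic iron oxide, USPIO, marking activated-macrophage
infiltration). The package is aimed at neuroimaging researchers studying
disease onset (clinically isolated syndrome) who want to move beyond total
lesion load: it classifies *how individual lesions evolve* and uses those
pattern counts to predict each patient's future chronic hypointense lesion
volume, a proxy for irreversible tissue destruction.

## The method

**Tier 1 — lesion patterns.** Each delineated lesion at each time point and
agent is reduced to a rotation-invariant shape descriptor. With the lesion's
m voxel coordinates (in mm) collected row-wise and centered in the data
matrix M, the coordinate covariance

    C = MᵀM / m  =  U Λ Uᵀ

is eigendecomposed; the eigenvectors U are discarded (orientation
invariance) and the sorted eigenvalues Λ = (λ₁ ≥ λ₂ ≥ λ₃), in mm², describe
size and anisotropy — for a solid ellipsoid with semi-axes (a, b, c) they
approach (a²/5, b²/5, c²/5). Ring-enhancing lesions are represented *as
filled* for the tensor, and the hollowness index

    H = A / A_fill,   H ∈ (0, 1]

(delineated area over per-axial-slice hole-filled area) records the
ring-vs-focal distinction. Lesions are matched across time points and
across agents by spatial overlap (largest-overlap, one-to-one), and each
trajectory yields the feature vector

    f = [f_Gd | f_USPIO],   f_agent = (λ₁, λ₂, λ₃, H) per time point,

with absent blocks set to zero (16 entries for 2 time points). Trajectories
are clustered by NJW spectral clustering (k-means in the eigenspace of the
symmetric normalized affinity), with the number of clusters chosen by
decision fusion — the rounded mean of four validity-index votes: Dunn,
Calinski-Harabasz, the gap statistic, and the Laplacian eigengap. Cluster
separation S (mean pairwise centroid distance normalized by the pooled
within-pair spread) is tested against randomization and permutation nulls.

**Tier 2 — patients.** Each patient i is summarized by the cardinalities
n_i = (n_i1, …, n_iK) of their trajectories per lesion cluster, and future
chronic hypointense load y_i (ml) is fit by no-intercept least squares

    y = N β,   β̂ = argmin ‖Nβ − y‖²,

evaluated by R² = 1 − SS_res/SS_tot in-sample and under leave-one-patient-
out and leave-one-lesion-out protocols. Patients with no active lesions
(group C) are excluded from the fit but carried through all reports.

Because no imaging data are distributable, the package ships a first-class
synthetic cohort generator (`sample_cohort()`) stating the study-scale
world: 25 patients (5/13/7 in groups A/B/C), two baseline time points,
~103 Gd and ~24 USPIO enhanced observations, 75% filled-ellipsoid / 25%
ring lesions, and three archetypal patterns — C1 (any size, t0 only,
generally Gd-only), C2 (medium-large, persistent, focal Gd + ringing
USPIO), C3 (medium, mainly t0, both agents ringing).

## Worked example

```r
library(lesionpatterns)

coh <- sample_cohort(cohort_spec(seed = 2))
cfg <- pipeline_config(seed = 2, k = 3, n_perm = 2000)
res <- run_pipeline(coh$volumes, coh$outcomes, cfg, verbose = TRUE)
print(res); print(res$separation)
```

prints

```
matched 130 observations into 95 trajectories
clustered 95 trajectories into 3 clusters (sizes 80/10/5)
fit 18 active patients, 7 excluded (group C); R2 = 0.999
pipeline_result [tensor/spectral/gd+uspio]: 95 trajectories, K = 3
regression_fit: K = 3, n = 18, R2 = 0.999, LOO pooled R2 = 0.998
beta: n1=0.113, n2=1.521, n3=0.911
separation_test: S = 3.8479, n_perm = 2000, p_rand = 0.0004997501, p_perm = 0.0004997501
```

Reading this: 130 enhanced lesion observations were matched into 95
trajectories; at K = 3 the largest cluster (80) is the benign C1-like
pattern and the two small clusters are the severe co-enhancing patterns.
The per-pattern outcome weights β̂ = (0.113, 1.521, 0.911) ml recover the
generator's ground truth (0.1, 1.5, 1.0) ml — one severe-pattern lesion
predicts an order of magnitude more future hypointense volume than a C1
lesion — and the cluster separation is significant under both null models
(p ≈ 5e-4 at 2000 draws). The patient table (`res$profiles`) mirrors the
study's per-patient report:

```
   patient_id n1 n2 n3 hypointense_m24_ml group
2         P02  2  2  2          5.0496192     A
5         P05  8  2  1          4.8690937     A
...
13        P13  8  0  0          0.9284038     B
```

A command-line interface covering every stage (simulate,
extract-features, estimate-k, cluster, separation-test, patient-model,
run-all, grid) is installed at `inst/cli/lesionpatterns`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/lesionpatterns", package="lesionpatterns"))')" \
    simulate --seed 1 --out cohort
```

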