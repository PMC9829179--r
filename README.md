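# polycorr

Bayesian correction of distance inflation in multi-fluorophore 3D
localization data.

## The problem

Fitting Gaussian profiles to diffraction-limited spots localizes
fluorophores to tens of nanometres, but the Euclidean distance between two
noisy spot centres systematically **over-estimates** small true
separations: the distance is a convex function of the noise, so its
expectation exceeds the truth (Jensen's inequality). At molecular scales
the bias is large — a 15 nm separation measured with a ~29 nm pair error
averages near 49 nm — and it also skews shape (measured triangles drift
towards equilateral). Anyone measuring intra-complex architecture from
multi-colour images (kinetochores, nuclear pores, adhesion complexes)
faces this bias.

## What the package does

polycorr infers the full 3D polygon formed by J fluorophores jointly,
instead of correcting one pair at a time. The model: every measurement n
arises from a shared canonical **template** {X_j} placed by a
rigid-body **perspective** (rotation R^n about node 1, translation T^n)
and observed with per-fluorophore anisotropic Gaussian error,

    X_j^n = R^n (X_j − X_1) + X_1 + T^n,
    X̃_j^n ~ N(X_j^n, diag(σ_j;xy², σ_j;xy², σ_j;z²)).

Posterior inference is by MCMC with uninformative priors (flat
translations, isotropic rotations, flat σ, template prior flat on the
joint edge-length region): exact Gibbs draws for translations, error
precisions and mixture proportions; Metropolis random walks for rotations
and template coordinates. A finite-mixture extension decomposes
heterogeneous populations into Z conformational states with per-subset
proportions, latent per-measurement state affiliations, a minimum
occupancy of three measurements per state, optional *state-informing*
(known-pure) subsets, and an optional anchor prior on state 1. Joint
inference guarantees the triangle inequality draw by draw, shares
information between edges (tightening short, weakly identified ones), and
identifies each fluorophore's localization error individually — all
impossible pair-wise.

Classical pair-wise baselines are included for comparison: the closed-form
isotropic distance likelihood (MLE and flat-prior posterior mean) and an
anisotropic pair-wise MCMC sampler, plus an independence-resampling
diagnostic that counts triangle-inequality violations when pair-wise
marginals are recombined naively.

## Worked example

Simulate the anisotropic triangle study design — true sides (50, 60, 15)
nm, per-fluorophore errors (10, 20), (10, 20), (15, 30) nm (lateral,
axial), N = 400 — and fit it:

```r
library(polycorr)

d <- simulate_polygons(design_preset("example_1_2"), seed = 11)
round(euclidean_distance_summary(d, c(2, 3)), 2)
#>   mean     se     sd      n
#>  42.34   1.02  20.45 400.00

fit <- polygon_fit(d, iterations = 12000, chains = 2, seed = 2)
summary(fit)
#> Posterior summary (J = 3, N = 400, Z = 1)
#>             mean     sd   2.5%  97.5%
#> l12       50.301  1.021 48.224 52.281
#> l13       57.796  1.375 55.081 60.439
#> l23       13.252  3.057  7.078 18.820
#> sigma1_xy  9.303  1.148  6.736 11.415
#> sigma3_z  31.712  1.623 28.649 34.988
#> ...
```

The uncorrected mean distance for the short side is 42.3 nm — nearly
three times the true 15 nm. The joint posterior pulls it back to
13.3 ± 3.1 nm, recovers the long sides at 50.3 and 57.8 nm, and estimates
each fluorophore's lateral and axial error (here 9.3 nm against a true
10, 31.7 against a true 30). Every stored draw is a realizable triangle,
so internal angles (`angle1..3` columns) and a consensus shape
(`average_polygon(fit)`) come for free.

Two-state mixtures, state-informing subsets and per-measurement state
classification (`state_affiliations()`, substantial-evidence thresholds
0.24/0.76) are covered in the vignette (`vignettes/polygon-inference.Rmd`),
along with the sampler details and design choices.

## Command-line use

```sh
exec/polycorr simulate --preset example_1_2 --seed 7 --out data.csv
exec/polycorr fit-single data.csv --iters 20000 --chains 2 --out run/
exec/polycorr fit-mixture mix.csv --states 2 --informing pure2:2 --out run2/
exec/polycorr fit-pairwise data.csv --pair 2,3 --method means
```

Input tables are CSV with columns `measurement_id`, `subset_id`,
`fluorophore` (1..J), `x_nm`, `y_nm`, `z_nm` (z = optical axis); traces
are written as `samples.csv` + `meta.json` directories readable with
`read_trace()`.
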