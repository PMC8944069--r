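# musclebayes

Bayesian sampling of plausible muscle forces for an elbow
flexion–extension motion.

## The problem

Estimating individual muscle forces from observed motion is
under-determined: the musculoskeletal system is redundant, so infinitely
many force combinations produce the same joint torque, and the usual
remedy — optimizing a hand-picked objective function — returns a single
trajectory that hides the uncertainty in the objective, the kinematics
and the model.  `musclebayes` is for movement scientists who want a
*range* of muscle-force trajectories consistent with a motion instead of
one "optimal" answer.

The package treats the excitations of six elbow muscles (brachialis,
biceps long/short heads; triceps long/lateral/medial heads) as unknowns.
Each excitation is built from ten compact radial basis functions (CRBFs)
with fixed centers c and width w and free amplitudes A, squashed to (0,1)
by a numerically stable inverse logit:

    F_m(t) = sum_i A_mi * exp[ 1 - 1/(1 - ((t - c_i)/w)^2) ],
    u_m(t) = logit^-1( F_m(t) )

The 60 amplitudes have the log posterior

    logPosterior = logLikelihood + logPrior
    logLikelihood = -1/2 * sum_t [ ((theta_ref - theta_pro)/0.4)^2
                                 + ((thetadot_ref - thetadot_pro)/1.6)^2 ]
    logPrior = -1/2 * ( sum_m integral u_m(t)^3 dt / 0.08 )^2 + U(A)

where the proposal kinematics theta_pro come from forward-simulating a
six-muscle Hill-type elbow model (rigid tendons, constant moment arms,
fixed-step RK4), the effort term encodes the hypothesis that the nervous
system avoids effortful co-activation, and U(A) is a uniform box on
[-30, 30] per amplitude.  The posterior is sampled with a
delayed-rejection adaptive Metropolis (DRAM) ensemble — derivative-free,
since the forward model is a black box — and summarized by
rank-normalized split R-hat, bulk effective sample size, rank plots,
parameter correlations, and mean ± SD envelopes of kinematics and muscle
forces over evenly spaced post-burn-in proposals.

A seeded generator produces the study's input data end to end: a smooth
0° → 90° → 0° flexion profile over 0.5 s, ground-truth excitations from
an effort-penalized tracking solve, Gaussian measurement noise
(SD 0.01 rad), zero-phase 15 Hz Butterworth filtering, and numerical
differentiation.  A mass-spring-damper benchmark with known parameters
validates the sampler separately.

## Worked example

```r
library(musclebayes)

# reference data + 4 DRAM chains x 150,000 iterations + summaries
study <- run_elbow_study(seed = 1)

study$reference
#> Reference dataset: 51 samples over 0.50 s, noise SD 0.010 rad, 15 Hz filter, seed 1
#>   ground-truth effort 0.0018, tracking RMSE 0.054 deg

study$summary
#> Posterior summary over 100 proposals
#>   average angle RMSE    3.28 deg
#>   average velocity RMSE 44.44 deg/s
#>   effort 0.029 +/- 0.030
```

The reference printout says the ground-truth solve tracked the ideal
motion to 0.05° RMSE at an integrated-cubed-excitation effort of 0.0018 —
a comfortable, low-effort solution.  The summary says the 100 subsampled
posterior proposals reproduce the noisy reference to 3.3° / 44 °/s on
average while exploring a spread of effort values (0.03 ± 0.03): many
different muscle coordination patterns, not one optimum, explain the
motion.  Convergence must be checked before reading the envelopes:

```r
draws <- post_burn_samples(study$ensemble)
node1 <- sapply(draws, function(s) s[, 1])   # brachialis, first node
split_rhat(node1)
#> [1] 1.44
effective_sample_size(node1)
#> [1] 8

adj <- adjacent_node_correlations(study$correlations)
mean(adj < 0)
#> [1] 0.63
```

R-hat of 1.44 (above the conventional 1.10) and a bulk ESS of 8 say the
four chains explore overlapping but not identical regions — the expected
behavior for a derivative-free sampler in 60 dimensions, and the reason
the envelopes are read as plausible ranges rather than exact posterior
bands.  The predominance of negative correlations between adjacent CRBF
nodes within a muscle (63%) reflects the redundancy being explored: a
larger amplitude at one node trades off against its temporal neighbor.

Per-muscle force envelopes are in `study$summary$force_mean` /
`$force_sd`; `run_pipeline()` writes the same artifacts (OpenSim-style
`.sto` tables, compressed-CSV chains, JSON reports) to disk, and
`inst/cli/musclebayes.R` exposes the stages as shell subcommands.

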