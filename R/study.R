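# One-call elbow study: reference generation, DRAM sampling, subsampling
# and posterior summarization under the package's standard conditions.

#' Run the complete elbow muscle-force study
#'
#' Generates the seeded synthetic reference dataset (raised-cosine
#' 0 -> 90 -> 0 degree motion over 0.5 s, measurement noise SD 0.01 rad,
#' 15 Hz zero-phase Butterworth filtering, numerical differentiation),
#' samples the 60-amplitude posterior with a DRAM ensemble, subsamples
#' evenly spaced post-burn-in proposals, and summarizes the posterior
#' kinematics and muscle forces.
#'
#' The default ensemble (4 chains of 150,000 iterations, 50% burn-in) is a
#' scaled-down version of the full-scale study geometry (7 chains of
#' 500,000), sized so the post-burn-in log-posterior trace is stationary
#' while a run completes in minutes on one CPU core.
#'
#' @param seed master seed for measurement noise and all chains.
#' @param n_iter,n_chains DRAM ensemble geometry.
#' @param per_chain evenly spaced post-burn-in proposals kept per chain.
#' @param spec,basis,cfg model, basis and Bayesian constants.
#' @param solve_args arguments forwarded to
#'   [solve_reference_excitations()].
#' @param quiet suppress progress messages.
#' @return list with `reference`, `ensemble`, `proposals`, `summary`,
#'   `correlations` and `n_diverged`.
#' @export
run_elbow_study <- function(seed = 1L, n_iter = 150000L, n_chains = 4L,
                            per_chain = 25L, spec = elbow_spec(),
                            basis = crbf_basis(), cfg = bayes_config(),
                            solve_args = list(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("generating reference dataset (seed %d)", seed)
  reference <- make_reference_dataset(seed = seed, spec = spec,
                                      basis = basis, cfg = cfg,
                                      solve_args = solve_args)
  post <- make_elbow_posterior(reference, spec, basis, cfg)
  scfg <- sampler_config(n_iter = n_iter, n_chains = n_chains, seed = seed)
  say("sampling %d chains x %d iterations", n_chains, n_iter)
  ensemble <- run_chains(function(a) suppressWarnings(post(a)),
                         attr(post, "d"), scfg)
  say("summarizing %d x %d subsampled proposals", n_chains, per_chain)
  proposals <- subsample_chains(ensemble, per_chain = per_chain)
  summary <- summarize_posterior(proposals, reference, spec, basis, cfg)
  correlations <- parameter_correlations(
    proposals, muscle_names = spec$muscles$name, n_nodes = basis$n_nodes)
  list(reference = reference, ensemble = ensemble, proposals = proposals,
       summary = summary, correlations = correlations,
       n_diverged = posterior_counters(post)$n_diverged)
}
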