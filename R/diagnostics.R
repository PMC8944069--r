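# Convergence diagnostics and posterior summarization.
#
# R-hat and ESS follow the rank-normalized split formulation (half-chains,
# rank-normalization with the 3/8 offset, folded variant for R-hat, Geyer
# initial-monotone-sequence truncation for ESS).  Rank plots use raw pooled
# ranks scaled to (0, 1); rank normalization is applied only inside R-hat
# and ESS.

split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- n %/% 2L
  cbind(x[seq_len(half), , drop = FALSE],
        x[seq.int(n - half + 1L, n), , drop = FALSE])
}

z_scale <- function(x) {
  dm <- dim(x)
  r <- rank(as.vector(x), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  dim(z) <- dm
  z
}

rhat_basic <- function(x) {
  n <- nrow(x)
  w <- mean(apply(x, 2L, var))
  b <- n * var(colMeans(x))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction statistic on rank-normalized half-chains; the
#' reported value is the larger of the bulk statistic and the statistic of
#' the folded (median-centered absolute) draws.  Values below 1.10 are
#' conventionally taken to indicate mixing.
#'
#' @param x draws of one parameter: matrix with one column per chain (at
#'   least 2 chains, 4 draws each).
#' @return R-hat; `NaN` with attribute `degenerate = TRUE` when a chain has
#'   zero variance.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L || nrow(x) < 4L)
    stop_shape("split_rhat needs >= 2 chains of >= 4 draws")
  if (isTRUE(all.equal(max(x) - min(x), 0)))
    return(structure(NaN, degenerate = TRUE))
  s <- split_chains(x)
  bulk <- rhat_basic(z_scale(s))
  folded <- rhat_basic(z_scale(abs(s - median(s))))
  max(bulk, folded)
}

# autocovariance by FFT, biased (divided by n), per column
autocov <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  nfft <- 2^ceiling(log2(2 * n))
  xc <- sweep(x, 2L, colMeans(x))
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    f <- fft(c(xc[, j], rep(0, nfft - n)))
    ac <- Re(fft(f * Conj(f), inverse = TRUE)) / nfft
    out[, j] <- ac[seq_len(n)] / n
  }
  out
}

ess_core <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  ac <- autocov(x)
  mean_var <- mean(ac[1L, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + var(colMeans(x))
  rho <- numeric(n)
  rho_even <- 1
  rho[1L] <- 1
  rho_odd <- 1 - (mean_var - mean(ac[2L, ])) / var_plus
  rho[2L] <- rho_odd
  t <- 1L
  while (t < n - 3L && (rho_even + rho_odd) > 0) {
    rho_even <- 1 - (mean_var - mean(ac[t + 2L, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(ac[t + 3L, ])) / var_plus
    if ((rho_even + rho_odd) >= 0) {
      rho[t + 2L] <- rho_even
      rho[t + 3L] <- rho_odd
    }
    t <- t + 2L
  }
  max_t <- t - 2L
  if (rho_even > 0) rho[max_t + 2L] <- rho_even
  # Geyer's initial monotone sequence
  t <- 1L
  while (t <= max_t - 2L) {
    if (rho[t + 2L] + rho[t + 3L] > rho[t] + rho[t + 1L]) {
      rho[t + 2L] <- (rho[t] + rho[t + 1L]) / 2
      rho[t + 3L] <- rho[t + 2L]
    }
    t <- t + 2L
  }
  ess <- n * m
  tau <- -1 + 2 * sum(rho[seq_len(max_t + 1L)]) + rho[max_t + 2L]
  tau <- max(tau, 1 / log10(ess))
  ess / tau
}

#' Bulk effective sample size
#'
#' Autocorrelation-adjusted number of independent draws, computed on
#' rank-normalized split chains with Geyer's initial positive/monotone
#' sequence truncation.  Values above the total draw count are possible
#' (and reported) for anticorrelated chains.
#'
#' @param x draws of one parameter: matrix with one column per chain.
#' @return ESS; 0 with attribute `degenerate = TRUE` for constant chains.
#' @export
effective_sample_size <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4L)
    stop_shape("effective_sample_size needs >= 4 draws per chain")
  if (isTRUE(all.equal(max(x) - min(x), 0)))
    return(structure(0, degenerate = TRUE))
  ess_core(z_scale(split_chains(x)))
}

#' Per-chain rank histograms
#'
#' Ranks all draws pooled across chains (average ranks on ties), scales
#' them to (0, 1), and histograms each chain's ranks.  When the chains mix,
#' every histogram is close to uniform; uniformity is summarized by a
#' chi-square statistic per chain.
#'
#' @param x draws of one parameter: matrix with one column per chain.
#' @param bins number of histogram bins.
#' @return list per chain with `counts`, `chisq`, `p_value`; plus
#'   `breaks`.
#' @export
rank_histograms <- function(x, bins = 20L) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  r <- rank(as.vector(x), ties.method = "average")
  scaled <- matrix((r - 0.5) / length(r), n, m)
  breaks <- seq(0, 1, length.out = bins + 1L)
  chains <- lapply(seq_len(m), function(j) {
    cnt <- tabulate(pmin(bins, findInterval(scaled[, j], breaks,
                                            rightmost.closed = TRUE)),
                    nbins = bins)
    expect <- n / bins
    chisq <- sum((cnt - expect)^2 / expect)
    list(counts = cnt, chisq = chisq,
         p_value = stats::pchisq(chisq, df = bins - 1L,
                                 lower.tail = FALSE))
  })
  structure(list(chains = chains, breaks = breaks, scaled = scaled),
            class = "rank_histograms")
}

#' Pairwise parameter correlations
#'
#' Pearson correlations between all amplitude parameters on pooled
#' (thinned) posterior draws, labeled `<muscle><node>` so the two views of
#' interest - across muscles within a node and across nodes within a
#' muscle - can be read off directly.
#'
#' @param samples pooled draws, one column per parameter (>= 30 rows).
#' @param muscle_names muscle names, used to build labels.
#' @param n_nodes nodes per muscle.
#' @return Correlation matrix with attribute `n` (draw count); columns with
#'   zero variance are masked to `NA`.
#' @export
parameter_correlations <- function(samples, muscle_names = NULL,
                                   n_nodes = 10L) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 30L)
    stop_shape("parameter_correlations needs >= 30 pooled draws")
  d <- ncol(samples)
  sds <- apply(samples, 2L, sd)
  cc <- suppressWarnings(cor(samples))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  if (!is.null(muscle_names)) {
    ab <- abbreviate(muscle_names, minlength = 2L)
    labs <- as.vector(t(outer(ab, seq_len(n_nodes), paste0)))
    if (length(labs) == d) dimnames(cc) <- list(labs, labs)
  }
  structure(cc, n = nrow(samples))
}

#' Correlations between adjacent nodes within each muscle
#'
#' @param cormat matrix from [parameter_correlations()] (muscle-major
#'   parameter order).
#' @param n_muscles,n_nodes layout of the amplitude matrix.
#' @return Numeric vector of the `n_muscles * (n_nodes - 1)` adjacent-node
#'   correlations.
#' @export
adjacent_node_correlations <- function(cormat, n_muscles = 6L,
                                       n_nodes = 10L) {
  out <- numeric(0)
  for (m in seq_len(n_muscles)) {
    off <- (m - 1L) * n_nodes
    for (i in seq_len(n_nodes - 1L))
      out <- c(out, cormat[off + i, off + i + 1L])
  }
  out
}

#' Evenly spaced post-burn-in subsampling
#'
#' Selects `per_chain` evenly spaced proposals from the post-burn-in
#' segment of each chain (spacing `floor(L/per_chain)`, so the full-scale
#' geometry of 500,000 iterations, 50% burn-in and 25 per chain yields one
#' proposal every 10,000 iterations; 7 chains give 175 proposals).
#'
#' @param ensemble a `chain_ensemble`.
#' @param per_chain proposals to keep per chain.
#' @param burn_in_frac overrides the configured burn-in fraction.
#' @return Matrix of stacked proposals with attributes `indices` (selected
#'   iteration numbers per chain), `spacing` and `chain` (row origin).
#' @export
subsample_chains <- function(ensemble, per_chain = 25L,
                             burn_in_frac = NULL) {
  cfg <- attr(ensemble, "config")
  if (is.null(burn_in_frac)) burn_in_frac <- cfg$burn_in_frac
  n <- nrow(ensemble[[1L]]$samples)
  burn <- as.integer(floor(n * burn_in_frac))
  L <- as.integer(n) - burn
  spacing <- L %/% as.integer(per_chain)
  if (spacing < 1L)
    stop_invalid(sprintf(
      "post-burn-in length %d is too short for %d subsamples (need >= %d)",
      L, per_chain, per_chain))
  idx <- burn + spacing * seq_len(per_chain)
  out <- do.call(rbind, lapply(ensemble, function(ch)
    ch$samples[idx, , drop = FALSE]))
  structure(out, indices = idx, spacing = spacing,
            chain = rep(seq_along(ensemble), each = per_chain))
}

#' Posterior summary of kinematics and muscle forces
#'
#' Forward-simulates every subsampled proposal and reports pointwise
#' mean/SD envelopes of angle, velocity and per-muscle force on the
#' likelihood grid, the per-proposal tracking RMSEs against the reference
#' (averaged over proposals, in degrees and degrees/s), and the effort
#' distribution.  Proposals whose simulation diverges are excluded and
#' counted.
#'
#' @param proposals matrix of amplitude vectors (rows), e.g. from
#'   [subsample_chains()].
#' @param reference a `reference_data`.
#' @param spec an [elbow_spec()].
#' @param basis a [crbf_basis()].
#' @param cfg a [bayes_config()].
#' @return Object of class `posterior_summary`.
#' @export
summarize_posterior <- function(proposals, reference, spec = elbow_spec(),
                                basis = crbf_basis(),
                                cfg = bayes_config()) {
  post <- make_elbow_posterior(reference, spec, basis, cfg)
  P <- nrow(proposals)
  nl <- length(cfg$t_lik)
  nm <- spec$n_muscles
  th <- om <- matrix(NA_real_, nl, P)
  fr <- array(NA_real_, c(nl, nm, P))
  rmse_pos <- rmse_vel <- effort <- rep(NA_real_, P)
  lp <- rep(NA_real_, P)
  n_div <- 0L
  for (p in seq_len(P)) {
    r <- suppressWarnings(post(proposals[p, ], want_traj = TRUE))
    if (!isTRUE(r$in_bounds))
      stop_bounds("subsampled proposal outside amplitude bounds")
    if (isTRUE(r$diverged)) {
      n_div <- n_div + 1L
      next
    }
    th[, p] <- r$theta_lik
    om[, p] <- r$omega_lik
    fr[, , p] <- r$forces_lik
    rmse_pos[p] <- sqrt(mean((r$theta_lik - reference$theta_ref)^2)) *
      180 / pi
    rmse_vel[p] <- sqrt(mean((r$omega_lik - reference$omega_ref)^2)) *
      180 / pi
    effort[p] <- r$effort
    lp[p] <- r$lp
  }
  ok <- !is.na(rmse_pos)
  force_mean <- apply(fr[, , ok, drop = FALSE], c(1L, 2L), mean)
  force_sd <- apply(fr[, , ok, drop = FALSE], c(1L, 2L), sd)
  colnames(force_mean) <- colnames(force_sd) <- spec$muscles$name
  structure(list(
    t = cfg$t_lik,
    theta_mean = rowMeans(th[, ok, drop = FALSE]),
    theta_sd = apply(th[, ok, drop = FALSE], 1L, sd),
    omega_mean = rowMeans(om[, ok, drop = FALSE]),
    omega_sd = apply(om[, ok, drop = FALSE], 1L, sd),
    force_mean = force_mean, force_sd = force_sd,
    rmse_pos_deg = rmse_pos[ok], rmse_vel_deg = rmse_vel[ok],
    avg_rmse_pos_deg = mean(rmse_pos[ok]),
    avg_rmse_vel_deg = mean(rmse_vel[ok]),
    effort = effort[ok], logpost = lp[ok],
    n_proposals = sum(ok), n_diverged = n_div),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary over %d proposals\n", x$n_proposals))
  cat(sprintf("  average angle RMSE    %.2f deg\n", x$avg_rmse_pos_deg))
  cat(sprintf("  average velocity RMSE %.2f deg/s\n", x$avg_rmse_vel_deg))
  cat(sprintf("  effort %.3f +/- %.3f\n", mean(x$effort), sd(x$effort)))
  if (x$n_diverged > 0)
    cat(sprintf("  (%d diverged proposals excluded)\n", x$n_diverged))
  invisible(x)
}

#' Convergence diagnostics report for an ensemble
#'
#' Per-parameter rank-normalized split R-hat and bulk ESS on the
#' post-burn-in draws, per-chain rank-histogram uniformity statistics, and
#' the parameter correlation matrix on the pooled subsampled proposals.
#'
#' @param ensemble a `chain_ensemble`.
#' @param muscle_names optional labels for the correlation matrix.
#' @param n_nodes nodes per muscle (for labeling).
#' @param per_chain subsamples per chain for the correlation matrix.
#' @param bins rank-histogram bins.
#' @return Object of class `diagnostics_report` with `rhat`, `ess`,
#'   `rank_chisq` (parameters x chains), `correlations`, `acc_rates`.
#' @export
diagnostics_report <- function(ensemble, muscle_names = NULL,
                               n_nodes = 10L, per_chain = 25L,
                               bins = 20L) {
  draws <- post_burn_samples(ensemble)
  d <- ncol(draws[[1L]])
  par_draws <- lapply(seq_len(d), function(j)
    sapply(draws, function(s) s[, j]))
  rhat <- sapply(par_draws, split_rhat)
  ess <- sapply(par_draws, effective_sample_size)
  rank_chisq <- t(sapply(par_draws, function(x)
    sapply(rank_histograms(x, bins = bins)$chains, `[[`, "chisq")))
  sub <- subsample_chains(ensemble, per_chain = per_chain)
  correlations <- parameter_correlations(sub, muscle_names = muscle_names,
                                         n_nodes = n_nodes)
  structure(list(rhat = rhat, ess = ess, rank_chisq = rank_chisq,
                 correlations = correlations,
                 acc_rates = sapply(ensemble, `[[`, "acc_rate"),
                 n_subsampled = nrow(sub)),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("Diagnostics over %d parameters, %d chains\n",
              length(x$rhat), length(x$acc_rates)))
  cat(sprintf("  R-hat: %.3f .. %.3f (%d of %d < 1.10)\n",
              min(x$rhat, na.rm = TRUE), max(x$rhat, na.rm = TRUE),
              sum(x$rhat < 1.10, na.rm = TRUE), length(x$rhat)))
  cat(sprintf("  ESS:   %.0f .. %.0f\n", min(x$ess), max(x$ess)))
  cat(sprintf("  acceptance rates: %s\n",
              paste(sprintf("%.2f", x$acc_rates), collapse = " ")))
  invisible(x)
}
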