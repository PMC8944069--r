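# Delayed-Rejection Adaptive Metropolis (DRAM) sampler.
#
# The target is a black box returning a log-density (no derivatives).  Each
# iteration perturbs the current point with a multivariate normal proposal;
# a rejected first-stage proposal triggers one narrowed second-stage
# proposal with the standard two-stage delayed-rejection acceptance ratio;
# the proposal covariance is adapted from the chain history (Haario-style
# scaling 2.4^2/d with a small ridge).

#' Sampler configuration
#'
#' @param n_iter iterations per chain.
#' @param n_chains number of parallel chains.
#' @param burn_in_frac fraction of each chain discarded as burn-in.
#' @param init_low,init_high bounds of the uniform initial proposal.
#' @param seed master seed; per-chain RNG streams are derived from it.
#' @param adapt_start first iteration at which adaptation may replace the
#'   initial diagonal proposal covariance; default `max(1000, 1%% of
#'   n_iter)`.
#' @param adapt_interval iterations between proposal-covariance rebuilds.
#' @param am_scale adaptive-Metropolis scale; default `2.4^2/d` at run time.
#' @param am_epsilon covariance ridge keeping the proposal positive
#'   definite.
#' @param dr_shrink second-stage proposal scale factor in (0, 1).
#' @param init_sd standard deviation of the initial diagonal proposal.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 500000L, n_chains = 7L,
                           burn_in_frac = 0.5, init_low = -15,
                           init_high = -5, seed = 1L, adapt_start = NULL,
                           adapt_interval = 100L, am_scale = NULL,
                           am_epsilon = 1e-6, dr_shrink = 0.2,
                           init_sd = 0.5) {
  n_iter <- as.integer(n_iter)
  if (n_iter < 2L) stop_invalid("n_iter must be at least 2")
  if (burn_in_frac <= 0 || burn_in_frac >= 1)
    stop_invalid("burn_in_frac must be in (0, 1)")
  if (dr_shrink <= 0 || dr_shrink >= 1)
    stop_invalid("dr_shrink must be in (0, 1)")
  if (is.null(adapt_start))
    adapt_start <- max(1000L, as.integer(ceiling(0.01 * n_iter)))
  structure(list(n_iter = n_iter, n_chains = as.integer(n_chains),
                 burn_in_frac = burn_in_frac, init_low = init_low,
                 init_high = init_high, seed = as.integer(seed),
                 adapt_start = as.integer(adapt_start),
                 adapt_interval = as.integer(adapt_interval),
                 am_scale = am_scale, am_epsilon = am_epsilon,
                 dr_shrink = dr_shrink, init_sd = init_sd),
            class = "sampler_config")
}

#' Uniform initial proposal
#'
#' Draws each of the `d` components independently from
#' `U(init_low, init_high)` (default U(-15, -5), which maps through the
#' inverse logit to near-silent muscles).
#'
#' @param d dimension.
#' @param cfg a [sampler_config()].
#' @return Numeric vector of length `d`.
#' @export
initial_proposal <- function(d, cfg = sampler_config()) {
  runif(d, cfg$init_low, cfg$init_high)
}

#' Metropolis accept/reject decision
#'
#' Always accepts when the new log-density is at least the old one;
#' otherwise accepts with probability `exp(lp_new - lp_old)` (the
#' density ratio).
#'
#' @param lp_new,lp_old log posterior densities.
#' @return TRUE to accept.
#' @export
mh_accept <- function(lp_new, lp_old) {
  if (is.nan(lp_new) || is.nan(lp_old))
    stop_invalid("NaN log-density in mh_accept")
  if (lp_old == -Inf) return(is.finite(lp_new))
  if (lp_new >= lp_old) return(TRUE)
  log(runif(1)) < lp_new - lp_old
}

#' Adapted proposal covariance from chain history
#'
#' `C = am_scale * cov(history) + am_scale * am_epsilon * I`.
#'
#' @param history matrix of past samples (rows = iterations).
#' @param cfg a [sampler_config()].
#' @return Symmetric positive-definite matrix.
#' @export
adapt_covariance <- function(history, cfg = sampler_config()) {
  d <- ncol(history)
  sc <- if (is.null(cfg$am_scale)) 2.4^2 / d else cfg$am_scale
  sc * stats::cov(history) + sc * cfg$am_epsilon * diag(d)
}

# log(1 - exp(x)) for x <= 0, -Inf for x >= 0
log1mexp <- function(x) {
  if (x >= 0) return(-Inf)
  if (x > -log(2)) log(-expm1(x)) else log1p(-exp(x))
}

# Second-stage delayed-rejection log acceptance probability.
# lq_y2y1 and lq_xy1 are the (unnormalized, same-covariance) log proposal
# densities q1(y1 | y2) and q1(y1 | x); the constants cancel.
dr_log_accept2 <- function(lp_x, lp_y1, lp_y2, lq_y2y1, lq_xy1) {
  if (lp_y2 == -Inf) return(-Inf)
  la1_num <- min(0, lp_y1 - lp_y2)  # alpha1(y2 -> y1)
  la1_den <- min(0, lp_y1 - lp_x)   # alpha1(x -> y1), < 0 after rejection
  num <- lp_y2 + lq_y2y1 + log1mexp(la1_num)
  den <- lp_x + lq_xy1 + log1mexp(la1_den)
  if (num == -Inf) return(-Inf)
  if (den == -Inf) return(0)
  min(0, num - den)
}

# normalize a target's return value to list(lp, loglik, logprior)
eval_target <- function(fn, x) {
  r <- fn(x)
  if (is.list(r)) {
    list(lp = r$lp,
         loglik = if (is.null(r$loglik)) NA_real_ else r$loglik,
         logprior = if (is.null(r$logprior)) NA_real_ else r$logprior)
  } else {
    list(lp = as.numeric(r), loglik = NA_real_, logprior = NA_real_)
  }
}

# run `code` under a per-chain L'Ecuyer RNG stream derived from (seed,
# chain_id); the caller's RNG state is restored afterwards
with_chain_rng <- function(seed, chain_id, code) {
  old_kind <- RNGkind()
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(chain_id)) s <- parallel::nextRNGStream(s)
  assign(".Random.seed", s, envir = globalenv())
  force(code)
}

#' Run one DRAM chain
#'
#' @param log_post target log-density: a function of the parameter vector
#'   returning either a numeric scalar or a list with components `lp`,
#'   `loglik`, `logprior` (as built by [make_elbow_posterior()]).
#' @param d parameter dimension.
#' @param cfg a [sampler_config()].
#' @param chain_id chain index (determines the RNG stream).
#' @param init optional fixed initial point; drawn with
#'   [initial_proposal()] when NULL.
#' @param init_cov optional initial proposal covariance (defaults to
#'   `init_sd^2 * I`); together with `init` this allows resuming a chain
#'   from a stored state.
#' @return Object of class `chain_result`: `samples` (n_iter x d),
#'   `logpost`/`loglik`/`logprior` traces, `accepted`, `stage` (1 =
#'   first-stage accept, 2 = delayed-rejection accept, 0 = rejected),
#'   acceptance summaries, final proposal covariance and the config echo.
#' @export
run_chain <- function(log_post, d, cfg = sampler_config(), chain_id = 1L,
                      init = NULL, init_cov = NULL) {
  with_chain_rng(cfg$seed, chain_id, {
    n <- cfg$n_iter
    sc <- if (is.null(cfg$am_scale)) 2.4^2 / d else cfg$am_scale
    samples <- matrix(NA_real_, n, d)
    lp_tr <- ll_tr <- lpr_tr <- numeric(n)
    accepted <- logical(n)
    stage <- integer(n)
    x <- if (is.null(init)) initial_proposal(d, cfg) else as.numeric(init)
    cur <- tryCatch(eval_target(log_post, x), error = function(e)
      stop_mb(sprintf("target failed at initialization: %s",
                      conditionMessage(e)), "musclebayes_target_error"))
    samples[1L, ] <- x
    lp_tr[1L] <- cur$lp
    ll_tr[1L] <- cur$loglik
    lpr_tr[1L] <- cur$logprior
    accepted[1L] <- TRUE  # the initial proposal is always accepted
    stage[1L] <- 1L
    C <- if (is.null(init_cov)) diag(cfg$init_sd^2, d) else init_cov
    R1 <- chol(C)
    # running mean / scatter for O(d^2) covariance adaptation
    run_mean <- x
    run_m2 <- matrix(0, d, d)
    n_seen <- 1L
    n_acc1 <- 0L
    n_acc2 <- 0L
    n_stage2 <- 0L
    for (it in 2:n) {
      z <- rnorm(d)
      y1 <- x + drop(z %*% R1)
      p1 <- tryCatch(eval_target(log_post, y1), error = function(e)
        stop_mb(sprintf("target failed at iteration %d: %s", it,
                        conditionMessage(e)), "musclebayes_target_error"))
      move <- FALSE
      if (mh_accept(p1$lp, cur$lp)) {
        x <- y1
        cur <- p1
        move <- TRUE
        stage[it] <- 1L
        n_acc1 <- n_acc1 + 1L
      } else {
        # delayed rejection: narrowed proposal around the current point
        n_stage2 <- n_stage2 + 1L
        z2 <- rnorm(d)
        y2 <- x + cfg$dr_shrink * drop(z2 %*% R1)
        p2 <- eval_target(log_post, y2)
        la2 <- if (p2$lp == -Inf) -Inf else {
          q_y2y1 <- -0.5 * sum(backsolve(R1, y1 - y2, transpose = TRUE)^2)
          q_xy1 <- -0.5 * sum(z^2)
          dr_log_accept2(cur$lp, p1$lp, p2$lp, q_y2y1, q_xy1)
        }
        if (la2 > -Inf && log(runif(1)) < la2) {
          x <- y2
          cur <- p2
          move <- TRUE
          stage[it] <- 2L
          n_acc2 <- n_acc2 + 1L
        }
      }
      samples[it, ] <- x
      lp_tr[it] <- cur$lp
      ll_tr[it] <- cur$loglik
      lpr_tr[it] <- cur$logprior
      accepted[it] <- move
      # Welford update of the history mean/scatter
      n_seen <- n_seen + 1L
      delta <- x - run_mean
      run_mean <- run_mean + delta / n_seen
      run_m2 <- run_m2 + tcrossprod(delta, x - run_mean)
      if (it >= cfg$adapt_start && it %% cfg$adapt_interval == 0L) {
        C <- sc * run_m2 / (n_seen - 1L) + sc * cfg$am_epsilon * diag(d)
        R1 <- chol(C)
      }
    }
    structure(list(samples = samples, logpost = lp_tr, loglik = ll_tr,
                   logprior = lpr_tr, accepted = accepted, stage = stage,
                   acc_rate = mean(accepted[-1L]),
                   n_accept_stage1 = n_acc1, n_accept_stage2 = n_acc2,
                   n_stage2_tried = n_stage2, proposal_cov = C,
                   chain_id = chain_id, seed = cfg$seed, config = cfg),
              class = "chain_result")
  })
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf(
    "DRAM chain %d: %d iterations, acceptance %.1f%% (stage 1 %d, stage 2 %d)\n",
    x$chain_id, length(x$logpost), 100 * x$acc_rate, x$n_accept_stage1,
    x$n_accept_stage2))
  invisible(x)
}

#' Run an ensemble of DRAM chains
#'
#' Chains run serially with independent RNG streams (L'Ecuyer) derived
#' from the master seed, so the ensemble is reproducible and identical to
#' any concurrent schedule.  A failing chain does not discard the chains
#' already completed: partial results are attached to the error.
#'
#' @inheritParams run_chain
#' @return Object of class `chain_ensemble`: list of `chain_result`s.
#' @export
run_chains <- function(log_post, d, cfg = sampler_config()) {
  if (cfg$n_chains < 1L) stop_invalid("n_chains must be >= 1")
  results <- vector("list", cfg$n_chains)
  for (k in seq_len(cfg$n_chains)) {
    results[[k]] <- tryCatch(
      run_chain(log_post, d, cfg, chain_id = k),
      error = function(e) {
        stop_mb(sprintf("chain %d failed: %s", k, conditionMessage(e)),
                "musclebayes_chain_error",
                partial = results[seq_len(k - 1L)])
      })
  }
  structure(results, class = "chain_ensemble", config = cfg)
}

#' @export
print.chain_ensemble <- function(x, ...) {
  cat(sprintf("DRAM ensemble: %d chains x %d iterations\n", length(x),
              length(x[[1L]]$logpost)))
  for (ch in x) print(ch)
  invisible(x)
}

#' Post-burn-in sample matrices from an ensemble
#'
#' @param ensemble a `chain_ensemble`.
#' @param burn_in_frac overrides the configured burn-in fraction.
#' @return list of matrices (one per chain) of retained draws.
#' @export
post_burn_samples <- function(ensemble, burn_in_frac = NULL) {
  cfg <- attr(ensemble, "config")
  if (is.null(burn_in_frac)) burn_in_frac <- cfg$burn_in_frac
  lapply(ensemble, function(ch) {
    n <- nrow(ch$samples)
    keep <- seq.int(floor(n * burn_in_frac) + 1L, n)
    ch$samples[keep, , drop = FALSE]
  })
}
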