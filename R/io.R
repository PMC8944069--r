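# File formats, run configuration and the end-to-end pipeline.
#
# Trajectories interchange as OpenSim-style storage (.sto/.mot) files;
# chains persist as compressed CSV (one file per chain) with a JSON
# metadata sidecar; run configuration is YAML.  Every artifact is stamped
# with the configuration hash and master seed.

#' Write an OpenSim-style storage (.sto) file
#'
#' Tab-delimited numeric table with a `nRows`/`nColumns`/`endheader`
#' header; the first column must be time on a uniform grid.
#'
#' @param table data.frame with a `time` first column.
#' @param path output file.
#' @param name table name recorded on the first header line.
#' @return `path`, invisibly.
#' @export
write_sto <- function(table, path, name = "musclebayes") {
  if (names(table)[1L] != "time") stop_invalid("first column must be time")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name, "version=1",
               sprintf("nRows=%d", nrow(table)),
               sprintf("nColumns=%d", ncol(table)),
               "inDegrees=no", "endheader",
               paste(names(table), collapse = "\t")), con)
  body <- apply(table, 1L, function(row)
    paste(sprintf("%.12g", row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an OpenSim-style storage (.sto/.mot) file
#'
#' @param path file to read.
#' @return data.frame; numeric columns as named in the file.
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", trimws(lines))
  if (is.na(end))
    stop_parse(sprintf("%s: no 'endheader' line found", path))
  hdr <- lines[seq_len(end - 1L)]
  get_num <- function(key) {
    ln <- grep(paste0("^", key, "="), trimws(hdr), value = TRUE)
    if (length(ln) != 1L)
      stop_parse(sprintf("%s: header line '%s=' missing", path, key))
    as.integer(sub(paste0(key, "="), "", ln))
  }
  n_rows <- get_num("nRows")
  n_cols <- get_num("nColumns")
  cols <- strsplit(trimws(lines[end + 1L]), "\t")[[1L]]
  if (length(cols) != n_cols)
    stop_parse(sprintf(
      "%s: header declares nColumns=%d but %d column names found (line %d)",
      path, n_cols, length(cols), end + 1L))
  body <- lines[seq.int(end + 2L, length.out = n_rows)]
  vals <- lapply(strsplit(body, "\t"), as.numeric)
  bad <- which(lengths(vals) != n_cols)
  if (length(bad))
    stop_parse(sprintf("%s: row at line %d has %d fields, expected %d",
                       path, end + 1L + bad[1L], lengths(vals)[bad[1L]],
                       n_cols))
  out <- as.data.frame(do.call(rbind, vals))
  names(out) <- cols
  out
}

#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; used to stamp artifacts so
#' outputs produced under identical configurations are identifiable.
#'
#' @param x any serializable R object.
#' @return Hex digest string.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Default run configuration
#'
#' Bundles the model, basis, Bayesian constants, sampler settings and
#' reference-generation settings into one serializable list.
#'
#' @param seed master seed.
#' @param n_iter,n_chains sampler geometry.
#' @param solve_args arguments forwarded to
#'   [solve_reference_excitations()] by the reference stage.
#' @param ... overrides passed to [sampler_config()].
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_iter = 20000L, n_chains = 4L,
                       solve_args = list(), ...) {
  structure(list(
    seed = as.integer(seed),
    sampler = sampler_config(n_iter = n_iter, n_chains = n_chains,
                             seed = seed, ...),
    bayes = bayes_config(),
    basis = crbf_basis(),
    spec = elbow_spec(),
    noise_sd = 0.01, cutoff = 15, peak = pi / 2,
    subsample_per_chain = 25L, solve_args = solve_args),
    class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file.
#' @return `read_run_config` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- list(
    seed = config$seed,
    sampler = unclass(config$sampler),
    bayes = unclass(config$bayes),
    basis = unclass(config$basis)[c("n_nodes", "t_f")],
    basis_range = range(config$basis$centers),
    basis_width = config$basis$width,
    muscles = config$spec$muscles,
    inertia = config$spec$I, m_g_d = config$spec$m_g_d,
    noise_sd = config$noise_sd, cutoff = config$cutoff,
    peak = config$peak,
    subsample_per_chain = config$subsample_per_chain)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config(seed = y$seed, n_iter = y$sampler$n_iter,
                    n_chains = y$sampler$n_chains)
  for (f in names(y$sampler)) cfg$sampler[[f]] <- y$sampler[[f]]
  cfg$sampler$n_iter <- as.integer(cfg$sampler$n_iter)
  cfg$sampler$n_chains <- as.integer(cfg$sampler$n_chains)
  cfg$bayes <- bayes_config(sigma_pos = y$bayes$sigma_pos,
                            sigma_vel = y$bayes$sigma_vel,
                            sigma_effort = y$bayes$sigma_effort,
                            amp_bound = y$bayes$amp_bound,
                            t_lik = y$bayes$t_lik,
                            dt_sim = y$bayes$dt_sim)
  cfg$basis <- crbf_basis(n_nodes = y$basis$n_nodes,
                          t_start = y$basis_range[1L],
                          t_end = y$basis_range[2L],
                          width = y$basis_width, t_f = y$basis$t_f)
  mus <- as.data.frame(y$muscles)
  cfg$spec <- elbow_spec(muscles = mus, I = y$inertia, m_g_d = y$m_g_d)
  cfg$noise_sd <- y$noise_sd
  cfg$cutoff <- y$cutoff
  cfg$peak <- y$peak
  cfg$subsample_per_chain <- as.integer(y$subsample_per_chain)
  cfg
}

#' Save / load a chain as compressed CSV
#'
#' One file per chain: the samples plus log-density traces and acceptance
#' bookkeeping, with a JSON sidecar carrying the seed, chain id and
#' configuration hash (enough to resume via `run_chain(init = ,
#' init_cov = )`).
#'
#' @param chain a `chain_result`.
#' @param path output `.csv.gz` file.
#' @return `load_chain` returns a list with `table` and `meta`.
#' @export
save_chain <- function(chain, path) {
  tab <- data.frame(chain$samples)
  names(tab) <- paste0("A", seq_len(ncol(chain$samples)))
  tab$logpost <- chain$logpost
  tab$loglik <- chain$loglik
  tab$logprior <- chain$logprior
  tab$accepted <- as.integer(chain$accepted)
  tab$stage <- chain$stage
  con <- gzfile(path, "w")
  write.csv(tab, con, row.names = FALSE)
  close(con)
  meta <- list(chain_id = chain$chain_id, seed = chain$seed,
               n_iter = nrow(chain$samples),
               acc_rate = chain$acc_rate,
               config_hash = config_hash(unclass(chain$config)),
               last_state = as.numeric(chain$samples[nrow(chain$samples), ]),
               proposal_cov = chain$proposal_cov)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_chain
#' @export
load_chain <- function(path) {
  tab <- read.csv(gzfile(path))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  list(table = tab, meta = meta)
}

#' Run the full pipeline: reference -> sampling -> diagnostics -> summary
#'
#' Executes the four stages with one configuration and seed, writing all
#' artifacts under `out_dir`: `reference.sto` + `reference_truth.json`,
#' `chains/chain_<k>.csv.gz`, `diagnostics.json` and `summary.json` +
#' `force_envelopes.sto`.  Idempotent: rerunning with the same
#' configuration and seed reproduces identical sample tables.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory `reference`, `ensemble`,
#'   `report` and `summary`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(list(seed = config$seed,
                           sampler = unclass(config$sampler),
                           bayes = unclass(config$bayes)))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[[3L]]
  say("[1/4] generating reference dataset (seed %d)", config$seed)
  reference <- make_reference_dataset(
    seed = config$seed, spec = config$spec, basis = config$basis,
    cfg = config$bayes, noise_sd = config$noise_sd,
    cutoff = config$cutoff, peak = config$peak,
    solve_args = if (is.null(config$solve_args)) list() else
      config$solve_args)
  ref_tab <- data.frame(time = reference$t, theta = reference$theta_ref,
                        omega = reference$omega_ref)
  write_sto(ref_tab, file.path(out_dir, "reference.sto"),
            name = "reference_kinematics")
  jsonlite::write_json(
    list(seed = config$seed, config_hash = hash,
         truth_amplitudes = reference$truth$A,
         truth_effort = reference$truth$effort,
         truth_rmse_deg = reference$truth$rmse_deg,
         noise_sd = reference$noise_sd, cutoff = reference$cutoff),
    file.path(out_dir, "reference_truth.json"), digits = NA)
  say("[2/4] sampling %d chains x %d iterations",
      config$sampler$n_chains, config$sampler$n_iter)
  post <- make_elbow_posterior(reference, config$spec, config$basis,
                               config$bayes)
  d <- attr(post, "d")
  ensemble <- run_chains(function(a) suppressWarnings(post(a)), d,
                         config$sampler)
  chain_dir <- file.path(out_dir, "chains")
  dir.create(chain_dir, showWarnings = FALSE)
  for (k in seq_along(ensemble))
    save_chain(ensemble[[k]],
               file.path(chain_dir, sprintf("chain_%d.csv.gz", k)))
  cnt <- posterior_counters(post)
  say("      %d simulations, %d diverged", cnt$n_sim, cnt$n_diverged)
  say("[3/4] diagnostics")
  report <- diagnostics_report(ensemble,
                               muscle_names = config$spec$muscles$name,
                               n_nodes = config$basis$n_nodes,
                               per_chain = config$subsample_per_chain)
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed, rhat = report$rhat,
         ess = report$ess, acc_rates = report$acc_rates,
         rank_chisq = report$rank_chisq,
         n_diverged = cnt$n_diverged),
    file.path(out_dir, "diagnostics.json"), digits = NA)
  say("[4/4] posterior summary")
  sub <- subsample_chains(ensemble,
                          per_chain = config$subsample_per_chain)
  summary <- summarize_posterior(sub, reference, config$spec,
                                 config$basis, config$bayes)
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         avg_rmse_pos_deg = summary$avg_rmse_pos_deg,
         avg_rmse_vel_deg = summary$avg_rmse_vel_deg,
         effort_mean = mean(summary$effort),
         effort_sd = sd(summary$effort),
         n_proposals = summary$n_proposals,
         n_diverged = summary$n_diverged),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  env <- data.frame(time = summary$t,
                    theta_mean = summary$theta_mean,
                    theta_sd = summary$theta_sd,
                    omega_mean = summary$omega_mean,
                    omega_sd = summary$omega_sd)
  for (m in seq_len(config$spec$n_muscles)) {
    env[[paste0("F_", config$spec$muscles$name[m], "_mean")]] <-
      summary$force_mean[, m]
    env[[paste0("F_", config$spec$muscles$name[m], "_sd")]] <-
      summary$force_sd[, m]
  }
  write_sto(env, file.path(out_dir, "force_envelopes.sto"),
            name = "posterior_envelopes")
  say("done in %.1f s", proc.time()[[3L]] - t0)
  invisible(list(reference = reference, ensemble = ensemble,
                 report = report, summary = summary, hash = hash))
}
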