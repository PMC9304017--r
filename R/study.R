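#' Simulation study driver
#'
#' Replicates the package's simulation experiments end to end: draw a true
#' tree (from a fixed tree or from the generalized or independent
#' -bifurcating prior with a minimum divergence-time gap), draw a shared
#' population size from its gamma prior, simulate biallelic characters,
#' run several MCMC chains under the requested inference model, and
#' summarize each replicate (convergence diagnostics and the posterior
#' probabilities of all merged neighboring divergences of the true tree).
#'
#' @param n_datasets number of simulated datasets.
#' @param N number of species (ignored when `fixed_tree` is given).
#' @param m characters per dataset (unlinked unless `loci`/`sites` given).
#' @param true_model `"MG"` or `"MIB"`: prior the true trees are drawn from.
#' @param fixed_tree optional `gtree` used for every replicate.
#' @param config a [prior_config()]; also used as the analysis prior.
#' @param min_gap minimum divergence-time separation for prior-drawn trees.
#' @param chains,generations,sample_freq,burn_in MCMC settings per dataset.
#' @param infer_model model used for inference (`"MG"` or `"MIB"`).
#' @param loci,sites linked-character design (NULL for unlinked).
#' @param filter `"all"`, `"variable"` (drop constant characters, corrected
#'   likelihood) or `"one_per_locus"`.
#' @param favorable run chains twice as long, sample half as often, and
#'   start from the true tree.
#' @param mix_generations topology-mixing generations for prior draws.
#' @param seed master seed; all replicate and chain seeds derive from it.
#' @return a `phygen_study`: per-replicate results plus pooled tables
#'   `merges` (merged-neighbor probabilities vs the true trees) and
#'   `diagnostics`.
#' @export
run_simulation_study <- function(n_datasets = 20, N = 6, m = 2000,
                                 true_model = c("MG", "MIB"),
                                 fixed_tree = NULL,
                                 config = prior_config(),
                                 min_gap = 0.001, chains = 4,
                                 generations = 1200, sample_freq = 2,
                                 burn_in = 1 / 3,
                                 infer_model = c("MG", "MIB"),
                                 loci = NULL, sites = NULL,
                                 filter = c("all", "variable",
                                            "one_per_locus"),
                                 favorable = FALSE,
                                 mix_generations = 1000, seed = 1) {
  true_model <- match.arg(true_model)
  infer_model <- match.arg(infer_model)
  filter <- match.arg(filter)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
  reps <- vector("list", n_datasets)
  merges <- NULL
  diags <- NULL
  for (i in seq_len(n_datasets)) {
    set.seed(rep_seeds[i])
    if (is.null(fixed_tree)) {
      tr <- sample_trees_min_gap(N, config, min_gap = min_gap,
                                 n_accept = 1, model = true_model,
                                 mix_generations = mix_generations)$trees[[1]]
    } else {
      tr <- fixed_tree
    }
    neu <- sample_ne_prior(config)
    params <- model_params(neu = neu, mu = config$mu,
                           u = 1, v = 1)
    dat <- simulate_matrix(tr, params, m = m, loci = loci, sites = sites)
    dat <- switch(filter, all = dat, variable = filter_variable(dat),
                  one_per_locus = one_variable_per_locus(dat))
    gens <- if (favorable) 2L * generations else generations
    sfreq <- if (favorable) 2L * sample_freq else sample_freq
    start <- if (favorable) tr else "random_bifurcating"
    chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
    traces <- lapply(seq_len(chains), function(ch)
      run_chain(dat, config, generations = gens, sample_freq = sfreq,
                seed = chain_seeds[ch], chain_id = ch, start = start,
                model = infer_model))
    kept <- lapply(traces, discard_burnin, burn_in = burn_in)
    pooled_trees <- do.call(c, lapply(kept, `[[`, "trees"))
    mp <- merged_divergence_probabilities(tr, pooled_trees)
    mp$dataset <- i
    dg <- convergence_diagnostics(kept)
    diags <- rbind(diags, data.frame(
      dataset = i, asdsf = dg$asdsf,
      psrf_root = dg$psrf["root_height"],
      psrf_treelen = dg$psrf["tree_length"], psrf_neu = dg$psrf["neu"],
      ess_root = dg$ess["root_height"],
      ess_treelen = dg$ess["tree_length"], ess_neu = dg$ess["neu"],
      row.names = NULL))
    merges <- rbind(merges, mp)
    reps[[i]] <- list(true_tree = tr, neu = neu, seed = rep_seeds[i],
                      traces = kept, merges = mp, diagnostics = dg)
  }
  structure(list(replicates = reps, merges = merges, diagnostics = diags,
                 settings = list(n_datasets = n_datasets, N = N, m = m,
                                 true_model = true_model,
                                 infer_model = infer_model,
                                 chains = chains, generations = generations,
                                 sample_freq = sample_freq, seed = seed,
                                 filter = filter)),
            class = "phygen_study")
}

#' @export
print.phygen_study <- function(x, ...) {
  s <- x$settings
  cat(sprintf("phygen_study: %d datasets (%s truth, %s inference)\n",
              s$n_datasets, s$true_model, s$infer_model))
  fp <- mean(x$merges$probability > 0.5)
  cat(sprintf("  merged-neighbor pairs: %d, fraction pp>0.5: %.3f\n",
              nrow(x$merges), fp))
  cat(sprintf("  max PSRF %.3f, min ESS %.0f, max ASDSF %.4f\n",
              max(x$diagnostics[, grep("psrf", names(x$diagnostics))]),
              min(x$diagnostics[, grep("ess", names(x$diagnostics))]),
              max(x$diagnostics$asdsf)))
  invisible(x)
}

#' False-positive summary of a simulation study
#'
#' The proportion of merged neighboring divergence pairs (relative to the
#' true trees) whose posterior probability exceeds `threshold`, and the
#' largest true time gap among pairs exceeding it.
#'
#' @param study a `phygen_study`.
#' @param threshold posterior-probability threshold (default 0.5).
#' @return list with `fpr_percent`, `n_pairs` and `max_gap_supported`.
#' @export
false_merge_summary <- function(study, threshold = 0.5) {
  p <- study$merges$probability
  hit <- p > threshold
  list(fpr_percent = 100 * mean(hit),
       n_pairs = length(p),
       max_gap_supported = if (any(hit)) max(study$merges$gap[hit]) else 0)
}
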