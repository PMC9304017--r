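#' Branch-score distance between two trees
#'
#' The square root of the sum of squared branch-length differences over the
#' union of splits of the two trees (a split absent from a tree contributes
#' length zero). With `include_tips = TRUE` (the Kuhner-Felsenstein
#' convention) terminal branches participate; with `FALSE` only internal
#' branches are compared.
#'
#' @param tree_a,tree_b `gtree`s over the same tip set.
#' @param include_tips include terminal branches (default `TRUE`).
#' @return nonnegative distance; zero iff the trees agree in topology and
#'   branch lengths.
#' @export
branch_score_distance <- function(tree_a, tree_b, include_tips = TRUE) {
  if (!setequal(tree_a$tips, tree_b$tips)) stop("tip sets differ")
  a <- gt_splits(tree_a, include_tips = include_tips)
  b <- gt_splits(tree_b, include_tips = include_tips)
  keys <- union(names(a), names(b))
  va <- ifelse(keys %in% names(a), a[keys], 0)
  vb <- ifelse(keys %in% names(b), b[keys], 0)
  sqrt(sum((va - vb)^2))
}

## ---------------------------------------------------------------------------
## node / split / shared-divergence records
## ---------------------------------------------------------------------------

## per-tree records: split keys (nontrivial), node records (split plus the
## multiset of child splits, capturing multifurcations), shared events
## (classes holding >= 2 node records), and a map node record -> class.
tree_records <- function(tree) {
  N <- n_tips(tree)
  below <- vector("list", N + n_internal(tree))
  for (i in seq_len(N)) below[[i]] <- tree$tips[i]
  rec <- function(id) {
    if (id <= N) return(below[[id]])
    below[[id]] <<- sort(unlist(lapply(tree$children[[id - N]], rec)))
    below[[id]]
  }
  rec(gt_root(tree))
  key_of <- function(id) paste(below[[id]], collapse = "|")
  node_key <- vapply(N + seq_len(n_internal(tree)), function(id) {
    kids <- vapply(tree$children[[id - N]], key_of, "")
    paste0(key_of(id), "=>", paste(sort(kids), collapse = ";"))
  }, "")
  parent <- gt_parents(tree)
  nontriv <- which(parent[N + seq_len(n_internal(tree))] != 0L)
  splits <- vapply(N + nontriv, key_of, "")
  events <- character(0)
  for (k in seq_len(n_classes(tree))) {
    mem <- which(tree$class_of == k)
    if (length(mem) >= 2L)
      events <- c(events, paste(sort(node_key[mem]), collapse = "&&"))
  }
  list(splits = splits, nodes = node_key, class_of_node = tree$class_of,
       events = events)
}

#' Split, node, shared-divergence and topology frequencies
#'
#' Frequencies of features across a posterior sample of generalized trees:
#' nontrivial splits (tip sets subtended by internal branches), nodes
#' (split plus the set of child splits, so a bifurcating node and its
#' multifurcating collapse are distinct records), shared-divergence events
#' (sets of two or more nodes mapped to one height class), and topologies.
#'
#' @param trees list of `gtree` posterior samples.
#' @return list of data frames `splits`, `nodes`, `events`, `topologies`
#'   with columns `item` and `frequency`.
#' @export
split_node_shared_frequencies <- function(trees) {
  stopifnot(length(trees) >= 1)
  n <- length(trees)
  recs <- lapply(trees, tree_records)
  freq_of <- function(field) {
    tab <- table(unlist(lapply(recs, function(r) unique(r[[field]]))))
    data.frame(item = names(tab), frequency = as.vector(tab) / n,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  topo <- table(vapply(trees, topology_key, ""))
  list(splits = freq_of("splits"), nodes = freq_of("nodes"),
       events = freq_of("events"),
       topologies = data.frame(item = names(topo),
                               frequency = as.vector(topo) / n,
                               row.names = NULL, stringsAsFactors = FALSE))
}

#' Posterior probabilities of merged neighboring divergences
#'
#' For every merge of two neighboring divergence times of a reference
#' (usually true) tree — each creating a shared divergence or a
#' multifurcation — the fraction of posterior samples containing that
#' divergence scenario: all node records produced by the merge are present
#' and mapped to a single height class.
#'
#' @param reference a `gtree` (e.g. the true simulation tree).
#' @param trees list of sampled `gtree`s with the same tips.
#' @return data frame with the merged pair's class heights, their time
#'   difference, and the posterior probability of the merged scenario.
#' @export
merged_divergence_probabilities <- function(reference, trees) {
  if (!setequal(reference$tips, trees[[1]]$tips)) stop("tip sets differ")
  merges <- enumerate_neighbor_merges(reference)
  samp <- lapply(trees, tree_records)
  out <- data.frame(young = numeric(0), old = numeric(0), gap = numeric(0),
                    probability = numeric(0))
  for (mg in merges) {
    mrec <- tree_records(mg$tree)
    ho <- reference$heights[mg$old]
    km <- which(mg$tree$heights == ho)
    mem <- which(mrec$class_of_node == km)
    scen <- mrec$nodes[mem]
    hit <- vapply(samp, function(r) {
      ix <- match(scen, r$nodes)
      if (anyNA(ix)) return(FALSE)
      length(unique(r$class_of_node[ix])) == 1L
    }, TRUE)
    out <- rbind(out, data.frame(young = reference$heights[mg$young],
                                 old = ho, gap = ho - reference$heights[mg$young],
                                 probability = mean(hit)))
  }
  out
}

## ---------------------------------------------------------------------------
## convergence diagnostics
## ---------------------------------------------------------------------------

#' Effective sample size of a scalar chain
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence: the
#' autocovariances are summed in adjacent pairs until a pair sum turns
#' nonpositive. For white noise the estimate approaches the chain length;
#' for an AR(1) chain with coefficient `phi` it approaches
#' `n (1-phi)/(1+phi)`.
#'
#' @param x numeric vector (one chain) or a list of chains pooled after
#'   per-chain centering.
#' @return estimated effective sample size.
#' @export
effective_sample_size <- function(x) {
  chains <- if (is.list(x)) x else list(x)
  n <- min(lengths(chains))
  m <- length(chains)
  if (n < 4) return(m * n)
  maxlag <- min(n - 2L, max(10L, floor(n / 3)))
  ## average autocovariance across chains (per-chain demeaning)
  gam <- rep(0, maxlag + 1L)
  v <- 0
  for (ch in chains) {
    y <- ch[seq_len(n)] - mean(ch[seq_len(n)])
    v <- v + sum(y^2) / n
    for (t in 0:maxlag) gam[t + 1L] <- gam[t + 1L] +
        sum(y[seq_len(n - t)] * y[seq_len(n - t) + t]) / n
  }
  gam <- gam / m
  if (gam[1] <= 0) return(m * n)
  rho <- gam / gam[1]
  s <- 0
  t <- 1L
  while (t + 1L <= maxlag) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  max(1, m * n / (1 + 2 * s))
}

#' Potential scale reduction factor (square-root form)
#'
#' The Brooks-Gelman corrected scale-reduction statistic computed from the
#' within- and between-chain variances of a scalar, returned as its square
#' root; values near 1 indicate the chains sample the same distribution.
#'
#' @param chains list of numeric vectors (one per chain, equal lengths).
#' @return the PSRF.
#' @export
potential_scale_reduction <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("need at least two chains")
  n <- min(lengths(chains))
  xs <- lapply(chains, function(ch) ch[seq_len(n)])
  W <- mean(vapply(xs, stats::var, 1))
  mu <- vapply(xs, mean, 1)
  B_over_n <- stats::var(mu)
  if (W <= 0) return(1)
  sigma2 <- (n - 1) / n * W + B_over_n
  sqrt((m + 1) / m * sigma2 / W - (n - 1) / (m * n))
}

#' Average standard deviation of split frequencies
#'
#' For every nontrivial split reaching at least `min_freq` in at least one
#' chain, the standard deviation of its frequency across chains; the ASDSF
#' is the mean of these standard deviations.
#'
#' @param chains_trees list over chains of lists of sampled `gtree`s.
#' @param min_freq minimum split frequency for inclusion (default 0.10).
#' @return the ASDSF (0 when no split qualifies).
#' @export
average_sd_split_frequencies <- function(chains_trees, min_freq = 0.1) {
  if (length(chains_trees) < 2) stop("need at least two chains")
  freqs <- lapply(chains_trees, function(trees) {
    n <- length(trees)
    tab <- table(unlist(lapply(trees, function(tr)
      unique(tree_records(tr)$splits))))
    stats::setNames(as.vector(tab) / n, names(tab))
  })
  keys <- unique(unlist(lapply(freqs, names)))
  if (!length(keys)) return(0)
  fm <- vapply(freqs, function(f) ifelse(keys %in% names(f), f[keys], 0),
               numeric(length(keys)))
  fm <- matrix(fm, nrow = length(keys))
  keep <- apply(fm, 1, max) >= min_freq
  if (!any(keep)) return(0)
  mean(apply(fm[keep, , drop = FALSE], 1, stats::sd))
}

#' Convergence diagnostics across chains
#'
#' Computes the ASDSF over sampled trees (10% minimum split frequency by
#' default) plus the PSRF and pooled ESS of the requested scalar columns of
#' the chains' trace tables.
#'
#' @param traces list of `phygen_trace` objects (post burn-in).
#' @param scalars trace columns to diagnose.
#' @param min_freq ASDSF split-frequency threshold.
#' @return list with `asdsf`, and named vectors `psrf`, `ess`.
#' @export
convergence_diagnostics <- function(traces,
                                    scalars = c("root_height", "tree_length",
                                                "neu"),
                                    min_freq = 0.1) {
  stopifnot(length(traces) >= 2)
  asdsf <- average_sd_split_frequencies(lapply(traces, `[[`, "trees"),
                                        min_freq = min_freq)
  psrf <- vapply(scalars, function(sc)
    potential_scale_reduction(lapply(traces, function(tr)
      tr$samples[[sc]])), 1)
  ess <- vapply(scalars, function(sc)
    effective_sample_size(lapply(traces, function(tr) tr$samples[[sc]])), 1)
  list(asdsf = asdsf, psrf = psrf, ess = ess)
}

## ---------------------------------------------------------------------------
## posterior summaries
## ---------------------------------------------------------------------------

#' Discard burn-in from a trace
#'
#' @param trace a `phygen_trace`.
#' @param burn_in fraction of initial samples to drop (default 1/3, as in
#'   retaining the last 1,000 of 1,500 samples).
#' @return the trimmed trace.
#' @export
discard_burnin <- function(trace, burn_in = 1 / 3) {
  n <- nrow(trace$samples)
  drop <- floor(n * burn_in)
  if (drop > 0) {
    trace$samples <- trace$samples[-seq_len(drop), , drop = FALSE]
    trace$trees <- trace$trees[-seq_len(drop)]
  }
  trace
}

ci95 <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)

#' Posterior summary of generalized-tree samples
#'
#' Combines retained samples of one or more chains into: posterior means
#' and equal-tailed 95% credible intervals of the root age, tree length,
#' population size and number of divergence times; split/node/shared-event
#' and topology frequencies; the MAP topology (ties broken toward the
#' lexicographically smallest key) with posterior mean node heights
#' conditional on it; and the posterior distribution of the number of
#' divergence times.
#'
#' @param traces list of `phygen_trace` objects.
#' @param burn_in initial fraction of each chain to discard.
#' @return a `phygen_summary` list.
#' @export
map_summary <- function(traces, burn_in = 1 / 3) {
  if (inherits(traces, "phygen_trace")) traces <- list(traces)
  traces <- lapply(traces, discard_burnin, burn_in = burn_in)
  samples <- do.call(rbind, lapply(traces, `[[`, "samples"))
  trees <- do.call(c, lapply(traces, `[[`, "trees"))
  stopifnot(length(trees) >= 1)
  freqs <- split_node_shared_frequencies(trees)
  topo <- freqs$topologies
  best <- topo$frequency == max(topo$frequency)
  map_key <- sort(topo$item[best])[1]
  in_map <- vapply(trees, function(tr) topology_key(tr) == map_key, TRUE)
  ## node heights conditional on the MAP topology
  map_tree <- trees[[which(in_map)[1]]]
  mrec <- tree_records(map_tree)
  hmat <- vapply(trees[in_map], function(tr) {
    r <- tree_records(tr)
    h <- node_height(tr)
    h[n_tips(tr) + match(mrec$nodes, r$nodes)]
  }, numeric(length(mrec$nodes)))
  hmat <- matrix(hmat, nrow = length(mrec$nodes))
  node_heights <- data.frame(
    node = mrec$nodes,
    mean = rowMeans(hmat),
    lower = apply(hmat, 1, function(x) ci95(x)[1]),
    upper = apply(hmat, 1, function(x) ci95(x)[2]),
    stringsAsFactors = FALSE)
  ## annotate the MAP tree with posterior mean heights (class means)
  map_annot <- map_tree
  map_annot$heights <- vapply(seq_len(n_classes(map_tree)), function(k) {
    mem <- which(map_tree$class_of == k)
    mean(node_heights$mean[mem])
  }, 1)
  ndiv <- table(factor(samples$n_heights,
                       levels = seq_len(length(trees[[1]]$tips) - 1L)))
  ndist <- data.frame(n_divergences = as.integer(names(ndiv)),
                      probability = as.vector(ndiv) / length(trees))
  scal <- function(x) {
    if (all(is.na(x)))
      return(c(mean = NA_real_, lower = NA_real_, upper = NA_real_))
    c(mean = mean(x), lower = ci95(x)[1], upper = ci95(x)[2])
  }
  structure(list(
    n_samples = length(trees),
    root_height = scal(samples$root_height),
    tree_length = scal(samples$tree_length),
    neu = scal(samples$neu),
    n_heights = scal(samples$n_heights),
    n_divergences = ndist,
    frequencies = freqs,
    map_topology = map_key,
    map_probability = max(topo$frequency),
    map_tree = map_annot,
    node_heights = node_heights),
    class = "phygen_summary")
}

#' @export
print.phygen_summary <- function(x, ...) {
  cat(sprintf("phygen_summary over %d samples\n", x$n_samples))
  cat(sprintf("  root age: %.4g [%.4g, %.4g]\n", x$root_height["mean"],
              x$root_height["lower"], x$root_height["upper"]))
  cat(sprintf("  MAP topology (pp = %.3f): %s\n", x$map_probability,
              x$map_topology))
  invisible(x)
}

#' Rescale sampled trees to a calibrated root age
#'
#' Multiplies every height of every sampled tree by one global factor so
#' that the posterior mean root age equals `target_mean_root_age` (e.g. a
#' secondary calibration in millions of years). Topologies and relative
#' node ages are untouched.
#'
#' @param trees list of `gtree` samples.
#' @param target_mean_root_age positive target mean root age.
#' @return list with `trees` (rescaled) and `factor`.
#' @export
rescale_to_calibration <- function(trees, target_mean_root_age) {
  stopifnot(target_mean_root_age > 0)
  roots <- vapply(trees, function(tr) max(tr$heights), 1)
  mu <- mean(roots)
  if (mu <= 0) stop("posterior mean root height is zero")
  f <- target_mean_root_age / mu
  trees <- lapply(trees, function(tr) {
    tr$heights <- tr$heights * f
    tr
  })
  list(trees = trees, factor = f)
}
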