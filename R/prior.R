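#' Prior configuration for the generalized tree model
#'
#' Bundles the hyperparameters of the joint prior: a parametric prior on the
#' root age (gamma or exponential, parameterized by shape and mean), the
#' alpha parameter of the nested beta distributions on non-root divergence
#' times, a gamma prior (shape, mean) on the mutation-scaled diploid
#' effective population size, the stationary frequency of the green state,
#' and the overall mutation rate. With `mu = 1`, time is measured in
#' expected substitutions per site.
#'
#' @param root_shape,root_mean shape and mean of the root-age prior.
#' @param root_dist `"gamma"` or `"exponential"` (mean-parameterized; shape
#'   is ignored for the exponential).
#' @param alpha_tau alpha of the beta distribution on each non-root
#'   divergence time (the second beta parameter is fixed at 1, so
#'   `alpha_tau = 1` makes non-root times uniform on their interval).
#' @param ne_shape,ne_mean gamma prior on the shared population size
#'   parameter `neu` (diploid effective size times mutation rate).
#' @param pi stationary frequency of the green state.
#' @param mu overall mutation rate.
#' @return a `prior_config` list.
#' @export
prior_config <- function(root_shape = 10, root_mean = 0.2,
                         root_dist = c("gamma", "exponential"),
                         alpha_tau = 1,
                         ne_shape = 20, ne_mean = 0.001,
                         pi = 0.5, mu = 1) {
  root_dist <- match.arg(root_dist)
  stopifnot(root_shape > 0, root_mean > 0, alpha_tau > 0,
            ne_shape > 0, ne_mean > 0, pi >= 0, pi <= 1, mu > 0)
  structure(list(root_shape = root_shape, root_mean = root_mean,
                 root_dist = root_dist, alpha_tau = alpha_tau,
                 ne_shape = ne_shape, ne_mean = ne_mean,
                 pi = pi, mu = mu),
            class = "prior_config")
}

log_root_prior <- function(h, config) {
  if (config$root_dist == "gamma") {
    stats::dgamma(h, shape = config$root_shape,
                  rate = config$root_shape / config$root_mean, log = TRUE)
  } else {
    stats::dexp(h, rate = 1 / config$root_mean, log = TRUE)
  }
}

sample_root_prior <- function(config) {
  if (config$root_dist == "gamma") {
    stats::rgamma(1, shape = config$root_shape,
                  rate = config$root_shape / config$root_mean)
  } else {
    stats::rexp(1, rate = 1 / config$root_mean)
  }
}

#' Log prior density of a generalized tree
#'
#' The density of the tree's divergence times under the generalized tree
#' distribution: the root height follows the configured parametric prior and
#' each non-root height class is beta(`alpha_tau`, 1)-distributed between 0
#' and the height of the youngest parent of any node mapped to the class.
#' Topologies are equally probable, so the (constant) topology term is
#' omitted. Returns `-Inf` for inadmissible height configurations.
#'
#' @param tree a `gtree`.
#' @param config a [prior_config()].
#' @return log density (up to the constant topology term).
#' @export
log_tree_prior <- function(tree, config) {
  h <- tree$heights
  cls <- tree$class_of
  N <- length(tree$tips)
  par <- tree$parent
  ## single pass: youngest parent height per class
  U <- rep(Inf, length(h))
  for (i in seq_along(cls)) {
    p <- par[N + i]
    if (p != 0L) {
      u <- h[cls[p - N]]
      if (u < U[cls[i]]) U[cls[i]] <- u
    }
  }
  root_k <- cls[tree$root - N]
  lp <- log_root_prior(h[root_k], config)
  a <- config$alpha_tau
  for (k in seq_along(h)) {
    if (k == root_k) next
    if (h[k] <= 0 || h[k] >= U[k]) return(-Inf)
    lp <- lp + log(a) + (a - 1) * log(h[k] / U[k]) - log(U[k])
  }
  lp
}

#' Log prior density of the population-size parameter
#'
#' Gamma density parameterized by shape and mean, on the mutation-scaled
#' diploid effective population size shared across branches.
#'
#' @param neu positive population-size parameter.
#' @param config a [prior_config()].
#' @return log density; `-Inf` for nonpositive values.
#' @export
log_ne_prior <- function(neu, config) {
  if (neu <= 0) return(-Inf)
  stats::dgamma(neu, shape = config$ne_shape,
                rate = config$ne_shape / config$ne_mean, log = TRUE)
}

#' @rdname log_ne_prior
#' @export
sample_ne_prior <- function(config) {
  stats::rgamma(1, shape = config$ne_shape,
                rate = config$ne_shape / config$ne_mean)
}

#' Redraw all divergence times of a tree from the prior
#'
#' Keeps the topology and height-class structure, draws the root age from
#' its prior, and then draws every other class height from its nested
#' beta distribution, processing classes so that all parents are assigned
#' before their descendants.
#'
#' @param tree a `gtree` (heights are ignored).
#' @param config a [prior_config()].
#' @return a `gtree` with freshly sampled heights.
#' @export
sample_heights_from_prior <- function(tree, config) {
  N <- n_tips(tree)
  parent <- gt_parents(tree)
  K <- n_classes(tree)
  cls_par <- lapply(seq_len(K), function(k) {
    members <- class_members(tree, k)
    ps <- parent[members]
    unique(tree$class_of[ps[ps != 0L] - N])
  })
  h <- rep(NA_real_, K)
  root_k <- tree$class_of[gt_root(tree) - N]
  h[root_k] <- sample_root_prior(config)
  done <- !is.na(h)
  while (!all(done)) {
    ready <- which(!done & vapply(cls_par, function(p) all(done[p]), TRUE))
    if (!length(ready)) stop("cyclic class structure")  # cannot happen
    for (k in ready) {
      members <- class_members(tree, k)
      Uk <- min(h[tree$class_of[parent[members] - N]])
      h[k] <- Uk * stats::runif(1)^(1 / config$alpha_tau)
      done[k] <- TRUE
    }
  }
  out <- tree
  out$heights <- h
  ## classes keep their indices; renormalize ordering via rebuild
  m <- gt_maps(out)
  gt_rebuild(out$tips, m$kids, m$cls, h)
}

## uniform random labelled rooted bifurcating topology via stepwise addition;
## every internal node gets its own class; heights drawn from the prior.
random_bifurcating_tree <- function(tip_labels, config) {
  N <- length(tip_labels)
  stopifnot(N >= 2)
  ## nested-list construction: start with cherry, insert tips on any edge or
  ## above the root (2n-1 insertion points keeps the topology uniform).
  tree <- list(1L, 2L)  # nested lists; leaves are tip indices
  count_edges <- function(nd) if (!is.list(nd)) 1L else
    1L + sum(vapply(nd, count_edges, 1L))
  for (tip in seq_len(N)[-(1:2)]) {
    npts <- count_edges(tree)  # edges incl. one above the root
    slot <- sample.int(npts, 1)
    ins <- function(nd, at) {
      ## returns list(node, consumed); insert sibling at edge index `at`
      if (at == 1L) return(list(node = list(nd, tip), used = TRUE))
      at <- at - 1L
      if (!is.list(nd)) return(list(node = nd, used = FALSE, left = at))
      for (i in seq_along(nd)) {
        r <- ins(nd[[i]], at)
        if (isTRUE(r$used)) {
          nd[[i]] <- r$node
          return(list(node = nd, used = TRUE))
        }
        at <- r$left
      }
      list(node = nd, used = FALSE, left = at)
    }
    r <- ins(tree, slot)
    stopifnot(isTRUE(r$used))
    tree <- r$node
  }
  ## flatten to gtree with unit heights, then redraw heights from the prior
  children <- list(); classes <- integer(0)
  depth_h <- function(nd) {
    if (!is.list(nd)) return(list(id = nd, h = 0))
    got <- lapply(nd, depth_h)
    children[[length(children) + 1L]] <<- vapply(got, function(g) g$id, 1L)
    classes <<- c(classes, length(classes) + 1L)
    list(id = N + length(children), h = max(vapply(got, function(g) g$h, 1)) + 1)
  }
  depth_h(tree)
  ## provisional heights = subtree depth (children were created postorder)
  prov_store <- numeric(length(children))
  for (i in seq_along(children)) {
    h <- 0
    for (ch in children[[i]]) if (ch > N) h <- max(h, prov_store[ch - N])
    prov_store[i] <- h + 1
  }
  gt <- gtree(tip_labels, children, seq_along(children), prov_store)
  sample_heights_from_prior(gt, config)
}

#' Draw generalized trees from the prior
#'
#' Under the independent-bifurcating model (`"MIB"`) a uniform labelled
#' rooted bifurcating topology is assembled by stepwise addition and all
#' `N - 1` divergence times are drawn from the nested prior. Under the
#' generalized model (`"MG"`) a random bifurcating tree is first assembled
#' and a prior-only MCMC chain of topology-changing moves (reversible-jump
#' merges/splits and constrained exchanges) is run to mix over the
#' generalized topology space before all heights are redrawn from the
#' prior. Uniformity over topology classes is verified against exhaustive
#' enumeration in the test suite rather than assumed.
#'
#' @param N number of tips (labelled `sp1..spN`) or a character vector of
#'   tip labels.
#' @param config a [prior_config()].
#' @param model `"MG"` (generalized) or `"MIB"` (independent bifurcating).
#' @param mix_generations MCMC generations used to mix over topologies for
#'   `"MG"` (`N` moves are attempted per generation).
#' @return a `gtree`.
#' @export
sample_tree_from_prior <- function(N, config = prior_config(),
                                   model = c("MG", "MIB"),
                                   mix_generations = 1000) {
  model <- match.arg(model)
  tips <- if (is.character(N)) N else paste0("sp", seq_len(N))
  if (length(tips) == 1L) stop("need at least two tips")
  tree <- random_bifurcating_tree(tips, config)
  if (model == "MIB") return(tree)
  tree <- prior_mix_tree(tree, config, generations = mix_generations)
  sample_heights_from_prior(tree, config)
}

#' Rejection-sample prior trees with a minimum divergence-time gap
#'
#' Draws trees from the prior and rejects any in which two divergence times
#' are closer together than `min_gap` (nested uniform height priors place
#' many divergence times close to zero and to one another; such trees are
#' practically unidentifiable from finite data).
#'
#' @param N tips (count or labels).
#' @param config a [prior_config()].
#' @param min_gap minimum separation in expected substitutions per site.
#' @param n_accept number of trees to accept.
#' @param model `"MG"` or `"MIB"`.
#' @param mix_generations topology-mixing generations for `"MG"` draws.
#' @return list with `trees` (accepted `gtree`s) and `n_rejected`.
#' @export
sample_trees_min_gap <- function(N, config = prior_config(), min_gap = 0.001,
                                 n_accept = 100, model = c("MG", "MIB"),
                                 mix_generations = 1000) {
  model <- match.arg(model)
  trees <- vector("list", n_accept)
  got <- 0L; rejected <- 0L
  while (got < n_accept) {
    tr <- sample_tree_from_prior(N, config, model = model,
                                 mix_generations = mix_generations)
    hs <- sort(tr$heights)
    if (min_gap > 0 && length(hs) > 1 && any(diff(hs) < min_gap)) {
      rejected <- rejected + 1L
    } else {
      got <- got + 1L
      trees[[got]] <- tr
    }
  }
  list(trees = trees, n_rejected = rejected)
}
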