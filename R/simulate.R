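#' Simulate a gene tree within a generalized species tree
#'
#' Gene copies sampled from the tips coalesce pairwise at rate
#' `1 / (2 * neu)` within each species-tree branch (time in expected
#' substitutions per site). At a multifurcating node the lineages of all
#' child populations enter the ancestral population simultaneously; above
#' the root, coalescence continues until a single lineage remains.
#'
#' @param tree a `gtree` species tree.
#' @param neu mutation-scaled diploid effective population size, shared
#'   across branches.
#' @param samples_per_species gene copies sampled per species (scalar or
#'   vector over tips).
#' @return a `gene_tree`: list with `n_copies`, `species` (tip species of
#'   each copy), `parent` (parent pointers over all genealogy nodes, 0 at
#'   the root) and `time` (node times; copies are at 0).
#' @export
sample_gene_tree <- function(tree, neu, samples_per_species = 2) {
  N <- n_tips(tree)
  spp <- rep_len(samples_per_species, N)
  n_copies <- sum(spp)
  species <- rep(seq_len(N), spp)
  ## genealogy node store (grown as coalescences happen)
  parent <- integer(n_copies)
  time <- numeric(n_copies)
  nxt <- n_copies
  lam <- 1 / (2 * neu)
  coalesce_in <- function(pool, t0, t1) {
    ## pairwise coalescence among `pool` from time t0 up to t1 (may be Inf)
    t <- t0
    while (length(pool) >= 2) {
      rate <- length(pool) * (length(pool) - 1) / 2 * lam
      t <- t + stats::rexp(1, rate)
      if (t > t1) return(pool)
      pick <- sample.int(length(pool), 2)
      nxt <<- nxt + 1L
      parent[nxt] <<- 0L
      parent[pool[pick]] <<- nxt
      time[nxt] <<- t
      pool <- c(pool[-pick], nxt)
    }
    pool
  }
  h <- node_height(tree)
  rec <- function(id) {
    ## returns lineages alive at the top (start) of node id's population
    if (id <= N) return(which(species == id))
    kids <- tree$children[[id - n_tips(tree)]]
    unlist(lapply(kids, function(ch) {
      pool <- rec(ch)
      coalesce_in(pool, h[ch], h[id])
    }))
  }
  ro <- gt_root(tree)
  pool <- rec(ro)
  pool <- coalesce_in(pool, h[ro], Inf)
  structure(list(n_copies = n_copies, species = species,
                 parent = parent[seq_len(nxt)], time = time[seq_len(nxt)]),
            class = "gene_tree")
}

#' Evolve biallelic characters along a gene tree
#'
#' A two-state CTMC (rates `u * mu` red to green and `v * mu` green to red,
#' forward in time) runs along every genealogy branch; the root state is
#' drawn from the stationary law. Several characters can share one gene
#' tree (linked characters), in which case they evolve independently along
#' the same genealogy.
#'
#' @param gt a `gene_tree`.
#' @param params a [model_params()].
#' @param n_char number of characters to evolve on this genealogy.
#' @return list with `n` and `r`: species-by-character allele count
#'   matrices.
#' @export
evolve_character <- function(gt, params, n_char = 1) {
  pi_g <- params$pi
  q <- (params$u + params$v) * params$mu
  nn <- length(gt$parent)
  ## process nodes root-down: root has parent 0
  ord <- order(gt$time, decreasing = TRUE)
  state <- matrix(NA, nn, n_char)  # TRUE = red
  for (id in ord) {
    p <- gt$parent[id]
    if (p == 0L) {
      state[id, ] <- stats::runif(n_char) >= pi_g
    } else {
      dt <- gt$time[p] - gt$time[id]
      ps <- state[p, ]
      ## two-state transition: P(end = red | start) with stationary
      ## frequency 1 - pi_g of red
      decay <- exp(-q * dt)
      p_red <- (1 - pi_g) + (ifelse(ps, pi_g, -(1 - pi_g))) * decay
      state[id, ] <- stats::runif(n_char) < p_red
    }
  }
  nsp <- max(gt$species)
  n <- matrix(tabulate(gt$species, nsp), nsp, n_char)
  r <- matrix(0L, nsp, n_char)
  for (s in seq_len(nsp)) {
    sel <- which(gt$species == s)
    r[s, ] <- if (length(sel) == 1L) as.integer(state[sel, ]) else
      colSums(state[sel, , drop = FALSE])
  }
  list(n = n, r = r)
}

#' Simulate a biallelic character matrix on a species tree
#'
#' In unlinked mode every character evolves along its own gene tree; in
#' linked mode each locus of `sites` characters shares one gene tree. All
#' characters (constant included) are retained; filtering is a separate
#' step ([filter_variable()], [one_variable_per_locus()]).
#'
#' @param tree a `gtree` species tree.
#' @param params a [model_params()].
#' @param m total number of characters (ignored when `loci` is given).
#' @param samples_per_species gene copies per species (default one diploid).
#' @param loci,sites numbers of loci and of linked characters per locus;
#'   both `NULL` for unlinked characters.
#' @return a [biallelic_matrix()] (with a locus map in linked mode).
#' @export
simulate_matrix <- function(tree, params, m, samples_per_species = 2,
                            loci = NULL, sites = NULL) {
  N <- n_tips(tree)
  if (is.null(loci)) {
    loci <- m
    sites <- 1L
    locus_map <- NULL
  } else {
    stopifnot(!is.null(sites))
    m <- loci * sites
    locus_map <- rep(seq_len(loci), each = sites)
  }
  nmat <- matrix(0L, N, m)
  rmat <- matrix(0L, N, m)
  at <- 0L
  for (l in seq_len(loci)) {
    gt <- sample_gene_tree(tree, params$neu, samples_per_species)
    ev <- evolve_character(gt, params, n_char = sites)
    cols <- at + seq_len(sites)
    nmat[, cols] <- ev$n
    rmat[, cols] <- ev$r
    at <- at + sites
  }
  biallelic_matrix(tree$tips, nmat, rmat,
                   locus = if (is.null(locus_map)) NULL else locus_map)
}

#' Drop constant characters
#'
#' @param data a [biallelic_matrix()].
#' @return a `biallelic_matrix` flagged `variable_only`.
#' @export
filter_variable <- function(data) {
  tot_r <- colSums(data$r)
  tot_n <- colSums(data$n)
  keep <- tot_r > 0 & tot_r < tot_n
  biallelic_matrix(data$species, data$n[, keep, drop = FALSE],
                   data$r[, keep, drop = FALSE], variable_only = TRUE,
                   locus = data$locus[keep])
}

#' Retain at most one variable character per locus
#'
#' For each locus, one of its variable characters is kept, chosen uniformly
#' at random; loci with no variable character contribute nothing. The
#' result is flagged `variable_only` so the ascertainment correction
#' applies.
#'
#' @param data a [biallelic_matrix()] with a locus map.
#' @return a `biallelic_matrix` with at most one character per locus.
#' @export
one_variable_per_locus <- function(data) {
  if (is.null(data$locus)) stop("data has no locus map")
  tot_r <- colSums(data$r)
  tot_n <- colSums(data$n)
  variable <- which(tot_r > 0 & tot_r < tot_n)
  keep <- integer(0)
  for (l in unique(data$locus)) {
    cand <- variable[data$locus[variable] == l]
    if (length(cand))
      keep <- c(keep, if (length(cand) == 1L) cand else sample(cand, 1))
  }
  keep <- sort(keep)
  biallelic_matrix(data$species, data$n[, keep, drop = FALSE],
                   data$r[, keep, drop = FALSE], variable_only = TRUE,
                   locus = data$locus[keep])
}
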