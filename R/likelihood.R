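#' Mutation and population parameters of the likelihood model
#'
#' The character-evolution model is a two-state continuous-time Markov chain
#' with relative rates `u` (red to green) and `v` (green to red) and overall
#' rate `mu`; the stationary frequency of the green state is
#' `pi = u / (u + v)`. Gene trees arise from a multispecies coalescent in
#' which each pair of lineages coalesces at rate `1 / (2 * neu)` per unit of
#' substitution time, `neu` being the mutation-scaled diploid effective
#' population size shared across branches. With `u = v` the chain is the
#' two-state analogue of the JC69 substitution model.
#'
#' @param neu mutation-scaled diploid effective population size (> 0).
#' @param u,v relative mutation rates (red->green, green->red).
#' @param mu overall mutation rate (1 puts time in substitutions per site).
#' @return a `model_params` list with derived `pi`.
#' @export
model_params <- function(neu, u = 1, v = 1, mu = 1) {
  stopifnot(neu > 0, u > 0, v > 0, mu > 0)
  structure(list(neu = neu, u = u, v = v, mu = mu, pi = u / (u + v)),
            class = "model_params")
}

## ---------------------------------------------------------------------------
## partial-likelihood tables: vector over states (k, r), k = 0..K, 0 <= r <= k
## ---------------------------------------------------------------------------

pt_dim <- function(K) (K + 1L) * (K + 2L) / 2L

pt_index <- function(k, r) k * (k + 1L) / 2L + r + 1L

#' Leaf initialization of a partial-likelihood table
#'
#' The table over lineage configurations `(k, r)` (k ancestral lineages, r of
#' them carrying the red state) for one species at one character: a point
#' mass at the observed allele counts. A species with no sampled copies
#' (`n = 0`) yields the neutral table (mass at `k = 0`), which is the
#' identity element of [combine_partials()].
#'
#' @param n number of gene copies sampled.
#' @param r number of red copies observed (`0 <= r <= n`).
#' @return numeric partial table with attribute `K = n`.
#' @export
leaf_partials <- function(n, r) {
  if (r < 0 || r > n) stop("need 0 <= r <= n")
  F <- numeric(pt_dim(n))
  F[pt_index(n, r)] <- 1
  attr(F, "K") <- as.integer(n)
  F
}

#' Generator of the branch lineage process
#'
#' The CTMC on states `(k, r)` used to pull partial tables down a branch:
#' pairwise coalescence at rate `1/(2 neu)` (a splitting red parent yields
#' two red children and vice versa) plus per-lineage color flips at rates
#' `u*mu` (red to green, forward in time) and `v*mu`.
#'
#' @param K maximum lineage count.
#' @param neu,u,v,mu model parameters (see [model_params()]).
#' @return dense square matrix of dimension `(K+1)(K+2)/2`.
#' @keywords internal
lineage_generator <- function(K, neu, u, v, mu) {
  d <- pt_dim(K)
  A <- matrix(0, d, d)
  lam <- 1 / (2 * neu)   # pairwise coalescence rate
  for (k in 0:K) for (r in 0:k) {
    i <- pt_index(k, r)
    A[i, i] <- -(k * (k - 1) / 2 * lam + r * u * mu + (k - r) * v * mu)
    if (r > 0) A[i, pt_index(k, r - 1L)] <- r * u * mu
    if (r < k) A[i, pt_index(k, r + 1L)] <- (k - r) * v * mu
    if (k < K) {
      ## F(k, r) receives from F(k+1, .): one of the k lineages splits
      A[i, pt_index(k + 1L, r + 1L)] <- lam * (k + 1) * r / 2
      A[i, pt_index(k + 1L, r)] <- lam * (k + 1) * (k - r) / 2
    }
  }
  A
}

## dense matrix exponential (scaling and squaring + Taylor, tol ~1e-15)
mat_exp <- function(M) {
  nrm <- max(rowSums(abs(M)))
  j <- if (nrm > 0) max(0L, ceiling(log2(nrm)) + 1L) else 0L
  M <- M / 2^j
  E <- diag(nrow(M))
  term <- E
  for (i in 1:40) {
    term <- term %*% M / i
    E <- E + term
    if (max(abs(term)) < 1e-17) break
  }
  for (i in seq_len(j)) E <- E %*% E
  E
}

#' Pull a partial table down a branch
#'
#' Evolves the partial-likelihood table from the top (tipward end) of a
#' branch to its bottom (rootward end) by exponentiating the lineage-process
#' generator over the branch duration.
#'
#' @param F partial table with attribute `K`.
#' @param duration branch length in expected substitutions per site (>= 0).
#' @param params a [model_params()] (or `neu`, `u`, `v`, `mu` given directly).
#' @return partial table of the same dimension.
#' @export
branch_pullback <- function(F, duration, params) {
  if (duration < 0) stop("negative branch duration")
  if (duration == 0) return(F)
  K <- attr(F, "K")
  A <- lineage_generator(K, params$neu, params$u, params$v, params$mu)
  out <- as.numeric(mat_exp(A * duration) %*% F)
  attr(out, "K") <- K
  out
}

#' Combine partial tables of sibling subtrees
#'
#' Merges the tables at the tops of the branches descending from one node,
#' folding pairwise with hypergeometric allocation weights: the probability
#' that a uniformly chosen subset of `k1` of the `k` exchangeable lineages
#' (of which `r` are red) contains `r1` red ones. The result is independent
#' of child order and association; a multifurcation is combined by folding
#' its children in arbitrary order.
#'
#' @param Fs list of partial tables.
#' @return the combined partial table.
#' @export
combine_partials <- function(Fs) {
  if (!length(Fs)) stop("need at least one table")
  out <- Fs[[1]]
  for (i in seq_along(Fs)[-1]) out <- combine_pair(out, Fs[[i]])
  out
}

combine_pair <- function(Fx, Fy) {
  K1 <- attr(Fx, "K"); K2 <- attr(Fy, "K")
  K <- K1 + K2
  Fz <- numeric(pt_dim(K))
  for (k in 0:K) {
    for (k1 in max(0, k - K2):min(k, K1)) {
      k2 <- k - k1
      for (r in 0:k) {
        acc <- 0
        for (r1 in max(0, r - k2):min(r, k1)) {
          r2 <- r - r1
          w <- exp(lchoose(r, r1) + lchoose(k - r, k1 - r1) - lchoose(k, k1))
          acc <- acc + w * Fx[pt_index(k1, r1)] * Fy[pt_index(k2, r2)]
        }
        i <- pt_index(k, r)
        Fz[i] <- Fz[i] + acc
      }
    }
  }
  attr(Fz, "K") <- as.integer(K)
  Fz
}

#' Terminate the likelihood recursion at the root
#'
#' Continues the root population's coalescent-with-mutation process to
#' absorption at a single lineage and weights that lineage's color by the
#' stationary law (`pi` green). Implemented exactly via the conserved left
#' null functional of the lineage-process generator, so no truncation of the
#' infinite root branch is involved.
#'
#' @param F combined partial table at the root.
#' @param params a [model_params()]; `params$neu` is the root population size.
#' @return the character probability contributed by this table.
#' @export
root_probability <- function(F, params) {
  K <- attr(F, "K")
  phi <- root_functional(K, params$neu, params$u, params$v, params$mu,
                         params$pi)
  sum(phi * F)
}

## left null vector of the generator, normalized so phi(1, .) matches the
## stationary color law; solved block-recursively upward in k.
root_functional <- function(K, neu, u, v, mu, pi) {
  lam <- 1 / (2 * neu)
  phi <- numeric(pt_dim(K))
  phi[pt_index(0L, 0L)] <- 1
  if (K >= 1) {
    phi[pt_index(1L, 0L)] <- pi       # r = 0: green lineage
    phi[pt_index(1L, 1L)] <- 1 - pi   # r = 1: red lineage
  }
  if (K < 2) return(phi)
  for (k in 2:K) {
    ## D_k: within-block columns (mutation + diagonal), C: from block k-1
    d <- k + 1L
    D <- matrix(0, d, d)  # rows/cols indexed by r = 0..k
    for (r in 0:k) {
      D[r + 1L, r + 1L] <- -(k * (k - 1) / 2 * lam + r * u * mu +
                               (k - r) * v * mu)
      if (r > 0) D[r + 1L, r] <- r * u * mu        # col (k, r-1)
      if (r < k) D[r + 1L, r + 2L] <- (k - r) * v * mu
    }
    ## b[r+1] = sum_{r'} phi(k-1, r') * A[(k-1, r'), (k, r)]
    b <- numeric(d)
    for (rp in 0:(k - 1)) {
      ## A[(k-1, rp), (k, rp+1)] = lam * k * rp / 2
      ## A[(k-1, rp), (k, rp)]   = lam * k * (k - 1 - rp) / 2
      b[rp + 2L] <- b[rp + 2L] + phi[pt_index(k - 1L, rp)] * lam * k * rp / 2
      b[rp + 1L] <- b[rp + 1L] +
        phi[pt_index(k - 1L, rp)] * lam * k * (k - 1 - rp) / 2
    }
    phi_k <- solve(t(D), -b)   # phi_k D + b = 0  (phi_k as row vector)
    phi[pt_index(k, 0:k)] <- phi_k
  }
  phi
}

## ---------------------------------------------------------------------------
## whole-tree probabilities (reference implementation)
## ---------------------------------------------------------------------------

#' Probability of one biallelic character on a generalized tree
#'
#' Post-order composition of [leaf_partials()], [branch_pullback()],
#' [combine_partials()] and [root_probability()]. This is the reference
#' (plain R) path; [data_log_likelihood()] uses the compiled engine.
#'
#' @param tree a `gtree`.
#' @param params a [model_params()].
#' @param n,r integer vectors over `tree$tips`: copies sampled and red
#'   copies observed for this character.
#' @return the character probability `p(n, r | tree, params)`.
#' @export
character_probability <- function(tree, params, n, r) {
  stopifnot(length(n) == n_tips(tree), length(r) == length(n), all(r <= n))
  N <- n_tips(tree)
  h <- node_height(tree)
  rec <- function(id) {
    if (id <= N) return(leaf_partials(n[id], r[id]))
    kids <- tree$children[[id - N]]
    tabs <- lapply(kids, function(ch)
      branch_pullback(rec(ch), h[id] - h[ch], params))
    combine_partials(tabs)
  }
  root_probability(rec(gt_root(tree)), params)
}

#' Probability that a character is constant
#'
#' For given per-species sample sizes, the probability of observing the
#' all-green or all-red pattern; used to correct the likelihood when only
#' variable characters are retained.
#'
#' @param tree a `gtree`.
#' @param params a [model_params()].
#' @param n integer sample sizes per species.
#' @return `p(all green) + p(all red)`.
#' @export
constant_probability <- function(tree, params, n) {
  character_probability(tree, params, n, rep(0L, length(n))) +
    character_probability(tree, params, n, n)
}

#' Biallelic character matrices
#'
#' Per-species allele counts for `m` biallelic characters: `n[i, j]` copies
#' sampled from species `i` at character `j`, `r[i, j]` of which carry the
#' red state. `n` may vary by character to encode missing data. When
#' `variable_only` is set the matrix is declared to contain no constant
#' characters and likelihood computations apply the ascertainment
#' correction.
#'
#' @param species character vector of species labels.
#' @param n,r integer matrices (species x characters).
#' @param variable_only logical flag.
#' @param locus optional integer vector assigning characters to loci.
#' @return a `biallelic_matrix`.
#' @export
biallelic_matrix <- function(species, n, r, variable_only = FALSE,
                             locus = NULL) {
  n <- as.matrix(n); r <- as.matrix(r)
  storage.mode(n) <- "integer"
  storage.mode(r) <- "integer"
  stopifnot(nrow(n) == length(species), all(dim(n) == dim(r)),
            all(r >= 0), all(r <= n))
  if (ncol(n) > 0 && any(colSums(n) == 0))
    stop("each character needs at least one sampled copy")
  if (variable_only && ncol(n) > 0) {
    const <- colSums(r) == 0 | colSums(r) == colSums(n)
    if (any(const)) stop("variable_only matrix contains constant characters")
  }
  structure(list(species = species, n = n, r = r,
                 variable_only = variable_only, locus = locus),
            class = "biallelic_matrix")
}

#' @export
print.biallelic_matrix <- function(x, ...) {
  cat(sprintf("biallelic_matrix: %d species x %d characters%s\n",
              length(x$species), ncol(x$n),
              if (x$variable_only) " (variable only)" else ""))
  invisible(x)
}

## collapse identical (n, r) columns into weighted patterns
collapse_patterns <- function(data) {
  key <- apply(rbind(data$n, data$r), 2, paste, collapse = ",")
  ux <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[ux])))
  list(n = data$n[, ux, drop = FALSE], r = data$r[, ux, drop = FALSE],
       weights = w)
}

#' Log likelihood of a biallelic character matrix
#'
#' Product over characters of the per-character probability (identical
#' patterns collapsed and weighted). For a `variable_only` matrix each
#' character's probability is divided by one minus the probability of a
#' constant character with that character's sample sizes.
#'
#' @param tree a `gtree`.
#' @param params a [model_params()].
#' @param data a [biallelic_matrix()].
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference path).
#' @return the log likelihood.
#' @export
data_log_likelihood <- function(tree, params, data, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (ncol(data$n) == 0L) return(0)
  stopifnot(identical(data$species, tree$tips))
  pat <- collapse_patterns(data)
  if (engine == "cpp") {
    p <- pattern_probabilities(tree, params, pat$n, pat$r)
  } else {
    p <- vapply(seq_len(ncol(pat$n)), function(j)
      character_probability(tree, params, pat$n[, j], pat$r[, j]), 1)
  }
  ll <- sum(pat$weights * log(p))
  if (data$variable_only) {
    nkey <- apply(pat$n, 2, paste, collapse = ",")
    for (uk in unique(nkey)) {
      sel <- nkey == uk
      nn <- pat$n[, which(sel)[1]]
      pc <- if (engine == "cpp") {
        sum(pattern_probabilities(tree, params,
                                  cbind(nn, nn), cbind(0L * nn, nn)))
      } else {
        constant_probability(tree, params, nn)
      }
      ll <- ll - sum(pat$weights[sel]) * log1p(-pc)
    }
  }
  ll
}

#' Per-pattern probabilities via the compiled engine
#'
#' @param tree a `gtree`.
#' @param params a [model_params()].
#' @param n,r integer matrices (species x patterns).
#' @return numeric vector of pattern probabilities.
#' @export
pattern_probabilities <- function(tree, params, n, r) {
  spec <- tree_flatten(tree)
  as.numeric(lik_patterns_cpp(spec$n_tips, spec$order, spec$children,
                              spec$durations, as.matrix(n), as.matrix(r),
                              params$neu, params$u, params$v, params$mu,
                              params$pi))
}

## flatten a gtree for the C++ engine: post-order list of internal nodes,
## each with child ids and child branch durations.
tree_flatten <- function(tree) {
  N <- n_tips(tree)
  h <- node_height(tree)
  ord <- integer(0)
  rec <- function(id) {
    if (id <= N) return(invisible())
    for (ch in tree$children[[id - N]]) rec(ch)
    ord <<- c(ord, id)
  }
  rec(gt_root(tree))
  children <- lapply(ord, function(id) tree$children[[id - N]])
  durations <- lapply(ord, function(id)
    h[id] - h[tree$children[[id - N]]])
  list(n_tips = N, order = ord, children = children, durations = durations)
}
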