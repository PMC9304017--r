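#' Move schedule for the generalized-tree sampler
#'
#' Relative weights of the Metropolis-Hastings and reversible-jump moves
#' attempted during MCMC. Setting `rj_enabled = FALSE` (or using
#' `model = "MIB"` in [run_chain()]) turns off the dimension-changing
#' merge/split moves, constraining the chain to trees with independent,
#' bifurcating divergences.
#'
#' @param height_slide,height_multiplier,root_scale,tree_scale,ne_multiplier,topology,rj
#'   nonnegative move weights; `rj` is shared equally between the merge and
#'   split proposals.
#' @param rj_enabled logical; allow dimension-changing moves.
#' @return a `move_schedule`.
#' @export
move_schedule <- function(height_slide = 3, height_multiplier = 2,
                          root_scale = 2, tree_scale = 1, ne_multiplier = 2,
                          topology = 3, rj = 3, rj_enabled = TRUE) {
  w <- c(height_slide = height_slide, height_multiplier = height_multiplier,
         root_scale = root_scale, tree_scale = tree_scale,
         ne_multiplier = ne_multiplier, topology = topology, rj = rj)
  stopifnot(all(w >= 0), any(w > 0))
  if (!rj_enabled) w["rj"] <- 0
  structure(list(weights = w, rj_enabled = rj_enabled),
            class = "move_schedule")
}

## fixed proposal tuning constants (window widths / multiplier scales)
move_tuning <- function() {
  list(slide_window = 0.02, mult_scale = 0.7, root_scale = 0.4,
       tree_scale = 0.3, ne_scale = 1.0)
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

## ---------------------------------------------------------------------------
## split-allocation machinery
## ---------------------------------------------------------------------------

## all collections of disjoint blocks (size >= 2) from `items`, including the
## empty collection; blocks are identified by their minimal element so each
## collection is generated exactly once.
partial_partitions <- function(items) {
  if (!length(items)) return(list(list()))
  first <- items[1]
  rest <- items[-1]
  out <- partial_partitions(rest)
  if (length(rest)) {
    nr <- length(rest)
    for (mask in seq_len(2^nr - 1)) {
      T <- rest[bitwAnd(mask, 2^(seq_len(nr) - 1)) > 0]
      blk <- c(first, T)
      for (pp in partial_partitions(setdiff(rest, T)))
        out <- c(out, list(c(list(blk), pp)))
    }
  }
  out
}

## canonical stay options memoized by child count (the validity constraint
## depends only on block sizes)
.stay_cache <- new.env(parent = emptyenv())

stay_options_canonical <- function(nc) {
  if (nc > 10L) stop("polytomy too large for split enumeration")
  key <- as.character(nc)
  hit <- .stay_cache[[key]]
  if (!is.null(hit)) return(hit)
  pp <- Filter(function(p) nc - sum(lengths(p)) + length(p) >= 2L,
               partial_partitions(seq_len(nc)))
  assign(key, pp, envir = .stay_cache)
  pp
}

## stay-type options of one node: partial partitions of its children that
## leave the node with >= 2 children (counting one new child per block)
stay_options <- function(kids) {
  lapply(stay_options_canonical(length(kids)),
         function(pp) lapply(pp, function(b) kids[b]))
}

## memoized stay-option counts by child count
stay_count <- local({
  cache <- c(1, 1)  # nc = 1, 2
  function(nc) {
    if (nc <= length(cache)) return(cache[nc])
    v <- length(stay_options_canonical(nc))
    if (nc == length(cache) + 1L) cache[nc] <<- v
    v
  }
})

## valid split-allocation counts for every class (0 = not splittable)
alloc_counts <- function(tree) {
  N <- n_tips(tree)
  ro <- gt_root(tree)
  nk <- lengths(tree$children)
  opts <- vapply(nk, stay_count, 1) +
    as.numeric(N + seq_along(nk) != ro)
  tot <- exp(rowsum(log(opts), tree$class_of, reorder = TRUE))[, 1]
  rootk <- tree$class_of[ro - N]
  tot - 1 - as.numeric(seq_along(tot) != rootk)
}

## number of valid allocations for splitting class k (0 = not splittable)
alloc_count <- function(tree, k) alloc_counts(tree)[k]

## classes of `tree` that admit at least one split allocation
splittable_classes <- function(tree) which(alloc_counts(tree) > 0.5)

## uniform draw over valid allocations; returns the allocation plus its
## structural young-side lower bound. Canonical stay collections are
## indexed, so only the chosen option is materialized.
sample_allocation <- function(tree, k) {
  members <- class_members(tree, k)
  ro <- gt_root(tree)
  N <- n_tips(tree)
  h <- node_height(tree)
  kidsl <- lapply(members, function(id) tree$children[[id - N]])
  movable <- members != ro
  canon <- lapply(kidsl, function(kk) stay_options_canonical(length(kk)))
  nopts <- vapply(canon, length, 1L) + movable
  repeat {
    pick <- vapply(nopts, function(m) sample.int(m, 1L), 1L)
    cidx <- ifelse(movable, pick - 1L, pick)   # 0 encodes "move"
    is_move <- cidx == 0L
    n_blocks <- sum(vapply(which(!is_move), function(i)
      length(canon[[i]][[cidx[i]]]), 1L))
    if ((any(is_move) || n_blocks > 0) && !all(is_move)) break
  }
  move <- members[is_move]
  resolve <- list()
  L <- 0
  for (i in seq_along(members)) {
    if (is_move[i]) {
      L <- max(L, h[kidsl[[i]]])
    } else if (length(canon[[i]][[cidx[i]]])) {
      blocks <- lapply(canon[[i]][[cidx[i]]], function(b) kidsl[[i]][b])
      resolve[[as.character(members[i])]] <- blocks
      L <- max(L, h[unlist(blocks)])
    }
  }
  list(allocation = list(move = move, resolve = resolve), L_struct = L)
}

## ---------------------------------------------------------------------------
## proposals: each returns list(tree, neu, lh) or NULL for auto-reject
## ---------------------------------------------------------------------------

propose_height_slide <- function(state, tune) {
  tree <- state$tree
  U <- class_upper_bounds(tree)
  nonroot <- which(is.finite(U))
  if (!length(nonroot)) return(NULL)
  k <- sample1(nonroot)
  b <- height_bounds(tree, k)
  if (stats::runif(1) < 0.5) {
    hp <- stats::runif(1, b$lower, b$upper)   # bounds-uniform redraw
  } else {
    hp <- tree$heights[k] + stats::runif(1, -tune$slide_window,
                                         tune$slide_window)
    if (hp <= b$lower || hp >= b$upper) return(NULL)
  }
  tree$heights[k] <- hp
  list(tree = tree, neu = state$neu, lh = 0)
}

propose_height_multiplier <- function(state, tune) {
  tree <- state$tree
  U <- class_upper_bounds(tree)
  nonroot <- which(is.finite(U))
  if (!length(nonroot)) return(NULL)
  k <- sample1(nonroot)
  b <- height_bounds(tree, k)
  f <- exp(tune$mult_scale * (stats::runif(1) - 0.5))
  hp <- tree$heights[k] * f
  if (hp <= b$lower || hp >= b$upper) return(NULL)
  tree$heights[k] <- hp
  list(tree = tree, neu = state$neu, lh = log(f))
}

propose_root_scale <- function(state, tune) {
  tree <- state$tree
  rk <- tree$class_of[gt_root(tree) - n_tips(tree)]
  lo <- class_lower_bound(tree, rk)
  f <- exp(tune$root_scale * (stats::runif(1) - 0.5))
  hp <- tree$heights[rk] * f
  if (hp <= lo) return(NULL)
  tree$heights[rk] <- hp
  list(tree = tree, neu = state$neu, lh = log(f))
}

propose_tree_scale <- function(state, tune) {
  tree <- state$tree
  f <- exp(tune$tree_scale * (stats::runif(1) - 0.5))
  tree$heights <- tree$heights * f
  list(tree = tree, neu = state$neu, lh = n_classes(tree) * log(f))
}

propose_ne_multiplier <- function(state, tune) {
  f <- exp(tune$ne_scale * (stats::runif(1) - 0.5))
  list(tree = state$tree, neu = state$neu * f, lh = log(f))
}

## valid (child-of-c, child-of-parent) exchange triples
## per-node eligible exchange partners: for internal node c with parent p,
## the siblings y of c with height(y) < height(c) that do not share c's
## class; an exchange swaps a child x of c with such a y.
exchange_partners <- function(tree, ci, h, cls) {
  N <- n_tips(tree)
  p <- tree$parent[N + ci]
  if (p == 0L) return(integer(0))
  sibs <- tree$children[[p - N]]
  ys <- sibs[sibs != N + ci & h[sibs] < h[N + ci]]
  ys[ys <= N | cls[pmax(ys - N, 1L)] != cls[ci]]
}

count_triples <- function(tree) {
  h <- node_height(tree)
  cls <- tree$class_of
  total <- 0L
  for (ci in seq_along(tree$children)) {
    nys <- length(exchange_partners(tree, ci, h, cls))
    if (nys) total <- total + nys * length(tree$children[[ci]])
  }
  total
}

propose_topology <- function(state, tune) {
  tree <- state$tree
  N <- n_tips(tree)
  h <- node_height(tree)
  cls <- tree$class_of
  ys_of <- lapply(seq_along(tree$children), function(ci)
    exchange_partners(tree, ci, h, cls))
  cnt <- lengths(ys_of) * lengths(tree$children)
  total <- sum(cnt)
  if (total == 0L) return(NULL)
  u <- sample.int(total, 1L)
  ci <- which(u <= cumsum(cnt))[1]
  u <- u - c(0, cumsum(cnt))[ci]
  nys <- length(ys_of[[ci]])
  x <- tree$children[[ci]][(u - 1L) %/% nys + 1L]
  y <- ys_of[[ci]][(u - 1L) %% nys + 1L]
  c_id <- N + ci
  p <- tree$parent[c_id]
  ## in-place child exchange: swap x (child of c) with y (child of p)
  tree2 <- tree
  tree2$children[[ci]] <- c(setdiff(tree$children[[ci]], x), y)
  tree2$children[[p - N]] <- c(setdiff(tree$children[[p - N]], y), x)
  tree2$parent[x] <- p
  tree2$parent[y] <- c_id
  list(tree = tree2, neu = state$neu,
       lh = log(total) - log(count_triples(tree2)))
}

## reversible-jump height proposal on (L, U): an equal mixture of a uniform
## draw and a draw concentrated just below U (truncated exponential with
## scale (U - L)/20). Splitting nearly simultaneous divergences needs new
## heights close to the old one; the concentrated component makes such
## splits reachable, and the density enters the Hastings ratio exactly.
rj_height_sample <- function(L, U) {
  s <- (U - L) / 20
  if (stats::runif(1) < 0.5) {
    stats::runif(1, L, U)
  } else {
    p <- stats::pexp(U - L, rate = 1 / s)
    U - stats::qexp(stats::runif(1) * p, rate = 1 / s)
  }
}

rj_height_logq <- function(h, L, U) {
  s <- (U - L) / 20
  p <- stats::pexp(U - L, rate = 1 / s)
  log(0.5 / (U - L) +
        0.5 * stats::dexp(U - h, rate = 1 / s) / p)
}

propose_rj_split <- function(state, tune) {
  tree <- state$tree
  ac <- alloc_counts(tree)
  spl <- which(ac > 0.5)
  if (!length(spl)) return(NULL)
  k <- sample1(spl)
  na <- ac[k]
  al <- sample_allocation(tree, k)
  hk <- tree$heights[k]
  below <- tree$heights[tree$heights < hk]
  L <- max(al$L_struct, if (length(below)) max(below) else 0)
  hnew <- rj_height_sample(L, hk)
  tree2 <- split_height_class(tree, k, al$allocation, hnew, validate = FALSE)
  n_pairs2 <- n_classes(tree2) - 1L
  list(tree = tree2, neu = state$neu,
       lh = log(length(spl)) + log(na) - rj_height_logq(hnew, L, hk) -
         log(n_pairs2))
}

propose_rj_merge <- function(state, tune) {
  tree <- state$tree
  prs <- neighbor_pairs(tree)
  if (!nrow(prs)) return(NULL)
  i <- sample.int(nrow(prs), 1L)
  k1 <- prs[i, 1]; k2 <- prs[i, 2]
  h1 <- tree$heights[k1]; h2 <- tree$heights[k2]
  tree2 <- merge_height_classes(tree, k1, k2, validate = FALSE)
  ## reverse-split quantities in the merged state
  ac2 <- alloc_counts(tree2)
  spl2 <- which(ac2 > 0.5)
  km <- which(tree2$heights == h2)
  na2 <- ac2[km]
  below <- tree$heights[tree$heights < h1]
  L_rev <- max(class_lower_bound(tree, k1),
               if (length(below)) max(below) else 0)
  list(tree = tree2, neu = state$neu,
       lh = log(nrow(prs)) - log(length(spl2)) - log(na2) +
         rj_height_logq(h1, L_rev, h2))
}

## ---------------------------------------------------------------------------
## likelihood closure
## ---------------------------------------------------------------------------

## builds a fast log-likelihood function of (tree, neu) backed by the
## compiled engine; NULL data gives the prior-only likelihood (constant 0)
make_loglik <- function(data, params_template) {
  if (is.null(data)) return(function(tree, neu) 0)
  pat <- collapse_patterns(data)
  if (params_template$u == params_template$v) {
    ## color symmetry: a pattern and its complement are equiprobable, so
    ## fold complements together (halves the table width)
    key <- apply(rbind(pat$n, pat$r), 2, paste, collapse = ",")
    ckey <- apply(rbind(pat$n, pat$n - pat$r), 2, paste, collapse = ",")
    canon <- pmin(key, ckey)
    ux <- !duplicated(canon)
    w2 <- as.vector(rowsum(pat$weights, canon, reorder = FALSE))
    r2 <- pat$r[, ux, drop = FALSE]
    flip <- key[ux] != canon[ux]
    r2[, flip] <- pat$n[, ux, drop = FALSE][, flip] - r2[, flip]
    pat <- list(n = pat$n[, ux, drop = FALSE], r = r2, weights = w2)
  }
  n <- pat$n; r <- pat$r; w <- pat$weights
  extra <- 0L
  profs <- NULL
  if (data$variable_only) {
    nkey <- apply(n, 2, paste, collapse = ",")
    profs <- lapply(unique(nkey), function(uk) {
      list(cols = which(nkey == uk), n = n[, which(nkey == uk)[1]])
    })
    for (pr in profs) {
      n <- cbind(n, pr$n, pr$n)
      r <- cbind(r, 0L * pr$n, pr$n)
    }
    extra <- 2L * length(profs)
  }
  P <- ncol(pat$n)
  u <- params_template$u; v <- params_template$v
  mu <- params_template$mu; pi <- params_template$pi
  eng <- engine_create(nrow(n), n, r, u, v, mu, pi)
  force(w); force(profs); force(P)
  function(tree, neu) {
    spec <- tree_flatten(tree)
    p <- engine_eval(eng, spec$order, spec$children, spec$durations, neu)
    ll <- sum(w * log(p[seq_len(P)]))
    if (!is.null(profs)) {
      for (i in seq_along(profs)) {
        pc <- p[P + 2L * i - 1L] + p[P + 2L * i]
        ll <- ll - sum(w[profs[[i]]$cols]) * log1p(-pc)
      }
    }
    ll
  }
}

## ---------------------------------------------------------------------------
## chain driver
## ---------------------------------------------------------------------------

movers <- list(height_slide = propose_height_slide,
               height_multiplier = propose_height_multiplier,
               root_scale = propose_root_scale,
               tree_scale = propose_tree_scale,
               ne_multiplier = propose_ne_multiplier,
               topology = propose_topology)

#' Apply one MCMC move to a chain state
#'
#' Draws a proposal of the requested kind, evaluates the prior, likelihood
#' and Hastings terms, and accepts or rejects by the Metropolis-Hastings
#' rule. Used internally by [run_chain()] and directly by tests auditing
#' reversibility.
#'
#' @param state list with `tree`, `neu`, `ll`, `lp`.
#' @param kind one of `"height_slide"`, `"height_multiplier"`,
#'   `"root_scale"`, `"tree_scale"`, `"ne_multiplier"`, `"topology"`,
#'   `"rj_merge"`, `"rj_split"`.
#' @param loglik function of `(tree, neu)` returning the log likelihood.
#' @param config a [prior_config()].
#' @param tune internal tuning constants.
#' @return the new state (identical to `state` if rejected), with an
#'   `accepted` flag.
#' @export
apply_move <- function(state, kind, loglik, config, tune = move_tuning()) {
  if (!kind %in% c(names(movers), "rj_merge", "rj_split"))
    stop("unknown move kind: ", kind)
  prop <- switch(kind,
                 rj_merge = propose_rj_merge(state, tune),
                 rj_split = propose_rj_split(state, tune),
                 movers[[kind]](state, tune))
  state$accepted <- FALSE
  if (is.null(prop)) return(state)
  lp2 <- log_tree_prior(prop$tree, config) + log_ne_prior(prop$neu, config)
  if (!is.finite(lp2)) return(state)
  ll2 <- loglik(prop$tree, prop$neu)
  if (log(stats::runif(1)) < ll2 + lp2 + prop$lh - state$ll - state$lp) {
    state <- list(tree = prop$tree, neu = prop$neu, ll = ll2, lp = lp2,
                  accepted = TRUE)
  }
  state
}

## star ("comb") tree: one internal node holding all tips
comb_tree <- function(tips, config) {
  gt <- gtree(tips, list(seq_along(tips)), 1L, sample_root_prior(config))
  gt
}

#' Run one MCMC chain over generalized trees
#'
#' Samples the joint posterior of the generalized tree (topology, shared
#' divergence classes, heights) and the shared population-size parameter
#' given a biallelic character matrix; with `data = NULL` the likelihood is
#' constant and the chain samples the prior (used for validating the
#' samplers). Each generation attempts `moves_per_generation` moves (the
#' number of tips, by default) drawn in proportion to the schedule weights.
#'
#' @param data a [biallelic_matrix()] or `NULL` for prior-only sampling.
#' @param config a [prior_config()].
#' @param n_tips_prior tip count (prior-only runs without data).
#' @param generations number of MCMC generations.
#' @param sample_freq record one sample every this many generations.
#' @param seed integer seed; runs are reproducible given the seed.
#' @param chain_id integer identifier recorded in the trace.
#' @param start `"random_bifurcating"`, `"comb"`, or a `gtree`.
#' @param schedule a [move_schedule()].
#' @param model `"MG"` (generalized) or `"MIB"` (independent bifurcating;
#'   reversible-jump moves disabled).
#' @param moves_per_generation moves attempted per generation.
#' @return a `phygen_trace`: list with `samples` (data frame of generation,
#'   lnL, lnPrior, root_height, tree_length, neu, n_heights, topology),
#'   `trees` (sampled `gtree`s), acceptance counts, seed and chain id.
#' @export
run_chain <- function(data = NULL, config = prior_config(),
                      n_tips_prior = NULL, generations = 1500,
                      sample_freq = 10, seed = 1, chain_id = 1L,
                      start = "random_bifurcating",
                      schedule = move_schedule(), model = c("MG", "MIB"),
                      moves_per_generation = NULL) {
  model <- match.arg(model)
  set.seed(seed)
  tips <- if (!is.null(data)) data$species else paste0("sp", seq_len(n_tips_prior))
  if (is.null(moves_per_generation)) moves_per_generation <- length(tips)
  if (model == "MIB") schedule <- move_schedule(rj_enabled = FALSE)
  tree <- if (inherits(start, "gtree")) start
          else if (identical(start, "comb")) comb_tree(tips, config)
          else random_bifurcating_tree(tips, config)
  if (model == "MIB" && n_classes(tree) != length(tips) - 1L)
    stop("MIB chains must start from a bifurcating tree")
  params <- model_params(neu = config$ne_mean)
  loglik <- make_loglik(data, params)
  tune <- move_tuning()
  neu <- sample_ne_prior(config)
  state <- list(tree = tree, neu = neu,
                ll = NA_real_, lp = log_tree_prior(tree, config) +
                  log_ne_prior(neu, config))
  state$ll <- loglik(tree, neu)
  w <- schedule$weights
  kinds <- names(w)
  prob <- w / sum(w)
  n_acc <- stats::setNames(numeric(length(kinds) + 1), c(kinds, "rj_split"))
  n_try <- n_acc
  n_samp <- floor(generations / sample_freq)
  samples <- data.frame(generation = integer(n_samp), lnL = numeric(n_samp),
                        lnPrior = numeric(n_samp),
                        root_height = numeric(n_samp),
                        tree_length = numeric(n_samp), neu = numeric(n_samp),
                        n_heights = integer(n_samp),
                        topology = character(n_samp))
  trees <- vector("list", n_samp)
  at <- 0L
  for (g in seq_len(generations)) {
    gen_kinds <- sample(kinds, moves_per_generation, TRUE, prob = prob)
    for (kind in gen_kinds) {
      if (kind == "rj")
        kind <- if (stats::runif(1) < 0.5) "rj_merge" else "rj_split"
      key <- if (kind == "rj_merge") "rj" else
        if (kind == "rj_split") "rj_split" else kind
      n_try[key] <- n_try[key] + 1
      state <- apply_move(state, kind, loglik, config, tune)
      if (state$accepted) {
        n_acc[key] <- n_acc[key] + 1
        ## dimension-changing moves chain an immediate height refinement,
        ## which improves mixing across merge/split modes
        if (kind %in% c("rj_merge", "rj_split"))
          state <- apply_move(state, "height_slide", loglik, config, tune)
      }
    }
    if (g %% sample_freq == 0L) {
      at <- at + 1L
      validate_gtree(state$tree)   # audit: every sampled state is valid
      h <- node_height(state$tree)
      parent <- gt_parents(state$tree)
      tl <- sum(h[parent[parent != 0L]] - h[which(parent != 0L)])
      rk <- state$tree$class_of[gt_root(state$tree) - n_tips(state$tree)]
      samples$generation[at] <- g
      samples$lnL[at] <- state$ll
      samples$lnPrior[at] <- state$lp
      samples$root_height[at] <- state$tree$heights[rk]
      samples$tree_length[at] <- tl
      samples$neu[at] <- state$neu
      samples$n_heights[at] <- n_classes(state$tree)
      samples$topology[at] <- topology_key(state$tree)
      trees[[at]] <- state$tree
    }
  }
  structure(list(samples = samples, trees = trees,
                 acceptance = list(tried = n_try, accepted = n_acc),
                 seed = seed, chain_id = chain_id, model = model,
                 final = state),
            class = "phygen_trace")
}

#' @export
print.phygen_trace <- function(x, ...) {
  cat(sprintf("phygen_trace: chain %d, %d samples (seed %d, %s)\n",
              x$chain_id, nrow(x$samples), x$seed, x$model))
  invisible(x)
}

#' Sample the prior with MCMC
#'
#' Runs [run_chain()] with the likelihood fixed at zero (log scale). The
#' long-run distribution over topology classes, divergence counts and
#' heights must match direct prior simulation; the test suite performs
#' those comparisons, which validate every Hastings ratio.
#'
#' @inheritParams run_chain
#' @param N number of tips.
#' @return a `phygen_trace`.
#' @export
run_prior_only <- function(config = prior_config(), N = 3,
                           generations = 3000, sample_freq = 5, seed = 1,
                           schedule = move_schedule(),
                           model = c("MG", "MIB"),
                           start = "random_bifurcating") {
  run_chain(data = NULL, config = config, n_tips_prior = N,
            generations = generations, sample_freq = sample_freq,
            seed = seed, schedule = schedule, model = match.arg(model),
            start = start)
}

## topology mixing used by the prior sampler: prior-only moves without
## recording; returns the final tree
prior_mix_tree <- function(tree, config, generations = 1000) {
  sched <- move_schedule(ne_multiplier = 0)
  tune <- move_tuning()
  loglik <- function(tree, neu) 0
  state <- list(tree = tree, neu = config$ne_mean,
                ll = 0, lp = log_tree_prior(tree, config) +
                  log_ne_prior(config$ne_mean, config))
  w <- sched$weights
  kinds <- names(w)
  prob <- w / sum(w)
  n_mv <- n_tips(tree)
  for (g in seq_len(generations)) {
    gen_kinds <- sample(kinds, n_mv, TRUE, prob = prob)
    for (kind in gen_kinds) {
      if (kind == "rj")
        kind <- if (stats::runif(1) < 0.5) "rj_merge" else "rj_split"
      state <- apply_move(state, kind, loglik, config, tune)
    }
  }
  state$tree
}
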