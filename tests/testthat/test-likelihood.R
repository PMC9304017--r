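test_that("leaf partials are point masses and missing data is neutral", {
  F <- leaf_partials(2, 1)
  expect_equal(sum(F), 1)
  expect_equal(F[phygen:::pt_index(2L, 1L)], 1)
  expect_error(leaf_partials(2, 3), "r <= n")
  ## neutral element: combining with an empty leaf changes nothing
  Fx <- leaf_partials(2, 0)
  expect_equal(as.numeric(combine_partials(list(Fx, leaf_partials(0, 0)))[
    seq_along(Fx)]), as.numeric(Fx))
})

test_that("branch pull-back matches two-state and coalescent closed forms", {
  par <- model_params(neu = 0.001)
  ## duration 0 is the identity
  F <- leaf_partials(2, 1)
  expect_equal(branch_pullback(F, 0, par), F)
  expect_error(branch_pullback(F, -0.1, par), "negative")
  ## single lineage: symmetric flip probability (1 - exp(-2t))/2
  for (t in c(0.01, 0.1, 0.6)) {
    G <- branch_pullback(leaf_partials(1, 1), t, par)
    expect_equal(G[phygen:::pt_index(1L, 0L)], (1 - exp(-2 * t)) / 2,
                 tolerance = 1e-10)
    expect_equal(G[phygen:::pt_index(1L, 1L)], (1 + exp(-2 * t)) / 2,
                 tolerance = 1e-10)
  }
  ## two lineages, negligible mutation: survival of the pair is
  ## exp(-t / (2 neu)) and the coalesced mass is its complement
  par2 <- model_params(neu = 0.002, mu = 1e-9)
  for (t in c(0.001, 0.004)) {
    G <- branch_pullback(leaf_partials(2, 0), t, par2)
    expect_equal(G[phygen:::pt_index(2L, 0L)], exp(-t / 0.004),
                 tolerance = 1e-6)
    expect_equal(G[phygen:::pt_index(1L, 0L)], 1 - exp(-t / 0.004),
                 tolerance = 1e-6)
  }
})

test_that("combine uses hypergeometric weights and is order-invariant", {
  ## two single copies of opposite color: all mass sits at r = 1 of k = 2
  ## (forced by counts), with the uniform-color-assignment weight 1/2
  F <- combine_partials(list(leaf_partials(1, 1), leaf_partials(1, 0)))
  expect_equal(F[phygen:::pt_index(2L, 1L)], 0.5)
  expect_equal(F[phygen:::pt_index(2L, 0L)], 0)
  expect_equal(F[phygen:::pt_index(2L, 2L)], 0)
  ## order and association invariance at float tolerance
  par <- model_params(neu = 0.003)
  tabs <- lapply(list(c(2, 1), c(2, 0), c(2, 2)), function(nr)
    branch_pullback(leaf_partials(nr[1], nr[2]), 0.01, par))
  a <- combine_partials(tabs)
  b <- combine_partials(tabs[c(3, 1, 2)])
  c2 <- combine_partials(list(combine_partials(tabs[1:2]), tabs[[3]]))
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
  expect_equal(as.numeric(a), as.numeric(c2), tolerance = 1e-12)
})

test_that("root termination reproduces stationary and heterozygosity forms", {
  par <- model_params(neu = 0.001)
  expect_equal(root_probability(leaf_partials(1, 1), par), 0.5)
  par_asym <- model_params(neu = 0.001, u = 2, v = 1)
  expect_equal(root_probability(leaf_partials(1, 0), par_asym), 2 / 3)
  ## one diploid: P(copies differ) = 4 neu / (1 + 8 neu)
  expect_equal(root_probability(leaf_partials(2, 1), par),
               4 * 0.001 / (1 + 8 * 0.001), tolerance = 1e-12)
  ## total probability over r for fixed n
  tot <- sum(vapply(0:2, function(r)
    root_probability(leaf_partials(2, r), par), 1))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("character probabilities normalize and respect color symmetry", {
  set.seed(3)
  for (rep in 1:3) {
    tr <- random_gtree(sample(3:4, 1))
    par <- model_params(neu = runif(1, 5e-4, 5e-3),
                        u = runif(1, 0.5, 2), v = 1)
    N <- n_tips(tr)
    pats <- as.matrix(expand.grid(rep(list(0:2), N)))
    n <- matrix(2L, N, nrow(pats))
    p <- pattern_probabilities(tr, par, n, t(pats))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p > 0))
  }
})

test_that("multifurcations equal their zero-branch binary expansions", {
  par <- model_params(neu = 0.002)
  for (nw in c("(A:0.2,B:0.2,C:0.2);",
               "((A:0.05,B:0.05):0.1,C:0.15,D:0.15,E:0.15);")) {
    tr <- parse_gtree(nw)
    bin <- polytomies_to_zero_branches(tr)
    N <- n_tips(tr)
    for (i in 1:4) {
      r <- sample(0:2, N, TRUE)
      pa <- character_probability(tr, par, rep(2L, N), r)
      pb <- character_probability(bin, par, rep(2L, N), r)
      expect_equal(pa, pb, tolerance = 1e-10)
    }
  }
})

test_that("compiled engine agrees with the reference implementation", {
  set.seed(8)
  for (rep in 1:4) {
    tr <- random_gtree(4)
    par <- model_params(neu = runif(1, 5e-4, 3e-3))
    n <- matrix(sample(c(0L, 1L, 2L), 4 * 6, TRUE, prob = c(.1, .2, .7)),
                4, 6)
    if (any(colSums(n) == 0)) n[1, colSums(n) == 0] <- 2L
    r <- matrix(0L, 4, 6)
    for (j in 1:6) for (s in 1:4) r[s, j] <- sample(0:n[s, j], 1)
    p_cpp <- pattern_probabilities(tr, par, n, r)
    p_ref <- vapply(1:6, function(j)
      character_probability(tr, par, n[, j], r[, j]), 1)
    expect_equal(p_cpp, p_ref, tolerance = 1e-10)
  }
})

test_that("constant-character probability behaves as an ascertainment term", {
  par <- model_params(neu = 0.001)
  ## single species, two copies: complement of heterozygosity
  tr2 <- parse_gtree("(A:0.02,B:0.02);")
  pc <- constant_probability(tr2, par, c(2L, 2L))
  expect_lt(pc, 1)
  ## decreases with root height (more time to vary)
  heights <- c(0.005, 0.02, 0.08, 0.3)
  pcs <- vapply(heights, function(h) {
    t2 <- tr2; t2$heights <- h
    constant_probability(t2, par, c(2L, 2L))
  }, 1)
  expect_true(all(diff(pcs) < 0))
  ## variable-only correction renormalizes the variable patterns
  probs <- sapply(0:2, function(rA) sapply(0:2, function(rB)
    character_probability(tr2, par, c(2L, 2L), c(rA, rB))))
  p_var <- sum(probs) - probs[1, 1] - probs[3, 3]
  expect_equal(p_var / (1 - pc), 1, tolerance = 1e-10)
})

test_that("data log likelihood collapses duplicates and applies corrections", {
  set.seed(21)
  tr <- tree_shared_cherries4()
  par <- model_params(neu = 0.001)
  dat <- simulate_matrix(tr, par, m = 60)
  ll1 <- data_log_likelihood(tr, par, dat)
  ## duplicating columns doubles the log likelihood
  dat2 <- biallelic_matrix(dat$species, cbind(dat$n, dat$n),
                           cbind(dat$r, dat$r))
  expect_equal(data_log_likelihood(tr, par, dat2), 2 * ll1,
               tolerance = 1e-8)
  ## empty matrix: zero
  expect_identical(data_log_likelihood(
    tr, par, biallelic_matrix(dat$species,
                              dat$n[, 0, drop = FALSE],
                              dat$r[, 0, drop = FALSE])), 0)
  ## R and cpp paths agree, with and without the variable-only correction
  expect_equal(ll1, data_log_likelihood(tr, par, dat, engine = "R"),
               tolerance = 1e-8)
  dv <- filter_variable(dat)
  expect_equal(data_log_likelihood(tr, par, dv),
               data_log_likelihood(tr, par, dv, engine = "R"),
               tolerance = 1e-8)
  ## the correction increases each character's contribution
  expect_gt(data_log_likelihood(tr, par, dv),
            data_log_likelihood(tr, par, biallelic_matrix(
              dv$species, dv$n, dv$r)))
})

test_that("the ascertainment correction removes height bias on
           variable-only data", {
  set.seed(33)
  tr <- parse_gtree("(A:0.02,B:0.02);")
  par <- model_params(neu = 0.001)
  grid <- seq(0.005, 0.06, by = 0.0025)
  est <- replicate(6, {
    dat <- simulate_matrix(tr, par, m = 4000)
    dv <- filter_variable(dat)
    dn <- biallelic_matrix(dv$species, dv$n, dv$r)  # correction off
    prof <- vapply(grid, function(h) {
      t2 <- tr
      t2$heights <- h
      c(data_log_likelihood(t2, par, dv), data_log_likelihood(t2, par, dn))
    }, c(0, 0))
    c(grid[which.max(prof[1, ])], grid[which.max(prof[2, ])])
  })
  expect_lt(abs(median(est[1, ]) - 0.02), 0.005)  # corrected: unbiased
  expect_gt(median(est[2, ]) - 0.02, 0.005)       # uncorrected: biased up
})

test_that("true tree beats a perturbed tree on simulated data", {
  set.seed(14)
  wins <- 0L
  for (i in 1:5) {
    tr <- random_gtree(4)
    par <- model_params(neu = 0.001)
    dat <- simulate_matrix(tr, par, m = 1000)
    wrong <- tr
    wrong$heights <- tr$heights * 1.6
    wins <- wins + (data_log_likelihood(tr, par, dat) >
                      data_log_likelihood(wrong, par, dat))
  }
  expect_gte(wins, 4L)
})
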