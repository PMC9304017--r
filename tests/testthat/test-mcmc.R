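prior_ll <- function(tree, neu) 0

test_that("move bookkeeping rejects impossible proposals in place", {
  cfg <- prior_config()
  tr <- tree_star3()   # single class: no rj merge, no slide targets
  st <- list(tree = tr, neu = 0.001, ll = 0,
             lp = log_tree_prior(tr, cfg) + log_ne_prior(0.001, cfg))
  set.seed(1)
  out <- apply_move(st, "rj_merge", prior_ll, cfg)
  expect_false(out$accepted)
  expect_identical(topology_key(out$tree), topology_key(tr))
  expect_error(apply_move(st, "bogus_move", prior_ll, cfg), "unknown move")
})

test_that("chains are reproducible bit for bit given a seed", {
  set.seed(77)
  tr <- tree_shared_cherries4()
  dat <- simulate_matrix(tr, model_params(neu = 0.001), m = 120)
  a <- run_chain(dat, prior_config(), generations = 60, sample_freq = 5,
                 seed = 42)
  b <- run_chain(dat, prior_config(), generations = 60, sample_freq = 5,
                 seed = 42)
  expect_identical(a$samples, b$samples)
  c2 <- run_chain(dat, prior_config(), generations = 60, sample_freq = 5,
                  seed = 43)
  expect_false(identical(a$samples$lnL, c2$samples$lnL))
})

test_that("state caches stay consistent with recomputation", {
  set.seed(3)
  tr <- tree_shared_cherries4()
  cfg <- prior_config()
  dat <- simulate_matrix(tr, model_params(neu = 0.001), m = 150)
  trc <- run_chain(dat, cfg, generations = 150, sample_freq = 10, seed = 9)
  fin <- trc$final
  expect_equal(fin$lp,
               log_tree_prior(fin$tree, cfg) + log_ne_prior(fin$neu, cfg),
               tolerance = 1e-8)
  expect_equal(fin$ll,
               data_log_likelihood(fin$tree, model_params(neu = fin$neu),
                                   dat),
               tolerance = 1e-6)
})

test_that("disabling reversible jump confines chains to the MIB space", {
  set.seed(15)
  tr <- random_gtree(4, model = "MIB")
  dat <- simulate_matrix(tr, model_params(neu = 0.001), m = 100)
  trc <- run_chain(dat, prior_config(), generations = 250, sample_freq = 5,
                   seed = 2, model = "MIB")
  expect_true(all(trc$samples$n_heights == 3L))
  for (t in trc$trees)
    expect_true(all(lengths(t$children) == 2L))
})

test_that("prior-only chains recover the prior at N = 3", {
  cfg <- prior_config()
  trc <- run_prior_only(N = 3, generations = 6000, sample_freq = 3,
                        seed = 11, config = cfg)
  s <- trc$samples[-seq_len(400), ]
  ## topology classes uniform over the 4-class enumeration
  tab <- table(factor(s$topology, levels = unique(s$topology)))
  expect_length(tab, count_tree_models(3))
  expect_gt(chisq.test(as.vector(tab), p = rep(1 / 4, 4))$p.value, 1e-4)
  ## root height matches its gamma prior (KS on thinned draws)
  thin <- s$root_height[seq(1, nrow(s), by = 8)]
  ks <- ks.test(thin, function(q) pgamma(q, shape = 10, rate = 50))
  expect_gt(ks$p.value, 1e-4)
  ## population size matches its gamma prior
  expect_equal(mean(s$neu), 0.001, tolerance = 0.05)
  ## divergence-count marginal matches direct prior simulation
  set.seed(99)
  direct <- replicate(600, n_classes(
    sample_tree_from_prior(3, cfg, model = "MG", mix_generations = 40)))
  p_direct <- mean(direct == 1)
  p_chain <- mean(s$n_heights == 1)
  expect_lt(abs(p_direct - p_chain), 0.08)
})

test_that("prior-only chains visit all 29 models uniformly at N = 4", {
  trc <- run_prior_only(N = 4, generations = 16000, sample_freq = 8,
                        seed = 7)
  s <- trc$samples[-seq_len(500), ]
  tab <- table(s$topology)
  expect_length(tab, count_tree_models(4))
  expect_gt(chisq.test(as.vector(tab), p = rep(1 / 29, 29))$p.value, 1e-4)
  ## analytic class sizes by divergence count: 1, 13, 15 of 29
  nh <- table(factor(s$n_heights, levels = 1:3)) / nrow(s)
  expect_equal(as.vector(nh), c(1, 13, 15) / 29, tolerance = 0.25)
})

test_that("MIB prior-only chains stay uniform over bifurcating topologies", {
  trc <- run_prior_only(N = 4, generations = 8000, sample_freq = 5,
                        seed = 3, model = "MIB")
  s <- trc$samples[-seq_len(300), ]
  expect_true(all(s$n_heights == 3L))
  tab <- table(s$topology)
  expect_length(tab, 15L)
  expect_gt(chisq.test(as.vector(tab), p = rep(1 / 15, 15))$p.value, 1e-4)
})

test_that("posterior matches quadrature on a grid-solvable problem", {
  set.seed(5)
  tr <- parse_gtree("((A:0.04,B:0.04):0.08,C:0.12);")
  dat <- simulate_matrix(tr, model_params(neu = 0.002), m = 250)
  cfg <- prior_config(ne_shape = 20, ne_mean = 0.001)
  pat <- phygen:::collapse_patterns(dat)
  h1g <- seq(0.004, 0.12, length.out = 30)
  h0g <- seq(0.02, 0.3, length.out = 30)
  neg <- seq(4e-4, 4e-3, length.out = 18)
  post <- array(-Inf, c(30, 30, 18))
  for (i in seq_along(h1g)) for (j in seq_along(h0g)) {
    if (h1g[i] >= h0g[j]) next
    t2 <- tr
    t2$heights <- c(h1g[i], h0g[j])
    for (k in seq_along(neg)) {
      p <- pattern_probabilities(t2, model_params(neu = neg[k]),
                                 pat$n, pat$r)
      post[i, j, k] <- sum(pat$weights * log(p)) +
        log_tree_prior(t2, cfg) + log_ne_prior(neg[k], cfg)
    }
  }
  w <- exp(post - max(post))
  W <- sum(w)
  q_h0 <- sum(rep(1, 30) %o% h0g %o% rep(1, 18) * w) / W
  q_ne <- sum(rep(1, 30) %o% rep(1, 30) %o% neg * w) / W
  sch <- move_schedule(topology = 0, rj = 0)
  trs <- lapply(1:2, function(s)
    discard_burnin(run_chain(dat, cfg, generations = 2500, sample_freq = 3,
                             seed = s, start = tr, schedule = sch)))
  samp <- do.call(rbind, lapply(trs, `[[`, "samples"))
  expect_equal(mean(samp$root_height), q_h0, tolerance = 0.03)
  expect_equal(mean(samp$neu), q_ne, tolerance = 0.05)
})
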