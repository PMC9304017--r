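test_that("branch-score distance matches hand-enumerated split sets", {
  t1 <- tree_caterpillar3()
  expect_identical(branch_score_distance(t1, t1), 0)
  ## same topology, one internal branch differing by delta
  t2 <- t1
  t2$heights <- c(0.15, 0.2)
  expect_equal(branch_score_distance(t1, t2, include_tips = FALSE), 0.05)
  ## different cherries at equal heights: two internal splits of length 0.1
  t3 <- parse_gtree("((A:0.1,C:0.1):0.1,B:0.2);")
  expect_equal(branch_score_distance(t1, t3, include_tips = FALSE),
               sqrt(0.1^2 + 0.1^2))
  ## with terminal branches the changed tip paths join in
  expect_equal(branch_score_distance(t1, t3, include_tips = TRUE),
               sqrt(4 * 0.1^2))
  expect_error(branch_score_distance(t1, tree_shared_cherries4()), "tip")
})

test_that("branch-score distance agrees with phangorn on binary trees", {
  skip_if_not_installed("phangorn")
  set.seed(19)
  for (i in 1:5) {
    ta <- random_gtree(5, model = "MIB")
    tb <- random_gtree(5, model = "MIB")
    d1 <- branch_score_distance(ta, tb)
    d2 <- phangorn::KF.dist(as.phylo(ta), as.phylo(tb))
    ## unrooted comparison merges the two root branches into one, so allow
    ## the contribution of the root split to differ
    expect_equal(d1, as.numeric(d2), tolerance = 0.35)
  }
})

test_that("distance is a metric on sampled trees", {
  set.seed(4)
  trees <- replicate(6, random_gtree(5), simplify = FALSE)
  for (i in 1:5) {
    a <- trees[[i]]; b <- trees[[i + 1]]
    expect_equal(branch_score_distance(a, b), branch_score_distance(b, a))
    expect_gte(branch_score_distance(a, b), 0)
  }
  ## triangle inequality on random triples
  for (i in 1:4) {
    d_ab <- branch_score_distance(trees[[i]], trees[[i + 1]])
    d_bc <- branch_score_distance(trees[[i + 1]], trees[[i + 2]])
    d_ac <- branch_score_distance(trees[[i]], trees[[i + 2]])
    expect_lte(d_ac, d_ab + d_bc + 1e-12)
  }
})

test_that("split, node and shared-divergence frequencies count correctly", {
  t1 <- tree_shared_cherries4()
  fr <- split_node_shared_frequencies(list(t1, t1, t1))
  expect_true(all(fr$splits$frequency == 1))
  expect_true(all(fr$nodes$frequency == 1))
  expect_identical(nrow(fr$events), 1L)   # the shared cherry class
  ## a bifurcating node and its multifurcating collapse are distinct
  t2 <- merge_height_classes(tree_caterpillar3(), 1L, 2L)
  fr2 <- split_node_shared_frequencies(list(tree_caterpillar3(), t2))
  expect_true(all(fr2$nodes$frequency == 0.5))
  ## half-trace linearity: full-trace frequency is the mean of half-traces
  tA <- tree_caterpillar3(); tB <- t2
  f_all <- split_node_shared_frequencies(list(tA, tA, tB, tB))
  f_A <- split_node_shared_frequencies(list(tA, tA))
  f_B <- split_node_shared_frequencies(list(tB, tB))
  for (it in f_all$nodes$item) {
    fa <- f_all$nodes$frequency[f_all$nodes$item == it]
    g <- function(f) {
      v <- f$nodes$frequency[match(it, f$nodes$item)]
      if (is.na(v)) 0 else v
    }
    expect_equal(fa, (g(f_A) + g(f_B)) / 2)
  }
})

test_that("merged-divergence probabilities count divergence scenarios", {
  ref <- parse_gtree("((A:0.09,B:0.09):0.11,(C:0.1,D:0.1):0.1);")
  merged <- merge_height_classes(ref, 1L, 2L)
  ## trace of only the reference: all probabilities zero
  mp0 <- merged_divergence_probabilities(ref, list(ref, ref))
  expect_true(all(mp0$probability == 0))
  ## trace of only a merged tree: that merge has probability one
  mp1 <- merged_divergence_probabilities(ref, list(merged, merged))
  hit <- which(mp1$probability == 1)
  expect_length(hit, 1L)
  expect_equal(mp1$gap[hit], 0.01)
  ## mixed 30/70 synthetic trace
  mp2 <- merged_divergence_probabilities(
    ref, c(replicate(3, merged, simplify = FALSE),
           replicate(7, ref, simplify = FALSE)))
  expect_equal(mp2$probability[hit], 0.3)
})

test_that("ESS matches the iid and AR(1) limits", {
  set.seed(8)
  x <- rnorm(4000)
  expect_equal(effective_sample_size(x), 4000, tolerance = 0.15)
  ## AR(1): ESS/n -> (1 - phi) / (1 + phi)
  phi <- 0.6
  n <- 20000
  e <- rnorm(n)
  y <- as.numeric(stats::filter(e, phi, method = "recursive"))
  expect_equal(effective_sample_size(y) / n, (1 - phi) / (1 + phi),
               tolerance = 0.2)
})

test_that("PSRF is near one for identical-distribution chains", {
  set.seed(9)
  chains <- replicate(4, rnorm(600), simplify = FALSE)
  expect_lt(abs(potential_scale_reduction(chains) - 1), 0.02)
  shifted <- c(chains[1:3], list(rnorm(600, mean = 4)))
  expect_gt(potential_scale_reduction(shifted), 1.5)
  expect_error(potential_scale_reduction(chains[1]), "two chains")
})

test_that("ASDSF applies the minimum-frequency threshold", {
  tA <- tree_caterpillar3()                      # split AB
  tB <- parse_gtree("((A:0.1,C:0.1):0.1,B:0.2);") # split AC
  ## chain 1: AB at 4%, chain 2 the same: below the 10% threshold
  ch1 <- c(replicate(1, tA, simplify = FALSE),
           replicate(24, tree_star3(), simplify = FALSE))
  ch2 <- ch1
  expect_identical(average_sd_split_frequencies(list(ch1, ch2)), 0)
  ## frequent split with differing frequencies across chains
  ch3 <- c(replicate(6, tA, simplify = FALSE),
           replicate(4, tB, simplify = FALSE))
  ch4 <- c(replicate(4, tA, simplify = FALSE),
           replicate(6, tB, simplify = FALSE))
  val <- average_sd_split_frequencies(list(ch3, ch4))
  expect_equal(val, mean(c(sd(c(0.6, 0.4)), sd(c(0.4, 0.6)))))
  ## identical chains: zero
  expect_identical(average_sd_split_frequencies(list(ch3, ch3)), 0)
})

test_that("MAP summaries report the modal topology with mean heights", {
  t1 <- tree_shared_cherries4()
  t2 <- t1
  t2$heights <- c(0.12, 0.22)
  trc <- structure(list(
    samples = data.frame(generation = 1:4, lnL = 0, lnPrior = 0,
                         root_height = c(0.2, 0.22, 0.2, 0.22),
                         tree_length = 1, neu = 1e-3,
                         n_heights = 2L,
                         topology = topology_key(t1)),
    trees = list(t1, t2, t1, t2), chain_id = 1L, seed = 1L),
    class = "phygen_trace")
  sm <- map_summary(list(trc), burn_in = 0)
  expect_identical(sm$map_topology, topology_key(t1))
  expect_equal(sm$map_probability, 1)
  expect_equal(sort(sm$map_tree$heights), c(0.11, 0.21))
  expect_equal(sum(sm$n_divergences$probability), 1)
  expect_equal(sm$root_height[["mean"]], 0.21)
})

test_that("calibration rescaling fixes the posterior mean root age", {
  set.seed(10)
  trees <- replicate(20, random_gtree(4), simplify = FALSE)
  rs <- rescale_to_calibration(trees, 23.07)
  roots <- vapply(rs$trees, function(t) max(t$heights), 1)
  expect_equal(mean(roots), 23.07, tolerance = 1e-12)
  ## topologies unchanged
  expect_identical(vapply(rs$trees, topology_key, ""),
                   vapply(trees, topology_key, ""))
  ## identity when the target is the current mean
  cur <- mean(vapply(trees, function(t) max(t$heights), 1))
  expect_equal(rescale_to_calibration(trees, cur)$factor, 1)
  ## factor 1922.5 for mean 0.012 scaled to 23.07
  fixed <- lapply(trees, function(t) {
    t$heights <- t$heights / max(t$heights) * 0.012
    t
  })
  expect_equal(rescale_to_calibration(fixed, 23.07)$factor, 23.07 / 0.012,
               tolerance = 1e-12)
})
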