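test_that("annotated newick parses to the expected generalized trees", {
  t1 <- tree_caterpillar3()
  expect_equal(c(n_tips(t1), n_internal(t1), n_classes(t1)), c(3L, 2L, 2L))
  expect_equal(sort(t1$heights), c(0.1, 0.2))

  t2 <- tree_shared_cherries4()
  expect_equal(c(n_tips(t2), n_internal(t2), n_classes(t2)), c(4L, 3L, 2L))
  expect_equal(sum(t2$class_of == 1L), 2L)  # two cherries share one class

  t3 <- tree_star3()
  expect_equal(c(n_tips(t3), n_internal(t3), n_classes(t3)), c(3L, 1L, 1L))
})

test_that("parse errors name the offence", {
  expect_error(parse_gtree("((A:0.1,B:0.2):0.1,C:0.2);"), "ultrametric")
  expect_error(parse_gtree("((A:0.1,B:0.1)"), "parse error")
})

test_that("write/parse round trip preserves topology, classes and heights", {
  set.seed(41)
  for (i in 1:12) {
    tr <- random_gtree(sample(3:7, 1))
    rt <- parse_gtree(write_gtree(tr))
    expect_identical(topology_key(rt), topology_key(tr))
    expect_equal(sort(rt$heights), sort(tr$heights), tolerance = 1e-9)
    expect_silent(validate_gtree(rt))
  }
})

test_that("height bounds are the youngest parent and oldest child", {
  t1 <- tree_caterpillar3()
  b <- height_bounds(t1, 1L)
  expect_equal(c(b$lower, b$upper), c(0, 0.2))
  b2 <- height_bounds(tree_shared_cherries4(), 1L)
  expect_equal(c(b2$lower, b2$upper), c(0, 0.2))
  ## grandchild at 0.05 under node at 0.1 under root at 0.2
  t3 <- parse_gtree("(((A:0.05,B:0.05):0.05,C:0.1):0.1,D:0.2);")
  b3 <- height_bounds(t3, 2L)
  expect_equal(c(b3$lower, b3$upper), c(0.05, 0.2))
  expect_error(height_bounds(t1, 2L), "root")
})

test_that("merging neighbor classes shares heights and forms polytomies", {
  ## two cherries at distinct heights merge into one shared class
  tr <- parse_gtree("((A:0.09,B:0.09):0.11,(C:0.1,D:0.1):0.1);")
  m <- merge_height_classes(tr, 1L, 2L)
  expect_equal(n_classes(m), 2L)
  expect_equal(sum(m$class_of == 1L), 2L)
  expect_equal(min(m$heights), 0.1)   # older height retained
  ## parent-child merge creates a multifurcation
  t1 <- tree_caterpillar3()
  s <- merge_height_classes(t1, 1L, 2L)
  expect_equal(n_internal(s), 1L)
  expect_equal(length(s$children[[1]]), 3L)
  ## non-neighbors rejected
  t3 <- parse_gtree("(((A:0.05,B:0.05):0.05,C:0.1):0.1,D:0.2);")
  expect_error(merge_height_classes(t3, 1L, 3L), "neighbors")
})

test_that("split and merge are mutual inverses", {
  set.seed(7)
  for (i in 1:10) {
    tr <- random_gtree(6)
    prs <- neighbor_pairs(tr)
    if (!nrow(prs)) next
    pick <- prs[sample.int(nrow(prs), 1), ]
    merged <- merge_height_classes(tr, pick[1], pick[2])
    expect_silent(validate_gtree(merged))
    expect_equal(n_classes(merged), n_classes(tr) - 1L)
    ## reconstruct the original via the inverse split
    ho <- tr$heights[pick[2]]; hy <- tr$heights[pick[1]]
    km <- which(merged$heights == ho)
    young <- class_members(tr, pick[1])
    ## reverse allocation: elevated nodes move back, deleted nodes are
    ## re-detached as blocks of their original children
    par <- gt_parents(tr)
    N <- n_tips(tr)
    labs_below <- function(t, id) {
      below <- function(j) if (j <= n_tips(t)) t$tips[j] else
        unlist(lapply(t$children[[j - n_tips(t)]], below))
      sort(below(id))
    }
    mem2 <- class_members(merged, km)
    move <- integer(0); resolve <- list()
    for (id in young) {
      p <- par[id]
      if (tr$class_of[p - N] == pick[2]) {
        ## deleted: find the merged-tree node holding its children
        tgt <- mem2[vapply(mem2, function(mid)
          all(vapply(tr$children[[id - N]], function(ch)
            paste(labs_below(tr, ch), collapse = "|") %in%
              vapply(merged$children[[mid - n_tips(merged)]], function(mc)
                paste(labs_below(merged, mc), collapse = "|"), ""),
            TRUE)), TRUE)][1]
        blocks <- lapply(tr$children[[id - N]], function(ch) {
          key <- paste(labs_below(tr, ch), collapse = "|")
          kk <- merged$children[[tgt - n_tips(merged)]]
          kk[vapply(kk, function(mc)
            paste(labs_below(merged, mc), collapse = "|") == key, TRUE)]
        })
        resolve[[as.character(tgt)]] <-
          c(resolve[[as.character(tgt)]], list(unlist(blocks)))
      } else {
        ## elevated: find the matching node record in merged tree
        key <- paste(labs_below(tr, id), collapse = "|")
        tgt <- mem2[vapply(mem2, function(mid)
          paste(labs_below(merged, mid), collapse = "|") == key, TRUE)]
        move <- c(move, tgt)
      }
    }
    back <- split_height_class(merged, km,
                               list(move = move, resolve = resolve), hy)
    expect_identical(topology_key(back), topology_key(tr))
    expect_equal(sort(back$heights), sort(tr$heights))
  }
})

test_that("neighbor-merge enumeration covers adjacent height pairs", {
  expect_length(enumerate_neighbor_merges(tree_star3()), 0L)
  cat3 <- parse_gtree("(((A:0.05,B:0.05):0.05,C:0.1):0.1,D:0.2);")
  expect_length(enumerate_neighbor_merges(cat3), 2L)
  set.seed(11)
  repeat {   # a tree with several classes
    tr <- random_gtree(7)
    if (n_classes(tr) >= 4) break
  }
  em <- enumerate_neighbor_merges(tr)
  expect_length(em, n_classes(tr) - 1L)
  for (e in em) expect_silent(validate_gtree(e$tree))
})

test_that("polytomies expand to zero-length bifurcations", {
  t1 <- tree_caterpillar3()
  expect_identical(topology_key(polytomies_to_zero_branches(t1)),
                   topology_key(t1))
  t3 <- tree_star3()
  b <- polytomies_to_zero_branches(t3)
  expect_equal(n_internal(b), 2L)
  expect_equal(total_tree_length(b), total_tree_length(t3))
  big <- parse_gtree("(A:0.2,B:0.2,C:0.2,D:0.2,E:0.2);")
  bb <- polytomies_to_zero_branches(big)
  expect_equal(n_internal(bb), 4L)
  expect_equal(total_tree_length(bb), total_tree_length(big))
})

test_that("model-space counts match an independently coded enumerator", {
  expect_equal(count_tree_models(2), 1L)
  expect_equal(count_tree_models(3), 4L)   # 3 bifurcating + 1 star
  for (N in 3:5) expect_equal(count_tree_models(N), oracle_count_models(N))
})

test_that("operations emit valid trees", {
  set.seed(13)
  for (i in 1:8) {
    tr <- random_gtree(sample(4:8, 1))
    expect_silent(validate_gtree(tr))
  }
})
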