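## Shared fixtures and independent oracles, built in code.

## canonical example trees
tree_caterpillar3 <- function()
  parse_gtree("((A:0.1,B:0.1):0.1,C:0.2);")

tree_shared_cherries4 <- function()
  parse_gtree(paste0("((A:0.1,B:0.1)[&hc=1]:0.1,",
                     "(C:0.1,D:0.1)[&hc=1]:0.1)[&hc=2];"))

tree_star3 <- function() parse_gtree("(A:0.2,B:0.2,C:0.2);")

## random valid generalized tree via the prior sampler (seeded by caller)
random_gtree <- function(N, model = "MG") {
  sample_tree_from_prior(N, prior_config(), model = model,
                         mix_generations = 60)
}

## ---------------------------------------------------------------------------
## independent enumeration oracle for the discrete model space: grows all
## multifurcating labelled topologies by adding one tip at a time (dedup via
## canonical strings), then counts node partitions whose class order can be
## realized by an explicit height assignment (constructive check).
## ---------------------------------------------------------------------------

oracle_count_models <- function(N) {
  canon <- function(tr) {
    if (!is.list(tr)) return(as.character(tr))
    paste0("(", paste(sort(vapply(tr, canon, "")), collapse = ","), ")")
  }
  trees <- list(1L)
  for (tip in 2:N) {
    nxt <- list()
    seen <- character(0)
    add_everywhere <- function(tr) {
      out <- list()
      ## as sibling of the whole tree (new root)
      out[[1]] <- list(tr, tip)
      if (is.list(tr)) {
        ## as an extra child of this node
        out[[length(out) + 1L]] <- c(tr, list(tip))
        for (i in seq_along(tr)) {
          for (sub in add_everywhere(tr[[i]])) {
            cp <- tr
            cp[[i]] <- sub
            out[[length(out) + 1L]] <- cp
          }
        }
      }
      out
    }
    for (tr in trees) {
      for (cand in add_everywhere(tr)) {
        key <- canon(cand)
        if (!key %in% seen) {
          seen <- c(seen, key)
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    trees <- nxt
  }
  ## count valid node partitions per topology by explicit height assignment
  count_partitions <- function(tr) {
    nodes <- 0L
    edges <- NULL   # ancestor pairs (a, d)
    walk <- function(x, anc) {
      if (!is.list(x)) return(invisible())
      nodes <<- nodes + 1L
      me <- nodes
      for (a in anc) edges <<- rbind(edges, c(a, me))
      for (ch in x) walk(ch, c(anc, me))
    }
    walk(tr, integer(0))
    if (nodes == 1L) return(1L)
    parts <- all_partitions_oracle(nodes)
    ok <- 0L
    for (p in parts) {
      blk <- integer(nodes)
      for (b in seq_along(p)) blk[p[[b]]] <- b
      ## constructive: iteratively assign decreasing heights to classes all
      ## of whose ancestor classes are already assigned
      nb <- length(p)
      above <- matrix(FALSE, nb, nb)
      bad <- FALSE
      if (!is.null(edges)) for (r in seq_len(nrow(edges))) {
        a <- blk[edges[r, 1]]; d <- blk[edges[r, 2]]
        if (a == d) { bad <- TRUE; break }
        above[a, d] <- TRUE
      }
      if (bad) next
      assigned <- logical(nb)
      repeat {
        ready <- which(!assigned & vapply(seq_len(nb), function(b)
          all(assigned[above[, b]]), TRUE))
        if (!length(ready)) break
        assigned[ready] <- TRUE
      }
      if (all(assigned)) ok <- ok + 1L
    }
    ok
  }
  sum(vapply(trees, count_partitions, 1L))
}

## plain set-partition generator (independent of the package's)
all_partitions_oracle <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in all_partitions_oracle(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

## total branch length of a gtree
total_tree_length <- function(tree) {
  h <- node_height(tree)
  p <- gt_parents(tree)
  sum(h[p[p != 0]] - h[which(p != 0)])
}
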