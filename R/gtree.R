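#' Generalized trees with shared and multifurcating divergences
#'
#' A `gtree` is a rooted, potentially multifurcating tree over `N` labelled
#' tips in which every internal node is assigned to one of `n_tau` divergence
#' -time classes. Two or more nodes mapped to the same class diverge at the
#' same moment (a *shared divergence*); a node with three or more children is
#' a *multifurcation*. Tips sit at time 0 and heights are measured in
#' expected substitutions per site.
#'
#' Internally a `gtree` stores:
#' \describe{
#'   \item{tips}{character vector of `N` tip labels; tip ids are `1..N`.}
#'   \item{children}{list over internal nodes (ids `N+1 .. N+M`, element `i`
#'     describes node `N+i`) holding integer vectors of child ids.}
#'   \item{class_of}{integer vector, the height class of each internal node.}
#'   \item{heights}{numeric vector of class heights (single source of truth;
#'     branch lengths are derived).}
#' }
#'
#' Invariants (checked by [validate_gtree()]): every class has at least one
#' node; every node is strictly younger than its parent; internal nodes have
#' at least two children; no node shares a class with one of its ancestors;
#' there is a single root, alone able to carry the oldest class.
#'
#' @param tips character vector of tip labels.
#' @param children list of integer child-id vectors, one per internal node.
#' @param class_of integer vector mapping internal nodes to height classes.
#' @param heights numeric vector of class heights.
#' @param validate logical; check invariants (default `TRUE`).
#' @return An object of class `gtree`.
#' @export
gtree <- function(tips, children, class_of, heights, validate = TRUE) {
  stopifnot(is.character(tips), is.list(children),
            length(class_of) == length(children))
  obj <- structure(
    list(tips = tips,
         children = lapply(children, as.integer),
         class_of = as.integer(class_of),
         heights = as.numeric(heights)),
    class = "gtree")
  ## cache the derived parent map and root id (hot paths in MCMC)
  N <- length(tips)
  parent <- integer(N + length(children))
  for (i in seq_along(obj$children)) parent[obj$children[[i]]] <- N + i
  obj$parent <- parent
  ids <- N + seq_along(obj$children)
  obj$root <- ids[parent[ids] == 0L]
  if (validate) validate_gtree(obj)
  obj
}

#' @export
print.gtree <- function(x, ...) {
  cat(sprintf("gtree: %d tips, %d internal nodes, %d height classes\n",
              n_tips(x), n_internal(x), n_classes(x)))
  cat(write_gtree(x), "\n")
  invisible(x)
}

#' Number of tips, internal nodes and height classes
#' @param tree a `gtree`.
#' @return integer count.
#' @export
n_tips <- function(tree) length(tree$tips)

#' @rdname n_tips
#' @export
n_internal <- function(tree) length(tree$children)

#' @rdname n_tips
#' @export
n_classes <- function(tree) length(tree$heights)

#' Parent map of a gtree
#'
#' @param tree a `gtree`.
#' @return integer vector over all node ids (tips first); 0 marks the root.
#' @export
gt_parents <- function(tree) {
  if (!is.null(tree$parent)) return(tree$parent)
  np <- n_tips(tree) + n_internal(tree)
  parent <- integer(np)
  for (i in seq_along(tree$children)) {
    parent[tree$children[[i]]] <- n_tips(tree) + i
  }
  parent
}

#' Root node id
#' @param tree a `gtree`.
#' @return integer id of the root (an internal node).
#' @export
gt_root <- function(tree) {
  if (!is.null(tree$root)) return(tree$root)
  parent <- gt_parents(tree)
  ids <- n_tips(tree) + seq_along(tree$children)
  ids[parent[ids] == 0L]
}

#' Node heights
#'
#' @param tree a `gtree`.
#' @param ids node ids (default all).
#' @return numeric heights; tips are 0.
#' @export
node_height <- function(tree, ids = NULL) {
  N <- n_tips(tree)
  h <- c(rep(0, N), tree$heights[tree$class_of])
  if (is.null(ids)) h else h[ids]
}

#' Internal members of a height class
#' @param tree a `gtree`.
#' @param k class index.
#' @return integer node ids mapped to class `k`.
#' @export
class_members <- function(tree, k) {
  n_tips(tree) + which(tree$class_of == k)
}

## ancestor matrix over internal nodes: anc[i, j] TRUE if internal node i is
## a (strict) ancestor of internal node j. ids are internal indices 1..M.
gt_ancestor_matrix <- function(tree) {
  M <- n_internal(tree)
  N <- n_tips(tree)
  parent <- gt_parents(tree)
  anc <- matrix(FALSE, M, M)
  for (j in seq_len(M)) {
    p <- parent[N + j]
    while (p != 0L) {
      anc[p - N, j] <- TRUE
      p <- parent[p]
    }
  }
  anc
}

#' Validate a generalized tree
#'
#' Checks all `gtree` invariants and stops with an informative error when one
#' fails. With `strict = FALSE`, equal parent/child heights are tolerated
#' (used for the zero-length-branch binary expansion of multifurcations).
#'
#' @param tree a `gtree`.
#' @param strict logical; require strictly decreasing heights along paths.
#' @return The tree, invisibly.
#' @export
validate_gtree <- function(tree, strict = TRUE) {
  N <- n_tips(tree); M <- n_internal(tree); K <- n_classes(tree)
  if (N < 1L) stop("gtree needs at least one tip")
  if (anyDuplicated(tree$tips)) stop("duplicate tip labels")
  if (M < 1L) stop("gtree needs at least one internal node")
  if (K < 1L || K > M) stop("need 1 <= n_tau <= n_internal")
  if (M > N - 1L) stop("too many internal nodes for ", N, " tips")
  if (length(tree$class_of) != M) stop("class_of length mismatch")
  if (any(tree$class_of < 1L | tree$class_of > K))
    stop("class index out of range")
  if (!all(seq_len(K) %in% tree$class_of))
    stop("every height class must have at least one node assigned to it")
  if (any(!is.finite(tree$heights)) || any(tree$heights < 0))
    stop("class heights must be finite and nonnegative")
  ## child structure
  allkids <- unlist(tree$children)
  np <- N + M
  if (length(allkids) != np - 1L || anyDuplicated(allkids) ||
      !all(allkids %in% seq_len(np)))
    stop("children must partition all non-root nodes")
  if (any(vapply(tree$children, length, 1L) < 2L))
    stop("every internal node needs at least two children")
  parent <- gt_parents(tree)
  roots <- which(parent[(N + 1L):np] == 0L)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  ## heights decrease rootward; acyclic by construction of parent map
  h <- node_height(tree)
  for (i in seq_len(M)) {
    hk <- h[tree$children[[i]]]
    if (strict && any(hk >= h[N + i]))
      stop("node ", N + i, ": child height >= parent height")
    if (!strict && any(hk > h[N + i] + 1e-12))
      stop("node ", N + i, ": child height > parent height")
  }
  ## no node shares a class with an ancestor
  if (strict && M > 1L) {
    anc <- gt_ancestor_matrix(tree)
    for (i in seq_len(M)) for (j in seq_len(M)) {
      if (anc[i, j] && tree$class_of[i] == tree$class_of[j])
        stop("node shares a height class with its ancestor")
    }
  }
  ## root class contains only the root (anything sharing it would be a
  ## descendant of the root, caught above); root must carry the oldest height
  ro <- roots + N
  if (strict && tree$heights[tree$class_of[ro - N]] < max(tree$heights))
    stop("root must carry the oldest height class")
  invisible(tree)
}

#' Youngest-parent height of each class
#'
#' For every height class, the minimum height over the parents of its member
#' nodes. This is the upper bound `U_k` used by the nested-beta prior on
#' non-root divergence times. The root class gets `Inf`.
#'
#' @param tree a `gtree`.
#' @return numeric vector over classes.
#' @export
class_upper_bounds <- function(tree) {
  N <- n_tips(tree)
  parent <- gt_parents(tree)
  h <- node_height(tree)
  U <- rep(Inf, n_classes(tree))
  for (i in seq_along(tree$class_of)) {
    p <- parent[N + i]
    if (p != 0L) {
      k <- tree$class_of[i]
      U[k] <- min(U[k], h[p])
    }
  }
  U
}

#' Legal interval for moving a height class
#'
#' The open interval of heights into which class `k` can be moved without
#' violating any tree invariant: bounded below by the oldest child of any
#' member node and above by the youngest parent of any member node.
#'
#' @param tree a `gtree`.
#' @param k non-root class index.
#' @return list with `lower` and `upper`.
#' @export
height_bounds <- function(tree, k) {
  U <- class_upper_bounds(tree)
  if (!is.finite(U[k]))
    stop("root class has no bounded interval (its upper bound is the root prior)")
  members <- class_members(tree, k)
  h <- node_height(tree)
  lo <- max(vapply(members, function(id)
    max(h[tree$children[[id - n_tips(tree)]]]), 0))
  list(lower = lo, upper = U[k])
}

## lower structural bound for a class: oldest child height over members
class_lower_bound <- function(tree, k) {
  members <- class_members(tree, k)
  h <- node_height(tree)
  max(vapply(members, function(id)
    max(h[tree$children[[id - n_tips(tree)]]]), 0))
}

## ---------------------------------------------------------------------------
## mutable node-map helpers: children/class maps keyed by original id
## ---------------------------------------------------------------------------

## rebuild a gtree from id-indexed maps: `kids` is a list over node ids
## (NULL for tips and deleted nodes), `cls` an integer vector over node ids.
## Internal ids are renumbered compactly; class ids renumbered by height.
gt_rebuild <- function(tips, kids, cls, heights, validate = TRUE) {
  N <- length(tips)
  old_ids <- which(!vapply(kids, is.null, TRUE))
  new_of_old <- integer(length(kids))
  new_of_old[old_ids] <- N + seq_along(old_ids)
  children <- lapply(old_ids, function(id) {
    v <- kids[[id]]
    sel <- v > N
    if (any(sel)) v[sel] <- new_of_old[v[sel]]
    v
  })
  class_raw <- cls[old_ids]
  used <- sort(unique(class_raw))
  ord <- used[order(heights[used])]
  class_of <- match(class_raw, ord)
  gtree(tips, children, class_of, heights[ord], validate = validate)
}

gt_maps <- function(tree) {
  N <- n_tips(tree); M <- n_internal(tree)
  kids <- vector("list", N + M)
  cls <- integer(N + M)
  for (i in seq_len(M)) {
    kids[[N + i]] <- tree$children[[i]]
    cls[N + i] <- tree$class_of[i]
  }
  list(kids = kids, cls = cls)
}

## ---------------------------------------------------------------------------
## merge / split
## ---------------------------------------------------------------------------

#' Pairs of neighboring height classes
#'
#' Classes adjacent in the sorted order of their heights. Merging any such
#' pair yields a valid generalized tree.
#'
#' @param tree a `gtree`.
#' @return a two-column matrix (`young`, `old`) of class indices, one row per
#'   adjacent pair; zero rows when `n_tau = 1`.
#' @export
neighbor_pairs <- function(tree) {
  ord <- order(tree$heights)
  k <- length(ord)
  if (k < 2L) return(matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("young", "old"))))
  cbind(young = ord[-k], old = ord[-1])
}

#' Merge two neighboring height classes
#'
#' All nodes of the younger class are raised to the older height. Any node
#' whose height then equals its parent's is deleted and its children are
#' attached to the parent, creating a multifurcation. `n_tau` drops by one.
#'
#' @param tree a `gtree`.
#' @param class_young,class_old indices of adjacent classes,
#'   `heights[class_young] < heights[class_old]` with no class in between.
#' @param validate check invariants of the result (default `TRUE`).
#' @return the merged `gtree`.
#' @export
merge_height_classes <- function(tree, class_young, class_old,
                                 validate = TRUE) {
  hy <- tree$heights[class_young]; ho <- tree$heights[class_old]
  if (!(hy < ho)) stop("class_young must be younger than class_old")
  if (any(tree$heights > hy & tree$heights < ho))
    stop("classes are not neighbors: another class lies between them")
  m <- gt_maps(tree)
  N <- n_tips(tree)
  young_ids <- class_members(tree, class_young)
  m$cls[young_ids] <- class_old
  ## delete nodes that now match their parent's height (parent in old class)
  parent <- gt_parents(tree)
  for (id in young_ids) {
    p <- parent[id]
    if (p != 0L && tree$class_of[p - N] == class_old) {
      m$kids[[p]] <- c(setdiff(m$kids[[p]], id), m$kids[[id]])
      m$kids[id] <- list(NULL)
    }
  }
  gt_rebuild(tree$tips, m$kids, m$cls, tree$heights, validate = validate)
}

#' Split a height class in two
#'
#' The reverse-jump counterpart of [merge_height_classes()]. The allocation
#' says, for every member node, whether it stays at the old height or moves
#' to the new younger height, and may additionally detach subsets of a
#' polytomy's children onto new nodes at the new height.
#'
#' @param tree a `gtree`.
#' @param k class index to split.
#' @param allocation list with `move` (integer node ids moving to the new
#'   class) and optionally `resolve`, a list named by node id holding lists
#'   of child-id vectors (each of size >= 2) to detach onto new nodes.
#' @param new_height height of the new class; must lie strictly between the
#'   allocation's structural lower bound and the height of class `k`.
#' @param validate check invariants of the result (default `TRUE`).
#' @return a `gtree` with `n_tau` increased by one.
#' @export
split_height_class <- function(tree, k, allocation, new_height,
                               validate = TRUE) {
  N <- n_tips(tree)
  members <- class_members(tree, k)
  move <- as.integer(allocation$move %||% integer(0))
  resolve <- allocation$resolve %||% list()
  if (!all(move %in% members)) stop("allocation moves a node not in class")
  if (length(intersect(as.integer(names(resolve)), move)))
    stop("a node cannot both move and resolve")
  ro <- gt_root(tree)
  if (ro %in% move) stop("the root cannot move to the younger class")
  n_new <- sum(vapply(resolve, length, 1L))
  if (length(move) + n_new == 0L)
    stop("allocation must move at least one node or resolve a polytomy")
  if (length(move) == length(members))
    stop("allocation may not empty the old class")
  ho <- tree$heights[k]
  if (!(new_height < ho)) stop("new height must be below the class height")
  m <- gt_maps(tree)
  heights <- c(tree$heights, new_height)
  knew <- length(heights)
  h <- node_height(tree)
  lo <- 0
  for (id in move) {
    m$cls[id] <- knew
    lo <- max(lo, h[m$kids[[id]]])
  }
  n_new <- sum(vapply(resolve, length, 1L))
  next_id <- length(m$kids)
  if (n_new > 0) {
    m$kids <- c(m$kids, vector("list", n_new))
    m$cls <- c(m$cls, integer(n_new))
  }
  for (nm in names(resolve)) {
    id <- as.integer(nm)
    if (!(id %in% members)) stop("resolve names a node not in class")
    subs <- resolve[[nm]]
    allsub <- unlist(subs)
    kids <- m$kids[[id]]
    if (anyDuplicated(allsub) || !all(allsub %in% kids))
      stop("resolution subsets must be disjoint children of the node")
    if (any(vapply(subs, length, 1L) < 2L))
      stop("resolution subsets must have >= 2 children")
    if (length(kids) - length(allsub) + length(subs) < 2L)
      stop("resolution would leave the node with fewer than two children")
    for (S in subs) {
      next_id <- next_id + 1L
      m$kids[[next_id]] <- as.integer(S)
      m$cls[next_id] <- knew
      kids <- c(setdiff(kids, S), next_id)
      lo <- max(lo, h[S])
    }
    m$kids[[id]] <- kids
  }
  if (!(new_height > lo))
    stop("new height must exceed the oldest child of the young class")
  gt_rebuild(tree$tips, m$kids, m$cls, heights, validate = validate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate all neighbor merges of a tree
#'
#' One merged tree per pair of height classes adjacent in the sorted height
#' order. Each merge creates either a shared divergence or a multifurcation.
#'
#' @param tree a `gtree`.
#' @return list of entries with `young`, `old` (class indices) and `tree`
#'   (the merged `gtree`); empty when `n_tau = 1`.
#' @export
enumerate_neighbor_merges <- function(tree) {
  prs <- neighbor_pairs(tree)
  out <- vector("list", nrow(prs))
  for (i in seq_len(nrow(prs))) {
    out[[i]] <- list(young = prs[i, 1], old = prs[i, 2],
                     tree = merge_height_classes(tree, prs[i, 1], prs[i, 2]))
  }
  out
}

#' Expand multifurcations into zero-length bifurcations
#'
#' Rewrites every polytomy as a left-nested series of bifurcations whose new
#' internal branches have length zero. Total branch length and tip set are
#' preserved. The result intentionally violates the strict-height invariant
#' (equal parent/child heights), so it is validated in relaxed mode; it is
#' used as a likelihood cross-check only.
#'
#' @param tree a `gtree`.
#' @return a binary `gtree` (relaxed validation).
#' @export
polytomies_to_zero_branches <- function(tree) {
  m <- gt_maps(tree)
  heights <- tree$heights
  N <- n_tips(tree)
  orig_ids <- N + seq_len(n_internal(tree))
  for (id in orig_ids) {
    kids <- m$kids[[id]]
    while (length(kids) > 2L) {
      heights <- c(heights, tree$heights[m$cls[id]])
      m$kids[[length(m$kids) + 1L]] <- kids[1:2]
      m$cls[length(m$kids)] <- length(heights)
      kids <- c(length(m$kids), kids[-(1:2)])
    }
    m$kids[[id]] <- kids
  }
  out <- gt_rebuild(tree$tips, m$kids, m$cls, heights, validate = FALSE)
  validate_gtree(out, strict = FALSE)
  out
}

## ---------------------------------------------------------------------------
## topology keys, splits, conversion
## ---------------------------------------------------------------------------

## canonical newick-like string of the topology (no heights): sorted children
topology_string <- function(tree) {
  N <- n_tips(tree)
  rec <- function(id) {
    if (id <= N) return(tree$tips[id])
    parts <- sort(vapply(tree$children[[id - N]], rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(gt_root(tree))
}

#' Canonical key of a generalized topology
#'
#' A string identifying the discrete tree model: the multifurcating topology
#' plus the partition of internal nodes into shared height classes (height
#' values and class ordering are ignored). Two samples with the same key are
#' draws from the same generalized topology.
#'
#' @param tree a `gtree`.
#' @return character scalar.
#' @export
topology_key <- function(tree) {
  N <- n_tips(tree)
  labs <- character(N + n_internal(tree))
  rec <- function(id) {
    if (id <= N) {
      labs[id] <<- tree$tips[id]
      return(labs[id])
    }
    parts <- sort(vapply(tree$children[[id - N]], rec, ""))
    labs[id] <<- paste0("(", paste(parts, collapse = ","), ")")
    labs[id]
  }
  rec(gt_root(tree))
  ## partition of internal nodes into classes, canonically ordered
  cls <- split(labs[n_tips(tree) + seq_len(n_internal(tree))], tree$class_of)
  blocks <- sort(vapply(cls, function(b) paste(sort(b), collapse = "+"), ""))
  paste0(labs[gt_root(tree)], "|", paste(blocks, collapse = ";"))
}

## splits: for each non-root node (internal or tip), the sorted tip labels
## below it, plus the branch length (parent height - node height).
gt_splits <- function(tree, include_tips = TRUE) {
  N <- n_tips(tree)
  parent <- gt_parents(tree)
  h <- node_height(tree)
  below <- vector("list", N + n_internal(tree))
  for (i in seq_len(N)) below[[i]] <- tree$tips[i]
  fill <- function(id) {
    if (id <= N) return(below[[id]])
    kids <- tree$children[[id - N]]
    below[[id]] <<- sort(unlist(lapply(kids, fill)))
    below[[id]]
  }
  fill(gt_root(tree))
  ids <- seq_len(N + n_internal(tree))
  ids <- ids[parent[ids] != 0L]
  if (!include_tips) ids <- ids[ids > N]
  keys <- vapply(ids, function(id) paste(below[[id]], collapse = "|"), "")
  lens <- h[parent[ids]] - h[ids]
  stats::setNames(lens, keys)
}

#' Convert a gtree to an ape phylo object
#'
#' @param x a `gtree`.
#' @param ... unused.
#' @return an [ape::phylo] object with branch lengths derived from heights.
#' @export
as.phylo.gtree <- function(x, ...) {
  N <- n_tips(x); M <- n_internal(x)
  parent <- gt_parents(x)
  h <- node_height(x)
  ## ape wants internal ids ordered with root = N+1
  ro <- gt_root(x)
  ids <- c(ro, setdiff(N + seq_len(M), ro))
  new_id <- integer(N + M)
  new_id[seq_len(N)] <- seq_len(N)
  new_id[ids] <- N + seq_len(M)
  edges <- NULL; lens <- NULL
  for (i in seq_len(M)) {
    for (ch in x$children[[i]]) {
      edges <- rbind(edges, c(new_id[N + i], new_id[ch]))
      lens <- c(lens, h[N + i] - h[ch])
    }
  }
  phy <- list(edge = edges, edge.length = lens, tip.label = x$tips,
              Nnode = M)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

## ---------------------------------------------------------------------------
## newick parsing / writing
## ---------------------------------------------------------------------------

#' Write a gtree as annotated newick
#'
#' Internal nodes carry a `[&hc=<class>]` comment recording their height
#' class, so shared divergences round-trip through text.
#'
#' @param tree a `gtree`.
#' @param digits significant digits for branch lengths.
#' @return a newick string terminated by `;`.
#' @export
write_gtree <- function(tree, digits = 12) {
  N <- n_tips(tree)
  h <- node_height(tree)
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(id, ph) {
    if (id <= N) {
      s <- tree$tips[id]
    } else {
      i <- id - N
      s <- paste0("(", paste(vapply(tree$children[[i]], rec, "", h[id]),
                             collapse = ","),
                  ")[&hc=", tree$class_of[i], "]")
    }
    if (is.na(ph)) s else paste0(s, ":", fmt(ph - h[id]))
  }
  paste0(rec(gt_root(tree), NA_real_), ";")
}

#' Parse an annotated newick string into a gtree
#'
#' Accepts standard newick with branch lengths; `[&hc=<int>]` comments on
#' internal nodes assign shared height classes. Nodes without a comment get
#' their own class. Node heights are recovered from branch lengths and must
#' be ultrametric to within `tol`.
#'
#' @param text newick string.
#' @param tol ultrametricity tolerance on recovered heights.
#' @return a `gtree`.
#' @export
parse_gtree <- function(text, tol = 1e-9) {
  s <- gsub("[[:space:]]", "", text)
  pos <- 1L
  peek <- function() substr(s, pos, pos)
  ## node records accumulated in parse order
  nodes <- list()   # each: list(kids=<indices into nodes or tip labels>)
  parse_clade <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- list(parse_clade())
      while (peek() == ",") {
        pos <<- pos + 1L
        kids <- c(kids, list(parse_clade()))
      }
      if (peek() != ")") stop("parse error: expected ')' at position ", pos)
      pos <<- pos + 1L
      ## optional internal label (ignored)
      lab <- parse_name()
      hc <- parse_comment()
      len <- parse_length()
      list(type = "internal", kids = kids, hc = hc, len = len)
    } else {
      nm <- parse_name()
      if (nm == "") stop("parse error: empty tip name at position ", pos)
      parse_comment()  # tolerated, ignored on tips
      len <- parse_length()
      list(type = "tip", name = nm, len = len)
    }
  }
  parse_comment <- function() {
    if (peek() != "[") return(NA_integer_)
    close <- regexpr("]", substr(s, pos, nchar(s)), fixed = TRUE)
    if (close < 0) stop("parse error: unterminated comment")
    com <- substr(s, pos, pos + close - 1L)
    pos <<- pos + close
    m <- regmatches(com, regexec("hc=([0-9]+)", com))[[1]]
    if (length(m) == 2L) as.integer(m[2]) else NA_integer_
  }
  parse_length <- function() {
    if (peek() != ":") return(NA_real_)
    pos <<- pos + 1L
    m <- regmatches(substr(s, pos, nchar(s)),
                    regexpr("^[-+0-9.eE]+", substr(s, pos, nchar(s))))
    if (!length(m)) stop("parse error: bad branch length at position ", pos)
    pos <<- pos + nchar(m)
    as.numeric(m)
  }
  parse_name <- function() {
    rest <- substr(s, pos, nchar(s))
    m <- regmatches(rest, regexpr("^[^]:,;()[]*", rest))
    pos <<- pos + nchar(m)
    m
  }
  top <- parse_clade()
  if (peek() != ";") stop("parse error: expected ';' at position ", pos)
  if (top$type != "internal") stop("tree must have an internal root")

  ## flatten: collect tips and internal nodes, compute heights bottom-up
  tips <- character(0)
  children <- list(); hcs <- integer(0); hts <- numeric(0)
  walk <- function(nd) {
    ## returns c(id, height)
    if (nd$type == "tip") {
      tips <<- c(tips, nd$name)
      return(c(length(tips), 0, nd$len))
    }
    got <- lapply(nd$kids, walk)
    ids <- vapply(got, `[`, 0, 1)
    hs <- vapply(got, function(g) g[2] + g[3], 0)
    if (any(is.na(hs))) stop("parse error: missing branch length")
    if (diff(range(hs)) > tol * max(1, max(hs)))
      stop("non-ultrametric input: child heights of a node disagree (",
           paste(format(hs), collapse = ", "), ")")
    children[[length(children) + 1L]] <<- ids
    hcs <<- c(hcs, nd$hc)
    hts <<- c(hts, mean(hs))
    c(-length(children), mean(hs), if (is.null(nd$len)) NA_real_ else nd$len)
  }
  walk(top)
  N <- length(tips)
  ## internal temp ids are negative indices into children; remap to N+i
  children <- lapply(children, function(v) ifelse(v < 0, N - v, v))
  ## assign classes: explicit hc indices shared; NA -> own class
  uniq <- unique(hcs[!is.na(hcs)])
  nxt <- length(uniq)
  cls <- integer(length(children))
  own <- 0L
  for (i in seq_along(children)) {
    if (is.na(hcs[i])) {
      own <- own + 1L
      cls[i] <- nxt + own
    } else cls[i] <- match(hcs[i], uniq)
  }
  nK <- nxt + own
  heights <- rep(NA_real_, nK)
  for (i in seq_along(children)) {
    k <- cls[i]
    if (is.na(heights[k])) {
      heights[k] <- hts[i]
    } else if (abs(heights[k] - hts[i]) > tol * max(1, heights[k])) {
      stop("node ", N + i, ": height disagrees with its class (hc=",
           hcs[i], ")")
    }
  }
  ## renumber classes by height so indices are stable across round trips
  ord <- order(heights)
  gtree(tips, children, match(cls, ord), heights[ord])
}

## ---------------------------------------------------------------------------
## counting the discrete model space
## ---------------------------------------------------------------------------

## all set partitions of 1..n (list of lists of integer vectors)
all_set_partitions <- function(n) {
  if (n == 0L) return(list(list()))
  out <- list()
  rec <- function(i, blocks) {
    if (i > n) {
      out[[length(out) + 1L]] <<- blocks
      return(invisible())
    }
    for (b in seq_along(blocks)) {
      nb <- blocks
      nb[[b]] <- c(nb[[b]], i)
      rec(i + 1L, nb)
    }
    rec(i + 1L, c(blocks, list(i)))
  }
  rec(2L, list(1L))
  if (n == 1L) return(list(list(1L)))
  out
}

## enumerate all labelled rooted multifurcating topologies on tip set `set`
## as nested lists; a tree is either an integer (tip) or a list of subtrees.
enumerate_topologies <- function(set) {
  n <- length(set)
  if (n == 1L) return(list(set))
  out <- list()
  for (part in all_set_partitions(n)) {
    if (length(part) < 2L) next
    blocks <- lapply(part, function(ix) set[ix])
    subl <- lapply(blocks, enumerate_topologies)
    ## cartesian product of subtree choices
    idx <- rep(1L, length(subl))
    repeat {
      out[[length(out) + 1L]] <- lapply(seq_along(subl),
                                        function(b) subl[[b]][[idx[b]]])
      j <- length(idx)
      while (j >= 1L) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(subl[[j]])) break
        idx[j] <- 1L; j <- j - 1L
      }
      if (j < 1L) break
    }
  }
  out
}

## internal-node ancestor pairs of a nested-list topology
topo_internal_relations <- function(topo) {
  ## returns list(n_internal, anc = matrix of strict ancestor pairs)
  cnt <- 0L
  pairs <- NULL
  rec <- function(nd, anc_ids) {
    if (!is.list(nd)) return(invisible())
    cnt <<- cnt + 1L
    id <- cnt
    for (a in anc_ids) pairs <<- rbind(pairs, c(a, id))
    for (ch in nd) rec(ch, c(anc_ids, id))
  }
  rec(topo, integer(0))
  list(n = cnt, pairs = pairs)
}

#' Count discrete generalized tree models
#'
#' The number of distinct (topology, height-sharing pattern) pairs for `N`
#' tips: labelled rooted multifurcating topologies combined with every valid
#' partition of their internal nodes into shared height classes (no class
#' may contain an ancestor and its descendant, and the induced class
#' ordering must be acyclic). Computed by exhaustive enumeration.
#'
#' @param N number of tips (2..8; enumeration grows super-exponentially).
#' @return integer count.
#' @export
count_tree_models <- function(N) {
  if (N < 1L || N > 8L) stop("N too large for exhaustive enumeration")
  if (N == 1L) return(0L)
  topos <- enumerate_topologies(seq_len(N))
  total <- 0L
  for (tp in topos) {
    rel <- topo_internal_relations(tp)
    if (rel$n == 1L) { total <- total + 1L; next }
    comparable <- matrix(FALSE, rel$n, rel$n)
    if (!is.null(rel$pairs)) {
      comparable[rel$pairs] <- TRUE
    }
    for (part in all_set_partitions(rel$n)) {
      ok <- TRUE
      ## no block with an ancestor-descendant pair
      for (b in part) {
        if (length(b) > 1L) {
          for (x in b) for (y in b) if (comparable[x, y]) { ok <- FALSE; break }
          if (!ok) break
        }
      }
      if (!ok) next
      ## class DAG must be acyclic
      nb <- length(part)
      blk <- integer(rel$n)
      for (b in seq_len(nb)) blk[part[[b]]] <- b
      adj <- matrix(FALSE, nb, nb)
      if (!is.null(rel$pairs)) {
        for (r in seq_len(nrow(rel$pairs))) {
          a <- blk[rel$pairs[r, 1]]; d <- blk[rel$pairs[r, 2]]
          if (a != d) adj[a, d] <- TRUE
        }
      }
      ## DFS cycle check
      state <- integer(nb)
      cyc <- FALSE
      visit <- function(v) {
        if (cyc) return(invisible())
        state[v] <<- 1L
        for (w in which(adj[v, ])) {
          if (state[w] == 1L) { cyc <<- TRUE; return(invisible()) }
          if (state[w] == 0L) visit(w)
        }
        state[v] <<- 2L
      }
      for (v in seq_len(nb)) if (state[v] == 0L) visit(v)
      if (cyc) next
      total <- total + 1L
    }
  }
  total
}
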