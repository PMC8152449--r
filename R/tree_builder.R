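#' Per-transcript compatible-read sets
#'
#' Derives, for each transcript, the set of (equivalence-class) row indices
#' with a positive compatibility entry. These sets drive the Jaccard
#' clustering heuristic for choosing a Polya tree topology.
#'
#' @param compat a [read_compat] object.
#' @return list of sorted integer vectors, one per transcript (possibly
#'   empty).
#' @export
compat_sets <- function(compat) {
  pt <- methods::as(compat$p, "CsparseMatrix")
  ptr <- pt@p
  lapply(seq_len(compat$n), function(j) {
    if (ptr[j + 1L] > ptr[j]) sort(pt@i[(ptr[j] + 1L):ptr[j + 1L]] + 1L)
    else integer(0)
  })
}

jaccard_index <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(0)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Greedy Jaccard clustering tree
#'
#' Builds a Polya tree topology by greedy agglomeration of per-transcript
#' compatible-read sets: at each step the pair of active clusters with
#' maximal Jaccard index (intersection over union) is merged, the merged
#' cluster taking the union of the read sets. Transcripts sharing many
#' reads therefore obtain a low common ancestor, so the induced
#' transformation mirrors the subcompositional independence structure of
#' the data. Ties are broken by the lexicographically smallest
#' (min transcript index, max transcript index) pair; pairs with Jaccard 0
#' are merged only after all positive-similarity merges are exhausted, in
#' cluster-index order (producing a left-deep caterpillar over the
#' remaining groups). Only cluster pairs sharing at least one read are ever
#' scored, which leaves the result unchanged (cross-group Jaccard is 0)
#' while avoiding the full quadratic pair scan.
#'
#' @param sets list of per-transcript read-index sets, as from
#'   [compat_sets], or a [read_compat] object.
#' @return a canonical [polya_tree].
#' @export
jaccard_cluster_tree <- function(sets) {
  if (inherits(sets, "read_compat")) sets <- compat_sets(sets)
  n <- length(sets)
  if (n == 1L) return(polya_tree(integer(0), integer(0), 1L))
  # cluster state; node ids: 1..n leaves, then internal ids as created
  cl_sets <- sets
  cl_min <- seq_len(n)          # smallest transcript index in cluster
  cl_node <- seq_len(n)         # tree-builder node id
  alive <- rep(TRUE, n)
  kids <- vector("list", 2L * n - 1L)
  leaf_transcript <- c(seq_len(n), rep(NA_integer_, n - 1L))
  next_node <- n + 1L

  merge_pair <- function(a, b) {
    # a, b are cluster slots; left child = smaller min transcript index
    if (cl_min[b] < cl_min[a]) { tmp <- a; a <- b; b <- tmp }
    kids[[next_node]] <<- c(cl_node[a], cl_node[b])
    cl_sets[[a]] <<- sort(unique(c(cl_sets[[a]], cl_sets[[b]])))
    cl_node[a] <<- next_node
    alive[b] <<- FALSE
    next_node <<- next_node + 1L
    a
  }

  # positive-similarity phase
  repeat {
    act <- which(alive)
    if (length(act) <= 1L) break
    # candidate pairs: clusters sharing at least one read
    by_read <- split(rep(act, lengths(cl_sets[act])),
                     unlist(cl_sets[act], use.names = FALSE))
    pairs <- unique(do.call(rbind, lapply(by_read, function(cs) {
      cs <- sort(unique(cs))
      if (length(cs) < 2L) return(NULL)
      t(utils::combn(cs, 2L))
    })))
    if (is.null(pairs) || nrow(pairs) == 0L) break
    jac <- vapply(seq_len(nrow(pairs)), function(k) {
      jaccard_index(cl_sets[[pairs[k, 1L]]], cl_sets[[pairs[k, 2L]]])
    }, numeric(1L))
    best <- max(jac)
    if (best <= 0) break
    cand <- which(jac == best)
    key_lo <- pmin(cl_min[pairs[cand, 1L]], cl_min[pairs[cand, 2L]])
    key_hi <- pmax(cl_min[pairs[cand, 1L]], cl_min[pairs[cand, 2L]])
    pick <- cand[order(key_lo, key_hi)][1L]
    merge_pair(pairs[pick, 1L], pairs[pick, 2L])
  }
  # zero-similarity phase: left-deep merge in min-transcript-index order
  act <- which(alive)
  act <- act[order(cl_min[act])]
  while (length(act) > 1L) {
    keep <- merge_pair(act[1L], act[2L])
    act <- c(keep, act[-(1:2)])
  }
  canonicalize_tree(cl_node[act], kids, leaf_transcript, n)
}

#' Sequential or random baseline tree
#'
#' `sequential` builds the caterpillar tree whose i-th break splits off
#' transcript i from the rest, so the induced transformation equals the
#' multiplicative log-ratio (mlr) after a logit. `random` draws a uniform
#' full binary topology (Remy's algorithm) with a uniformly permuted leaf
#' labeling, reproducible from `seed`.
#'
#' @param n transcript count.
#' @param kind `"sequential"` or `"random"`.
#' @param seed integer seed (random trees only).
#' @return a canonical [polya_tree].
#' @export
baseline_tree <- function(n, kind = c("sequential", "random"), seed = 1L) {
  kind <- match.arg(kind)
  if (n == 1L) return(polya_tree(integer(0), integer(0), 1L))
  if (kind == "sequential") {
    # internal node i has left child = leaf for transcript i,
    # right child = internal node i+1 (or final leaf)
    left <- integer(n - 1L)
    right <- integer(n - 1L)
    # pre-order numbering: internal i gets number i; leaves numbered in
    # encounter order n, n+1, ... => leaf for transcript i is node n+i-1
    for (i in seq_len(n - 1L)) {
      left[i] <- n + i - 1L
      right[i] <- if (i < n - 1L) i + 1L else 2L * n - 1L
    }
    return(polya_tree(left, right, seq_len(n)))
  }
  set.seed(seed)
  # Remy's algorithm on child-pointer lists
  kids <- vector("list", 2L * n - 1L)
  leaf_transcript <- rep(NA_integer_, 2L * n - 1L)
  leaf_transcript[1L] <- 1L
  root <- 1L
  nodes <- 1L          # ids in use
  parent <- rep(NA_integer_, 2L * n - 1L)
  side <- rep(NA_integer_, 2L * n - 1L)
  for (k in 2L:n) {
    v <- sample(nodes, 1L)
    s <- sample(2L, 1L)
    internal <- nodes + 1L
    leaf <- nodes + 2L
    leaf_transcript[leaf] <- k
    kids[[internal]] <- if (s == 1L) c(leaf, v) else c(v, leaf)
    if (is.na(parent[v])) {
      root <- internal
    } else {
      kids[[parent[v]]][side[v]] <- internal
      parent[internal] <- parent[v]
      side[internal] <- side[v]
    }
    parent[v] <- internal
    side[v] <- if (s == 1L) 2L else 1L
    parent[leaf] <- internal
    side[leaf] <- if (s == 1L) 1L else 2L
    nodes <- nodes + 2L
  }
  # uniform leaf relabeling
  perm <- sample(n)
  leaf_transcript[!is.na(leaf_transcript)] <-
    perm[leaf_transcript[!is.na(leaf_transcript)]]
  canonicalize_tree(root, kids, leaf_transcript, n)
}
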