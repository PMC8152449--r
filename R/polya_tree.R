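#' Polya tree data structure
#'
#' A Polya tree is a full binary tree with `n` leaves (2n-1 nodes in total)
#' that defines a hierarchical stick-breaking bijection between break
#' fractions in (0,1)^(n-1) and the open unit simplex. Nodes are numbered so
#' that the root is node 1, internal nodes are 1..n-1 and leaves are
#' n..2n-1, with every node's index strictly greater than its parent's
#' (e.g. a pre-order numbering). `leaf_to_transcript` maps leaf k (node
#' n-1+k) to the transcript whose expression that leaf's stick piece holds.
#'
#' @param left,right integer vectors of length `n-1`; `left[i]` / `right[i]`
#'   give the node index of internal node `i`'s children. Empty for `n = 1`.
#' @param leaf_to_transcript integer permutation of `1:n`; entry `k` is the
#'   transcript index assigned to leaf node `n-1+k`.
#' @return an object of class `polya_tree` with fields `n`, `left`, `right`,
#'   `leaf_to_transcript`.
#' @examples
#' tr <- polya_tree(left = 2L, right = 3L, leaf_to_transcript = 1:2)
#' ptt_forward(tr, 0.25)$x
#' @export
polya_tree <- function(left, right, leaf_to_transcript) {
  left <- as.integer(left)
  right <- as.integer(right)
  leaf_to_transcript <- as.integer(leaf_to_transcript)
  n <- length(leaf_to_transcript)
  tree <- structure(
    list(n = n, left = left, right = right,
         leaf_to_transcript = leaf_to_transcript),
    class = "polya_tree")
  validate_polya_tree(tree)
  tree
}

#' Validate a Polya tree
#'
#' Checks the structural invariants: 2n-1 nodes, internal nodes 1..n-1,
#' leaves n..2n-1, each non-root node the child of exactly one internal
#' node, child indices strictly greater than their parent's, and
#' `leaf_to_transcript` a permutation.
#'
#' @param tree a `polya_tree`.
#' @return `tree`, invisibly; stops with an informative error otherwise.
#' @export
validate_polya_tree <- function(tree) {
  n <- tree$n
  if (n < 1L) stop("polya_tree: need at least one leaf")
  if (!setequal(tree$leaf_to_transcript, seq_len(n))) {
    stop("polya_tree: leaf_to_transcript must be a permutation of 1..n")
  }
  if (n == 1L) {
    if (length(tree$left) != 0L || length(tree$right) != 0L) {
      stop("polya_tree: n = 1 tree must have no internal nodes")
    }
    return(invisible(tree))
  }
  if (length(tree$left) != n - 1L || length(tree$right) != n - 1L) {
    stop("polya_tree: left/right must have length n - 1")
  }
  kids <- c(tree$left, tree$right)
  if (any(is.na(kids)) || !setequal(kids, 2:(2L * n - 1L)) ||
      length(kids) != length(unique(kids))) {
    stop("polya_tree: children must cover nodes 2..2n-1 exactly once")
  }
  parent_idx <- rep(seq_len(n - 1L), 2L)
  if (any(kids <= parent_idx)) {
    stop("polya_tree: every child index must exceed its parent's index")
  }
  invisible(tree)
}

#' Forward Polya tree transformation
#'
#' Maps an initial stick length `u1` and break fractions `y` to `n` stick
#' pieces by a top-down traversal: node `i` splits its stick `u_i` into
#' `y_i * u_i` (left child) and `(1 - y_i) * u_i` (right child). Leaf
#' pieces, read out through `leaf_to_transcript`, form the output vector;
#' with `u1 = 1` the result lies on the open unit simplex.
#'
#' @param tree a `polya_tree` with `n` leaves.
#' @param y numeric vector of `n-1` break fractions, each in (0,1).
#' @param u1 initial stick length (default 1).
#' @return list with `x` (length-`n` result) and `u` (length `2n-1`
#'   intermediate stick lengths, one per node).
#' @export
ptt_forward <- function(tree, y, u1 = 1) {
  n <- tree$n
  if (length(y) != n - 1L) stop("ptt_forward: y must have length n - 1")
  if (u1 <= 0) stop("ptt_forward: u1 must be positive")
  if (n > 1L && (any(y <= 0) || any(y >= 1))) {
    stop("ptt_forward: break fractions must lie strictly in (0,1)")
  }
  u <- numeric(2L * n - 1L)
  u[1L] <- u1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      u[tree$left[i]] <- y[i] * u[i]
      u[tree$right[i]] <- (1 - y[i]) * u[i]
    }
  }
  x <- numeric(n)
  x[tree$leaf_to_transcript] <- u[n:(2L * n - 1L)]
  list(x = x, u = u)
}

#' Inverse Polya tree transformation
#'
#' Reconstructs intermediate stick lengths bottom-up (children sum to their
#' parent) and recovers each break fraction as `y_i = u_left(i) / u_i`.
#'
#' @param tree a `polya_tree`.
#' @param x strictly positive vector of `n` stick pieces (need not sum to 1;
#'   the implied initial length is `sum(x)`).
#' @return list with `y` (break fractions), `u` (intermediate values) and
#'   `u1 = sum(x)`.
#' @export
ptt_inverse <- function(tree, x) {
  n <- tree$n
  if (length(x) != n) stop("ptt_inverse: x must have length n")
  if (any(x <= 0)) stop("ptt_inverse: x must be strictly positive")
  u <- numeric(2L * n - 1L)
  u[(n):(2L * n - 1L)] <- x[tree$leaf_to_transcript]
  y <- numeric(max(n - 1L, 0L))
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      u[i] <- u[tree$left[i]] + u[tree$right[i]]
      y[i] <- u[tree$left[i]] / u[i]
    }
  } else {
    u[1L] <- x
  }
  list(y = y, u = u, u1 = u[1L])
}

#' Log absolute Jacobian determinant of the Polya tree transformation
#'
#' For the general map (u1, y) -> x the absolute Jacobian determinant is the
#' product of the internal-node intermediate values, so its log is
#' `sum(log(u[1:(n-1)]))`. For `n = 1` the map is the identity and the
#' log-determinant is 0.
#'
#' @param u intermediate values from [ptt_forward] or [ptt_inverse].
#' @param n leaf count.
#' @return the log absolute Jacobian determinant.
#' @export
ptt_log_jacobian <- function(u, n) {
  if (n <= 1L) return(0)
  sum(log(u[seq_len(n - 1L)]))
}

#' Sample from the HierarchicalBeta family
#'
#' Pushes independent Beta-distributed break fractions through a Polya tree
#' transformation. The Beta parameters at internal node `i` are the sums of
#' the leaf intensities `alpha` under its left and right subtrees. By the
#' Dirichlet-equivalence theorem the resulting distribution is
#' `Dirichlet(alpha)` for every valid tree topology, which makes this an
#' exact sampler in the zero-read-ambiguity regime where the normalized
#' likelihood is itself Dirichlet.
#'
#' @param tree a `polya_tree`.
#' @param alpha positive intensity per transcript (length `n`).
#' @param count number of draws.
#' @param seed integer RNG seed (optional; uses the current RNG state when
#'   `NULL`).
#' @return a `count x n` matrix of simplex points.
#' @export
hierarchical_beta_sample <- function(tree, alpha, count, seed = NULL) {
  n <- tree$n
  if (length(alpha) != n || any(alpha <= 0)) {
    stop("hierarchical_beta_sample: alpha must be positive and length n")
  }
  if (!is.null(seed)) set.seed(seed)
  if (n == 1L) return(matrix(1, nrow = count, ncol = 1L))
  # subtree intensity sums, bottom-up
  a <- numeric(2L * n - 1L)
  a[n:(2L * n - 1L)] <- alpha[tree$leaf_to_transcript]
  for (i in (n - 1L):1L) {
    a[i] <- a[tree$left[i]] + a[tree$right[i]]
  }
  al <- a[tree$left]
  ar <- a[tree$right]
  x <- matrix(0, nrow = count, ncol = n)
  u <- matrix(0, nrow = count, ncol = 2L * n - 1L)
  u[, 1L] <- 1
  y <- matrix(stats::rbeta(count * (n - 1L),
                           shape1 = rep(al, each = count),
                           shape2 = rep(ar, each = count)),
              nrow = count)
  for (i in seq_len(n - 1L)) {
    u[, tree$left[i]] <- y[, i] * u[, i]
    u[, tree$right[i]] <- (1 - y[, i]) * u[, i]
  }
  x[, tree$leaf_to_transcript] <- u[, n:(2L * n - 1L)]
  x
}

# Canonicalize an arbitrary full binary tree given as child pointers.
#
# `kids` is a list indexed by arbitrary node ids; internal ids map to an
# integer vector c(left_id, right_id), leaf ids to NULL. `leaf_transcript`
# maps node id -> transcript index for leaves. Returns a polya_tree with
# pre-order numbering (internal nodes 1..n-1 in pre-order, leaves numbered
# n..2n-1 in encounter order).
canonicalize_tree <- function(root, kids, leaf_transcript, n) {
  if (n == 1L) {
    return(polya_tree(integer(0), integer(0), 1L))
  }
  left <- integer(n - 1L)
  right <- integer(n - 1L)
  leaf_to_transcript <- integer(n)
  next_internal <- 1L
  next_leaf <- n
  # manual stack-based pre-order with deferred right-child numbering
  stack <- list(list(id = root, parent = NA_integer_, side = NA_character_))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    id <- fr$id
    ch <- kids[[id]]
    if (is.null(ch)) {
      num <- next_leaf
      next_leaf <- next_leaf + 1L
      leaf_to_transcript[num - (n - 1L)] <- leaf_transcript[[id]]
    } else {
      num <- next_internal
      next_internal <- next_internal + 1L
    }
    if (!is.na(fr$parent)) {
      if (fr$side == "left") left[fr$parent] <- num else right[fr$parent] <- num
    }
    if (!is.null(ch)) {
      # push right first so left is popped (and numbered) first
      stack[[length(stack) + 1L]] <- list(id = ch[2L], parent = num,
                                          side = "right")
      stack[[length(stack) + 1L]] <- list(id = ch[1L], parent = num,
                                          side = "left")
    }
  }
  polya_tree(left, right, leaf_to_transcript)
}

#' @export
print.polya_tree <- function(x, ...) {
  cat(sprintf("Polya tree: %d leaves, %d nodes\n", x$n, 2L * x$n - 1L))
  invisible(x)
}
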