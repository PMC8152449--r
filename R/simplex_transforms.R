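#' Additive log-ratio transformation
#'
#' `alr(x)_i = log(x_i / x_d)` for a fixed divisor component `d`
#' (default the last). A bijection from the open simplex to R^(n-1); the
#' inverse is a softmax with the divisor's coordinate pinned at zero.
#'
#' @param x strictly positive composition (length `n`, typically on the
#'   simplex).
#' @param divisor_index index of the divisor component, in `1..n`.
#' @return numeric vector of length `n - 1`.
#' @export
alr <- function(x, divisor_index = length(x)) {
  check_positive_composition(x)
  d <- as.integer(divisor_index)
  if (d < 1L || d > length(x)) stop("alr: divisor_index out of range")
  log(x[-d] / x[d])
}

#' Inverse additive log-ratio transformation
#'
#' @param v real coordinates of length `n - 1`.
#' @param divisor_index index of the divisor component in the output.
#' @return a point on the open unit simplex of length `n = length(v) + 1`.
#' @export
alr_inv <- function(v, divisor_index = length(v) + 1L) {
  n <- length(v) + 1L
  d <- as.integer(divisor_index)
  if (d < 1L || d > n) stop("alr_inv: divisor_index out of range")
  w <- numeric(n)
  w[-d] <- v
  # softmax with a fixed zero at the divisor, stabilized
  w <- w - max(w)
  e <- exp(w)
  e / sum(e)
}

#' Multiplicative log-ratio transformation
#'
#' `mlr(x)_i = log(x_i / (1 - sum_{j<=i} x_j))`: the log-ratio of each stick
#' piece to what remains of the stick after it is broken off, i.e. the logit
#' of the sequential stick-breaking break fractions.
#'
#' @param x strictly positive point on the open unit simplex.
#' @return numeric vector of length `n - 1`.
#' @export
mlr <- function(x) {
  check_positive_composition(x, simplex = TRUE)
  n <- length(x)
  rem <- 1 - cumsum(x[seq_len(n - 1L)])
  log(x[seq_len(n - 1L)] / rem)
}

#' Inverse multiplicative log-ratio transformation
#'
#' @param v real coordinates of length `n - 1`.
#' @return a point on the open unit simplex.
#' @export
mlr_inv <- function(v) {
  n <- length(v) + 1L
  y <- stats::plogis(v)  # sequential break fractions
  x <- numeric(n)
  rem <- 1
  for (i in seq_len(n - 1L)) {
    x[i] <- y[i] * rem
    rem <- rem - x[i]
  }
  x[n] <- rem
  x
}

# Balanced full binary tree over leaves 1..n: recursively split
# ceiling(k/2) | floor(k/2). Returns the sign/basis bookkeeping used by the
# balanced ilr: a list of splits, each with left and right leaf index sets.
balanced_splits <- function(n) {
  splits <- list()
  recurse <- function(leaves) {
    k <- length(leaves)
    if (k == 1L) return(invisible(NULL))
    h <- ceiling(k / 2)
    l <- leaves[seq_len(h)]
    r <- leaves[(h + 1L):k]
    splits[[length(splits) + 1L]] <<- list(left = l, right = r)
    recurse(l)
    recurse(r)
    invisible(NULL)
  }
  recurse(seq_len(n))
  splits
}

# Orthonormal contrast matrix (n x (n-1)) for the balanced-tree ilr basis.
ilr_basis_matrix <- function(n) {
  splits <- balanced_splits(n)
  V <- matrix(0, nrow = n, ncol = n - 1L)
  for (i in seq_along(splits)) {
    l <- splits[[i]]$left
    r <- splits[[i]]$right
    rs <- length(l)
    ss <- length(r)
    V[l, i] <- sqrt(ss / (rs * (rs + ss)))
    V[r, i] <- -sqrt(rs / (ss * (rs + ss)))
  }
  V
}

#' Isometric log-ratio transformation (balanced-tree basis)
#'
#' Orthonormal balance coordinates built from a balanced full binary tree
#' over the components: the coordinate for a split with left leaf set L
#' (size r) and right leaf set R (size s) is
#' `sqrt(rs/(r+s)) * log(g(x_L)/g(x_R))` with `g` the geometric mean. The
#' transformation is an isometry between the Aitchison geometry on the
#' simplex and Euclidean R^(n-1); the balanced tree is the single supported
#' basis.
#'
#' @param x strictly positive point on the open unit simplex.
#' @return numeric vector of length `n - 1`.
#' @export
ilr_balanced <- function(x) {
  check_positive_composition(x, simplex = TRUE)
  V <- ilr_basis_matrix(length(x))
  as.vector(crossprod(V, log(x)))
}

#' Inverse isometric log-ratio transformation (balanced-tree basis)
#'
#' @param v real coordinates of length `n - 1`.
#' @return a point on the open unit simplex.
#' @export
ilr_balanced_inv <- function(v) {
  n <- length(v) + 1L
  V <- ilr_basis_matrix(n)
  w <- as.vector(V %*% v)
  w <- w - max(w)
  e <- exp(w)
  e / sum(e)
}

#' Aitchison distance between two compositions
#'
#' The Euclidean distance between centered log-ratio images; equals the
#' Euclidean distance between ilr coordinates for any orthonormal basis.
#'
#' @param x,y strictly positive compositions of equal length.
#' @return nonnegative real.
#' @export
aitchison_dist <- function(x, y) {
  clr <- function(z) log(z) - mean(log(z))
  sqrt(sum((clr(x) - clr(y))^2))
}

check_positive_composition <- function(x, simplex = FALSE) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("composition must be strictly positive and finite")
  }
  if (simplex && abs(sum(x) - 1) > 1e-6) {
    stop("composition must sum to 1")
  }
  invisible(x)
}
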