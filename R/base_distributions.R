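#' Mean-field base distribution parameters
#'
#' Bundles the per-break parameters of a mean-field distribution on
#' (0,1)^(n-1) that is pushed through a simplex transformation. Three
#' families are supported, all admitting the reparameterization trick:
#'
#' * `logit_normal`: `y = logistic(mu + sigma * z)`, `z ~ Normal(0,1)`.
#' * `logit_skew_normal`: `y = logistic(mu + sigma * sinh(skew +
#'   asinh(z)))`; the one-parameter sinh-arcsinh map adds a skewness
#'   control and reduces exactly to `logit_normal` at `skew = 0`.
#' * `kumaraswamy`: `y = (1 - (1-u)^(1/b))^(1/a)`, `u ~ Uniform(0,1)`; a
#'   Beta-like family with closed-form quantile function.
#'
#' @param family one of `"logit_normal"`, `"logit_skew_normal"`,
#'   `"kumaraswamy"`.
#' @param mu,sigma location and positive scale on the logit scale (normal
#'   families), length `n-1`.
#' @param skew sinh-arcsinh skewness (logit_skew_normal only).
#' @param kum_a,kum_b positive Kumaraswamy shapes (kumaraswamy only).
#' @return an object of class `base_params`.
#' @export
base_params <- function(family = c("logit_normal", "logit_skew_normal",
                                   "kumaraswamy"),
                        mu = NULL, sigma = NULL, skew = NULL,
                        kum_a = NULL, kum_b = NULL) {
  family <- match.arg(family)
  if (family == "kumaraswamy") {
    if (is.null(kum_a) || is.null(kum_b)) {
      stop("base_params: kumaraswamy requires kum_a and kum_b")
    }
    if (length(kum_a) != length(kum_b)) stop("base_params: length mismatch")
    if (any(kum_a <= 0) || any(kum_b <= 0)) {
      stop("base_params: kum_a and kum_b must be positive")
    }
    d <- length(kum_a)
    p <- list(family = family, d = d, kum_a = as.numeric(kum_a),
              kum_b = as.numeric(kum_b))
  } else {
    if (is.null(mu) || is.null(sigma)) {
      stop("base_params: normal families require mu and sigma")
    }
    if (length(mu) != length(sigma)) stop("base_params: length mismatch")
    if (any(sigma <= 0)) stop("base_params: sigma must be positive")
    d <- length(mu)
    if (family == "logit_skew_normal") {
      if (is.null(skew)) skew <- numeric(d)
      if (length(skew) != d) stop("base_params: length mismatch")
    } else {
      skew <- NULL
    }
    p <- list(family = family, d = d, mu = as.numeric(mu),
              sigma = as.numeric(sigma), skew = as.numeric(skew))
    if (family == "logit_normal") p$skew <- NULL
  }
  structure(p, class = "base_params")
}

# clamp to the open interval used throughout the package
clamp01 <- function(y, eps = 1e-12) pmin(pmax(y, eps), 1 - eps)

#' Reparameterized sampling from a base distribution
#'
#' Deterministically maps raw draws (standard normal for the two normal
#' families, uniform for Kumaraswamy) to break fractions in (0,1)^(n-1).
#' Being a deterministic, differentiable function of the parameters given
#' the raw draws, this is the reparameterization used for pathwise
#' gradients of expectations.
#'
#' @param params a [base_params] object.
#' @param base_draw numeric vector of length `n-1`, or a `draws x (n-1)`
#'   matrix of raw draws.
#' @return break fractions with the same shape as `base_draw`, clamped to
#'   `[1e-12, 1 - 1e-12]`.
#' @export
reparam_sample <- function(params, base_draw) {
  stopifnot(inherits(params, "base_params"))
  is_mat <- is.matrix(base_draw)
  z <- if (is_mat) base_draw else matrix(base_draw, nrow = 1L)
  if (ncol(z) != params$d) stop("reparam_sample: dimension mismatch")
  y <- switch(params$family,
    logit_normal = stats::plogis(sweep(sweep(z, 2L, params$sigma, `*`),
                                       2L, params$mu, `+`)),
    logit_skew_normal = {
      g <- sinh(sweep(asinh(z), 2L, params$skew, `+`))
      stats::plogis(sweep(sweep(g, 2L, params$sigma, `*`),
                          2L, params$mu, `+`))
    },
    kumaraswamy = {
      t <- exp(sweep(log1p(-z), 2L, params$kum_b, `/`))
      exp(sweep(log1p(-t), 2L, params$kum_a, `/`))
    })
  y <- clamp01(y)
  if (is_mat) y else as.vector(y)
}

#' Draw raw reparameterization noise for a family
#'
#' @param params a [base_params] object.
#' @param count number of draws.
#' @return `count x (n-1)` matrix of standard-normal (normal families) or
#'   uniform (Kumaraswamy) raw draws.
#' @export
base_raw_draws <- function(params, count) {
  d <- params$d
  if (params$family == "kumaraswamy") {
    matrix(stats::runif(count * d), nrow = count)
  } else {
    matrix(stats::rnorm(count * d), nrow = count)
  }
}

# Per-coordinate log-density matrix (same shape as y).
base_log_density_terms <- function(params, y) {
  is_mat <- is.matrix(y)
  ym <- if (is_mat) y else matrix(y, nrow = 1L)
  if (ncol(ym) != params$d) stop("log density: dimension mismatch")
  if (any(ym <= 0) || any(ym >= 1)) {
    stop("log density: y must lie strictly in (0,1)")
  }
  ld <- switch(params$family,
    logit_normal = {
      w <- stats::qlogis(ym)
      zz <- sweep(sweep(w, 2L, params$mu, `-`), 2L, params$sigma, `/`)
      sweep(stats::dnorm(zz, log = TRUE), 2L, log(params$sigma), `-`) -
        log(ym) - log1p(-ym)
    },
    logit_skew_normal = {
      w <- stats::qlogis(ym)
      t <- sweep(sweep(w, 2L, params$mu, `-`), 2L, params$sigma, `/`)
      arg <- sweep(asinh(t), 2L, params$skew, `-`)
      zz <- sinh(arg)
      # dz/dt = cosh(asinh(t) - skew) / sqrt(1 + t^2)
      ljac <- log(cosh(arg)) - 0.5 * log1p(t^2)
      sweep(stats::dnorm(zz, log = TRUE) + ljac, 2L, log(params$sigma), `-`) -
        log(ym) - log1p(-ym)
    },
    kumaraswamy = {
      a <- params$kum_a
      b <- params$kum_b
      la <- sweep(log(ym), 2L, a, `*`)        # log(y^a)
      sweep(sweep(log(ym), 2L, a - 1, `*`), 2L, log(a) + log(b), `+`) +
        sweep(log1p(-exp(la)), 2L, b - 1, `*`)
    })
  if (is_mat) ld else as.vector(ld)
}

#' Log-density of a base distribution
#'
#' Exact density on (0,1)^(n-1) obtained by change of variables (normal
#' density with logit and sinh-arcsinh Jacobians for the normal families;
#' the closed-form Kumaraswamy pdf `a b y^(a-1) (1 - y^a)^(b-1)`), summed
#' over the independent coordinates.
#'
#' @param params a [base_params] object.
#' @param y break fractions strictly inside (0,1); vector or `draws x (n-1)`
#'   matrix.
#' @return the total log-density (scalar for a vector `y`, one value per row
#'   for a matrix).
#' @export
base_log_density <- function(params, y) {
  ld <- base_log_density_terms(params, y)
  if (is.matrix(ld)) rowSums(ld) else sum(ld)
}
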