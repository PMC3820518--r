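#' Generalized coordinates of motion
#'
#' A generalized vector represents a quantity together with its temporal
#' derivatives up to an embedding order: order 0 is the value, order 1 the
#' velocity, and so on.  Internally generalized quantities are stored as
#' (order + 1) x dim matrices, row k + 1 holding the k-th derivative; stacked
#' vectors use order-major ordering so that Kronecker-structured operators
#' (derivative correlations x component precision) apply directly.
#'
#' @param orders numeric matrix (or list of equal-length vectors), one row
#'   (element) per derivative order starting at order 0.
#' @return an object of class \code{generalized_vector}.
#' @export
generalized_vector <- function(orders) {
  if (is.list(orders)) {
    d <- lengths(orders)
    if (length(unique(d)) != 1L)
      stop("all derivative orders must have identical dimension")
    orders <- do.call(rbind, orders)
  }
  orders <- as.matrix(orders)
  if (!is.numeric(orders) || nrow(orders) < 1L)
    stop("need at least the order-0 value")
  if (any(!is.finite(orders))) stop("non-finite generalized coordinates")
  structure(list(orders = orders, embedding_order = nrow(orders) - 1L,
                 dim = ncol(orders)),
            class = "generalized_vector")
}

#' @export
print.generalized_vector <- function(x, ...) {
  cat(sprintf("Generalized vector: dim %d, embedding order %d\n",
              x$dim, x$embedding_order))
  rownames(x$orders) <- paste0("d", seq_len(nrow(x$orders)) - 1L)
  print(x$orders, ...)
  invisible(x)
}

## Block shift operator D on a stacked generalized vector: maps the stack of
## derivatives to the stack of their derivatives (order k <- order k + 1, top
## order annihilated).
shift_operator <- function(n_orders, dim = 1L) {
  S <- matrix(0, n_orders, n_orders)
  if (n_orders > 1L) S[cbind(seq_len(n_orders - 1L), seq_len(n_orders - 1L) + 1L)] <- 1
  if (dim == 1L) S else kronecker(S, diag(dim))
}

## Taylor design matrix for samples at offsets o (in units of dt) around the
## expansion point; least-squares inverse gives the embedding weights that map
## local samples to derivative estimates.
embedding_weights <- function(offsets, dt, order) {
  n <- order + 1L
  if (length(offsets) < n) stop("need at least order + 1 samples to embed")
  t_off <- offsets * dt
  Tm <- outer(t_off, 0:order, function(h, k) h^k / factorial(k))
  ## exact for polynomials up to `order`; least squares if over-determined
  if (length(offsets) == n) solve(Tm) else
    solve(crossprod(Tm), t(Tm))
}

#' Embed a sampled signal in generalized coordinates
#'
#' Estimates the value and first \code{order} temporal derivatives of a
#' uniformly sampled signal at one sample index, by a local polynomial
#' (Taylor) fit over a window of neighbouring samples.  Exact for polynomial
#' signals of degree \code{<= order}.
#'
#' @param y numeric vector or matrix (time along rows).
#' @param at sample index (1-based) at which to embed.
#' @param order embedding order (number of derivatives).
#' @param dt sampling interval.
#' @return \code{generalized_vector} with \code{order + 1} rows.
#' @export
embed_signal <- function(y, at, order, dt = 1) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < order + 1L) stop("insufficient samples for requested embedding order")
  half <- order %/% 2L
  lo <- at - half
  lo <- max(1L, min(lo, n - order))     # clamp window at the boundaries
  idx <- lo:(lo + order)
  W <- embedding_weights(idx - at, dt, order)
  generalized_vector(W %*% y[idx, , drop = FALSE])
}

## double factorial (2k-1)!! with (-1)!! = 1
double_factorial_odd <- function(k) {
  if (k == 0L) return(1)
  prod(seq(1, 2 * k - 1, by = 2))
}

#' Covariance of generalized coordinates under smooth noise
#'
#' For a stationary unit-variance process whose autocorrelation is Gaussian
#' with width \code{sigma}, returns the covariance among its derivatives of
#' order 0..\code{order} at a fixed time.  Odd-order cross terms vanish;
#' even moments follow from the derivatives of the autocorrelation at lag 0.
#'
#' @param order highest derivative order.
#' @param sigma autocorrelation width (time units), > 0.
#' @return (order + 1) x (order + 1) positive-definite matrix.
#' @export
smoothness_covariance <- function(order, sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  n <- order + 1L
  C <- matrix(0, n, n)
  for (i in 0:order) for (j in 0:order) {
    m <- i + j
    if (m %% 2L == 0L) {
      k <- m %/% 2L
      C[i + 1L, j + 1L] <- (-1)^j * (-1)^k * double_factorial_odd(k) / sigma^m
    }
  }
  C
}

#' Generalized precision with Kronecker structure
#'
#' Builds the precision of a generalized random vector whose components have
#' precision matrix \code{Pi} and whose temporal roughness is set by a
#' Gaussian autocorrelation of width \code{sigma}:
#' \code{solve(smoothness_covariance(order, sigma)) \%x\% Pi}.
#'
#' @param Pi component precision matrix (or scalar / vector of diagonal
#'   precisions).
#' @param order embedding order.
#' @param sigma noise autocorrelation width.
#' @return list with the full generalized precision \code{Pi_gen}, the
#'   derivative-correlation precision factor \code{R} and inputs, classed
#'   \code{temporal_precision}.
#' @export
temporal_precision <- function(Pi, order, sigma) {
  if (is.vector(Pi)) Pi <- diag(Pi, nrow = length(Pi))
  if (any(diag(Pi) <= 0)) stop("precisions must be positive")
  C <- smoothness_covariance(order, sigma)
  R <- solve(C)
  R <- (R + t(R)) / 2
  P <- kronecker(R, Pi)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("generalized precision is not positive definite")
  structure(list(Pi_gen = P, R = R, Pi = Pi, order = order, sigma = sigma),
            class = "temporal_precision")
}
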