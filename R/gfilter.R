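#' Generalized filtering: online inversion of hierarchical dynamic models
#'
#' The recognition engine integrates the belief dynamics
#' \deqn{\dot{\tilde\mu} = D\tilde\mu - \partial_{\tilde\mu}
#'   \tfrac12 \tilde\varepsilon^\top \tilde\Pi \tilde\varepsilon}
#' where \eqn{D} is the block-shift (derivative) operator on generalized
#' coordinates and \eqn{\tilde\varepsilon} collects sensory, state-motion and
#' cause prediction errors weighted by their generalized precisions.  Posterior
#' expectations follow a mixture of prior prediction (the \eqn{D\tilde\mu}
#' term) and gradient descent on precision-weighted prediction error.
#'
#' @name gfilter
NULL

## ---- generic filter-model interface ---------------------------------------
## A gf_model bundles everything the filter needs; auditory_hdm objects are
## converted by as_gf_model().  n_x = 0 describes a static model (no hidden
## states), used e.g. for conjugate-Gaussian oracle checks.

#' Build a filter model
#'
#' Low-level constructor for the model object consumed by
#' \code{\link{gf_step}} / \code{\link{filter_run}}.  Most users should pass
#' an \code{\link{auditory_hdm}} to \code{\link{filter_run}} directly.
#'
#' @param g observation function \code{g(x, v)}; \code{gx}, \code{gv} its
#'   Jacobians (functions of x, v).
#' @param f flow function and \code{fx}, \code{fv} Jacobians; NULL if
#'   \code{n_x = 0}.
#' @param n_x,n_v,n_y dimensions of hidden states, causes, data.
#' @param Pi_y,Pi_x,Pi_v component precisions (vectors of diagonal entries or
#'   matrices); \code{Pi_v} is the prior precision on the causes.
#' @param eta function of time returning the generalized prior mean of the
#'   causes as an (order_causes + 1) x n_v matrix.
#' @param order_states,order_causes embedding orders.
#' @param smoothness noise autocorrelation width shared by all streams.
#' @param dt integration step.
#' @return object of class \code{gf_model}.
#' @export
gf_model <- function(g, gx, gv, f = NULL, fx = NULL, fv = NULL,
                     n_x, n_v, n_y, Pi_y, Pi_x = NULL, Pi_v,
                     eta, order_states = 4L, order_causes = 2L,
                     smoothness = 2, dt = 1) {
  ny1 <- order_states + 1L
  nv1 <- order_causes + 1L
  Py <- temporal_precision(Pi_y, order_states, smoothness)
  Pv <- temporal_precision(Pi_v, order_causes, smoothness)
  Px <- if (n_x > 0L) temporal_precision(Pi_x, order_states, smoothness) else NULL
  ## selector mapping cause orders into state/data orders (truncation)
  Tsel <- matrix(0, ny1, nv1)
  diag(Tsel) <- 1
  m <- list(g = g, gx = gx, gv = gv, f = f, fx = fx, fv = fv,
            n_x = n_x, n_v = n_v, n_y = n_y,
            order_states = order_states, order_causes = order_causes,
            smoothness = smoothness, dt = dt,
            Py = Py, Px = Px, Pv = Pv, Tsel = Tsel,
            eta = eta,
            divergence_bound = 1e8)
  ## block-shift operator on the stacked belief
  Dx <- if (n_x > 0L) shift_operator(ny1, n_x) else NULL
  Dv <- shift_operator(nv1, n_v)
  m$D_u <- if (n_x > 0L) as.matrix(Matrix::bdiag(Dx, Dv)) else Dv
  class(m) <- "gf_model"
  m$P_gen <- gf_precision_blocks(m)   # cached full generalized precision
  m
}

## convert the auditory model (recognition side) into a filter model
as_gf_model <- function(model) {
  stopifnot(inherits(model, "auditory_hdm"))
  cf <- model$config
  jac <- hdm_flow_jacobian(model)
  env <- model$loudness_cause_envelope
  d <- cf$embedding$order_causes
  eta_fun <- function(t) {
    E <- matrix(0, d + 1L, model$n_v)
    for (k in 0:d) E[k + 1L, 1L] <- loudness_cause_deriv(t, env, k)
    E[1L, 2L] <- model$prior_mean_freq
    E
  }
  gf_model(
    g = function(x, v) generate_observation(x, model),
    gx = function(x, v) hdm_obs_jacobian(x, model),
    gv = function(x, v) matrix(0, model$n_y, model$n_v),
    f = function(x, v) hdm_flow(x, v, model),
    fx = function(x, v) jac$fx,
    fv = function(x, v) jac$fv,
    n_x = model$n_x, n_v = model$n_v, n_y = model$n_y,
    Pi_y = rep(exp(model$log_precisions$recognition$obs), model$n_y),
    Pi_x = rep(exp(model$log_precisions$recognition$state), model$n_x),
    Pi_v = c(exp(cf$priors$cause_loudness_logprec), model$prior_precision_freq),
    eta = eta_fun,
    order_states = cf$embedding$order_states,
    order_causes = cf$embedding$order_causes,
    smoothness = model$smoothness,
    dt = cf$grid$dt)
}

## ---- belief state ---------------------------------------------------------

#' Initial belief state
#'
#' Posterior expectations initialized at the prior: order-0 components at the
#' prior means, all derivatives zero.
#'
#' @param gfm a \code{gf_model}.
#' @param t0 time of the first sample.
#' @return object of class \code{belief_state} with generalized expectation
#'   matrices \code{mu_x} and \code{mu_v}.
#' @export
belief_init <- function(gfm, t0 = 0) {
  eta0 <- gfm$eta(t0)
  mu_v <- matrix(0, gfm$order_causes + 1L, gfm$n_v)
  mu_v[1L, ] <- eta0[1L, ]
  mu_x <- NULL
  if (gfm$n_x > 0L) {
    mu_x <- matrix(0, gfm$order_states + 1L, gfm$n_x)
    ## auditory convention: loudness at rest, log-frequency at the prior mean
    if (gfm$n_x >= 3L && gfm$n_v >= 2L) mu_x[1L, 3L] <- eta0[1L, 2L]
  }
  structure(list(mu_x = mu_x, mu_v = mu_v), class = "belief_state")
}

## stack a belief into a single order-major vector, and back
belief_pack <- function(b) c(if (!is.null(b$mu_x)) as.vector(t(b$mu_x)),
                             as.vector(t(b$mu_v)))
belief_unpack <- function(u, gfm) {
  nx <- gfm$n_x * (gfm$order_states + 1L)
  mu_x <- NULL
  if (gfm$n_x > 0L)
    mu_x <- matrix(u[seq_len(nx)], ncol = gfm$n_x, byrow = TRUE)
  mu_v <- matrix(u[(nx + 1L):length(u)], ncol = gfm$n_v, byrow = TRUE)
  structure(list(mu_x = mu_x, mu_v = mu_v), class = "belief_state")
}

## ---- prediction errors ----------------------------------------------------

#' Prediction errors and their precision-weighted forms
#'
#' Computes the three error streams at the current belief: sensory errors
#' (data minus generalized prediction), state-motion errors (shifted state
#' expectations minus the generalized flow) and cause errors (cause
#' expectations minus the generalized prior mean), together with the
#' precision-weighted errors \code{xi = Pi_gen * eps}.
#'
#' @param belief a \code{belief_state}.
#' @param y_t \code{\link{generalized_vector}} of the current sensory sample
#'   (embedding order = the model's state order).
#' @param gfm a \code{gf_model}.
#' @param t current time (for the cause prior mean).
#' @return list with raw errors \code{eps} and weighted errors \code{xi},
#'   each holding matrices \code{y}, \code{x} (NULL for static models) and
#'   \code{v} of dimension orders x components.
#' @export
prediction_errors <- function(belief, y_t, gfm, t = 0) {
  n1 <- gfm$order_states + 1L
  d1 <- gfm$order_causes + 1L
  mu_x <- belief$mu_x
  mu_v <- belief$mu_v
  x0 <- if (gfm$n_x > 0L) mu_x[1L, ] else numeric(0)
  v0 <- mu_v[1L, ]
  gx <- gfm$gx(x0, v0); gv <- gfm$gv(x0, v0)
  ## generalized prediction g~: nonlinear at order 0, linearized above
  G <- matrix(0, n1, gfm$n_y)
  G[1L, ] <- gfm$g(x0, v0)
  for (k in 2:n1) {
    gk <- numeric(gfm$n_y)
    if (gfm$n_x > 0L) gk <- gk + as.numeric(gx %*% mu_x[k, ])
    if (k <= d1) gk <- gk + as.numeric(gv %*% mu_v[k, ])
    G[k, ] <- gk
  }
  Y <- y_t$orders
  if (nrow(Y) != n1) stop("data embedding order must match the model's state order")
  eps_y <- Y - G
  eps_x <- NULL
  if (gfm$n_x > 0L) {
    fx <- gfm$fx(x0, v0); fv <- gfm$fv(x0, v0)
    Fm <- matrix(0, n1, gfm$n_x)
    Fm[1L, ] <- gfm$f(x0, v0)
    for (k in 2:n1) {
      fk <- as.numeric(fx %*% mu_x[k, ])
      if (k <= d1) fk <- fk + as.numeric(fv %*% mu_v[k, ])
      Fm[k, ] <- fk
    }
    Dmu <- rbind(mu_x[-1L, , drop = FALSE], matrix(0, 1L, gfm$n_x))
    eps_x <- Dmu - Fm
  }
  eps_v <- mu_v - gfm$eta(t)
  xi <- list(y = gfm$Py$R %*% eps_y %*% gfm$Py$Pi,
             x = if (gfm$n_x > 0L) gfm$Px$R %*% eps_x %*% gfm$Px$Pi else NULL,
             v = gfm$Pv$R %*% eps_v %*% gfm$Pv$Pi)
  list(eps = list(y = eps_y, x = eps_x, v = eps_v), xi = xi)
}

## error Jacobian d(vec errors)/d(vec belief), order-major stacking
gf_error_jacobian <- function(belief, gfm) {
  n1 <- gfm$order_states + 1L
  d1 <- gfm$order_causes + 1L
  x0 <- if (gfm$n_x > 0L) belief$mu_x[1L, ] else numeric(0)
  v0 <- belief$mu_v[1L, ]
  gx <- gfm$gx(x0, v0); gv <- gfm$gv(x0, v0)
  Jy_v <- -kronecker(gfm$Tsel, gv)
  Iv <- diag(d1 * gfm$n_v)
  if (gfm$n_x > 0L) {
    fx <- gfm$fx(x0, v0); fv <- gfm$fv(x0, v0)
    Jy_x <- -kronecker(diag(n1), gx)
    Jx_x <- shift_operator(n1, gfm$n_x) - kronecker(diag(n1), fx)
    Jx_v <- -kronecker(gfm$Tsel, fv)
    J <- rbind(cbind(Jy_x, Jy_v),
               cbind(Jx_x, Jx_v),
               cbind(matrix(0, d1 * gfm$n_v, n1 * gfm$n_x), Iv))
  } else {
    J <- rbind(Jy_v, Iv)
  }
  J
}

## block-diagonal generalized precision applied to a stacked error vector
gf_precision_blocks <- function(gfm) {
  blocks <- list(kronecker(gfm$Py$R, gfm$Py$Pi))
  if (gfm$n_x > 0L) blocks <- c(blocks, list(kronecker(gfm$Px$R, gfm$Px$Pi)))
  blocks <- c(blocks, list(kronecker(gfm$Pv$R, gfm$Pv$Pi)))
  as.matrix(Matrix::bdiag(blocks))
}

## ---- one filtering step ---------------------------------------------------

#' One generalized-filtering update
#'
#' Integrates the belief dynamics over one step of length \code{dt} by local
#' linearization (matrix exponential of the update Jacobian), falling back to
#' sub-stepped explicit Euler when the Jacobian is numerically singular.
#'
#' @param belief current \code{belief_state}.
#' @param y_t generalized sensory sample at the current time.
#' @param gfm a \code{gf_model}.
#' @param t current time.
#' @param dt step length (> 0); defaults to the model's grid step.
#' @return updated \code{belief_state}.
#' @export
gf_step <- function(belief, y_t, gfm, t = 0, dt = gfm$dt) {
  stopifnot(dt > 0)
  u <- belief_pack(belief)
  pe <- prediction_errors(belief, y_t, gfm, t)
  xi_vec <- c(as.vector(t(pe$xi$y)),
              if (gfm$n_x > 0L) as.vector(t(pe$xi$x)),
              as.vector(t(pe$xi$v)))
  J <- gf_error_jacobian(belief, gfm)
  grad <- as.numeric(crossprod(J, xi_vec))
  h <- as.numeric(gfm$D_u %*% u) - grad
  Jh <- gfm$D_u - crossprod(J, gfm$P_gen %*% J)
  du <- tryCatch({
    E <- as.matrix(Matrix::expm(Jh * dt))
    as.numeric(solve(Jh, (E - diag(nrow(Jh))) %*% h))
  }, error = function(e) NULL)
  if (is.null(du) || any(!is.finite(du))) {
    ## fallback: sub-stepped explicit Euler on the same vector field
    m <- 32L
    uu <- u
    for (i in seq_len(m)) {
      b <- belief_unpack(uu, gfm)
      pe_i <- prediction_errors(b, y_t, gfm, t)
      xv <- c(as.vector(t(pe_i$xi$y)),
              if (gfm$n_x > 0L) as.vector(t(pe_i$xi$x)),
              as.vector(t(pe_i$xi$v)))
      Ji <- gf_error_jacobian(b, gfm)
      hh <- as.numeric(gfm$D_u %*% uu) - as.numeric(crossprod(Ji, xv))
      uu <- uu + (dt / m) * hh
    }
    du <- uu - u
  }
  u_new <- u + du
  if (any(!is.finite(u_new)) || max(abs(u_new)) > gfm$divergence_bound)
    stop(sprintf(paste0("generalized filtering diverged at t = %g ",
                        "(max |mu| = %.3g, bound %.3g)"),
                 t, max(abs(u_new)), gfm$divergence_bound))
  belief_unpack(u_new, gfm)
}

## ---- full run -------------------------------------------------------------

#' Run generalized filtering over a stimulus
#'
#' Sequentially applies \code{\link{gf_step}} to every sample of the
#' spectrogram, embedding the sensory data in generalized coordinates at each
#' step.  The prior on the target log-frequency (mean and precision) is the
#' one carried by the recognition model, i.e. set from the oddball condition.
#'
#' @param stimulus a \code{\link{generate_stimulus}} spectrogram.
#' @param model an \code{\link{auditory_hdm}} (recognition side), or a
#'   prebuilt \code{gf_model}.
#' @return object of class \code{gf_run}: belief trajectories (order-0
#'   posterior expectations of states and causes over time), the
#'   \code{error_trajectory} of precision-weighted errors, and the final
#'   belief.
#' @export
filter_run <- function(stimulus, model) {
  gfm <- if (inherits(model, "gf_model")) model else as_gf_model(model)
  Y <- stimulus$channels
  times <- stimulus$times
  n <- nrow(Y)
  dt <- stimulus$dt
  belief <- belief_init(gfm, times[1L])
  mu_x0 <- if (gfm$n_x > 0L) matrix(NA_real_, n, gfm$n_x) else NULL
  mu_v0 <- matrix(NA_real_, n, gfm$n_v)
  xi_y <- matrix(NA_real_, n, gfm$n_y)
  xi_x <- if (gfm$n_x > 0L) matrix(NA_real_, n, gfm$n_x) else NULL
  xi_v <- matrix(NA_real_, n, gfm$n_v)
  for (i in seq_len(n)) {
    y_t <- embed_signal(Y, i, gfm$order_states, dt)
    pe <- prediction_errors(belief, y_t, gfm, times[i])
    if (gfm$n_x > 0L) {
      mu_x0[i, ] <- belief$mu_x[1L, ]
      xi_x[i, ] <- pe$xi$x[1L, ]
    }
    mu_v0[i, ] <- belief$mu_v[1L, ]
    xi_y[i, ] <- pe$xi$y[1L, ]
    xi_v[i, ] <- pe$xi$v[1L, ]
    belief <- gf_step(belief, y_t, gfm, times[i], dt)
  }
  errors <- structure(list(times = times, xi_sensory = xi_y,
                           xi_states = xi_x, xi_causes = xi_v,
                           native_dt = dt),
                      class = "error_trajectory")
  structure(list(times = times, mu_x = mu_x0, mu_v = mu_v0,
                 errors = errors, final_belief = belief, model = gfm),
            class = "gf_run")
}

#' @export
print.gf_run <- function(x, ...) {
  cat(sprintf("Generalized filtering run: %d steps\n", length(x$times)))
  cat(sprintf("  peak |xi_sensory| = %.3g, peak |xi_causes| = %.3g\n",
              max(abs(x$errors$xi_sensory)), max(abs(x$errors$xi_causes))))
  invisible(x)
}

#' @export
print.error_trajectory <- function(x, ...) {
  cat(sprintf("Precision-weighted prediction errors over %d steps\n",
              length(x$times)))
  cat(sprintf("  A1 (sensory): %d units; Heschl (states): %s; IFG (causes): %d units\n",
              ncol(x$xi_sensory),
              if (is.null(x$xi_states)) "none" else paste(ncol(x$xi_states), "units"),
              ncol(x$xi_causes)))
  invisible(x)
}

#' @export
plot.gf_run <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$mu_v, x$mu_x[, 3]), type = "l",
                    xlab = "native time", ylab = "posterior expectation",
                    main = "Belief trajectories", ...)
  graphics::legend("topright", c("mu_v (loudness cause)", "mu_v (target log-freq)",
                                 "mu_x (log-frequency)"),
                   col = 1:3, lty = 1:3, cex = 0.7)
  invisible(x)
}
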