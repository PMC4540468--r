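#' Plasticity configuration
#'
#' Bundles the learning rates and targets of the four rules applied per
#' time step (Euler discretization of the continuous-time rules):
#' afferent Hebbian learning of `V`, homeostatic intrinsic plasticity of
#' `b`, and one of two recurrent rules for `Wexc` -- wake-sleep (contrast
#' of coactivations under input-driven sampling and a companion prior
#' sampler sharing the recurrent weights) or the heuristic local rule
#' with the weight-dependent LTD function
#' `phi(W) = m_k m_j + tan(pi/2 * W / wmax) / gamma`.
#'
#' @param eta_v,eta_b,eta_w learning rates in 1/s (0 freezes a rule).
#' @param m homeostatic target activations in `(0, 1)`.
#' @param rule recurrent rule: `"none"`, `"wakesleep"`, or `"heuristic"`.
#' @param wmax,gamma heuristic-LTD parameters (`wmax > 0`, `gamma > 0`).
#' @param nonneg clip `V` and `Wexc` at zero (the neuroscientific
#'   convention; the theory also supports signed weights).
#' @param eta_b_sleep homeostatic rate of the companion prior sampler's
#'   biases (wake-sleep only); defaults to `eta_b`.
#' @param bsleep_init initial companion biases (defaults to zero).
#' @export
plasticity_config <- function(eta_v = 0, eta_b = 0, eta_w = 0, m = 0.1,
                              rule = c("none", "wakesleep", "heuristic"),
                              wmax = 1.41, gamma = 31.6, nonneg = TRUE,
                              eta_b_sleep = eta_b, bsleep_init = NULL) {
  rule <- match.arg(rule)
  stopifnot(eta_v >= 0, eta_b >= 0, eta_w >= 0, wmax > 0, gamma > 0,
            all(m > 0 & m < 1))
  structure(list(eta_v = eta_v, eta_b = eta_b, eta_w = eta_w, m = m,
                 rule = rule, wmax = wmax, gamma = gamma, nonneg = nonneg,
                 eta_b_sleep = eta_b_sleep, bsleep_init = bsleep_init),
            class = "plasticity_config")
}

#' One afferent Hebbian update
#'
#' `dV_ki = dt * eta_v * z_k * (y_i - sigmoid(V_ki + V_0i))` on the
#' afferent fields (Bernoulli family; for Poisson or Gaussian families the
#' sigmoid is replaced by the family's mean function `dA/dV`).
#'
#' @param V `K x N` afferent weights.
#' @param V0 default log-parameters.
#' @param z,y current binary states.
#' @param eta_v learning rate (1/s); `dt` step (s).
#' @param fields afferent index sets (default: all inputs).
#' @param nonneg clip at zero.
#' @param family likelihood family for the expected-input term.
#' @param sigma2 Gaussian variance.
#' @export
afferent_update <- function(V, V0, z, y, eta_v, dt, fields = NULL,
                            nonneg = TRUE,
                            family = c("bernoulli", "poisson", "gaussian"),
                            sigma2 = 1) {
  family <- match.arg(family)
  K <- nrow(V); N <- ncol(V)
  if (is.null(fields)) fields <- rep(list(seq_len(N)), K)
  for (k in seq_len(K)) {
    if (!z[k]) next
    idx <- fields[[k]]
    mean_y <- switch(family,
      bernoulli = stats::plogis(V[k, idx] + V0[idx]),
      poisson   = exp(V[k, idx] + V0[idx]),
      gaussian  = sigma2 * (V[k, idx] + V0[idx]))
    nv <- V[k, idx] + dt * eta_v * (y[idx] - mean_y)
    if (nonneg) nv <- pmax(nv, 0)
    V[k, idx] <- nv
  }
  V
}

#' One homeostatic intrinsic update
#'
#' `db_k = dt * eta_b * (m_k - z_k)`: the sample-based variational E-step.
#'
#' @param b excitabilities; `z` current state; `m` targets.
#' @param eta_b rate (1/s); `dt` step (s).
#' @export
homeostatic_update <- function(b, z, m, eta_b, dt) {
  b + dt * eta_b * (m - as.numeric(z))
}

#' One wake-sleep recurrent update
#'
#' `dW_kj = dt * eta_w * (z_k z_j - s_k s_j)` on the excitatory mask,
#' where `s` is the companion prior sampler's state (sleep phase).
#' Computed once per unordered pair and mirrored.
#'
#' @param Wexc recurrent weights; `z_wake`, `z_sleep` binary states;
#'   `mask` logical `K x K` excitatory support.
#' @param eta_w rate (1/s); `dt` step (s); `nonneg` clip at zero.
#' @export
wakesleep_update <- function(Wexc, z_wake, z_sleep, mask, eta_w, dt,
                             nonneg = TRUE) {
  if (any(Wexc[!mask & Wexc != 0] != 0))
    stop("nonzero recurrent weight outside the excitatory mask")
  pairs <- which(mask & upper.tri(mask), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    k <- pairs[r, 1]; j <- pairs[r, 2]
    dw <- dt * eta_w * (z_wake[k] * z_wake[j] - z_sleep[k] * z_sleep[j])
    nw <- Wexc[k, j] + dw
    if (nonneg) nw <- max(nw, 0)
    Wexc[k, j] <- Wexc[j, k] <- nw
  }
  Wexc
}

#' LTD function of the heuristic recurrent rule
#'
#' `phi(W) = m_k m_j + tan(pi/2 * W / wmax) / gamma`; strictly increasing
#' in `W` and divergent as `W` approaches `wmax`, which bounds the
#' weights.
#'
#' @param W weight (vectorized); `mk`, `mj` homeostatic targets;
#'   `wmax`, `gamma` rule parameters.
#' @export
ltd_phi <- function(W, mk, mj, wmax, gamma) {
  mk * mj + tan(pi / 2 * W / wmax) / gamma
}

#' One heuristic recurrent update
#'
#' `dW_kj = dt * eta_w * (z_k z_j - phi(W_kj))`, applied symmetrically on
#' the excitatory mask; weights are kept in `[0, wmax - 1e-6 * wmax]` so
#' the tangent stays finite.
#'
#' @inheritParams wakesleep_update
#' @param m homeostatic targets (length `K`).
#' @param wmax,gamma LTD parameters.
#' @export
heuristic_update <- function(Wexc, z, mask, m, eta_w, dt,
                             wmax = 1.41, gamma = 31.6, nonneg = TRUE) {
  eps <- 1e-6 * wmax
  pairs <- which(mask & upper.tri(mask), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    k <- pairs[r, 1]; j <- pairs[r, 2]
    w <- Wexc[k, j]
    if (w >= wmax) {
      warning("recurrent weight at or above wmax; clamping")
      w <- wmax - eps
    }
    dw <- dt * eta_w * (z[k] * z[j] - ltd_phi(w, m[k], m[j], wmax, gamma))
    nw <- w + dw
    if (nonneg) nw <- max(nw, 0)
    nw <- min(nw, wmax - eps)
    Wexc[k, j] <- Wexc[j, k] <- nw
  }
  Wexc
}

#' Running means and covariances of network states
#'
#' Plug-in estimates of `<z_k>`, `<z_k z_j>` and the covariances
#' `c_kj = <z_k z_j> - <z_k><z_j>` over a recorded window.
#'
#' @param z_trace binary `T x K` state matrix.
#' @return a `coactivation_stats` list with `zbar`, `coact`, `cov`, `n`.
#' @export
estimate_covariance <- function(z_trace) {
  z <- as.matrix(z_trace)
  storage.mode(z) <- "double"
  n <- nrow(z)
  if (n == 0) stop("empty window")
  zbar <- colMeans(z)
  coact <- crossprod(z) / n
  structure(list(zbar = zbar, coact = coact,
                 cov = coact - outer(zbar, zbar), n = n),
            class = "coactivation_stats")
}

#' Fit the heuristic-LTD parameters from optimized weights
#'
#' Least-squares fit of the weight--covariance map
#' `W(c) = wmax / (pi/2) * arctan(gamma * c)` to pairs of converged
#' wake-sleep weights and measured covariances.  Only synapses with
#' weight above `weight_floor` enter the fit (weaker synapses may have
#' been clipped at zero and would distort it).  The fit profiles `wmax`
#' (linear given `gamma`) and optimizes `gamma` on a log grid.
#'
#' @param W converged weights; `c_kj` matching covariances.
#' @param weight_floor exclusion threshold on `W`.
#' @return list with `wmax`, `gamma`, `fitted`, `residuals`, `n`.
#' @export
fit_ltd_parameters <- function(W, c_kj, weight_floor = 0.01) {
  keep <- W > weight_floor
  W <- W[keep]; cc <- c_kj[keep]
  if (length(W) < 2)
    stop("need at least two synapses above the weight floor to fit")
  if (all(cc <= 0))
    stop("degenerate data: no positive covariances to fit")
  sse <- function(log_gamma) {
    a <- atan(exp(log_gamma) * cc) / (pi / 2)
    wmax <- sum(W * a) / sum(a^2)
    sum((W - wmax * a)^2)
  }
  opt <- stats::optimize(sse, c(log(1e-3), log(1e7)))
  gamma <- exp(opt$minimum)
  a <- atan(gamma * cc) / (pi / 2)
  wmax <- sum(W * a) / sum(a^2)
  fitted <- wmax * a
  list(wmax = wmax, gamma = gamma, fitted = fitted,
       residuals = W - fitted, n = length(W))
}
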