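#' Enumerate network states compatible with the lateral inhibition structure
#'
#' A state `z` in `{0,1}^K` is *valid* when no two mutually inhibiting
#' neurons are simultaneously active.  States are returned in
#' lexicographic order of `(z_1, ..., z_K)`.
#'
#' @param inhibition_mask symmetric `K x K` logical matrix with `FALSE`
#'   diagonal; `TRUE` marks an inhibiting pair.
#' @param cap refuse enumeration above this many neurons (guards against
#'   combinatorial blow-up; the count-only path [count_valid_states()] has
#'   no such limit).
#' @return integer matrix, one valid state per row.
#' @export
valid_states <- function(inhibition_mask, cap = 24) {
  mask <- as.matrix(inhibition_mask)
  K <- nrow(mask)
  if (!isTRUE(all(mask == t(mask))) || any(diag(mask) != 0))
    stop("inhibition mask must be symmetric with empty diagonal")
  if (K > cap)
    stop("refusing to enumerate states for K = ", K, " > cap = ", cap,
         " (the state count may still be obtained via count_valid_states)")
  if (K > 16 && !any(mask))
    warning("enumerating all 2^", K, " states; this may be large")
  .cpp_valid_states(matrix(as.logical(mask), K, K))
}

#' Count valid states without enumerating them
#' @inheritParams valid_states
#' @export
count_valid_states <- function(inhibition_mask) {
  mask <- as.matrix(inhibition_mask)
  .cpp_count_valid_states(matrix(as.logical(mask), nrow(mask), nrow(mask)))
}

# all 2^K states, lexicographic in (z_1, .., z_K); K small
all_states <- function(K) {
  if (K == 0) return(matrix(0L, 1, 0))
  if (K > 24) stop("full state enumeration capped at K = 24")
  s <- 0:(2^K - 1)
  m <- matrix(0L, length(s), K)
  for (k in seq_len(K)) {
    m[, k] <- bitwAnd(bitwShiftR(s, K - k), 1L)
  }
  m
}

#' Unnormalized prior log-probability of a state
#'
#' `log w(z) = 1/2 z' W z + z' bhat` with `W = Wexc_hat + Winh_hat`
#' (strong inhibition as its finite surrogate).
#'
#' @param z binary vector of length `K` (or a matrix, one state per row).
#' @param model a [generative_model()].
#' @export
prior_log_prob <- function(z, model) {
  W <- model$Wexc_hat + model$Winh_hat
  if (is.matrix(z)) {
    0.5 * rowSums((z %*% W) * z) + drop(z %*% model$bhat)
  } else {
    z <- as.numeric(z)
    0.5 * sum((W %*% z) * z) + sum(z * model$bhat)
  }
}

posterior_table <- function(states, log_weights) {
  lw <- log_weights - max(log_weights)
  p <- exp(lw)
  p <- p / sum(p)
  structure(list(states = states, log_weights = log_weights, probs = p,
                 marginals = drop(crossprod(states, p))),
            class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("<posterior_table> %d states over K = %d units\n",
              nrow(x$states), ncol(x$states)))
  cat("  marginals:", paste(sprintf("%.4f", x$marginals), collapse = " "),
      "\n")
  invisible(x)
}

#' Enumerated prior distribution
#'
#' Normalizes the Boltzmann prior over all `2^K` states, with strong
#' inhibition entering as its finite surrogate weight (states violating
#' the winner-take-all constraint keep mass of order `exp(-100)`).
#'
#' @inheritParams prior_log_prob
#' @return a `posterior_table` (states, log weights, probabilities,
#'   marginals).
#' @export
prior_table <- function(model) {
  S <- all_states(model$K)
  posterior_table(S, prior_log_prob(S, model))
}

#' Likelihood log-probability up to a z-independent constant
#'
#' Evaluates `z' V y - z' A`, the part of `log p(y | z, theta)` that
#' depends on the network state.  The base-measure term `h(y)` is a
#' constant in `z` and is dropped here (restored by [log_likelihood()]).
#'
#' @param y observed vector (binary for Bernoulli, counts for Poisson,
#'   reals for Gaussian).
#' @param z binary state vector.
#' @param model a [generative_model()].
#' @export
likelihood_log_prob <- function(y, z, model) {
  check_support(y, model)
  tr <- translate_likelihood(model$family, model$params, model$defaults,
                             model$fields, model$sigma2)
  sum(z * drop(tr$V %*% y)) - sum(z * rowSums(tr$A))
}

check_support <- function(y, model) {
  ok <- switch(model$family,
    bernoulli = all(y %in% c(0, 1)),
    poisson   = all(y >= 0 & y == round(y)),
    gaussian  = all(is.finite(y)))
  if (!ok) stop("observation outside the support of the ", model$family,
                " likelihood")
  invisible(TRUE)
}

#' Exact posterior over network states by enumeration
#'
#' Per-state log weight `1/2 z' W z + z' V y + z' (bhat - A)`, normalized
#' over all `2^K` states.  With no observed inputs (`N = 0`) this reduces
#' to the prior.
#'
#' @inheritParams likelihood_log_prob
#' @param cap enumeration cap on `K`.
#' @return a `posterior_table`.
#' @export
exact_posterior <- function(y, model, cap = 20) {
  if (model$K > cap) stop("exact posterior enumeration capped at K = ", cap)
  S <- all_states(model$K)
  net <- network_from_model(model)
  lw <- prior_log_prob(S, model) - drop(S %*% net$A)
  if (model$N > 0) {
    check_support(y, model)
    lw <- lw + drop(S %*% (net$V %*% y))
  }
  posterior_table(S, lw)
}

#' Conditional log-odds of one unit given the rest
#'
#' Computes `log p(z_k = 1 | z_{\k}, y) / p(z_k = 0 | z_{\k}, y)` from the
#' enumerated joint (difference of unnormalized posterior log weights at
#' the two completions of the state).  For a network built by
#' [network_from_model()] this equals the membrane potential exactly --
#' the neural computability condition.
#'
#' @param k unit index.
#' @param z_rest binary vector of length `K` whose `k`-th entry is ignored.
#' @param y observed vector.
#' @param model a [generative_model()].
#' @export
conditional_log_odds <- function(k, z_rest, y, model) {
  net <- network_from_model(model)
  z1 <- as.numeric(z_rest); z1[k] <- 1
  z0 <- as.numeric(z_rest); z0[k] <- 0
  lw <- function(z) {
    prior_log_prob(z, model) - sum(z * net$A) +
      if (model$N > 0) sum(z * drop(net$V %*% y)) else 0
  }
  lw(z1) - lw(z0)
}

#' Calibrate prior biases to target activations
#'
#' Finds biases `bhat` such that the enumerated prior exhibits the
#' homeostatic target activations, `<z_k> = m_k`, by damped fixed-point
#' iteration `bhat <- bhat + damping * (log m - log <z>)`.  This is the
#' canonical choice of prior biases when evaluating the log-likelihood of
#' a learned network: the biases a Bayesian observer would infer from the
#' network's long-term response.
#'
#' @param Wexc,Winh `K x K` prior couplings (inhibition as the finite
#'   surrogate weight).
#' @param m target activations in `(0, 1)`, feasibility checked by the
#'   solve itself.
#' @param tol convergence tolerance on `max |<z_k> - m_k|`.
#' @param damping step damping of the fixed-point iteration.
#' @param max_iter iteration limit; non-convergence is an error reporting
#'   the residuals.
#' @param use_valid_states enumerate only inhibition-respecting states
#'   (hard constraint) instead of all `2^K`; automatic for `K > 16`.
#' @return length-`K` vector `bhat`.
#' @export
calibrate_prior_biases <- function(Wexc, Winh, m, tol = 1e-6,
                                   damping = 0.5, max_iter = 2000,
                                   use_valid_states = NULL) {
  Wexc <- as.matrix(Wexc); Winh <- as.matrix(Winh)
  K <- nrow(Wexc)
  m <- rep_len(as.numeric(m), K)
  if (any(m <= 0 | m >= 1)) stop("targets m must lie in (0,1)")
  if (is.null(use_valid_states)) use_valid_states <- K > 16
  if (use_valid_states) {
    S <- valid_states(Winh != 0)
    W <- Wexc
  } else {
    S <- all_states(K)
    W <- Wexc + Winh
  }
  w0 <- 0.5 * rowSums((S %*% W) * S)
  bhat <- stats::qlogis(m)
  for (iter in seq_len(max_iter)) {
    lw <- w0 + drop(S %*% bhat)
    lw <- lw - max(lw)
    p <- exp(lw); p <- p / sum(p)
    marg <- drop(crossprod(S, p))
    if (max(abs(marg - m)) < tol) return(bhat)
    bhat <- bhat + damping * (log(m) - log(pmax(marg, 1e-300)))
  }
  stop("prior-bias calibration did not converge; residuals: ",
       paste(sprintf("%.2e", marg - m), collapse = " "))
}

#' Average data log-likelihood under the model
#'
#' `L = (1/S) sum_s log sum_z p(z | theta) prod_i p(y_i^s | z, theta)`,
#' with the sum over the inhibition-respecting states and the full
#' likelihood (base measure restored), so values are absolute and
#' comparable across parameter settings.  The prior over valid states is
#' built from `Wexc_hat` and `bhat`; supply `bhat` from
#' [calibrate_prior_biases()] for a learned network.
#'
#' @param y_samples matrix of observations, one sample per row (`S x N`).
#' @param model a [generative_model()]; a model with `K = 0` scores the
#'   samples under the default hypothesis alone.
#' @param chunk number of samples scored per block (memory control).
#' @export
log_likelihood <- function(y_samples, model, chunk = 1000) {
  y_samples <- as.matrix(y_samples)
  if (nrow(y_samples) == 0) stop("empty sample list")
  if (model$family != "bernoulli")
    stop("log_likelihood implemented for the Bernoulli family")
  if (model$K == 0) {
    V0 <- stats::qlogis(model$defaults)
    lh <- drop(y_samples %*% V0) - sum(log1p(exp(V0)))
    return(mean(lh))
  }
  net <- network_from_model(model)
  S <- valid_states(model$Winh_hat != 0)
  lw_prior <- 0.5 * rowSums((S %*% model$Wexc_hat) * S) +
    drop(S %*% model$bhat)
  lw_prior <- lw_prior - logsumexp(lw_prior)       # log p(z | theta)
  SA <- drop(S %*% net$A)
  SV <- S %*% net$V                                 # n_states x N
  V0 <- net$V0
  logh_const <- -sum(log1p(exp(V0)))
  total <- 0
  n <- nrow(y_samples)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    Y <- y_samples[idx, , drop = FALSE]
    M <- SV %*% t(Y)                                # n_states x |idx|
    M <- M + (lw_prior - SA)
    lse <- apply(M, 2, logsumexp)
    logh <- drop(Y %*% V0) + logh_const
    total <- total + sum(lse + logh)
  }
  total / n
}

logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Reconstruct the average input expected from a network response
#'
#' Adopts the generative perspective: given a window of sampled states
#' `z(t)`, the expected input under the learned model is the time average
#' of `sigmoid(V_0i + sum_k z_k(t) V_ki)` (Bernoulli family).
#'
#' @param z_trace binary matrix, one time step per row (`T x K`).
#' @param network a `sheet_network`.
#' @return length-`N` vector of mean reconstructed activations.
#' @export
reconstruct_input <- function(z_trace, network) {
  z_trace <- as.matrix(z_trace)
  if (nrow(z_trace) == 0) stop("reconstruction window is empty")
  drive <- sweep(z_trace %*% network$V, 2, network$V0, "+")
  colMeans(stats::plogis(drive))
}
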