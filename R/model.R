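#' Construct a generative model for the spiking sheet
#'
#' Defines the joint distribution `p(y, z | theta)` that a spiking sheet
#' samples from: a Boltzmann-machine prior over `K` binary hidden causes
#' `z`, shaped by symmetric zero-diagonal couplings (`Wexc_hat >= 0`,
#' `Winh_hat <= 0`) and biases `bhat`, together with conditionally
#' independent exponential-family likelihoods for `N` observed inputs `y`.
#' Every input `i` in the afferent field of hidden cause `k` follows the
#' cause-specific parameter (success probability `pi[k, i]`, rate
#' `lambda[k, i]`, or mean `mu[k, i]`) when `z_k = 1`, and the default
#' parameter (`pi0[i]` etc.) when no parent is active.  Strong negative
#' couplings between causes with overlapping afferent fields enforce the
#' at-most-one-parent assumption of the likelihood.
#'
#' @param family one of `"bernoulli"`, `"poisson"`, `"gaussian"`.
#' @param params `K x N` matrix of per-edge likelihood parameters
#'   (`pi_ki`, `lambda_ki`, or `mu_ki`); entries outside the afferent
#'   fields are ignored.
#' @param defaults length-`N` vector of default parameters (`pi_0i`,
#'   `lambda_0i`, or `mu_0i`).
#' @param fields list of `K` integer vectors: the afferent field `I_k` of
#'   each hidden cause.  Defaults to all inputs for every cause.
#' @param Wexc_hat,Winh_hat `K x K` symmetric zero-diagonal prior
#'   couplings; excitatory entries must be `>= 0`, inhibitory `<= 0`, and
#'   their nonzero supports disjoint.  Any pair of causes with overlapping
#'   fields must carry the strong inhibitory coupling (`inh_weight`).
#' @param bhat length-`K` prior biases.
#' @param sigma2 shared Gaussian variance (`family = "gaussian"` only).
#' @param inh_weight the finite surrogate for "infinitely strong"
#'   inhibition; `-100` throughout.
#' @return an object of class `sheet_model`.
#' @export
generative_model <- function(family = c("bernoulli", "poisson", "gaussian"),
                             params, defaults, fields = NULL,
                             Wexc_hat = NULL, Winh_hat = NULL, bhat = NULL,
                             sigma2 = 1, inh_weight = -100) {
  family <- match.arg(family)
  params <- as.matrix(params)
  K <- nrow(params)
  N <- ncol(params)
  defaults <- as.numeric(defaults)
  if (length(defaults) != N)
    stop("`defaults` must have one entry per input (length ", N, ")")
  if (is.null(fields)) fields <- rep(list(seq_len(N)), K)
  if (length(fields) != K) stop("`fields` must list one index set per cause")
  fields <- lapply(fields, function(i) sort(unique(as.integer(i))))
  if (is.null(Wexc_hat)) Wexc_hat <- matrix(0, K, K)
  if (is.null(Winh_hat)) Winh_hat <- matrix(0, K, K)
  if (is.null(bhat)) bhat <- rep(0, K)
  Wexc_hat <- as.matrix(Wexc_hat); Winh_hat <- as.matrix(Winh_hat)
  bhat <- as.numeric(bhat)
  m <- structure(list(K = K, N = N, family = family, params = params,
                      defaults = defaults, fields = fields,
                      Wexc_hat = Wexc_hat, Winh_hat = Winh_hat,
                      bhat = bhat, sigma2 = sigma2,
                      inh_weight = inh_weight),
                 class = "sheet_model")
  validate_model(m)
  m
}

validate_model <- function(m) {
  with(m, {
    if (!isTRUE(all.equal(Wexc_hat, t(Wexc_hat))) ||
        !isTRUE(all.equal(Winh_hat, t(Winh_hat))))
      stop("prior couplings must be symmetric")
    if (any(diag(Wexc_hat) != 0) || any(diag(Winh_hat) != 0))
      stop("prior couplings must have zero diagonal")
    if (any(Wexc_hat < 0)) stop("Wexc_hat must be nonnegative")
    if (any(Winh_hat > 0)) stop("Winh_hat must be nonpositive")
    if (any(Wexc_hat != 0 & Winh_hat != 0))
      stop("excitatory and inhibitory supports must be disjoint")
    check_family_domain(family, params, defaults, fields, sigma2)
    # overlap => strong inhibition
    for (k in seq_len(K)) for (j in seq_len(K)) {
      if (j <= k) next
      if (length(intersect(fields[[k]], fields[[j]])) > 0 &&
          Winh_hat[k, j] > inh_weight)
        stop(sprintf(paste0("causes %d and %d share inputs but lack the ",
                            "strong inhibitory coupling (%g)"),
                     k, j, inh_weight))
    }
  })
  invisible(m)
}

check_family_domain <- function(family, params, defaults, fields, sigma2) {
  K <- nrow(params)
  for (k in seq_len(K)) {
    idx <- fields[[k]]
    v <- params[k, idx]
    bad <- switch(family,
      bernoulli = which(!(v > 0 & v < 1)),
      poisson   = which(!(v > 0)),
      gaussian  = integer(0))
    if (length(bad))
      stop(sprintf("likelihood parameter out of domain at (k = %d, i = %d)",
                   k, idx[bad[1]]))
  }
  bad0 <- switch(family,
    bernoulli = which(!(defaults > 0 & defaults < 1)),
    poisson   = which(!(defaults > 0)),
    gaussian  = integer(0))
  if (length(bad0))
    stop(sprintf("default parameter out of domain at i = %d", bad0[1]))
  if (family == "gaussian" && !(sigma2 > 0))
    stop("sigma2 must be positive")
  invisible(TRUE)
}

#' @export
print.sheet_model <- function(x, ...) {
  cat(sprintf("<sheet_model> %s likelihood, K = %d hidden causes, N = %d inputs\n",
              x$family, x$K, x$N))
  cat(sprintf("  excitatory couplings: %d pairs; inhibitory pairs: %d (weight %g)\n",
              sum(x$Wexc_hat[upper.tri(x$Wexc_hat)] != 0),
              sum(x$Winh_hat[upper.tri(x$Winh_hat)] != 0), x$inh_weight))
  invisible(x)
}

#' Translate likelihood parameters to exponential-family form
#'
#' Rewrites the per-edge likelihood parameters relative to the default
#' hypothesis in natural-parameter form, returning the afferent weights
#' `V`, the default log-parameters `V0`, and the log-normalizers `A`
#' (per edge, relative to the default normalizer `A0`).  For a Bernoulli
#' family, `V_ki = logit(pi_ki) - V_0i` with `V_0i = logit(pi_0i)` and
#' `A_ki = log(1 + exp(V_ki + V_0i)) - A_0i`; Poisson and Gaussian
#' families follow the analogous identities.  The round trip
#' `pi_ki = sigmoid(V_ki + V_0i)` holds for the Bernoulli family.
#'
#' @inheritParams generative_model
#' @return list with `V` (`K x N`, zero outside the afferent fields),
#'   `V0` (`N`), `A` (`K x N` per-edge normalizers), `A0` (`N`).
#' @export
translate_likelihood <- function(family, params, defaults, fields = NULL,
                                 sigma2 = 1) {
  family <- match.arg(family, c("bernoulli", "poisson", "gaussian"))
  params <- as.matrix(params)
  K <- nrow(params); N <- ncol(params)
  if (is.null(fields)) fields <- rep(list(seq_len(N)), K)
  check_family_domain(family, params, defaults, fields, sigma2)
  V <- matrix(0, K, N); A <- matrix(0, K, N)
  if (family == "bernoulli") {
    V0 <- stats::qlogis(defaults)
    A0 <- log1p(exp(V0))
    for (k in seq_len(K)) {
      idx <- fields[[k]]
      V[k, idx] <- stats::qlogis(params[k, idx]) - V0[idx]
      A[k, idx] <- log1p(exp(V[k, idx] + V0[idx])) - A0[idx]
    }
  } else if (family == "poisson") {
    V0 <- log(defaults)
    A0 <- exp(V0)
    for (k in seq_len(K)) {
      idx <- fields[[k]]
      V[k, idx] <- log(params[k, idx]) - V0[idx]
      A[k, idx] <- exp(V[k, idx] + V0[idx]) - A0[idx]
    }
  } else {
    V0 <- defaults / sigma2
    A0 <- sigma2 / 2 * V0^2
    for (k in seq_len(K)) {
      idx <- fields[[k]]
      V[k, idx] <- params[k, idx] / sigma2 - V0[idx]
      A[k, idx] <- sigma2 / 2 * (V[k, idx] + V0[idx])^2 - A0[idx]
    }
  }
  list(V = V, V0 = V0, A = A, A0 = A0)
}

#' Build neuronal parameters from a generative model
#'
#' Applies the inference-mode identification between abstract model
#' parameters and neuronal parameters: afferent weights `V` from the
#' likelihood translation, recurrent weights equal to the prior couplings,
#' and excitabilities `b_k = bhat_k - A_k` with `A_k = sum_i A_ki`.  A
#' network built this way satisfies the neural computability condition:
#' its membrane potential equals the conditional log-odds of the posterior
#' exactly, for every state.
#'
#' @param model a [generative_model()].
#' @return an object of class `sheet_network` with fields `V`, `V0`,
#'   `A` (length `K`), `A0`, `b`, `Wexc`, `Winh`, `fields`.
#' @export
network_from_model <- function(model) {
  stopifnot(inherits(model, "sheet_model"))
  tr <- translate_likelihood(model$family, model$params, model$defaults,
                             model$fields, model$sigma2)
  A_k <- rowSums(tr$A)
  structure(list(K = model$K, N = model$N, family = model$family,
                 V = tr$V, V0 = tr$V0, A = A_k, A0 = tr$A0,
                 b = model$bhat - A_k,
                 Wexc = model$Wexc_hat, Winh = model$Winh_hat,
                 fields = model$fields),
            class = "sheet_network")
}

#' Assemble neuronal parameters directly (learning mode)
#'
#' In learning mode the excitability `b` is a free parameter (homeostatic
#' plasticity absorbs the normalizers `A_k` and the variational
#' multipliers), so the network is specified directly rather than derived
#' from a generative model.
#'
#' @param V `K x N` afferent weights; `V0` length-`N` default
#'   log-parameters; `b` length-`K` excitabilities; `Wexc`, `Winh`
#'   `K x K` recurrent weights; `fields` afferent index sets.
#' @return a `sheet_network`.
#' @export
sheet_network <- function(V, V0, b, Wexc, Winh, fields = NULL,
                          family = "bernoulli") {
  V <- as.matrix(V)
  K <- nrow(V); N <- ncol(V)
  if (is.null(fields)) fields <- rep(list(seq_len(N)), K)
  for (k in seq_len(K)) {
    out <- setdiff(which(V[k, ] != 0), fields[[k]])
    if (length(out))
      stop(sprintf("V[%d, %d] is nonzero outside the afferent field",
                   k, out[1]))
  }
  structure(list(K = K, N = N, family = family, V = V, V0 = as.numeric(V0),
                 A = NULL, A0 = NULL, b = as.numeric(b),
                 Wexc = as.matrix(Wexc), Winh = as.matrix(Winh),
                 fields = fields),
            class = "sheet_network")
}

#' @export
print.sheet_network <- function(x, ...) {
  cat(sprintf("<sheet_network> K = %d neurons, N = %d inputs (%s family)\n",
              x$K, x$N, x$family))
  cat(sprintf("  excitatory pairs: %d, inhibitory pairs: %d\n",
              sum(x$Wexc[upper.tri(x$Wexc)] != 0),
              sum(x$Winh[upper.tri(x$Winh)] != 0)))
  invisible(x)
}
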