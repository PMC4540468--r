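# Small fixture models built in code.

# K hidden causes on a chain of overlapping 3-input fields: cause k reads
# inputs (2k-1, 2k, 2k+1), so consecutive causes share one input and carry
# the strong inhibitory coupling.
chain_wta_model <- function(K = 3, seed = 1, exc_pairs = NULL,
                            pi0 = 0.15, bhat = NULL) {
  set.seed(seed)
  N <- 2 * K + 1
  fields <- lapply(seq_len(K), function(k) (2 * k - 1):(2 * k + 1))
  Winh <- matrix(0, K, K)
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (k != j && length(intersect(fields[[k]], fields[[j]])))
      Winh[k, j] <- -100
  }
  Wexc <- matrix(0, K, K)
  if (!is.null(exc_pairs)) {
    for (r in seq_len(nrow(exc_pairs))) {
      k <- exc_pairs[r, 1]; j <- exc_pairs[r, 2]
      stopifnot(Winh[k, j] == 0)
      Wexc[k, j] <- Wexc[j, k] <- 0.8
    }
  }
  pi_mat <- matrix(stats::runif(K * N, 0.2, 0.8), K, N)
  if (is.null(bhat)) bhat <- stats::rnorm(K, -0.5, 0.5)
  generative_model("bernoulli", pi_mat, rep(pi0, N), fields,
                   Wexc, Winh, bhat)
}

# constant-input dense trace for replays
constant_input_trace <- function(y, n_steps) {
  matrix(rep(as.integer(y), each = n_steps), n_steps, length(y))
}

# single-site Gibbs sampler over p(z | y) built from the written joint
# (prior couplings + likelihood translation); the enumeration path under
# test never enters here.
gibbs_posterior_freqs <- function(model, y, sweeps = 1e5, burn = 1000,
                                  seed = 1) {
  set.seed(seed)
  net <- network_from_model(model)
  W <- model$Wexc_hat + model$Winh_hat
  a <- drop(net$V %*% y) + model$bhat - net$A  # per-site constant drive
  K <- model$K
  z <- integer(K)
  counts <- numeric(2^K)
  for (s in seq_len(sweeps)) {
    for (k in seq_len(K)) {
      lo <- a[k] + sum(W[k, ] * z)
      z[k] <- as.integer(stats::runif(1) < stats::plogis(lo))
    }
    if (s > burn) {
      code <- sum(z * 2^(seq_len(K) - 1)) + 1
      counts[code] <- counts[code] + 1
    }
  }
  counts / sum(counts)
}

# align a posterior_table with the 2^K code order used above
table_probs_by_code <- function(tab) {
  K <- ncol(tab$states)
  codes <- drop(tab$states %*% 2^(seq_len(K) - 1)) + 1
  p <- numeric(2^K)
  p[codes] <- tab$probs
  p
}
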