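test_that("likelihood translation matches the closed forms", {
  # identical to the default hypothesis: no relative weight, no normalizer
  tr <- translate_likelihood("bernoulli", matrix(0.1, 1, 1), 0.1)
  expect_equal(tr$V[1, 1], 0)
  expect_equal(tr$A[1, 1], 0)

  tr <- translate_likelihood("bernoulli", matrix(0.6, 1, 1), 0.1)
  expect_equal(tr$V0, qlogis(0.1), tolerance = 1e-12)
  expect_equal(tr$V0, -2.1972246, tolerance = 1e-6)
  expect_equal(tr$V[1, 1], qlogis(0.6) - qlogis(0.1), tolerance = 1e-12)
  expect_equal(tr$V[1, 1], 2.6026897, tolerance = 1e-6)
  # A_ki = log((1 - pi0) / (1 - pi)) for the Bernoulli family
  expect_equal(tr$A[1, 1], log((1 - 0.1) / (1 - 0.6)), tolerance = 1e-12)
  expect_equal(tr$A[1, 1], 0.8109302, tolerance = 1e-6)

  trp <- translate_likelihood("poisson", matrix(2.5, 1, 1), 2.5)
  expect_equal(trp$V[1, 1], 0)
  expect_equal(trp$A[1, 1], 0)

  trg <- translate_likelihood("gaussian", matrix(1.2, 1, 1), 0.4,
                              sigma2 = 0.5)
  expect_equal(trg$V[1, 1], 1.2 / 0.5 - 0.4 / 0.5)
  expect_equal(trg$A[1, 1],
               0.5 / 2 * (1.2 / 0.5)^2 - 0.5 / 2 * (0.4 / 0.5)^2)
})

test_that("translation round trip recovers the success probabilities", {
  set.seed(4)
  for (rep in 1:5) {
    pi_mat <- matrix(runif(12, 0.01, 0.99), 3, 4)
    pi0 <- runif(4, 0.05, 0.5)
    tr <- translate_likelihood("bernoulli", pi_mat, pi0)
    expect_equal(plogis(sweep(tr$V, 2, tr$V0, "+")), pi_mat,
                 tolerance = 1e-12)
  }
})

test_that("out-of-domain likelihood parameters are rejected by location", {
  p <- matrix(0.5, 2, 2); p[2, 1] <- 1.2
  expect_error(translate_likelihood("bernoulli", p, c(0.1, 0.1)),
               "k = 2, i = 1")
  expect_error(translate_likelihood("poisson", matrix(-1, 1, 1), 2),
               "k = 1, i = 1")
})

test_that("network construction follows the inference-mode identification", {
  mod <- generative_model("bernoulli", matrix(0.6, 1, 1), 0.1,
                          bhat = -1)
  net <- network_from_model(mod)
  expect_equal(net$b, -1 - 0.8109302, tolerance = 1e-6)
  # all parameters at default, zero bias: a fully neutral network
  mod0 <- generative_model("bernoulli", matrix(0.2, 2, 3), rep(0.2, 3),
                           fields = list(1:3, 1:3),
                           Winh_hat = -100 * (1 - diag(2)))
  net0 <- network_from_model(mod0)
  expect_equal(net0$V, matrix(0, 2, 3))
  expect_equal(net0$b, c(0, 0))
  expect_error(generative_model("bernoulli", matrix(0.5, 2, 2),
                                rep(0.2, 2), fields = list(1, 2),
                                Wexc_hat = matrix(c(0, 1, 0, 0), 2, 2)),
               "symmetric")
})

test_that("valid state enumeration respects the inhibition mask", {
  expect_equal(nrow(valid_states(matrix(FALSE, 3, 3))), 8)
  # two mutually inhibiting neurons: (1,1) excluded
  mask <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  vs <- valid_states(mask)
  expect_equal(nrow(vs), 3)
  expect_false(any(rowSums(vs) == 2))
  # lexicographic order in (z_1, .., z_K)
  vs3 <- valid_states(matrix(FALSE, 2, 2))
  expect_equal(vs3, rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))
  expect_error(valid_states(matrix(FALSE, 30, 30)), "cap")
})

test_that("enumerated prior matches a brute-force summation", {
  # uniform when couplings and biases vanish
  mod0 <- generative_model("bernoulli", matrix(0.5, 3, 3), rep(0.5, 3),
                           fields = list(1, 2, 3))
  pt <- prior_table(mod0)
  expect_equal(pt$probs, rep(1 / 8, 8))
  # strong inhibition suppresses coactivation below exp(-100)
  mod2 <- chain_wta_model(2, seed = 2)
  pt2 <- prior_table(mod2)
  p11 <- pt2$probs[rowSums(pt2$states) == 2]
  expect_lt(p11, 1e-40)
  # random K = 3 prior vs direct summation over the 8 states
  mod3 <- chain_wta_model(3, seed = 3)
  pt3 <- prior_table(mod3)
  W <- mod3$Wexc_hat + mod3$Winh_hat
  direct <- apply(pt3$states, 1, function(z)
    exp(0.5 * sum((W %*% z) * z) + sum(z * mod3$bhat)))
  expect_equal(pt3$probs, direct / sum(direct), tolerance = 1e-12)
  expect_equal(sum(pt3$probs), 1, tolerance = 1e-12)
})

test_that("likelihood log-probability equals the Bernoulli log ratio", {
  mod <- generative_model("bernoulli", matrix(0.6, 1, 1), 0.1)
  expect_equal(likelihood_log_prob(1, 1, mod), 2.6026897 - 0.8109302,
               tolerance = 1e-6)
  expect_equal(likelihood_log_prob(1, 1, mod), log(0.6 / 0.1),
               tolerance = 1e-12)
  expect_equal(likelihood_log_prob(c(1, 0, 1, 0, 0), c(0, 0),
                                   chain_wta_model(2)), 0)
  expect_error(likelihood_log_prob(2, 1, mod), "support")
})

test_that("the full Bernoulli pmf integrates to one for fixed valid z", {
  mod <- chain_wta_model(2, seed = 5)  # N = 5
  net <- network_from_model(mod)
  logh <- function(y) sum(net$V0 * y) - sum(log1p(exp(net$V0)))
  ally <- as.matrix(expand.grid(rep(list(0:1), mod$N)))
  for (z in list(c(0, 0), c(1, 0), c(0, 1))) {
    tot <- sum(apply(ally, 1, function(y)
      exp(likelihood_log_prob(y, z, mod) + logh(y))))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("exact posterior reduces to the prior and obeys symmetry", {
  mod <- chain_wta_model(3, seed = 7)
  prior_only <- mod
  prior_only$N <- 0
  prior_only$params <- mod$params[, 0, drop = FALSE]
  prior_only$defaults <- numeric(0)
  prior_only$fields <- rep(list(integer(0)), 3)
  pt <- exact_posterior(numeric(0), prior_only)
  expect_equal(pt$probs, prior_table(mod)$probs, tolerance = 1e-12)

  # two identical neurons with identical input rows: equal marginals
  pi_mat <- matrix(rep(c(0.7, 0.3, 0.6), 2), 2, 3, byrow = TRUE)
  mod2 <- generative_model("bernoulli", pi_mat, rep(0.2, 3),
                           fields = list(1:3, 1:3),
                           Winh_hat = -100 * (1 - diag(2)),
                           bhat = c(-1, -1))
  pt2 <- exact_posterior(c(1, 0, 1), mod2)
  expect_equal(pt2$marginals[1], pt2$marginals[2], tolerance = 1e-12)
  expect_equal(sum(pt2$probs), 1, tolerance = 1e-12)
  expect_equal(drop(crossprod(pt2$states, pt2$probs)), pt2$marginals)
})

test_that("exact posterior agrees with an independent Gibbs sampler", {
  mod <- chain_wta_model(3, seed = 11,
                         exc_pairs = rbind(c(1, 3)))
  set.seed(12)
  y <- rbinom(mod$N, 1, 0.5)
  tab <- exact_posterior(y, mod)
  emp <- gibbs_posterior_freqs(mod, y, sweeps = 3e5, seed = 13)
  tv <- 0.5 * sum(abs(emp - table_probs_by_code(tab)))
  expect_lt(tv, 0.01)
})

test_that("conditional log-odds follow the single-unit closed form", {
  mod <- generative_model("bernoulli", matrix(c(0.6, 0.3), 1, 2),
                          c(0.1, 0.2), bhat = 0.5)
  net <- network_from_model(mod)
  y <- c(1, 1)
  expect_equal(conditional_log_odds(1, 0, y, mod),
               net$b + sum(net$V * y), tolerance = 1e-12)
  # flipping a non-coupled neighbour leaves the value unchanged
  mod3 <- chain_wta_model(3, seed = 21)
  expect_equal(mod3$Wexc_hat[1, 3] + mod3$Winh_hat[1, 3], 0)
  y3 <- rbinom(mod3$N, 1, 0.5)
  expect_equal(conditional_log_odds(1, c(0, 0, 0), y3, mod3),
               conditional_log_odds(1, c(0, 0, 1), y3, mod3),
               tolerance = 1e-12)
})

test_that("prior-bias calibration hits the target activations", {
  K <- 3
  expect_equal(calibrate_prior_biases(matrix(0, K, K), matrix(0, K, K),
                                      rep(0.5, K)), rep(0, K),
               tolerance = 1e-5)
  b1 <- calibrate_prior_biases(matrix(0, K, K), matrix(0, K, K),
                               rep(0.1, K))
  expect_equal(b1, rep(qlogis(0.1), K), tolerance = 1e-4)
  # 2-neuron WTA: round trip through the enumerated prior
  Winh <- -100 * (1 - diag(2))
  bb <- calibrate_prior_biases(matrix(0, 2, 2), Winh, c(0.3, 0.3))
  mod <- generative_model("bernoulli", matrix(0.5, 2, 1), 0.5,
                          fields = list(1, 1), Winh_hat = Winh, bhat = bb)
  expect_equal(prior_table(mod)$marginals, c(0.3, 0.3), tolerance = 1e-5)
})

test_that("log-likelihood matches hand-computed mixtures", {
  # no hidden causes: independent Bernoulli score
  mod0 <- generative_model("bernoulli",
                           matrix(numeric(0), 0, 2), c(0.3, 0.6),
                           fields = list())
  Y <- rbind(c(1, 0), c(0, 0), c(1, 1))
  expect_equal(log_likelihood(Y, mod0),
               mean(c(log(0.3) + log(0.4), log(0.7) + log(0.4),
                      log(0.3) + log(0.6))), tolerance = 1e-12)
  # single cause, single input: two-term mixture
  mod1 <- generative_model("bernoulli", matrix(0.7, 1, 1), 0.2,
                           bhat = -0.4)
  pz1 <- plogis(-0.4)
  expect_equal(log_likelihood(matrix(1, 1, 1), mod1),
               log((1 - pz1) * 0.2 + pz1 * 0.7), tolerance = 1e-12)
})

test_that("log-likelihood is maximal at the generating parameters", {
  set.seed(31)
  mod <- chain_wta_model(2, seed = 31, bhat = c(-0.8, -0.8))
  # sample y from the model itself: z from the prior, y | z
  S <- 1e4
  pt <- prior_table(mod)
  zi <- sample.int(nrow(pt$states), S, replace = TRUE, prob = pt$probs)
  P <- matrix(mod$defaults, S, mod$N, byrow = TRUE)
  for (k in 1:mod$K) {
    on <- pt$states[zi, k] == 1
    P[on, mod$fields[[k]]] <- matrix(mod$params[k, mod$fields[[k]]],
                                     sum(on), 3, byrow = TRUE)
  }
  Y <- matrix(rbinom(length(P), 1, as.numeric(P)), S, mod$N)
  ll_true <- log_likelihood(Y, mod)
  pert <- mod
  pert$params <- pmin(pmax(mod$params + 0.15, 0.02), 0.98)
  ll_pert <- log_likelihood(Y, pert)
  expect_gt(ll_true, ll_pert)
})

test_that("input reconstruction averages the generative expectation", {
  mod <- chain_wta_model(2, seed = 41)
  net <- network_from_model(mod)
  N <- mod$N
  expect_equal(reconstruct_input(matrix(0, 10, 2), net),
               rep(0.15, N), tolerance = 1e-12)
  z1 <- matrix(rep(c(1, 0), each = 10), 10, 2)
  rec1 <- reconstruct_input(z1, net)
  expect_equal(rec1[mod$fields[[1]]], mod$params[1, mod$fields[[1]]],
               tolerance = 1e-12)
  half <- rbind(matrix(0, 5, 2), z1[1:5, ])
  expect_equal(reconstruct_input(half, net)[1],
               (0.15 + mod$params[1, 1]) / 2, tolerance = 1e-12)
})

test_that("network serialization round-trips exactly", {
  mod <- chain_wta_model(3, seed = 51)
  net <- network_from_model(mod)
  f <- tempfile(fileext = ".txt")
  write_network(net, f, extra = list(bhat = mod$bhat))
  back <- read_network(f)
  expect_equal(back$network$V, net$V)
  expect_equal(back$network$b, net$b)
  expect_equal(back$network$Winh, net$Winh)
  expect_equal(back$bhat, mod$bhat)
  expect_equal(back$network$fields, net$fields)
  unlink(f)
})
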