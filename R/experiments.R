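#' Experiment configuration with simulation-table defaults
#'
#' Returns the full parameter set of one of the five packaged experiment
#' protocols; any field can be overridden through `...`.  The defaults
#' are the reference simulation parameters of each protocol (durations,
#' grid sizes, background activities, homeostatic targets, learning
#' rates, initial excitabilities).
#'
#' @param experiment one of `"fig2"` (fixed-parameter inference demo),
#'   `"fig3"` (afferent learning in an overlapping sheet), `"fig4"`
#'   (recurrent learning of cue structure), `"fig5"` (large sheet with
#'   sparse recurrent excitation), `"fig6"` (two-neuron homeostasis
#'   illustration).
#' @param seed integer seed.
#' @param ... overrides (e.g. `T`, `eta_w`, `recurrent_rule`).
#' @export
experiment_config <- function(experiment = c("fig2", "fig3", "fig4",
                                             "fig5", "fig6"),
                              seed = 1, ...) {
  experiment <- match.arg(experiment)
  base <- list(
    fig2 = list(T = 2.5, K = 6, pi0 = 0.2, act_range = c(0.2, 0.55),
                bhat = -1, Wexc_val = 1, eta_b = 0, eta_v = 0, eta_w = 0,
                m = NA, recurrent_rule = "none"),
    fig3 = list(T = 10000, n_loc = 7, pop_size = 3, pi0 = 0.1,
                act_range = c(0.1, 0.6), m = 0.065, b_init = -2,
                eta_b = 1, eta_v = 0.2, eta_w = 0,
                recurrent_rule = "none"),
    fig4 = list(T = 25000, n_pops = 7, pop_size = 3, pi0 = 0.1,
                act_low = 0.1, act_high = 0.4, m = 0.95 / 3, b_init = -1,
                eta_b = 0.1, eta_v = 0.1, eta_w = 0.005,
                recurrent_rule = "heuristic", wmax = 1.41, gamma = 31.6,
                eta_w_wakesleep = 0.05),
    fig5 = list(T = 10000, pi0 = 0.1, act_high = 0.5, m = 0.025,
                b_init = -3, eta_b = 10, eta_v = 2, eta_w = 1,
                recurrent_rule = "heuristic", wmax = 2.70, gamma = 734,
                p_conn = 0.25, pattern_dur = 0.1, inh_range = 2),
    fig6 = list(T = 5000, pi0 = 0.2, act_high = 0.8, m = 0.32,
                b_init = -2, eta_b = 1.5, eta_v = 0.3, eta_w = 0,
                recurrent_rule = "none", pattern_dur = 1))[[experiment]]
  cfg <- utils::modifyList(c(list(experiment = experiment, seed = seed,
                                  dt = 0.001, tau = 0.010), base),
                           list(...))
  class(cfg) <- "experiment_config"
  cfg
}

# ---------------------------------------------------------------------------
# schedule utilities

#' Slice a schedule to a time window
#'
#' Restricts a piecewise-constant schedule to `[t0, t1)`, splitting the
#' boundary segments, so long protocols can be simulated in chunks.
#'
#' @param schedule an [input_schedule()].
#' @param t0,t1 window bounds in seconds.
#' @export
schedule_slice <- function(schedule, t0, t1) {
  ends <- cumsum(schedule$durations)
  starts <- c(0, ends[-length(ends)])
  keep <- which(ends > t0 + 1e-12 & starts < t1 - 1e-12)
  dur <- pmin(ends[keep], t1) - pmax(starts[keep], t0)
  input_schedule(dur, schedule$X[keep, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# fig2: fixed-parameter inference on transient patterned input

#' Generate the six-neuron chain protocol (inference demonstration)
#'
#' Six neurons with overlapping 6x6 fields shifted by 3 on an 18-column
#' input torus; each neuron owns a random preferred activity pattern in
#' `(0.2, 0.55)`; afferent weights are set from the patterns, recurrent
#' excitatory links connect pairs (1,3), (3,5), (4,6), and excitabilities
#' are `b_k = -1 - A_k`.  The schedule alternates background segments
#' with structured segments where a conflict-free subset of patterns is
#' shown (no two adjacent neurons' patterns at once).
#'
#' @param T schedule duration (s).
#' @param config an [experiment_config()] for `"fig2"`.
#' @return list with `schedule`, `patterns` (6 x 36), `model`,
#'   `network`, `topology`.
#' @export
gen_fig2_input <- function(T = 2.5, config = experiment_config("fig2")) {
  topo <- build_grid_sheet(c(6, 18), c(1, 6), c(6, 6), c(0, 3), c(0, 1))
  topo <- set_excitatory_pairs(topo, rbind(c(1, 3), c(3, 5), c(4, 6)))
  K <- topo$K; N <- topo$N
  patterns <- matrix(stats::runif(K * 36, config$act_range[1],
                                  config$act_range[2]), K, 36)
  pi_mat <- matrix(config$pi0, K, N)
  for (k in seq_len(K)) pi_mat[k, topo$fields[[k]]] <- patterns[k, ]
  model <- generative_model("bernoulli", pi_mat, rep(config$pi0, N),
                            fields = topo$fields,
                            Wexc_hat = config$Wexc_val * topo$exc_pairs,
                            Winh_hat = -100 * topo$inh_pairs,
                            bhat = rep(config$bhat, K))
  network <- network_from_model(model)

  durations <- numeric(0); Xs <- list(); t <- 0
  while (t < T) {
    d <- stats::runif(1, 0.1, 0.3)
    x <- rep(config$pi0, N)
    active <- logical(K)
    for (k in sample.int(K)) {
      nb <- c(k - 1, k + 1); nb <- ifelse(nb < 1, K, ifelse(nb > K, 1, nb))
      if (!any(active[nb]) && stats::runif(1) < 0.4) {
        active[k] <- TRUE
        x[topo$fields[[k]]] <- patterns[k, ]
      }
    }
    durations <- c(durations, d); Xs[[length(Xs) + 1]] <- x
    t <- t + d
  }
  durations[length(durations)] <- durations[length(durations)] - (t - T)
  list(schedule = input_schedule(durations, do.call(rbind, Xs)),
       patterns = patterns, model = model, network = network,
       topology = topo)
}

# ---------------------------------------------------------------------------
# fig3: Dirichlet patterns presented through Gamma-timed chains

#' Generate the overlapping-sheet learning protocol
#'
#' Seven overlapping 6x6 input locations (shifted by 3 columns), three
#' random activity patterns per location drawn as
#' `0.5 * Dirichlet(0.3, 0.3, 0.3) + 0.1` per input, presented through
#' three on/off chains with Gamma-distributed inactive (shape 10, scale
#' 10 ms) and active (shape 10, scale 20 ms) durations; an activating
#' chain picks a uniform pattern and a location whose field does not
#' overlap any other active chain's.
#'
#' @param T schedule duration (s).
#' @param config an [experiment_config()] for `"fig3"`.
#' @return list with `schedule`, `patterns` (location x pattern x 36
#'   array), `topology`, `loc_fields`, and the chain `events` matrix
#'   (time, chain, active, location, pattern).
#' @export
gen_fig3_input <- function(T, config = experiment_config("fig3")) {
  topo <- build_grid_sheet(c(6, 21), c(3, 7), c(6, 6), c(0, 3),
                           c(Inf, 1))
  n_loc <- config$n_loc
  loc_fields <- lapply(seq_len(n_loc),
                       function(l) topo$fields[[(l - 1) * 3 + 1]])
  patterns <- array(0, c(n_loc, 3, 36))
  for (l in seq_len(n_loc)) for (j in seq_len(36)) {
    g <- stats::rgamma(3, shape = 0.3, rate = 1)
    patterns[l, , j] <- 0.5 * g / sum(g) + 0.1
  }
  # three chains in continuous time
  n_chains <- 3
  ch_active <- rep(FALSE, n_chains)
  ch_loc <- rep(NA_integer_, n_chains); ch_pat <- rep(NA_integer_, n_chains)
  ch_next <- stats::rgamma(n_chains, 10, scale = 10) / 1000
  events <- vector("list", 20000)  # (time, chain, active, loc, pat)
  ne <- 0
  repeat {
    cidx <- which.min(ch_next)
    tc <- ch_next[cidx]
    if (tc >= T) break
    ne <- ne + 1
    if (ch_active[cidx]) {
      ch_active[cidx] <- FALSE
      events[[ne]] <- c(tc, cidx, 0, ch_loc[cidx], ch_pat[cidx])
      ch_loc[cidx] <- NA; ch_pat[cidx] <- NA
      ch_next[cidx] <- tc + stats::rgamma(1, 10, scale = 10) / 1000
    } else {
      occupied <- ch_loc[!is.na(ch_loc)]
      free <- which(vapply(seq_len(n_loc), function(l)
        all(torus_dist(l - 1, occupied - 1, n_loc) >= 2), TRUE))
      if (length(free) == 0)
        stop("no non-overlapping location available")  # cannot happen here
      l <- free[sample.int(length(free), 1)]
      p <- sample.int(3, 1)
      ch_active[cidx] <- TRUE
      ch_loc[cidx] <- l; ch_pat[cidx] <- p
      events[[ne]] <- c(tc, cidx, 1, l, p)
      ch_next[cidx] <- tc + stats::rgamma(1, 10, scale = 20) / 1000
    }
  }
  ev <- do.call(rbind, events[seq_len(ne)])
  times <- sort(unique(c(0, ev[, 1], T)))
  N <- topo$N
  X <- matrix(config$pi0, length(times) - 1, N)
  cur <- matrix(NA_real_, n_chains, 2)  # loc, pat per chain
  ei <- 1
  for (s in seq_len(length(times) - 1)) {
    while (ei <= nrow(ev) && ev[ei, 1] <= times[s] + 1e-12) {
      ch <- ev[ei, 2]
      if (ev[ei, 3] == 1) cur[ch, ] <- ev[ei, 4:5] else cur[ch, ] <- NA
      ei <- ei + 1
    }
    for (ch in seq_len(n_chains)) {
      if (!is.na(cur[ch, 1])) {
        l <- cur[ch, 1]; p <- cur[ch, 2]
        X[s, loc_fields[[l]]] <- patterns[l, p, ]
      }
    }
  }
  colnames(ev) <- c("time", "chain", "active", "loc", "pattern")
  list(schedule = input_schedule(diff(times), X),
       patterns = patterns, topology = topo, loc_fields = loc_fields,
       events = ev)
}

# ---------------------------------------------------------------------------
# fig4: stripe patterns with cue/consistency structure

fig4_stripe <- function(p, high = 0.4, low = 0.1) {
  cols <- floor((0:35 %% 6) / 2)  # width-2 vertical stripes
  ifelse(cols == (p - 1), high, low)
}

#' Generate the cue/consistency protocol over seven populations
#'
#' Three width-2 vertical stripe patterns ("red", "green", "blue") on
#' each population's 6x6 field.  The two outer locations are independent
#' cues; the five inner locations all show the unique pattern different
#' from both cues (distinct cues, one 500 ms segment) or, for equal cues,
#' each of the two valid patterns for 250 ms.  The nine cue combinations
#' cycle deterministically.
#'
#' @param T schedule duration (s).
#' @param config an [experiment_config()] for `"fig4"`.
#' @param mode `"train"` for the stripe protocol, `"cue_test"` for the
#'   incomplete-observation probe (high-contrast cues at 0.6, gray inner
#'   input at 0.35) cycling the nine cue combinations.
#' @return list with `schedule`, `topology`, `segments` (data frame of
#'   cue and inner labels), `stripes` (3 x 36 template matrix).
#' @export
gen_fig4_input <- function(T, config = experiment_config("fig4"),
                           mode = c("train", "cue_test")) {
  mode <- match.arg(mode)
  topo <- build_population_topology(config$n_pops, config$pop_size)
  n_pops <- config$n_pops
  N <- topo$N
  loc_fields <- lapply(seq_len(n_pops),
                       function(l) topo$fields[[(l - 1) * config$pop_size + 1]])
  stripes <- t(vapply(1:3, fig4_stripe, numeric(36),
                      high = config$act_high, low = config$act_low))
  combos <- expand.grid(pl = 1:3, pr = 1:3)
  seg_dur <- numeric(0); seg_lab <- list(); Xs <- list()
  make_x <- function(pl, pr, inner) {
    x <- rep(config$pi0, N)
    if (mode == "train") {
      x[loc_fields[[1]]] <- stripes[pl, ]
      x[loc_fields[[n_pops]]] <- stripes[pr, ]
      for (l in 2:(n_pops - 1)) x[loc_fields[[l]]] <- stripes[inner, ]
    } else {
      hi <- t(vapply(1:3, fig4_stripe, numeric(36), high = 0.6,
                     low = config$act_low))
      x[loc_fields[[1]]] <- hi[pl, ]
      x[loc_fields[[n_pops]]] <- hi[pr, ]
      for (l in 2:(n_pops - 1)) x[loc_fields[[l]]] <- (0.6 + 0.1) / 2
    }
    x
  }
  add_seg <- function(d, pl, pr, inner) {
    seg_dur[[length(seg_dur) + 1]] <<- d
    Xs[[length(Xs) + 1]] <<- make_x(pl, pr, inner)
    seg_lab[[length(seg_lab) + 1]] <<- c(pl, pr, inner)
  }
  t <- 0
  while (t < T) {
    for (r in seq_len(nrow(combos))) {
      pl <- combos$pl[r]; pr <- combos$pr[r]
      if (mode == "cue_test") {
        add_seg(0.5, pl, pr, NA)
        t <- t + 0.5
      } else if (pl != pr) {
        add_seg(0.5, pl, pr, setdiff(1:3, c(pl, pr)))
        t <- t + 0.5
      } else {
        valid <- setdiff(1:3, pl)
        for (v in valid) { add_seg(0.25, pl, pr, v); t <- t + 0.25 }
      }
      if (t >= T) break
    }
  }
  dur <- unlist(seg_dur)
  over <- sum(dur) - T
  if (over > 0) dur[length(dur)] <- dur[length(dur)] - over
  labs <- do.call(rbind, seg_lab)
  list(schedule = input_schedule(dur, do.call(rbind, Xs)),
       topology = topo,
       segments = data.frame(cue_left = labs[, 1], cue_right = labs[, 2],
                             inner = labs[, 3], duration = dur),
       stripes = stripes, loc_fields = loc_fields)
}

# ---------------------------------------------------------------------------
# fig5: spatial motifs at random locations on a large sheet

fig5_template <- function(which, r, c) {
  switch(which,
         (r %% 3 == 0) | (c %% 3 == 0),   # grid
         ((r - c) %% 4) < 2,              # diagonal stripes
         ((r + c) %% 2) == 0)             # checkerboard
}

#' Generate the random-motif protocol for the 12x12 sheet
#'
#' Three binary motifs (grid, diagonal stripes, checkerboard) at high
#' rate 0.5 over background 0.1.  Every `pattern_dur` seconds two motifs
#' (possibly equal) are placed at non-overlapping random torus locations;
#' motif diameters are drawn uniformly from 8..12 input units, always
#' exceeding the 6x6 afferent fields.
#'
#' @param T schedule duration (s).
#' @param config an [experiment_config()] for `"fig5"`.
#' @param topology optionally a prebuilt topology (so the excitatory
#'   mask can be fixed across calls).
#' @return list with `schedule`, `topology`, `placements`.
#' @export
gen_fig5_input <- function(T, config = experiment_config("fig5"),
                           topology = NULL) {
  if (is.null(topology)) {
    topology <- build_grid_sheet(c(24, 24), c(12, 12), c(6, 6), c(2, 2),
                                 config$inh_range)
    topology <- sample_excitatory_mask(topology, config$p_conn)
  }
  dim_in <- topology$input_dim
  n_seg <- ceiling(T / config$pattern_dur)
  X <- matrix(config$pi0, n_seg, topology$N)
  placements <- vector("list", n_seg)
  overlap_1d <- function(a0, ad, b0, bd, n) {
    # circular interval overlap on a ring of length n
    da <- ((b0 - a0) %% n)
    db <- ((a0 - b0) %% n)
    da < ad || db < bd
  }
  for (s in seq_len(n_seg)) {
    for (attempt in seq_len(1000)) {
      p <- sample.int(3, 2, replace = TRUE)
      d <- sample(8:12, 2, replace = TRUE)
      r0 <- sample.int(dim_in[1], 2) - 1L
      c0 <- sample.int(dim_in[2], 2) - 1L
      ok <- !(overlap_1d(r0[1], d[1], r0[2], d[2], dim_in[1]) &&
              overlap_1d(c0[1], d[1], c0[2], d[2], dim_in[2]))
      if (ok) break
      if (attempt == 1000) stop("motif placement retry budget exhausted")
    }
    x <- matrix(config$pi0, dim_in[1], dim_in[2])
    for (q in 1:2) {
      rr <- (r0[q] + 0:(d[q] - 1)) %% dim_in[1]
      cc <- (c0[q] + 0:(d[q] - 1)) %% dim_in[2]
      for (r in rr) for (cl in cc) {
        x[r + 1, cl + 1] <- if (fig5_template(p[q], r, cl))
          config$act_high else config$pi0
      }
    }
    X[s, ] <- as.numeric(t(x))  # row-major to match input indexing
    placements[[s]] <- data.frame(pattern = p, diameter = d,
                                  row = r0, col = c0)
  }
  dur <- rep(config$pattern_dur, n_seg)
  dur[n_seg] <- T - (n_seg - 1) * config$pattern_dur
  list(schedule = input_schedule(dur, X), topology = topology,
       placements = placements)
}

# ---------------------------------------------------------------------------
# fig6: nested weak/strong patterns for two WTA neurons

#' Generate the nested-pattern protocol for a two-neuron WTA
#'
#' Three patterns over one 6x6 field, cycled for equal time: a strong
#' pattern (a 4x4 block active at 0.8, rest 0.2), a weak pattern whose
#' active set is a strict subset of the strong one (its 2x2 corner), and
#' the uniform background (0.2 everywhere).
#'
#' @param T schedule duration (s).
#' @param config an [experiment_config()] for `"fig6"`.
#' @return list with `schedule`, `topology`, `patterns` (3 x 36),
#'   `active_sets`.
#' @export
gen_fig6_input <- function(T, config = experiment_config("fig6")) {
  topo <- build_population_topology(1, 2)
  grid <- matrix(seq_len(36), 6, 6, byrow = TRUE)
  strong_set <- as.integer(grid[1:4, 1:4])
  weak_set <- as.integer(grid[1:2, 1:2])
  pat <- matrix(config$pi0, 3, 36)
  pat[1, strong_set] <- config$act_high
  pat[2, weak_set] <- config$act_high
  n_cycle <- ceiling(T / (3 * config$pattern_dur))
  X <- pat[rep(1:3, n_cycle), , drop = FALSE]
  dur <- rep(config$pattern_dur, 3 * n_cycle)
  total <- sum(dur); X <- X[cumsum(dur) - dur < T, , drop = FALSE]
  dur <- dur[seq_len(nrow(X))]
  dur[length(dur)] <- T - sum(dur[-length(dur)])
  list(schedule = input_schedule(dur, X), topology = topo,
       patterns = pat,
       active_sets = list(strong = strong_set, weak = weak_set))
}

# ---------------------------------------------------------------------------
# driver

#' Run a configured experiment
#'
#' Wires topology, input generator, simulator and plasticity for one of
#' the five protocols and runs it in chunks, optionally evaluating the
#' data log-likelihood `L(theta(t))` at checkpoints (afferent-learning
#' protocols): prior biases are calibrated to the homeostatic targets on
#' the enumerated valid states and `L` is averaged over input samples
#' drawn from the training distribution.
#'
#' @param config an [experiment_config()].
#' @param ll_every checkpoint spacing in seconds (`NULL` disables the
#'   log-likelihood trace).
#' @param ll_samples input samples per log-likelihood evaluation.
#' @param chunk chunk length in seconds for the simulation loop.
#' @param wavg_frac final fraction of the run over which recurrent
#'   weights are time-averaged for the converged-weight summary.
#' @return a `sheet_experiment` list: `network`, `topology`, `generated`
#'   (generator output), `report` (log-likelihood trace, mean
#'   activities, weight summaries where applicable).
#' @export
run_experiment <- function(config, ll_every = NULL, ll_samples = 2000,
                           chunk = 250, wavg_frac = 0.1) {
  set.seed(config$seed)
  exp <- config$experiment
  gen <- switch(exp,
    fig2 = gen_fig2_input(config$T, config),
    fig3 = gen_fig3_input(config$T, config),
    fig4 = gen_fig4_input(config$T, config),
    fig5 = gen_fig5_input(config$T, config),
    fig6 = gen_fig6_input(config$T, config))
  topo <- gen$topology
  K <- topo$K; N <- topo$N

  if (exp == "fig2") {
    network <- gen$network
    plast <- NULL
  } else {
    network <- sheet_network(V = matrix(0, K, N),
                             V0 = stats::qlogis(rep(config$pi0, N)),
                             b = rep(config$b_init, K),
                             Wexc = matrix(0, K, K),
                             Winh = -100 * topo$inh_pairs,
                             fields = topo$fields)
    eta_w <- if (config$recurrent_rule == "wakesleep" &&
                 !is.null(config$eta_w_wakesleep))
      config$eta_w_wakesleep else config$eta_w
    plast <- plasticity_config(
      eta_v = config$eta_v, eta_b = config$eta_b,
      eta_w = if (config$recurrent_rule == "none") 0 else eta_w,
      m = config$m, rule = config$recurrent_rule,
      wmax = if (!is.null(config$wmax)) config$wmax else 1.41,
      gamma = if (!is.null(config$gamma)) config$gamma else 31.6)
  }

  wavg_start <- config$T * (1 - wavg_frac)
  ll_trace <- NULL
  ll_y <- NULL
  if (!is.null(ll_every)) {
    ll_y <- sample_inputs_from_schedule(gen$schedule, ll_samples)
    ll_trace <- data.frame(time = numeric(0), value = numeric(0))
  }
  eval_ll <- function(net, time) {
    bhat <- calibrate_prior_biases(net$Wexc, net$Winh,
                                   rep_len(config$m, K),
                                   use_valid_states = TRUE)
    model <- model_from_network(net, bhat, config$pi0)
    data.frame(time = time, value = log_likelihood(ll_y, model))
  }

  state <- NULL
  t0 <- 0
  seeds <- sample.int(.Machine$integer.max, ceiling(config$T / chunk) + 1)
  ci <- 0
  last <- NULL
  while (t0 < config$T - 1e-9) {
    ci <- ci + 1
    t1 <- min(t0 + chunk, config$T)
    if (!is.null(ll_trace) &&
        (t0 == 0 || floor(t0 / ll_every) != floor((t1 - 1e-9) / ll_every)))
      ll_trace <- rbind(ll_trace, eval_ll(network, t0))
    sl <- schedule_slice(gen$schedule, t0, t1)
    cc <- sim_config(T = t1 - t0, dt = config$dt, tau = config$tau,
                     seed = seeds[ci])
    ws <- max(0, wavg_start - t0)
    last <- run_network(network, topo, sl, cc, plasticity = plast,
                        init = state,
                        stat_start = if (t1 > wavg_start) ws else 0,
                        wavg_start = if (t1 > wavg_start) ws else NULL)
    network <- last$network
    state <- last$state
    if (ci == 1) wavg_acc <- NULL
    if (!is.null(last$stats$wavg)) {
      wpart <- last$stats$wavg * (t1 - max(t0, wavg_start))
      wavg_acc <- if (is.null(wavg_acc)) wpart else wavg_acc + wpart
    }
    t0 <- t1
  }
  if (!is.null(ll_trace))
    ll_trace <- rbind(ll_trace, eval_ll(network, config$T))

  wavg <- if (!is.null(wavg_acc))
    wavg_acc / (config$T - wavg_start) else network$Wexc

  report <- list(log_likelihood = ll_trace,
                 zbar_final = last$stats$zbar,
                 rate_hz_final = last$stats$rate_hz)
  if (exp == "fig4") {
    report$tuning <- fig4_tuning_labels(network, gen)
    report$weights <- fig4_weight_summary(wavg, report$tuning, config)
  }
  if (exp == "fig5") {
    report$tuning <- fig5_tuning_labels(network, topo)
    report$weights <- fig5_weight_summary(wavg, report$tuning, topo)
  }
  structure(list(config = config, network = network, topology = topo,
                 generated = gen, wavg = wavg, report = report),
            class = "sheet_experiment")
}

# Bernoulli model whose parameters mirror a (learned) network, used for
# log-likelihood scoring: pi_ki = sigmoid(V_ki + V_0i) on the fields.
model_from_network <- function(network, bhat, pi0) {
  K <- network$K; N <- network$N
  pi_mat <- matrix(pi0, K, N)
  for (k in seq_len(K)) {
    idx <- network$fields[[k]]
    pi_mat[k, idx] <- stats::plogis(network$V[k, idx] + network$V0[idx])
  }
  generative_model("bernoulli", pi_mat, rep(pi0, N),
                   fields = network$fields, Wexc_hat = network$Wexc,
                   Winh_hat = network$Winh, bhat = bhat)
}

# draw approximate input samples y ~ p*(y): segment by time share, then
# independent Bernoulli(x_i) (the marginal activation of the PSP process)
sample_inputs_from_schedule <- function(schedule, S) {
  seg <- sample.int(nrow(schedule$X), S, replace = TRUE,
                    prob = schedule$durations)
  X <- schedule$X[seg, , drop = FALSE]
  Y <- matrix(stats::rbinom(length(X), 1, as.numeric(X)), nrow(X), ncol(X))
  Y
}

# label each neuron by the stripe pattern its afferent weights match best
fig4_tuning_labels <- function(network, gen) {
  K <- network$K
  lab <- integer(K)
  for (k in seq_len(K)) {
    v <- network$V[k, network$fields[[k]]]
    lab[k] <- which.max(as.numeric(gen$stripes %*% v))
  }
  lab
}

# grouped converged-weight means for the cue/consistency task
fig4_weight_summary <- function(wavg, tuning, config) {
  n_pops <- config$n_pops; ps <- config$pop_size
  pop <- rep(seq_len(n_pops), each = ps)
  inner <- pop >= 2 & pop <= n_pops - 1
  cue <- pop == 1 | pop == n_pops
  K <- length(pop)
  grp <- matrix("", K, K)
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j == k || pop[k] == pop[j]) next
    same <- tuning[k] == tuning[j]
    grp[k, j] <-
      if (inner[k] && inner[j] && same) "inner_same"
      else if ((cue[k] && inner[j] && !same) ||
               (inner[k] && cue[j] && !same)) "cue_inner_compatible"
      else if (cue[k] && cue[j] && pop[k] != pop[j] && same) "cue_cue_same"
      else "other"
  }
  ut <- upper.tri(grp)
  sel <- function(g) wavg[ut & grp == g]
  list(inner_same = mean(sel("inner_same")),
       cue_inner_compatible = mean(sel("cue_inner_compatible")),
       cue_cue_same = mean(sel("cue_cue_same")),
       other_max = if (length(sel("other"))) max(sel("other")) else 0,
       groups = grp)
}

# label each neuron of the large sheet by its best-correlated motif
fig5_tuning_labels <- function(network, topo) {
  K <- network$K
  dim_in <- topo$input_dim
  lab <- integer(K)
  for (k in seq_len(K)) {
    idx <- topo$fields[[k]]
    rc <- cbind((idx - 1) %/% dim_in[2], (idx - 1) %% dim_in[2])
    v <- network$V[k, idx]
    cors <- vapply(1:3, function(p) {
      tmpl <- as.numeric(fig5_template(p, rc[, 1], rc[, 2]))
      if (stats::sd(v) == 0 || stats::sd(tmpl) == 0) return(-Inf)
      stats::cor(v, tmpl)
    }, numeric(1))
    lab[k] <- which.max(cors)
  }
  lab
}

# same-tuning vs different-tuning and distance-binned weight means
fig5_weight_summary <- function(wavg, tuning, topo) {
  ep <- excitatory_pairs(topo)
  w <- wavg[ep]
  same <- tuning[ep[, 1]] == tuning[ep[, 2]]
  co <- topo$coords
  d <- sqrt(torus_dist(co[ep[, 1], 1], co[ep[, 2], 1],
                       topo$neuron_dim[1])^2 +
            torus_dist(co[ep[, 1], 2], co[ep[, 2], 2],
                       topo$neuron_dim[2])^2)
  bins <- cut(d, breaks = c(0, 3, 5, 7, Inf))
  list(same_tuning_mean = mean(w[same]),
       diff_tuning_mean = mean(w[!same]),
       by_distance = tapply(w, bins, mean),
       n_synapses = length(w))
}

#' Compare repeated-run marginals with the exact posterior
#'
#' For identical input across runs, computes the per-(neuron, time)
#' mismatch `p_net - p_theo` between the run-averaged network response
#' and the analytically computed posterior marginals, raw and box-kernel
#' smoothed.
#'
#' @param traces list of binary `T x K` state matrices from repeated runs
#'   with spike-level identical input.
#' @param exact_marginals `T x K` matrix of exact posterior marginals.
#' @param kernel_width box-kernel width (s); `dt` step (s).
#' @return list with `mismatch_raw`, `mismatch_smoothed` (matrices),
#'   `median_abs_raw`, `median_abs_smoothed`.
#' @export
marginal_comparison <- function(traces, exact_marginals,
                                kernel_width = 0.020, dt = 0.001) {
  p_net_raw <- empirical_marginals(traces, kernel_width = 0, dt = dt)
  if (nrow(p_net_raw) != nrow(exact_marginals))
    stop("trace and oracle lengths differ")
  p_net_sm <- empirical_marginals(traces, kernel_width = kernel_width,
                                  dt = dt)
  p_th_sm <- empirical_marginals(exact_marginals,
                                 kernel_width = kernel_width, dt = dt)
  raw <- p_net_raw - exact_marginals
  smo <- p_net_sm - p_th_sm
  list(mismatch_raw = raw, mismatch_smoothed = smo,
       median_abs_raw = stats::median(abs(raw)),
       median_abs_smoothed = stats::median(abs(smo)))
}

#' Exact posterior marginals along a recorded input trace
#'
#' @param y_trace binary `T x N` input matrix.
#' @param model a [generative_model()] (small `K`).
#' @return `T x K` matrix of marginals `p(z_k = 1 | y(t))`.
#' @export
posterior_marginals_trace <- function(y_trace, model) {
  S <- all_states(model$K)
  net <- network_from_model(model)
  base <- prior_log_prob(S, model) - drop(S %*% net$A)
  M <- S %*% net$V %*% t(y_trace)          # states x T
  M <- M + base
  M <- sweep(M, 2, apply(M, 2, max))
  P <- exp(M)
  P <- sweep(P, 2, colSums(P), "/")
  t(crossprod(S, P))                       # T x K
}
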