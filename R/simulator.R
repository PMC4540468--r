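#' Simulation configuration
#'
#' @param T total simulated duration in seconds.
#' @param dt time step in seconds (1 ms).
#' @param tau PSP and refractory duration in seconds; `tau / dt` must be a
#'   whole number of steps.
#' @param seed integer seed for the run's private random stream.
#' @return a `sim_config` list with the derived step counts.
#' @export
sim_config <- function(T, dt = 0.001, tau = 0.010, seed = 1) {
  stopifnot(dt > 0, T >= 0)
  tau_steps <- tau / dt
  if (abs(tau_steps - round(tau_steps)) > 1e-9 || round(tau_steps) < 1)
    stop("tau must be a positive whole number of time steps")
  structure(list(T = T, dt = dt, tau = tau,
                 tau_steps = as.integer(round(tau_steps)),
                 n_steps = as.integer(round(T / dt)),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Piecewise-constant input schedule
#'
#' Target activations `x_i(t) in [0, 1)` held constant on consecutive
#' segments that tile `[0, T]`.
#'
#' @param durations segment durations in seconds.
#' @param X matrix of target activations, one segment per row.
#' @export
input_schedule <- function(durations, X) {
  X <- as.matrix(X)
  if (length(durations) != nrow(X))
    stop("one duration per schedule segment required")
  if (any(X < 0 | X >= 1))
    stop("target activations must lie in [0, 1)")
  structure(list(durations = as.numeric(durations), X = X,
                 T = sum(durations)),
            class = "input_schedule")
}

#' Per-step spike probability achieving a target activation
#'
#' With rectangular PSPs of `tau_steps` steps, an input is active iff it
#' spiked within the last `tau_steps` steps, so drawing spikes with
#' probability `p = 1 - (1 - x)^(1 / tau_steps)` per step yields
#' `<y_i> = x`.
#'
#' @param x target activation in `[0, 1)`.
#' @param tau_steps PSP duration in steps.
#' @export
input_spike_probability <- function(x, tau_steps) {
  if (any(x < 0 | x >= 1)) stop("target activation must lie in [0, 1)")
  1 - (1 - x)^(1 / tau_steps)
}

#' Membrane potential of all network neurons
#'
#' `u_k = b_k + sum_j (Wexc_kj + Winh_kj) z_j + sum_i V_ki y_i`.
#'
#' @param network a `sheet_network`.
#' @param z,y binary state vectors.
#' @export
membrane_potential <- function(network, z, y) {
  drop(network$b + (network$Wexc + network$Winh) %*% as.numeric(z) +
         network$V %*% as.numeric(y))
}

# CSR helpers for the C++ core (0-based)
fields_to_csr <- function(fields) {
  idx <- unlist(lapply(fields, function(i) as.integer(i) - 1L),
                use.names = FALSE)
  ptr <- c(0L, cumsum(vapply(fields, length, 1L)))
  list(idx = as.integer(idx), ptr = as.integer(ptr))
}

projections_to_csr <- function(fields, N) {
  lst <- vector("list", N)
  for (k in seq_along(fields))
    for (i in fields[[k]]) lst[[i]] <- c(lst[[i]], k - 1L)
  list(idx = as.integer(unlist(lst, use.names = FALSE)),
       ptr = c(0L, cumsum(vapply(lst, length, 1L))))
}

neighbours_to_csr <- function(Wexc_support, Winh) {
  K <- nrow(Winh)
  adj <- Wexc_support | (Winh != 0)
  diag(adj) <- FALSE
  lst <- lapply(seq_len(K), function(k) which(adj[k, ]) - 1L)
  list(idx = as.integer(unlist(lst, use.names = FALSE)),
       ptr = c(0L, cumsum(vapply(lst, length, 1L))))
}

#' Run the discrete-time spiking simulation
#'
#' Advances the network for `config$T` seconds.  Optionally applies the
#' plasticity rules each step (see [plasticity_config()]) and records
#' dense state traces, spike events, state occupancy counts, and running
#' statistics.  The run is reproducible bit-for-bit from `config$seed`.
#'
#' @param network a `sheet_network`.
#' @param topology a `sheet_topology`; its excitatory pair list defines
#'   which recurrent weights are plastic.  May be `NULL` for fully
#'   connected toy networks (fields and masks taken from the network).
#' @param schedule an [input_schedule()]; ignored when `y_given` is
#'   supplied.
#' @param config a [sim_config()].
#' @param plasticity a [plasticity_config()] or `NULL` (frozen weights).
#' @param y_given optional dense binary input trace (`n_steps x N`) for
#'   spike-level identical replays.
#' @param record character vector among `"z"`, `"y"`, `"spikes"`,
#'   `"occupancy"`, `"coactivation"`.
#' @param init carry-over state from a previous chunk (the `state` field
#'   of a previous result), for chunked long runs.
#' @param stat_start,wavg_start start times (s) of the activity-statistics
#'   window and of the recurrent-weight time-average window (`NULL`
#'   disables weight averaging; `0` covers the whole run).
#' @param flush_every batching interval (s) for the synaptic plasticity
#'   flush: pre/post coincidences are accumulated per step but the slow
#'   weight-dependent terms are applied in one Euler update per interval
#'   (far below the learning timescales `1/eta`).
#' @param occupancy_burn_in discarded prefix (s) for occupancy counts.
#' @return a `sheet_run` list: updated `network`, `state`, recordings
#'   (`z`, `y`, `spikes`), `occupancy`, and `stats` (`zbar`, `rate_hz`,
#'   `coact`, `wavg`, `n_steps`).
#' @export
run_network <- function(network, topology = NULL, schedule = NULL, config,
                        plasticity = NULL, y_given = NULL,
                        record = character(0), init = NULL,
                        stat_start = 0, wavg_start = NULL,
                        occupancy_burn_in = 0, flush_every = 0.05) {
  K <- network$K; N <- network$N
  fields <- if (!is.null(topology)) topology$fields else network$fields
  exc_support <- if (!is.null(topology)) topology$exc_pairs
                 else network$Wexc != 0
  fcsr <- fields_to_csr(fields)
  pcsr <- projections_to_csr(fields, N)
  ncsr <- neighbours_to_csr(exc_support, network$Winh)
  ep <- which(exc_support & upper.tri(exc_support), arr.ind = TRUE)
  n_steps <- config$n_steps

  if (!is.null(y_given)) {
    y_given <- as.matrix(y_given)
    storage.mode(y_given) <- "integer"
    if (nrow(y_given) != n_steps || ncol(y_given) != N)
      stop("y_given must be an n_steps x N binary matrix")
    seg_steps <- integer(0); X <- matrix(0, 0, N)
  } else {
    if (is.null(schedule)) stop("either a schedule or y_given is required")
    # align segment boundaries on absolute step counts so rounding
    # errors cannot accumulate across many fractional-length segments
    seg_steps <- as.integer(diff(c(0, round(cumsum(schedule$durations) /
                                              config$dt))))
    X <- schedule$X
    if (ncol(X) != N) stop("schedule width does not match the input count")
    if (sum(seg_steps) < n_steps)
      stop("schedule does not cover the simulated duration")
    y_given <- matrix(0L, 0, N)
  }

  if (is.null(init)) {
    init <- list(z_countdown = integer(K), y_countdown = integer(N),
                 sleep_countdown = integer(K),
                 bsleep = if (!is.null(plasticity)) plasticity$bsleep_init
                          else numeric(K))
    if (is.null(init$bsleep)) init$bsleep <- numeric(K)
  }

  pl <- plasticity
  plastic <- !is.null(pl)
  if (!plastic)
    pl <- list(eta_v = 0, eta_b = 0, eta_w = 0, m = numeric(K),
               rule = "none", wmax = 1, gamma = 1, nonneg = TRUE,
               eta_b_sleep = 0)
  rule_code <- match(pl$rule, c("none", "wakesleep", "heuristic")) - 1L

  res <- .cpp_run_sheet(
    n_steps, config$tau_steps, config$dt,
    network$V, network$V0, network$b, network$Wexc, network$Winh,
    fcsr$idx, fcsr$ptr, pcsr$idx, pcsr$ptr, ncsr$idx, ncsr$ptr,
    as.integer(ep[, 1] - 1L), as.integer(ep[, 2] - 1L),
    seg_steps, X, y_given,
    as.integer(init$z_countdown), as.integer(init$y_countdown),
    as.integer(init$sleep_countdown), as.numeric(init$bsleep),
    plastic, pl$eta_v, pl$eta_b, pl$eta_w,
    rep_len(as.numeric(pl$m), K), rule_code, pl$wmax, pl$gamma,
    pl$nonneg, pl$eta_b_sleep,
    "z" %in% record, "y" %in% record, "spikes" %in% record,
    "occupancy" %in% record, "coactivation" %in% record,
    as.integer(round(occupancy_burn_in / config$dt)),
    as.integer(round(stat_start / config$dt)),
    if (is.null(wavg_start)) -1L else as.integer(round(wavg_start / config$dt)),
    as.integer(round(flush_every / config$dt)),
    as.double(config$seed))

  network$V <- res$V; network$b <- res$b; network$Wexc <- res$Wexc

  spikes <- NULL
  if ("spikes" %in% record) {
    spikes <- data.frame(
      t_ms = res$spike_step * config$dt * 1000,
      population = c("network", "input")[res$spike_pop + 1L],
      unit_id = res$spike_id)
  }
  occupancy <- NULL
  if ("occupancy" %in% record) {
    ord <- order(res$occ_code)
    occupancy <- list(code = res$occ_code[ord], count = res$occ_count[ord])
  }
  stat_n <- max(res$stat_n, 1)
  stats <- list(
    zbar = res$zsum / stat_n,
    rate_hz = res$spike_count / (stat_n * config$dt),
    n_steps = n_steps, stat_n = res$stat_n)
  if ("coactivation" %in% record) stats$coact <- res$coact / stat_n
  if (!is.null(wavg_start) && res$wavg_n > 0)
    stats$wavg <- res$wavg / res$wavg_n

  structure(list(
    network = network,
    bsleep = res$bsleep,
    state = list(z_countdown = res$z_countdown,
                 y_countdown = res$y_countdown,
                 sleep_countdown = res$sleep_countdown,
                 bsleep = res$bsleep),
    z = if ("z" %in% record) res$zmat else NULL,
    y = if ("y" %in% record) res$ymat else NULL,
    spikes = spikes, occupancy = occupancy, stats = stats,
    config = config), class = "sheet_run")
}

#' Generate an input spike realization without a network
#'
#' Produces the dense binary input trace `y(t)` a schedule would induce,
#' for spike-level identical replays across repeated network runs.
#'
#' @inheritParams run_network
#' @export
generate_input_trace <- function(schedule, config) {
  net <- sheet_network(V = matrix(0, 1, ncol(schedule$X)),
                       V0 = numeric(ncol(schedule$X)),
                       b = -1e6, Wexc = matrix(0, 1, 1),
                       Winh = matrix(0, 1, 1))
  run <- run_network(net, schedule = schedule, config = config,
                     record = "y")
  run$y
}

#' Box-kernel smoothed per-neuron activation time series
#'
#' Averages binary state traces across repeated runs (if a list is given)
#' and smooths each neuron's trace with a centred boxcar kernel.
#'
#' @param traces a binary `T x K` matrix or a list of such matrices from
#'   repeated runs with identical input.
#' @param kernel_width kernel width in seconds.
#' @param dt time step (s).
#' @return numeric `T x K` matrix of smoothed activations.
#' @export
empirical_marginals <- function(traces, kernel_width = 0.020, dt = 0.001) {
  if (is.list(traces)) {
    avg <- Reduce(`+`, lapply(traces, function(m) {
      m <- as.matrix(m); storage.mode(m) <- "double"; m
    })) / length(traces)
  } else {
    avg <- as.matrix(traces); storage.mode(avg) <- "double"
  }
  w <- max(1L, as.integer(round(kernel_width / dt)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(avg)
  kern <- rep(1 / w, w)
  apply(avg, 2, function(x) {
    sm <- stats::filter(x, kern, sides = 2)
    # renormalized partial windows at the edges
    n <- length(x)
    h <- (w - 1L) / 2L
    for (t in seq_len(h)) {
      sm[t] <- mean(x[1:(t + h)])
      sm[n - t + 1] <- mean(x[(n - t + 1 - h):n])
    }
    as.numeric(sm)
  })
}

#' Empirical distribution over network states
#'
#' Converts recorded occupancy counts (or a dense state trace) into state
#' frequencies after discarding a burn-in prefix.
#'
#' @param run a `sheet_run` with occupancy recording, or a binary state
#'   matrix.
#' @param burn_in discarded prefix in steps (only for dense traces; for
#'   occupancy recordings the burn-in was fixed at run time).
#' @return data frame with columns `code` (bit `k` set iff `z_k = 1`)
#'   and `freq`, summing to 1.
#' @export
empirical_state_distribution <- function(run, burn_in = 0) {
  if (inherits(run, "sheet_run")) {
    if (is.null(run$occupancy))
      stop("run was not recorded with occupancy counts")
    cnt <- run$occupancy$count
    return(data.frame(code = run$occupancy$code, freq = cnt / sum(cnt)))
  }
  z <- as.matrix(run)
  if (burn_in > 0) z <- z[-seq_len(burn_in), , drop = FALSE]
  K <- ncol(z)
  code <- drop(z %*% 2^(seq_len(K) - 1))
  tab <- table(code)
  data.frame(code = as.numeric(names(tab)),
             freq = as.numeric(tab) / nrow(z))
}

#' Probabilities of a posterior table keyed by state code
#'
#' Helper aligning an enumerated posterior with
#' [empirical_state_distribution()]: bit `k` of the code is `z_k`.
#'
#' @param table a `posterior_table`.
#' @export
state_codes <- function(table) {
  K <- ncol(table$states)
  drop(table$states %*% 2^(seq_len(K) - 1))
}

#' Total-variation distance between an empirical and an exact state law
#'
#' @param empirical data frame from [empirical_state_distribution()].
#' @param table a `posterior_table`.
#' @export
tv_distance <- function(empirical, table) {
  codes <- state_codes(table)
  p <- table$probs
  q <- numeric(length(p))
  idx <- match(empirical$code, codes)
  if (anyNA(idx)) stop("empirical states outside the enumerated table")
  q[idx] <- empirical$freq
  0.5 * sum(abs(p - q))
}

#' Write spike events as columnar text
#'
#' Format: tab-separated `t_ms`, `population`, `unit_id` with a header
#' line and 0-based unit ids.
#'
#' @param spikes spike data frame from [run_network()].
#' @param path output file.
#' @export
write_spikes <- function(spikes, path) {
  out <- spikes
  out$unit_id <- out$unit_id  # already 0-based from the core
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read spike events written by [write_spikes()]
#' @param path input file.
#' @export
read_spikes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
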