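#' Build a sheet topology on a torus grid
#'
#' Places neurons on a grid of sites over a (row, col) input grid.  The
#' neuron at grid position `(a, b)` (0-based) reads a contiguous
#' `field_dim` window of inputs whose top-left corner sits at
#' `(a * field_shift[1], b * field_shift[2])`, wrapped on the torus.  A
#' zero shift along an axis makes all neurons in that direction share the
#' same window (e.g. three neurons per column of a sheet).  Inhibition
#' pairs are declared by per-axis torus distance on the neuron grid
#' (`<= inh_range` on both axes); the builder validates the lower bound
#' that any two neurons with overlapping afferent fields inhibit each
#' other, which the generative model requires.
#'
#' @param input_dim `c(rows, cols)` of the input grid.
#' @param neuron_dim `c(rows, cols)` of the neuron grid.
#' @param field_dim `c(rows, cols)` of each afferent field.
#' @param field_shift `c(row, col)` input-grid units per neuron step.
#' @param inh_range per-axis inhibition range in neuron-grid units
#'   (scalar recycled; `Inf` means the whole axis).
#' @param torus wrap fields and distances (the only supported mode; kept
#'   explicit because boundary handling is a modelling statement).
#' @return an object of class `sheet_topology` with fields `fields`
#'   (list `I_k`), `projections` (list `P_i`), `inh_pairs`, `exc_pairs`
#'   (logical `K x K`), `coords` (neuron grid coordinates, 0-based),
#'   and the geometry arguments.
#' @export
build_grid_sheet <- function(input_dim, neuron_dim, field_dim, field_shift,
                             inh_range, torus = TRUE) {
  stopifnot(torus)
  input_dim <- as.integer(input_dim); neuron_dim <- as.integer(neuron_dim)
  field_dim <- as.integer(field_dim)
  field_shift <- as.integer(rep_len(field_shift, 2))
  inh_range <- rep_len(inh_range, 2)
  if (any(field_dim > input_dim))
    stop("afferent field larger than the input grid")
  K <- prod(neuron_dim)
  N <- prod(input_dim)
  coords <- cbind(row = rep(0:(neuron_dim[1] - 1), times = neuron_dim[2]),
                  col = rep(0:(neuron_dim[2] - 1), each = neuron_dim[1]))
  # input index, row-major on the torus (0-based coords -> 1-based index)
  input_index <- function(r, c) {
    r <- r %% input_dim[1]; c <- c %% input_dim[2]
    r * input_dim[2] + c + 1L
  }
  fields <- vector("list", K)
  for (k in seq_len(K)) {
    r0 <- coords[k, 1] * field_shift[1]
    c0 <- coords[k, 2] * field_shift[2]
    rr <- rep(r0 + 0:(field_dim[1] - 1), each = field_dim[2])
    cc <- rep(c0 + 0:(field_dim[2] - 1), times = field_dim[1])
    fields[[k]] <- sort(unique(input_index(rr, cc)))
  }
  inh <- matrix(FALSE, K, K)
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j == k) next
    dr <- torus_dist(coords[k, 1], coords[j, 1], neuron_dim[1])
    dc <- torus_dist(coords[k, 2], coords[j, 2], neuron_dim[2])
    inh[k, j] <- dr <= inh_range[1] && dc <= inh_range[2]
  }
  topo <- new_topology(input_dim, neuron_dim, fields, inh,
                       matrix(FALSE, K, K), coords,
                       field_dim = field_dim, field_shift = field_shift)
  validate_topology(topo)
  topo
}

torus_dist <- function(a, b, n) {
  d <- abs(a - b)
  pmin(d, n - d)
}

new_topology <- function(input_dim, neuron_dim, fields, inh_pairs,
                         exc_pairs, coords, ...) {
  K <- length(fields)
  N <- prod(input_dim)
  projections <- vector("list", N)
  for (k in seq_len(K))
    for (i in fields[[k]])
      projections[[i]] <- c(projections[[i]], k)
  structure(list(K = K, N = N, input_dim = input_dim,
                 neuron_dim = neuron_dim, fields = fields,
                 projections = projections, inh_pairs = inh_pairs,
                 exc_pairs = exc_pairs, coords = coords, torus = TRUE, ...),
            class = "sheet_topology")
}

validate_topology <- function(topo) {
  K <- topo$K
  inh <- topo$inh_pairs; exc <- topo$exc_pairs
  if (!all(inh == t(inh)) || !all(exc == t(exc)))
    stop("pair masks must be symmetric")
  if (any(diag(inh)) || any(diag(exc)))
    stop("pair masks must have empty diagonal")
  if (any(inh & exc))
    stop("a pair cannot be both inhibitory and excitatory")
  offenders <- NULL
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j <= k) next
    if (length(intersect(topo$fields[[k]], topo$fields[[j]])) > 0 &&
        !inh[k, j])
      offenders <- rbind(offenders, c(k, j))
  }
  if (!is.null(offenders))
    stop("inhibition range too small: overlapping afferent fields ",
         "without inhibition for pairs ",
         paste(apply(offenders, 1, paste, collapse = "-"), collapse = ", "))
  invisible(topo)
}

#' @export
print.sheet_topology <- function(x, ...) {
  cat(sprintf("<sheet_topology> %d neurons (%d x %d) over %d inputs (%d x %d)\n",
              x$K, x$neuron_dim[1], x$neuron_dim[2],
              x$N, x$input_dim[1], x$input_dim[2]))
  cat(sprintf("  inhibitory pairs: %d, excitatory pairs: %d\n",
              sum(x$inh_pairs[upper.tri(x$inh_pairs)]),
              sum(x$exc_pairs[upper.tri(x$exc_pairs)])))
  invisible(x)
}

#' Sample a sparse recurrent excitatory mask
#'
#' Each unordered neuron pair outside the inhibition range receives a
#' reciprocal excitatory connection independently with probability
#' `p_conn`.  Uses R's RNG (seed with [set.seed()] for reproducibility).
#'
#' @param topology a `sheet_topology`.
#' @param p_conn connection probability in `[0, 1]`.
#' @return the topology with `exc_pairs` filled in.
#' @export
sample_excitatory_mask <- function(topology, p_conn) {
  stopifnot(p_conn >= 0, p_conn <= 1)
  K <- topology$K
  exc <- matrix(FALSE, K, K)
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j <= k) next
    if (topology$inh_pairs[k, j]) next
    if (stats::runif(1) < p_conn) exc[k, j] <- exc[j, k] <- TRUE
  }
  topology$exc_pairs <- exc
  validate_topology(topology)
  topology
}

#' Set the excitatory mask from an explicit pair list
#'
#' @param topology a `sheet_topology`.
#' @param pairs two-column matrix of neuron index pairs.
#' @export
set_excitatory_pairs <- function(topology, pairs) {
  K <- topology$K
  exc <- matrix(FALSE, K, K)
  if (length(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    for (r in seq_len(nrow(pairs))) {
      k <- pairs[r, 1]; j <- pairs[r, 2]
      if (topology$inh_pairs[k, j])
        stop("pair ", k, "-", j, " lies within the inhibition range")
      exc[k, j] <- exc[j, k] <- TRUE
    }
  }
  topology$exc_pairs <- exc
  validate_topology(topology)
  topology
}

#' Build disjoint local populations with optional all-to-all excitation
#'
#' `n_pops` populations of `pop_size` neurons each; the neurons of a
#' population share one `field_dim` block of inputs, blocks of different
#' populations are disjoint.  Inhibition acts within populations;
#' excitatory pairs link all neurons of different populations when
#' `all_to_all_excitation` is set.
#'
#' @param n_pops number of populations.
#' @param pop_size neurons per population.
#' @param field_dim input block per population, `c(rows, cols)`.
#' @param all_to_all_excitation link all cross-population pairs.
#' @return a `sheet_topology`.
#' @export
build_population_topology <- function(n_pops, pop_size,
                                      field_dim = c(6, 6),
                                      all_to_all_excitation = TRUE) {
  field_dim <- as.integer(field_dim)
  K <- n_pops * pop_size
  input_dim <- c(field_dim[1], field_dim[2] * n_pops)
  block <- prod(field_dim)
  input_index <- function(r, c) r * input_dim[2] + c + 1L
  fields <- vector("list", K)
  pop <- rep(seq_len(n_pops), each = pop_size)
  for (k in seq_len(K)) {
    l <- pop[k]
    c0 <- (l - 1L) * field_dim[2]
    rr <- rep(0:(field_dim[1] - 1), each = field_dim[2])
    cc <- rep(c0 + 0:(field_dim[2] - 1), times = field_dim[1])
    fields[[k]] <- sort(input_index(rr, cc))
  }
  inh <- outer(pop, pop, "==") & !diag(K)
  exc <- matrix(FALSE, K, K)
  if (all_to_all_excitation && n_pops > 1)
    exc <- outer(pop, pop, "!=")
  coords <- cbind(row = (seq_len(K) - 1L) %% pop_size,
                  col = pop - 1L)
  topo <- new_topology(input_dim, c(pop_size, n_pops), fields, inh, exc,
                       coords, field_dim = field_dim, population = pop)
  validate_topology(topo)
  topo
}

#' Excitatory pair list of a topology
#'
#' @param topology a `sheet_topology`.
#' @return two-column integer matrix of unordered pairs `(k < j)`.
#' @export
excitatory_pairs <- function(topology) {
  which(topology$exc_pairs & upper.tri(topology$exc_pairs), arr.ind = TRUE)
}
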