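#' Agent population on a network
#'
#' Holds the per-agent public and private opinion vectors together with the
#' interaction network. `network = NULL` is the complete-graph sentinel (the
#' setting in which the mean-field description becomes exact as N grows);
#' otherwise a list of integer neighbour vectors (1-based, one per agent)
#' describes an arbitrary simple graph.
#'
#' @param public,private integer vectors of -1/+1 opinions, equal length.
#' @param network `NULL` for the complete graph, or a list of neighbour
#'   index vectors of length `length(public)`.
#' @return an object of class `"qv_population"`.
#' @export
agent_population <- function(public, private, network = NULL) {
  public <- as_spin(public, "public opinions")
  private <- as_spin(private, "private opinions")
  if (length(public) != length(private)) {
    stop("public and private opinion vectors must have equal length",
         call. = FALSE)
  }
  N <- length(public)
  if (!is.null(network)) {
    if (!is.list(network) || length(network) != N) {
      stop("network must be a list of neighbour vectors, one per agent",
           call. = FALSE)
    }
    network <- lapply(seq_len(N), function(i) {
      v <- as.integer(network[[i]])
      if (anyNA(v) || any(v < 1 | v > N) || any(v == i) || anyDuplicated(v)) {
        stop("invalid neighbour list for vertex ", i, call. = FALSE)
      }
      v
    })
  }
  structure(list(N = N, public = public, private = private,
                 network = network),
            class = "qv_population")
}

#' Generate an initial population
#'
#' All built-in initial conditions start every agent in internal harmony
#' (public equals private), so the initial dissonance is zero:
#' \describe{
#'   \item{`"ordered"`}{all agents hold +1 at both levels (the default
#'     used throughout for low-independence / hysteresis scans).}
#'   \item{`"symmetric-random"`}{each agent draws one value, -1 or +1 with
#'     probability 1/2, shared by both levels; the population is disordered
#'     on average but still dissonance-free.}
#' }
#' Arbitrary feasible `(c_S0, c_sigma0, d0)` triples are available through
#' [population_from_fractions()].
#'
#' @param N number of agents.
#' @param init `"ordered"` or `"symmetric-random"`.
#' @param network as in [agent_population()].
#' @return a `"qv_population"`.
#' @export
init_population <- function(N, init = c("ordered", "symmetric-random"),
                            network = NULL) {
  init <- match.arg(init)
  v <- if (init == "ordered") {
    rep(1L, N)
  } else {
    sample(c(-1L, 1L), N, replace = TRUE)
  }
  agent_population(v, v, network = network)
}

#' Population realising given macroscopic fractions
#'
#' Builds a complete-graph population whose four class counts match the
#' requested `(c_S0, c_sigma0, d0)` triple as closely as integer rounding
#' allows. The triple must be feasible: the implied four class fractions
#' `c_pp = (c_S + c_sigma - d)/2`, `c_pm = (c_S - c_sigma + d)/2`,
#' `c_mp = (c_sigma - c_S + d)/2` and `c_mm = 1 - c_pp - c_pm - c_mp` must
#' all be nonnegative.
#'
#' @param N number of agents.
#' @param c_S0,c_sigma0,d0 target fractions in `[0, 1]`.
#' @return a `"qv_population"` on the complete graph.
#' @export
population_from_fractions <- function(N, c_S0, c_sigma0, d0) {
  cc <- fractions_to_classes(c_S0, c_sigma0, d0)
  n <- round(cc * N)
  n[4] <- N - sum(n[1:3])
  if (any(n < 0)) stop("rounded class counts became negative", call. = FALSE)
  public <- rep(c(1L, 1L, -1L, -1L), times = n)
  private <- rep(c(1L, -1L, 1L, -1L), times = n)
  agent_population(public, private)
}

# (c_S, c_sigma, d) -> four class fractions, with feasibility check
fractions_to_classes <- function(c_S, c_sigma, d) {
  cc <- c(c_pp = (c_S + c_sigma - d) / 2,
          c_pm = (c_S - c_sigma + d) / 2,
          c_mp = (c_sigma - c_S + d) / 2,
          c_mm = 1 - (c_S + c_sigma + d) / 2)
  if (any(cc < -1e-12)) {
    stop("infeasible (c_S, c_sigma, d) triple: implied class fractions ",
         paste(sprintf("%.4f", cc), collapse = ", "), call. = FALSE)
  }
  pmax(cc, 0)
}

#' Sample a q-panel for a focal agent
#'
#' Draws `q` distinct neighbours of agent `i` (the focal agent itself is
#' never included, and neighbours are not repeated) and returns their
#' current public opinions.
#'
#' @param population a `"qv_population"`.
#' @param i focal agent index.
#' @param q panel size.
#' @return integer vector of length `q` of public opinions.
#' @export
sample_panel <- function(population, i, q) {
  stopifnot(inherits(population, "qv_population"))
  N <- population$N
  if (i < 1 || i > N) stop("focal index out of range", call. = FALSE)
  nbrs <- if (is.null(population$network)) {
    setdiff(seq_len(N), i)
  } else {
    population$network[[i]]
  }
  if (length(nbrs) < q) {
    stop("vertex ", i, " has degree ", length(nbrs), " < q = ", q,
         call. = FALSE)
  }
  idx <- nbrs[sample.int(length(nbrs), q)]
  population$public[idx]
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

counts_from_population <- function(population) {
  s <- population$public
  sg <- population$private
  class_counts(sum(s == 1 & sg == 1), sum(s == 1 & sg == -1),
               sum(s == -1 & sg == 1), sum(s == -1 & sg == -1))
}

#' Run one Monte Carlo trajectory
#'
#' Simulates the random sequential dynamics: at each elementary step one
#' agent is chosen uniformly at random and performs one
#' [elementary_update()]; time advances by `1/N`, so one Monte Carlo step
#' (MCS) corresponds to `N` elementary updates.
#'
#' On the complete graph the simulation may run in a compressed
#' representation that tracks only the four class counts, with panel
#' compositions drawn hypergeometrically from the `N - 1` non-focal agents;
#' this is statistically equivalent to the per-agent dynamics and much
#' faster for large `N`. The per-agent engine is used for explicit networks
#' and whenever influence events are recorded.
#'
#' @param params a [model_params()] object.
#' @param init a `"qv_population"` or a [class_counts()] object (counts
#'   imply the complete graph).
#' @param horizon number of MCS to simulate.
#' @param seed integer seed; identical `(params, init, seed)` yield an
#'   identical trajectory. `NULL` continues from the current RNG state.
#' @param record_every recording cadence in MCS (default 1).
#' @param engine `"auto"`, `"counts"` (compressed, complete graph only) or
#'   `"agent"` (per-agent).
#' @param record_events if positive, record up to this many influence
#'   events (forces the per-agent engine); see [tally_events()].
#' @return a `"qv_trajectory"`: a data frame with columns `t`, the four
#'   class counts, `c_S`, `c_sigma`, `d` and `rho`, with the run metadata
#'   in attributes (`params`, `seed`, `N`); recorded events, if any, in
#'   attribute `events`.
#' @export
run_trajectory <- function(params, init, horizon, seed = NULL,
                           record_every = 1,
                           engine = c("auto", "counts", "agent"),
                           record_events = 0) {
  stopifnot(inherits(params, "qv_params"))
  engine <- match.arg(engine)
  if (horizon < 1 || horizon != round(horizon)) {
    stop("horizon must be a positive integer number of MCS", call. = FALSE)
  }
  if (record_every < 1 || record_every != round(record_every)) {
    stop("record_every must be a positive integer", call. = FALSE)
  }

  is_counts <- inherits(init, "qv_counts")
  if (is_counts && engine == "agent") {
    init <- population_from_counts(init)
    is_counts <- FALSE
  }
  if (record_events > 0 && engine != "agent") {
    engine <- "agent"
    if (is_counts) { init <- population_from_counts(init); is_counts <- FALSE }
  }
  if (engine == "auto") {
    engine <- if (is_counts || (inherits(init, "qv_population") &&
                                is.null(init$network))) "counts" else "agent"
  }

  events <- NULL
  if (engine == "counts") {
    counts0 <- if (is_counts) init else counts_from_population(init)
    N <- sum(counts0)
    if (params$q >= N) stop("q must be smaller than N", call. = FALSE)
    raw <- with_seed(seed, sim_counts_cpp(as.integer(counts0), params$q,
                                          params$p, params$ordering == "AT",
                                          as.integer(horizon),
                                          as.integer(record_every)))
  } else {
    stopifnot(inherits(init, "qv_population"))
    N <- init$N
    adj <- if (is.null(init$network)) list() else init$network
    if (is.null(init$network) && params$q >= N) {
      stop("q must be smaller than N", call. = FALSE)
    }
    res <- with_seed(seed, sim_agents_cpp(init$public, init$private, adj,
                                          params$q, params$p,
                                          params$ordering == "AT",
                                          as.integer(horizon),
                                          as.integer(record_every),
                                          as.integer(record_events)))
    raw <- res$counts
    if (record_events > 0 && res$n_events > 0) {
      ev <- res$events[seq_len(res$n_events), , drop = FALSE]
      events <- data.frame(pre_pub = ev[, 1], pre_priv = ev[, 2],
                           post_pub = ev[, 3], post_priv = ev[, 4],
                           source = ifelse(ev[, 5] == 0L, NA_integer_, ev[, 5]),
                           conf_pub = ev[, 6] == 1L,
                           conf_priv = ev[, 7] == 1L)
    }
  }

  traj <- trajectory_from_counts_matrix(raw)
  attr(traj, "params") <- params
  attr(traj, "seed") <- seed
  attr(traj, "N") <- sum(raw[1, 2:5])
  attr(traj, "events") <- events
  class(traj) <- c("qv_trajectory", class(traj))
  traj
}

population_from_counts <- function(counts) {
  n <- as.integer(counts)
  agent_population(rep(c(1L, 1L, -1L, -1L), times = n),
                   rep(c(1L, -1L, 1L, -1L), times = n))
}

trajectory_from_counts_matrix <- function(raw) {
  N <- sum(raw[1, 2:5])
  c_S <- (raw[, 2] + raw[, 3]) / N
  c_sigma <- (raw[, 2] + raw[, 4]) / N
  d <- (raw[, 3] + raw[, 4]) / N
  var_prod <- c_S * (1 - c_S) * c_sigma * (1 - c_sigma)
  rho <- ifelse(var_prod <= 0, NA_real_,
                (raw[, 2] / N - c_S * c_sigma) / sqrt(var_prod))
  data.frame(t = raw[, 1], n_pp = raw[, 2], n_pm = raw[, 3],
             n_mp = raw[, 4], n_mm = raw[, 5],
             c_S = c_S, c_sigma = c_sigma, d = d, rho = rho)
}

#' Stationary summary of a trajectory
#'
#' Averages the observables over the final fraction of the recorded horizon
#' (by default the last 25%), the window over which the system is assumed
#' to have settled.
#'
#' @param traj a `"qv_trajectory"`.
#' @param window fraction of the horizon to average over, in `(0, 1]`.
#' @return named list of time-averaged `c_S`, `c_sigma`, `d`, `rho`.
#' @export
stationary_summary <- function(traj, window = 0.25) {
  stopifnot(window > 0, window <= 1)
  t_max <- max(traj$t)
  keep <- traj$t >= (1 - window) * t_max
  sub <- traj[keep, , drop = FALSE]
  list(c_S = mean(sub$c_S), c_sigma = mean(sub$c_sigma), d = mean(sub$d),
       rho = mean(sub$rho, na.rm = TRUE), n_recorded = nrow(sub))
}

#' Run an ensemble of trajectories
#'
#' Repeats [run_trajectory()] `n_samples` times with seeds
#' `base_seed + 1, ..., base_seed + n_samples` and summarises the ensemble
#' per recorded time point: the ensemble mean, standard deviation, standard
#' error of the mean, and empirical central quantile bands. The quantiles
#' are computed for each time point separately, so e.g. the 10th/90th
#' percentile pair bounds the central 80% of realisations at that time.
#'
#' @param params,init,horizon,record_every as in [run_trajectory()].
#' @param n_samples number of independent trajectories (>= 2).
#' @param base_seed integer; member k runs with seed `base_seed + k`.
#' @param probs quantile probabilities for the bands.
#' @param keep_trajectories also return the individual trajectories.
#' @return an object of class `"qv_ensemble"`: a list with element
#'   `summary` (data frame with, per observable `x` in `c_S`, `c_sigma`,
#'   `d`: `x` = ensemble mean, `x_sd`, `x_se` and one `x_qNN` column per
#'   requested quantile) and optionally `trajectories`.
#' @export
run_ensemble <- function(params, init, horizon, n_samples, base_seed,
                         record_every = 1, probs = c(0.1, 0.25, 0.75, 0.9),
                         keep_trajectories = FALSE) {
  if (n_samples < 2) stop("n_samples must be at least 2", call. = FALSE)
  runs <- lapply(seq_len(n_samples), function(k) {
    run_trajectory(params, init, horizon, seed = base_seed + k,
                   record_every = record_every)
  })
  times <- runs[[1]]$t
  obs <- c("c_S", "c_sigma", "d")
  out <- data.frame(t = times)
  for (v in obs) {
    m <- vapply(runs, function(r) r[[v]], numeric(length(times)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    out[[v]] <- rowMeans(m)
    out[[paste0(v, "_sd")]] <- apply(m, 1, stats::sd)
    out[[paste0(v, "_se")]] <- out[[paste0(v, "_sd")]] / sqrt(n_samples)
    qs <- apply(m, 1, stats::quantile, probs = probs, names = FALSE,
                type = 7)
    if (is.null(dim(qs))) qs <- matrix(qs, nrow = length(probs))
    for (j in seq_along(probs)) {
      out[[sprintf("%s_q%02d", v, round(100 * probs[j]))]] <- qs[j, ]
    }
  }
  structure(list(summary = out,
                 trajectories = if (keep_trajectories) runs else NULL,
                 params = params, n_samples = n_samples,
                 base_seed = base_seed, probs = probs),
            class = "qv_ensemble")
}
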