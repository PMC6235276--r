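#' Validated run configuration
#'
#' Bundles everything needed for a reproducible simulation experiment.
#' Defaults: `model = "AT"`, `init = "ordered"`, `samples = 1`,
#' `record_every = 1` MCS, `seed = 1`.
#'
#' @param model `"AT"` or `"TA"`.
#' @param N number of agents.
#' @param q panel size.
#' @param p independence probability.
#' @param init `"ordered"`, `"symmetric-random"`, or a list with `c_S0`,
#'   `c_sigma0`, `d0`.
#' @param horizon simulation length in MCS.
#' @param samples number of ensemble members.
#' @param seed base seed.
#' @param record_every recording cadence in MCS.
#' @param out optional output path prefix.
#' @return an object of class `"qv_config"`.
#' @export
run_config <- function(model = "AT", N, q, p, init = "ordered",
                       horizon = 1000, samples = 1, seed = 1,
                       record_every = 1, out = NULL) {
  model <- match.arg(model, c("AT", "TA"))
  params <- model_params(q, p, ordering = model)  # validates q and p
  check_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != round(x)) {
      stop(name, " must be an integer >= ", min, call. = FALSE)
    }
    as.integer(x)
  }
  N <- check_count(N, "N", min = 2)
  if (q >= N) stop("q must be smaller than N", call. = FALSE)
  horizon <- check_count(horizon, "horizon")
  samples <- check_count(samples, "samples")
  record_every <- check_count(record_every, "record_every")
  seed <- check_count(seed, "seed", min = 0)
  if (is.list(init)) {
    need <- c("c_S0", "c_sigma0", "d0")
    if (!all(need %in% names(init))) {
      stop("init as a list must supply c_S0, c_sigma0, d0", call. = FALSE)
    }
    fractions_to_classes(init$c_S0, init$c_sigma0, init$d0)  # feasibility
  } else {
    init <- match.arg(init, c("ordered", "symmetric-random"))
  }
  structure(list(model = model, N = N, q = as.integer(q), p = p,
                 init = init, horizon = horizon, samples = samples,
                 seed = seed, record_every = record_every, out = out,
                 params = params),
            class = "qv_config")
}

#' Parse a run configuration document
#'
#' Reads a YAML (or simple `key: value`) document into a validated
#' [run_config()]. Unknown keys are rejected so that typos fail loudly
#' rather than silently falling back to defaults.
#'
#' @param text a character scalar holding the document, or a length-1
#'   path to a file when `file = TRUE`.
#' @param file whether `text` names a file.
#' @return a `"qv_config"`.
#' @export
parse_config <- function(text, file = FALSE) {
  # keep YAML-1.1 boolean-like scalars (notably the key "N") literal
  handlers <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  doc <- if (file) {
    yaml::read_yaml(text, handlers = handlers)
  } else {
    yaml::yaml.load(text, handlers = handlers)
  }
  if (!is.list(doc)) stop("config must be a key-value mapping", call. = FALSE)
  known <- c("model", "N", "q", "p", "init", "horizon", "samples", "seed",
             "record_every", "out")
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  required <- c("N", "q", "p")
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0) {
    stop("missing required config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, doc)
}

#' Build the initial population described by a run configuration
#'
#' For `init = "symmetric-random"` the draw is part of the seeded
#' experiment, so the configuration seed fixes it.
#'
#' @param config a `"qv_config"`.
#' @return a `"qv_population"`.
#' @export
make_init <- function(config) {
  if (is.list(config$init)) {
    population_from_fractions(config$N, config$init$c_S0,
                              config$init$c_sigma0, config$init$d0)
  } else if (config$init == "ordered") {
    init_population(config$N, "ordered")
  } else {
    # the symmetric-random draw is part of the seeded experiment
    with_seed(config$seed, init_population(config$N, "symmetric-random"))
  }
}

fmt10 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

#' Write a trajectory as CSV
#'
#' Columns `t,c_S,c_sigma,d,rho`, one row per recorded MCS, floats with 10
#' significant digits; byte-stable for identical inputs.
#'
#' @param traj a `"qv_trajectory"` (or any data frame with those columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  lines <- c("t,c_S,c_sigma,d,rho",
             paste(traj$t, fmt10(traj$c_S), fmt10(traj$c_sigma),
                   fmt10(traj$d), fmt10(traj$rho), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a trajectory CSV
#' @param path file written by [write_trajectory_csv()].
#' @return data frame.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, na.strings = "NA")
}

#' Write an ensemble summary as CSV
#'
#' Per observable: the ensemble mean plus the recorded quantile band
#' columns (e.g. `c_S_q10, ..., c_S_q90`).
#'
#' @param ensemble a `"qv_ensemble"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  s <- ensemble$summary
  cols <- names(s)[names(s) == "t" | !grepl("_(sd|se)$", names(s))]
  s <- s[, cols, drop = FALSE]
  header <- paste(cols, collapse = ",")
  body <- apply(s, 1, function(r) {
    paste(c(format(r[["t"]], scientific = FALSE, trim = TRUE),
            fmt10(as.numeric(r[-1]))), collapse = ",")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a phase diagram as TSV
#'
#' Columns `q, p, branch, c_S, c_sigma, d, rho, stability`.
#'
#' @param df output of [phase_diagram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phase_tsv <- function(df, path) {
  lines <- c(paste(c("q", "p", "branch", "c_S", "c_sigma", "d", "rho",
                     "stability"), collapse = "\t"),
             paste(df$q, fmt10(df$p), df$branch, fmt10(df$c_S),
                   fmt10(df$c_sigma), fmt10(df$d), fmt10(df$rho),
                   df$stability, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON run summary
#'
#' Embeds the full configuration and seed alongside the stationary means
#' and standard errors, so a run can be reproduced from its summary alone.
#'
#' @param config a `"qv_config"`.
#' @param stationary named list of stationary observables (e.g. from
#'   [stationary_summary()]).
#' @param path output file.
#' @param extra optional named list merged into the summary.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(config, stationary, path, extra = NULL) {
  obj <- c(list(config = unclass(config)[c("model", "N", "q", "p", "init",
                                           "horizon", "samples", "seed",
                                           "record_every")],
                stationary = stationary),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  invisible(path)
}
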