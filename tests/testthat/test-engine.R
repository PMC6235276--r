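test_that("observables follow exactly from the four class counts", {
  o <- observables_from_counts(class_counts(50, 20, 10, 20))
  expect_equal(o$c_S, 0.70)
  expect_equal(o$c_sigma, 0.60)
  expect_equal(o$d, 0.30)
  expect_equal(o$rho, 0.08 / sqrt(0.7 * 0.3 * 0.6 * 0.4), tolerance = 1e-12)

  o2 <- observables_from_counts(class_counts(100, 0, 0, 0))
  expect_equal(c(o2$c_S, o2$c_sigma, o2$d), c(1, 1, 0))
  expect_true(is.na(o2$rho))

  o3 <- observables_from_counts(class_counts(25, 25, 25, 25))
  expect_equal(c(o3$c_S, o3$c_sigma, o3$d, o3$rho), c(0.5, 0.5, 0.5, 0))

  expect_error(observables_from_counts(c(-1, 2, 0, 0)), "nonnegative")
})

test_that("panel sampling excludes the focal agent and has the right margins", {
  pop <- agent_population(c(1L, -1L, 1L, -1L, 1L), c(1L, 1L, 1L, 1L, 1L))
  # complete graph, N = 5, q = 4: panel composition is forced
  set.seed(1)
  panel <- sample_panel(pop, 1, 4)
  expect_equal(sort(panel), sort(pop$public[-1]))

  pop2 <- agent_population(rep(1L, 100), rep(1L, 100))
  expect_equal(sample_panel(pop2, 3, 2), c(1L, 1L))
  expect_error(sample_panel(pop2, 3, 100), "degree")

  # each neighbour appears with probability q/(N-1): mark one agent with a
  # -1 public opinion and count how often it is drawn
  N <- 11; q <- 2; n_draw <- 2e4
  pop3 <- agent_population(c(rep(1L, N - 1), -1L), rep(1L, N))
  set.seed(99)
  hits <- vapply(seq_len(n_draw),
                 function(i) any(sample_panel(pop3, 1, q) == -1L),
                 logical(1))
  p_inc <- q / (N - 1)
  expect_lt(abs(mean(hits) - p_inc),
            3 * sqrt(p_inc * (1 - p_inc) / n_draw))
})

test_that("explicit networks are validated and respected", {
  # 4-cycle: each vertex has degree 2
  ring <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(3L, 1L))
  pop <- agent_population(c(1L, -1L, 1L, -1L), rep(1L, 4), network = ring)
  set.seed(5)
  expect_equal(sort(sample_panel(pop, 1, 2)), sort(c(-1L, -1L)))
  expect_error(
    agent_population(rep(1L, 3), rep(1L, 3), network = list(1L, 1L, 2L)),
    "vertex 1")
  tr <- run_trajectory(model_params(2, 0.3), pop, horizon = 20, seed = 2)
  expect_equal(nrow(tr), 21)
  expect_error(run_trajectory(model_params(3, 0.3), pop, 5, seed = 1),
               "degree")
})

test_that("trajectories are reproducible and conserve the population", {
  params <- model_params(3, 0.4)
  a <- run_trajectory(params, ordered_counts(500), 50, seed = 7)
  b <- run_trajectory(params, ordered_counts(500), 50, seed = 7)
  expect_identical(a$c_S, b$c_S)
  expect_true(all(a$n_pp + a$n_pm + a$n_mp + a$n_mm == 500))
  c <- run_trajectory(params, ordered_counts(500), 50, seed = 8)
  expect_false(identical(a$c_S, c$c_S))
})

test_that("frozen dynamics and the p = 1 limits behave as predicted", {
  # p = 0 from full consensus: nothing can ever change
  tr <- run_trajectory(model_params(4, 0), ordered_counts(1000), 30,
                       seed = 1)
  expect_true(all(tr$c_S == 1 & tr$c_sigma == 1 & tr$d == 0))

  # TA at p = 1: the public level copies the fresh private value, so the
  # dissonance vanishes at every recorded time once every agent updated
  ta <- run_trajectory(model_params(3, 1, "TA"), ordered_counts(10000),
                       100, seed = 3)
  expect_true(all(ta$d[ta$t >= 5] < 0.01))
  expect_equal(tail(ta$d, 1), 0, tolerance = 1e-3)

  # AT at p = 1: the private flip lands the agent in conflict half the time
  at <- run_trajectory(model_params(3, 1, "AT"), ordered_counts(10000),
                       500, seed = 4)
  expect_equal(stationary_summary(at)$d, 0.5, tolerance = 0.02)
})

test_that("compressed and per-agent engines agree on the complete graph", {
  # two-sample comparison of stationary observables at N = 2000, q = 4
  for (p in c(0.2, 0.5)) {
    params <- model_params(4, p)
    st <- function(engine, seeds) {
      vapply(seeds, function(s) {
        tr <- run_trajectory(params, ordered_counts(2000), 300, seed = s,
                             engine = engine, record_every = 5)
        unlist(stationary_summary(tr)[c("c_S", "d")])
      }, numeric(2))
    }
    a <- st("counts", 1:8)
    b <- st("agent", 101:108)
    for (i in 1:2) {
      se <- sqrt(stats::var(a[i, ]) / 8 + stats::var(b[i, ]) / 8)
      expect_lt(abs(mean(a[i, ]) - mean(b[i, ])), 4 * se + 1e-4)
    }
  }
})

test_that("ensembles summarise trajectories with faithful quantile bands", {
  params <- model_params(4, 0)
  ens0 <- run_ensemble(params, ordered_counts(200), 10, n_samples = 5,
                       base_seed = 1)
  expect_true(all(ens0$summary$c_S_q10 == ens0$summary$c_S_q90))
  expect_true(all(ens0$summary$c_S_sd == 0))

  ens <- run_ensemble(model_params(4, 0.4), ordered_counts(500), 20,
                      n_samples = 10, base_seed = 3,
                      keep_trajectories = TRUE)
  # sort-based order-statistics oracle (linear interpolation between order
  # statistics, the same convention as the engine claims to use)
  m <- vapply(ens$trajectories, function(r) r$c_S, numeric(21))
  oracle_q <- function(x, pr) {
    x <- sort(x)
    h <- (length(x) - 1) * pr + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
  }
  for (pr in c(0.1, 0.9)) {
    col <- sprintf("c_S_q%02d", round(100 * pr))
    expect_equal(ens$summary[[col]],
                 apply(m, 1, oracle_q, pr = pr), tolerance = 1e-12)
  }
  expect_equal(ens$summary$c_S, rowMeans(m), tolerance = 1e-12)
})

test_that("stationary summaries average the requested trailing window", {
  tr <- data.frame(t = 0:100, n_pp = 1, n_pm = 0, n_mp = 0, n_mm = 0,
                   c_S = c(rep(0, 76), rep(1, 25)), c_sigma = 0.5,
                   d = 0.25, rho = 0)
  # the window is inclusive: t >= 75 keeps 26 rows, 25 of which are 1
  expect_equal(stationary_summary(tr, window = 0.25)$c_S, 25 / 26)
  expect_equal(stationary_summary(tr, window = 1)$c_S, 25 / 101)
})
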