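test_that("simplified rates match direct symbolic substitution", {
  params <- model_params(2, 0.5)
  g <- rates_simplified(0.6, 0.4, params)
  expect_equal(unname(g$S["plus"]), 0.1904, tolerance = 1e-12)
  expect_equal(unname(g$S["minus"]), 0.3144, tolerance = 1e-12)
  expect_equal(unname(g$sigma["plus"]), 0.258, tolerance = 1e-12)
  expect_equal(unname(g$sigma["minus"]), 0.132, tolerance = 1e-12)

  # consensus: every conformity channel is quenched, but independence
  # still flips private opinions away at rate p/2 — consensus is only
  # absorbing at p = 0
  g1 <- rates_simplified(1, 1, model_params(3, 0.7))
  expect_equal(unname(c(g1$S, g1$sigma["plus"])), rep(0, 3))
  expect_equal(unname(g1$sigma["minus"]), 0.7 / 2)
  g0 <- rates_simplified(1, 1, model_params(3, 0))
  expect_equal(unname(c(g0$S, g0$sigma)), rep(0, 4))

  # p = 1 suppresses the conformity term on the private level
  g2 <- rates_simplified(0.3, 0.8, model_params(4, 1))
  expect_equal(unname(g2$sigma["plus"]), (1 - 0.8) / 2)
  expect_equal(unname(g2$sigma["minus"]), 0.8 / 2)
})

test_that("pair-state rates equal the enumeration oracle", {
  states <- random_simplex_states(8, seed = 11)
  for (ord in c("AT", "TA")) {
    for (q in 1:3) {
      for (p in c(0, 0.5, 1)) {
        params <- model_params(q, p, ordering = ord)
        for (st in states[1:3]) {
          expect_equal(rates_pairstate(st, params),
                       drift_oracle(st, params), tolerance = 1e-12)
        }
      }
    }
  }
  # drifts always sum to zero (probability conservation)
  for (st in states) {
    expect_equal(sum(rates_pairstate(st, model_params(5, 0.3, "TA"))), 0,
                 tolerance = 1e-14)
  }
})

test_that("product-state marginals reduce to the simplified rates", {
  cs <- 0.63; csg <- 0.41
  prod_state <- c(cs * csg, cs * (1 - csg), (1 - cs) * csg,
                  (1 - cs) * (1 - csg))
  for (q in c(2, 3)) {
    for (p in c(0.2, 0.7)) {
      at <- model_params(q, p, "AT")
      g <- rates_simplified(cs, csg, at)
      dr <- rates_pairstate(prod_state, at)
      # AT: both marginal drifts collapse onto the independent-levels rates
      expect_equal(unname(dr["c_pp"] + dr["c_pm"]),
                   unname(g$S["plus"] - g$S["minus"]), tolerance = 1e-12)
      expect_equal(unname(dr["c_pp"] + dr["c_mp"]),
                   unname(g$sigma["plus"] - g$sigma["minus"]),
                   tolerance = 1e-12)
      # TA: the private marginal collapses too; the public step sees the
      # updated private opinion, so its marginal is coupled off-stationarity
      dr_ta <- rates_pairstate(prod_state, model_params(q, p, "TA"))
      expect_equal(unname(dr_ta["c_pp"] + dr_ta["c_mp"]),
                   unname(g$sigma["plus"] - g$sigma["minus"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("consensus is absorbing at p = 0 and the symmetric point is fixed", {
  for (ord in c("AT", "TA")) {
    expect_equal(max(abs(rates_pairstate(c(1, 0, 0, 0),
                                         model_params(3, 0, ord)))), 0)
    # the uniform four-class state has symmetric marginals, which stay
    # pinned at 1/2 by the spin-flip symmetry even while d keeps evolving
    dr <- rates_pairstate(rep(0.25, 4), model_params(4, 0.6, ord))
    expect_equal(unname(dr["c_pp"] + dr["c_pm"]), 0, tolerance = 1e-15)
    expect_equal(unname(dr["c_pp"] + dr["c_mp"]), 0, tolerance = 1e-15)
  }
})

test_that("mean-field trajectories conserve and reach the right attractors", {
  # p = 0 ordered init: constant trajectory
  tr0 <- integrate_meanfield("ordered", model_params(4, 0), 50)
  expect_true(all(abs(tr0$c_S - 1) < 1e-9 & tr0$d < 1e-9))

  # pair-state fractions stay a probability vector along the flow
  tr <- integrate_meanfield("ordered", model_params(5, 0.26, "AT"), 300)
  sums <- tr$c_pp + tr$c_pm + tr$c_mp + tr$c_mm
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_true(all(tr[, c("c_pp", "c_pm", "c_mp", "c_mm")] > -1e-10))

  # metastability at q = 6, p = 0.2: ordered stays ordered, disordered
  # stays disordered
  pm <- model_params(6, 0.2, "AT")
  up <- integrate_meanfield("ordered", pm, 500)
  down <- integrate_meanfield("disordered", pm, 500)
  expect_gt(tail(up$c_S, 1), 0.8)
  expect_equal(tail(down$c_S, 1), 0.5, tolerance = 1e-6)

  # p = 1 limits of the dissonance
  at1 <- integrate_meanfield("ordered", model_params(3, 1, "AT"), 200)
  ta1 <- integrate_meanfield("ordered", model_params(3, 1, "TA"), 200)
  expect_equal(tail(at1$d, 1), 0.5, tolerance = 1e-8)
  expect_equal(tail(ta1$d, 1), 0, tolerance = 1e-8)
})

test_that("stationary states and their stability track the phase structure", {
  # disordered phase: unique stable point at 1/2
  fp <- stationary_states(model_params(4, 0.5))
  stable <- fp[fp$stability == "stable", ]
  expect_equal(nrow(stable), 1)
  expect_equal(c(stable$c_S, stable$c_sigma), c(0.5, 0.5), tolerance = 1e-9)

  # ordered phase: mirror pair of stable ordered points + unstable
  # symmetric point
  fp2 <- stationary_states(model_params(4, 0.2))
  st2 <- fp2[fp2$stability == "stable", ]
  expect_equal(nrow(st2), 2)
  expect_setequal(st2$branch, c("ordered-", "ordered+"))
  expect_equal(st2$c_S[1] + st2$c_S[2], 1, tolerance = 1e-8)  # Z2 mirror
  # below p* the symmetric point repels along the order-parameter direction
  expect_true(fp2$stability[fp2$branch == "symmetric"] %in%
                c("unstable", "saddle"))
  expect_true(all(fp2$residual < 1e-10))

  # metastable region: ordered pair AND stable symmetric point coexist
  fp3 <- stationary_states(model_params(6, 0.2))
  st3 <- fp3[fp3$stability == "stable", ]
  expect_true(any(st3$branch == "symmetric"))
  expect_true(any(st3$branch == "ordered+"))
})

test_that("pair-state stationary solver reproduces simplified concentrations", {
  for (ord in c("AT", "TA")) {
    fp <- stationary_states(model_params(4, 0.3, ordering = ord),
                            variant = "pairstate")
    stable_up <- fp[fp$stability == "stable" & fp$branch == "ordered+", ]
    simp <- stationary_states(model_params(4, 0.3))
    simp_up <- simp[simp$stability == "stable" & simp$branch == "ordered+", ]
    expect_equal(stable_up$c_S, simp_up$c_S, tolerance = 1e-7)
    expect_equal(stable_up$c_sigma, simp_up$c_sigma, tolerance = 1e-7)
  }
  # ... while the dissonance distinguishes the orderings
  d_at <- stationary_states(model_params(4, 0.3, "AT"), "pairstate")
  d_ta <- stationary_states(model_params(4, 0.3, "TA"), "pairstate")
  pick <- function(df) df[df$stability == "stable" &
                            df$branch == "ordered+", ]
  expect_gt(pick(d_at)$d, pick(d_ta)$d)
  expect_gt(pick(d_ta)$rho, pick(d_at)$rho)
})

test_that("analytic critical point matches its closed form and domain", {
  expect_identical(critical_point(2), 0.5)
  expect_equal(critical_point(4), (-7 + sqrt(97)) / 8, tolerance = 1e-15)
  expect_error(critical_point(1), ">= 2")
})

test_that("one-level baseline has the known fixed-point structure", {
  # p = 0: consensus absorbing; c = 1/2 fixed by symmetry
  fp0 <- original_qvoter_stationary(0, 4)
  expect_true(any(abs(fp0$c - 1) < 1e-12))
  expect_true(any(abs(fp0$c - 0.5) < 1e-12))
  fp <- original_qvoter_stationary(0.3, 4)
  expect_true(all(fp$residual < 1e-10))
  expect_true(any(abs(fp$c - 0.5) < 1e-12))

  # the one-level transition sits at smaller independence than the
  # two-level one at the same q
  p_orig <- symmetric_stability_threshold(4, "original")
  expect_lt(p_orig, critical_point(4))
  # closed form of the baseline threshold: p/(1-p) = (q-1) 2^(1-q)
  a <- 3 * 2^(-3)
  expect_equal(p_orig, a / (1 + a), tolerance = 1e-9)
})

test_that("dissonance and correlation formulas evaluate exactly", {
  expect_equal(dissonance_independent(0.5, 0.5), 0.5)
  expect_equal(dissonance_independent(1, 1), 0)
  expect_equal(dissonance_independent(0.8, 0.8), 0.32)

  expect_equal(pearson_correlation(0.5, 0.5, 0), 1)
  expect_equal(pearson_correlation(0.5, 0.5, 0.5), 0)
  expect_true(is.na(pearson_correlation(1, 0.5, 0)))
  # independent levels imply zero correlation at any interior point
  for (cs in c(0.2, 0.5, 0.9)) {
    for (csg in c(0.3, 0.6)) {
      expect_equal(pearson_correlation(cs, csg,
                                       dissonance_independent(cs, csg)), 0,
                   tolerance = 1e-14)
    }
  }
})
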