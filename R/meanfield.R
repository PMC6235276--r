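#' Simplified mean-field transition rates
#'
#' Rates of change of the two marginal concentrations per elementary step,
#' derived under the mean-field approximation *and* the simplifying
#' assumption that the public and private opinion states are statistically
#' independent. Under that assumption the rates are identical for the AT
#' and TA updating orders:
#' \deqn{\gamma_S^+ = (1-c_S)\{p c_\sigma + (1-p)[c_\sigma(1-(1-c_S)^q) +
#'   (1-c_\sigma) c_S^q]\}}
#' \deqn{\gamma_S^- = c_S\{p(1-c_\sigma) + (1-p)[c_\sigma(1-c_S)^q +
#'   (1-c_\sigma)(1-c_S^q)]\}}
#' \deqn{\gamma_\sigma^+ = (1-c_\sigma)[p/2 + (1-p)c_S^q]}
#' \deqn{\gamma_\sigma^- = c_\sigma[p/2 + (1-p)(1-c_S)^q]}
#'
#' @param c_S,c_sigma concentrations in `[0, 1]`.
#' @param params a [model_params()] object (only `q` and `p` are used).
#' @return list with elements `S` and `sigma`, each `c(plus = , minus = )`.
#' @export
rates_simplified <- function(c_S, c_sigma, params) {
  stopifnot(inherits(params, "qv_params"),
            c_S >= 0, c_S <= 1, c_sigma >= 0, c_sigma <= 1)
  q <- params$q; p <- params$p
  gSp <- (1 - c_S) * (p * c_sigma +
    (1 - p) * (c_sigma * (1 - (1 - c_S)^q) + (1 - c_sigma) * c_S^q))
  gSm <- c_S * (p * (1 - c_sigma) +
    (1 - p) * (c_sigma * (1 - c_S)^q + (1 - c_sigma) * (1 - c_S^q)))
  gsp <- (1 - c_sigma) * (p / 2 + (1 - p) * c_S^q)
  gsm <- c_sigma * (p / 2 + (1 - p) * (1 - c_S)^q)
  list(S = c(plus = gSp, minus = gSm), sigma = c(plus = gsp, minus = gsm))
}

# --- exact four-class kernels --------------------------------------------
#
# Classes are ordered (pp, pm, mp, mm): first index public, second private.
# `a` is the current concentration of +1 public opinions; in the infinite-N
# limit each panel member is +1 independently with probability a.

cls_S <- c(1L, 1L, -1L, -1L)
cls_sg <- c(1L, -1L, 1L, -1L)

# P(new public opinion = +1) for the conformity/independence mixture
pub_plus_prob <- function(S, sg, a, q, p) {
  if (S != sg) {
    a_sig <- if (sg > 0) a else 1 - a
    match_prob <- 1 - (1 - a_sig)^q      # at least one member supports sigma
    conf <- match_prob * (sg > 0) + (1 - match_prob) * (S > 0)
  } else {
    conf <- a^q + (1 - a^q - (1 - a)^q) * (S > 0)
  }
  p * (sg > 0) + (1 - p) * conf
}

# P(new private opinion = +1); the independent branch flips with prob 1/2,
# so it lands on +1 with probability 1/2 regardless of the current value
priv_plus_prob <- function(sg, a, q, p) {
  conf <- a^q + (1 - a^q - (1 - a)^q) * (sg > 0)
  p * 0.5 + (1 - p) * conf
}

# 4x4 single-step transition matrix between classes; row = origin class.
# AT: the public step sees the pre-update private opinion; TA: the public
# step sees the already-updated private opinion, which couples the levels
# within one elementary step.
pair_transition_matrix <- function(state, params) {
  cc <- as.numeric(state)
  stopifnot(length(cc) == 4, all(cc >= -1e-12), abs(sum(cc) - 1) < 1e-8)
  a <- cc[1] + cc[2]
  q <- params$q; p <- params$p
  T <- matrix(0, 4, 4)
  for (k in 1:4) {
    S <- cls_S[k]; sg <- cls_sg[k]
    p_sg1 <- priv_plus_prob(sg, a, q, p)      # P(sigma' = +1)
    for (sg1 in c(1L, -1L)) {
      w_sg <- if (sg1 > 0) p_sg1 else 1 - p_sg1
      sg_seen <- if (params$ordering == "AT") sg else sg1
      p_S1 <- pub_plus_prob(S, sg_seen, a, q, p)
      for (S1 in c(1L, -1L)) {
        w_S <- if (S1 > 0) p_S1 else 1 - p_S1
        j <- which(cls_S == S1 & cls_sg == sg1)
        T[k, j] <- T[k, j] + w_S * w_sg
      }
    }
  }
  T
}

#' Exact mean-field drift of the four class concentrations
#'
#' Expected change, per unit time measured in MCS, of the four joint
#' (public, private) class concentrations under the exact mean-field
#' description on the infinite complete graph. Unlike the simplified rates,
#' these drifts do not assume independence of the two levels and they
#' differ between the AT and TA updating orders (in TA the public step sees
#' the already-updated private opinion).
#'
#' @param state numeric vector `(c_pp, c_pm, c_mp, c_mm)` summing to 1.
#' @param params a [model_params()] object (`q`, `p` and `ordering` used).
#' @return named numeric vector of the four drifts (summing to zero).
#' @export
rates_pairstate <- function(state, params) {
  stopifnot(inherits(params, "qv_params"))
  cc <- as.numeric(state)
  T <- pair_transition_matrix(cc, params)
  drift <- as.vector(crossprod(T, cc)) - cc
  names(drift) <- c("c_pp", "c_pm", "c_mp", "c_mm")
  drift
}

#' Brute-force enumeration oracle for the class drifts
#'
#' Computes the same expected per-step class drifts as [rates_pairstate()]
#' by exhaustively enumerating every branch of one elementary update —
#' focal class, the two per-level independence decisions, the private flip
#' coin, and both panel compositions (binomial in the public concentration,
#' i.e. the infinite-N limit) — and routing each branch through the
#' microscopic rule [elementary_update()]. It shares no code with the
#' analytic kernel, so agreement between the two is a strong check of the
#' re-derived rates.
#'
#' @param state numeric vector `(c_pp, c_pm, c_mp, c_mm)` summing to 1.
#' @param params a [model_params()] object; `q` must not exceed 8 (the
#'   enumeration grows quadratically in the panel compositions).
#' @return named numeric vector of the four drifts.
#' @export
drift_oracle <- function(state, params) {
  stopifnot(inherits(params, "qv_params"))
  if (params$q > 8) stop("drift_oracle supports q <= 8 only", call. = FALSE)
  cc <- as.numeric(state)
  stopifnot(length(cc) == 4, all(cc >= -1e-12), abs(sum(cc) - 1) < 1e-8)
  a <- cc[1] + cc[2]
  q <- params$q; p <- params$p
  k_weights <- stats::dbinom(0:q, q, a)
  chan <- list(indep = p, conf = 1 - p)
  drift <- numeric(4)

  for (k_cls in 1:4) {
    w_cls <- cc[k_cls]
    if (w_cls == 0) next
    state0 <- list(public = cls_S[k_cls], private = cls_sg[k_cls])
    for (pub_ch in names(chan)) {
      w_pub <- chan[[pub_ch]]
      if (w_pub == 0) next
      coin_pub <- if (pub_ch == "indep") 0 else p
      for (priv_ch in names(chan)) {
        w_priv <- chan[[priv_ch]]
        if (w_priv == 0) next
        coin_priv <- if (priv_ch == "indep") 0 else p
        for (flip in c(TRUE, FALSE)) {
          coin_flip <- if (flip) 0.25 else 0.75
          for (k1 in 0:q) {
            panel1 <- c(rep(1L, k1), rep(-1L, q - k1))
            for (k2 in 0:q) {
              panel2 <- c(rep(1L, k2), rep(-1L, q - k2))
              w <- w_cls * w_pub * w_priv * 0.5 *
                k_weights[k1 + 1] * k_weights[k2 + 1]
              if (w == 0) next
              out <- elementary_update(state0, params,
                                       list(panel1, panel2),
                                       c(coin_pub, coin_priv, coin_flip))
              j <- which(cls_S == out$public & cls_sg == out$private)
              drift[j] <- drift[j] + w
              drift[k_cls] <- drift[k_cls] - w
            }
          }
        }
      }
    }
  }
  names(drift) <- c("c_pp", "c_pm", "c_mp", "c_mm")
  drift
}

# --- ODE integration -----------------------------------------------------

# normalise the various accepted initial-condition spellings to class
# fractions
meanfield_init <- function(init) {
  if (is.character(init)) {
    return(switch(match.arg(init, c("ordered", "disordered")),
                  ordered = c(1, 0, 0, 0),
                  disordered = rep(0.25, 4)))
  }
  if (is.list(init) && !is.null(init$c_S)) {
    d0 <- if (is.null(init$d)) 0 else init$d
    return(as.numeric(fractions_to_classes(init$c_S, init$c_sigma, d0)))
  }
  cc <- as.numeric(init)
  if (length(cc) == 4) {
    stopifnot(all(cc >= 0), abs(sum(cc) - 1) < 1e-8)
    return(cc)
  }
  stop("unrecognised mean-field initial condition", call. = FALSE)
}

#' Integrate the mean-field rate equations
#'
#' Solves the deterministic rate equations `dc/dt = gamma^+ - gamma^-` with
#' time in MCS, either for the two marginal concentrations under the
#' independent-levels simplification (`variant = "simplified"`) or for the
#' exact four-class system (`variant = "pairstate"`, the default; this is
#' the description that resolves the AT/TA difference in the dissonance).
#'
#' @param init initial condition: `"ordered"`, `"disordered"`, a numeric
#'   vector of four class fractions, or a list with `c_S`, `c_sigma` and
#'   optionally `d` (default 0, i.e. no initial dissonance).
#' @param params a [model_params()] object.
#' @param t_max integration horizon in MCS.
#' @param variant `"pairstate"` or `"simplified"`.
#' @param n_out number of equally spaced output times.
#' @return data frame with columns `t`, `c_S`, `c_sigma`, `d`, `rho` and,
#'   for the pair-state variant, the four class fractions.
#' @export
integrate_meanfield <- function(init, params, t_max,
                                variant = c("pairstate", "simplified"),
                                n_out = 201) {
  stopifnot(inherits(params, "qv_params"), t_max > 0)
  variant <- match.arg(variant)
  times <- seq(0, t_max, length.out = n_out)
  cc0 <- meanfield_init(init)

  if (variant == "simplified") {
    y0 <- c(c_S = cc0[1] + cc0[2], c_sigma = cc0[1] + cc0[3])
    rhs <- function(t, y, parms) {
      g <- rates_simplified(min(max(y[1], 0), 1), min(max(y[2], 0), 1),
                            params)
      list(c(g$S["plus"] - g$S["minus"], g$sigma["plus"] - g$sigma["minus"]))
    }
    sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    if (any(!is.finite(sol))) {
      stop("non-finite state during mean-field integration", call. = FALSE)
    }
    return(data.frame(t = sol[, 1], c_S = sol[, 2], c_sigma = sol[, 3],
                      d = NA_real_, rho = NA_real_))
  }

  rhs <- function(t, y, parms) {
    y <- pmin(pmax(y, 0), 1)
    y <- y / sum(y)
    list(rates_pairstate(y, params))
  }
  sol <- deSolve::ode(cc0, times, rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  if (any(!is.finite(sol))) {
    stop("non-finite state during mean-field integration", call. = FALSE)
  }
  cc <- sol[, 2:5, drop = FALSE]
  obs <- t(apply(cc, 1, function(x) {
    o <- observables_from_counts(pmax(x, 0))
    c(o$c_S, o$c_sigma, o$d, if (is.na(o$rho)) NA_real_ else o$rho)
  }))
  data.frame(t = sol[, 1], c_pp = cc[, 1], c_pm = cc[, 2], c_mp = cc[, 3],
             c_mm = cc[, 4], c_S = obs[, 1], c_sigma = obs[, 2],
             d = obs[, 3], rho = obs[, 4])
}

# --- root finding & stability helpers ------------------------------------

num_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    hp <- x; hm <- x
    hp[j] <- hp[j] + h; hm[j] <- hm[j] - h
    J[, j] <- (f(hp) - f(hm)) / (2 * h)
  }
  J
}

stability_from_eigen <- function(ev, marginal_tol = 1e-9) {
  re <- Re(ev)
  if (any(abs(re) < marginal_tol)) return("marginal")
  if (all(re < 0)) return("stable")
  if (all(re > 0)) return("unstable")
  "saddle"
}

branch_label <- function(c_S, tol = 1e-6) {
  if (abs(c_S - 0.5) < tol) "symmetric"
  else if (c_S > 0.5) "ordered+" else "ordered-"
}

# all sign-change roots of f on [lo, hi] over an n-point grid, polished by
# uniroot; grid points that are (numerically) exact zeros are kept as-is
find_roots_1d <- function(f, lo = 0, hi = 1, n = 401, zero_tol = 1e-13) {
  xs <- seq(lo, hi, length.out = n)
  fx <- vapply(xs, f, numeric(1))
  roots <- xs[abs(fx) < zero_tol]
  for (i in seq_len(n - 1)) {
    if (abs(fx[i]) < zero_tol || abs(fx[i + 1]) < zero_tol) next
    if (fx[i] * fx[i + 1] < 0) {
      r <- stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-14)$root
      roots <- c(roots, r)
    }
  }
  merge_close(sort(roots), 1e-8)
}

merge_close <- function(x, tol) {
  if (length(x) <= 1) return(x)
  keep <- c(TRUE, diff(x) > tol)
  x[keep]
}

# --- stationary states ---------------------------------------------------

# private-level balance solved for c_sigma as a function of c_S
csigma_of_cS <- function(c_S, q, p) {
  (p / 2 + (1 - p) * c_S^q) /
    (p + (1 - p) * (c_S^q + (1 - c_S)^q))
}

#' Stationary states of the mean-field equations
#'
#' Finds the fixed points of the rate equations together with their
#' stability, classified from the sign pattern of the Jacobian eigenvalues
#' (central differences, step 1e-6; eigenvalues with real part within
#' 1e-9 of zero are flagged `"marginal"` rather than silently classified).
#'
#' For `variant = "simplified"` the private-level balance is solved
#' analytically for `c_sigma(c_S)` and the remaining one-dimensional public
#' balance is bracketed on a 401-point grid and polished by bisection; the
#' symmetric point `c_S = c_sigma = 1/2` is always a fixed point by the
#' global spin-flip symmetry and is always reported. For
#' `variant = "pairstate"` a multi-start damped Newton search over the
#' 3-simplex is used, seeded from product states built on the simplified
#' fixed points, from symmetric states of varying dissonance, and from a
#' coarse simplex grid.
#'
#' @param params a [model_params()] object.
#' @param variant `"simplified"` or `"pairstate"`.
#' @return data frame with one row per fixed point: concentrations
#'   (`c_S`, `c_sigma`, and for the pair-state variant the four class
#'   fractions, `d` and `rho`), `stability`, `branch` and the residual
#'   norm.
#' @export
stationary_states <- function(params, variant = c("simplified", "pairstate")) {
  stopifnot(inherits(params, "qv_params"))
  variant <- match.arg(variant)
  if (variant == "simplified") {
    stationary_simplified(params)
  } else {
    stationary_pairstate(params)
  }
}

stationary_simplified <- function(params) {
  q <- params$q; p <- params$p
  g_fun <- function(c_S) {
    cs <- csigma_of_cS(c_S, q, p)
    g <- rates_simplified(c_S, cs, params)
    unname(g$S["plus"] - g$S["minus"])
  }
  roots <- find_roots_1d(g_fun)
  if (!any(abs(roots - 0.5) < 1e-8)) roots <- sort(c(roots, 0.5))
  # p = 0: the consensus states are absorbing but sit exactly on the
  # boundary, where the grid may miss them
  if (p == 0) roots <- merge_close(sort(unique(c(0, roots, 1))), 1e-8)

  rows <- lapply(roots, function(r) {
    cs <- csigma_of_cS(r, q, p)
    f2 <- function(y) {
      g <- rates_simplified(min(max(y[1], 0), 1), min(max(y[2], 0), 1),
                            params)
      c(unname(g$S["plus"] - g$S["minus"]),
        unname(g$sigma["plus"] - g$sigma["minus"]))
    }
    res <- f2(c(r, cs))
    J <- num_jacobian(f2, c(r, cs))
    data.frame(c_S = r, c_sigma = cs,
               stability = stability_from_eigen(eigen(J,
                 only.values = TRUE)$values),
               branch = branch_label(r),
               residual = max(abs(res)))
  })
  out <- do.call(rbind, rows)
  out[order(out$c_S), , drop = FALSE]
}

# damped Newton on the three free class fractions (c_mm eliminated)
newton_pairstate <- function(x0, params, max_iter = 100, tol = 1e-12) {
  f <- function(x) {
    cc <- c(x, 1 - sum(x))
    if (any(cc < -1e-6) || any(cc > 1 + 1e-6)) return(rep(NA_real_, 3))
    cc <- pmin(pmax(cc, 0), 1)
    rates_pairstate(cc / sum(cc), params)[1:3]
  }
  x <- x0
  fx <- f(x)
  if (anyNA(fx)) return(NULL)
  for (it in seq_len(max_iter)) {
    if (max(abs(fx)) < tol) break
    J <- num_jacobian(f, x)
    if (anyNA(J)) return(NULL)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      fx_new <- f(x_new)
      if (!anyNA(fx_new) && max(abs(fx_new)) < max(abs(fx))) break
      lambda <- lambda / 2
      if (lambda < 1e-8) return(NULL)
    }
    x <- x_new; fx <- fx_new
  }
  if (max(abs(fx)) >= 1e-9) return(NULL)
  cc <- c(x, 1 - sum(x))
  if (any(cc < -1e-8)) return(NULL)
  pmin(pmax(cc, 0), 1)
}

stationary_pairstate <- function(params) {
  starts <- list()
  simp <- stationary_simplified(params)
  for (i in seq_len(nrow(simp))) {
    cs <- simp$c_S[i]; csg <- simp$c_sigma[i]
    starts <- c(starts, list(c(cs * csg, cs * (1 - csg), (1 - cs) * csg,
                               (1 - cs) * (1 - csg))))
  }
  for (d in c(0, 0.25, 0.5)) {
    starts <- c(starts, list(c((1 - d) / 2, d / 2, d / 2, (1 - d) / 2)))
  }
  grid <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  grid <- grid[rowSums(grid) <= 3, ]
  for (i in seq_len(nrow(grid))) {
    starts <- c(starts, list(c(as.numeric(grid[i, ]),
                               3 - sum(grid[i, ])) / 3))
  }

  sols <- list()
  for (s in starts) {
    cc <- newton_pairstate(s[1:3], params)
    if (is.null(cc)) {
      # pre-relax hard starts along the flow before polishing
      relax <- tryCatch(
        integrate_meanfield(s, params, t_max = 500, n_out = 2),
        error = function(e) NULL)
      if (!is.null(relax)) {
        last <- as.numeric(relax[nrow(relax), c("c_pp", "c_pm", "c_mp",
                                                "c_mm")])
        cc <- newton_pairstate(last[1:3], params)
      }
    }
    if (!is.null(cc)) sols <- c(sols, list(cc))
  }
  if (length(sols) == 0) {
    stop("pair-state stationary search found no fixed point", call. = FALSE)
  }
  m <- do.call(rbind, sols)
  dup <- duplicated(round(m, 8))
  m <- m[!dup, , drop = FALSE]

  rows <- lapply(seq_len(nrow(m)), function(i) {
    cc <- m[i, ]
    f <- function(x) {
      v <- c(x, 1 - sum(x))
      rates_pairstate(pmin(pmax(v, 0), 1) / sum(pmin(pmax(v, 0), 1)),
                      params)[1:3]
    }
    J <- num_jacobian(f, cc[1:3])
    res <- max(abs(rates_pairstate(cc, params)))
    o <- observables_from_counts(cc)
    data.frame(c_pp = cc[1], c_pm = cc[2], c_mp = cc[3], c_mm = cc[4],
               c_S = o$c_S, c_sigma = o$c_sigma, d = o$d,
               rho = if (is.na(o$rho)) NA_real_ else o$rho,
               stability = stability_from_eigen(eigen(J,
                 only.values = TRUE)$values),
               branch = branch_label(o$c_S),
               residual = res)
  })
  out <- do.call(rbind, rows)
  out[order(out$c_S, out$d), , drop = FALSE]
}

# --- critical points and transition type ---------------------------------

#' Analytic critical independence level of the two-level model
#'
#' For `q <= 4` the order-disorder transition is continuous and occurs at
#' \deqn{p^* = \frac{1 - 2^{q-1} + \sqrt{(1 - 2^{q-1})^2 + 4q(q-1)}}{2q};}
#' for larger `q` the same expression gives the lower bound of the
#' metastable (hysteresis) region, i.e. the independence level below which
#' the disordered symmetric state loses stability.
#'
#' @param q panel size, integer `>= 2`.
#' @return the critical independence probability.
#' @export
critical_point <- function(q) {
  if (any(q < 2) || any(q != round(q))) {
    stop("q must be an integer >= 2", call. = FALSE)
  }
  b <- 1 - 2^(q - 1)
  (b + sqrt(b^2 + 4 * q * (q - 1))) / (2 * q)
}

# leading real part of the Jacobian spectrum at the symmetric point
symmetric_leading_eigen <- function(p, q, variant) {
  if (variant == "original") {
    f <- function(c) original_qvoter_drift(c, p, q)
    return(num_jacobian(f, 0.5)[1, 1])
  }
  params <- model_params(q, p)
  f2 <- function(y) {
    g <- rates_simplified(y[1], y[2], params)
    c(unname(g$S["plus"] - g$S["minus"]),
      unname(g$sigma["plus"] - g$sigma["minus"]))
  }
  max(Re(eigen(num_jacobian(f2, c(0.5, 0.5)),
               only.values = TRUE)$values))
}

#' Independence level at which the symmetric state changes stability
#'
#' Locates numerically the `p` at which the leading Jacobian eigenvalue of
#' the symmetric fixed point `c = 1/2` crosses zero. This is the
#' independent numerical check of the closed-form [critical_point()]
#' (and, for discontinuous transitions, the lower spinodal).
#'
#' @param q panel size (`>= 2`).
#' @param variant `"two_level"` (simplified two-concentration system) or
#'   `"original"` (one-level q-voter baseline).
#' @return the threshold probability, to bisection tolerance 1e-12.
#' @export
symmetric_stability_threshold <- function(q,
                                          variant = c("two_level",
                                                      "original")) {
  variant <- match.arg(variant)
  f <- function(p) symmetric_leading_eigen(p, q, variant)
  stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}

original_qvoter_drift <- function(c, p, q) {
  (1 - c) * (p / 2 + (1 - p) * c^q) - c * (p / 2 + (1 - p) * (1 - c)^q)
}

#' Stationary states of the original one-level q-voter model
#'
#' The baseline model with a single (public-only) opinion per agent and
#' random-flip independence: `dc/dt = (1-c)[p/2 + (1-p)c^q] -
#' c[p/2 + (1-p)(1-c)^q]`. Fixed points are located on a 401-point grid
#' with bisection polish; stability follows the sign of the drift
#' derivative.
#'
#' @param p independence probability in `[0, 1]`.
#' @param q panel size (`>= 2`).
#' @return data frame with columns `c`, `stability`, `branch`, `residual`.
#' @export
original_qvoter_stationary <- function(p, q) {
  stopifnot(p >= 0, p <= 1, q >= 2, q == round(q))
  f <- function(c) original_qvoter_drift(c, p, q)
  roots <- find_roots_1d(f)
  if (!any(abs(roots - 0.5) < 1e-8)) roots <- sort(c(roots, 0.5))
  if (p == 0) roots <- merge_close(sort(unique(c(0, roots, 1))), 1e-8)
  rows <- lapply(roots, function(r) {
    slope <- num_jacobian(f, r)[1, 1]
    data.frame(c = r,
               stability = stability_from_eigen(slope),
               branch = branch_label(r),
               residual = abs(f(r)))
  })
  do.call(rbind, rows)
}

has_stable_ordered <- function(p, q, variant) {
  fp <- if (variant == "original") {
    df <- original_qvoter_stationary(p, q)
    data.frame(c_S = df$c, stability = df$stability)
  } else {
    stationary_simplified(model_params(q, p))
  }
  any(fp$stability == "stable" & abs(fp$c_S - 0.5) > 1e-3)
}

#' Classify the order-disorder transition for a given panel size
#'
#' Determines whether the transition in `p` is continuous or discontinuous
#' by looking for an independence range in which stable ordered and stable
#' symmetric (disordered) fixed points coexist. The lower bound of such a
#' metastable region is the symmetric-state spinodal; the upper bound (the
#' largest `p` still supporting a stable ordered state) is located by
#' bisection to 1e-6.
#'
#' @param q panel size (`>= 2`).
#' @param variant `"two_level"` or `"original"`.
#' @return list with elements `q`, `p_star` (lower spinodal; for the
#'   two-level variant the analytic [critical_point()]), `p_upper`, `type`
#'   (`"continuous"` or `"discontinuous"`), and `metastable` (the interval
#'   `c(p_star, p_upper)`, or `NULL` for continuous transitions).
#' @export
transition_type <- function(q, variant = c("two_level", "original")) {
  variant <- match.arg(variant)
  p_sym <- symmetric_stability_threshold(q, variant)
  p_star <- if (variant == "two_level") critical_point(q) else p_sym

  # bisection for the upper spinodal: ordered states always exist just
  # below the symmetric spinodal, never at p close to 1
  lo <- max(p_sym - 1e-4, 1e-6)
  hi <- 1 - 1e-6
  if (!has_stable_ordered(lo, q, variant)) {
    lo <- p_sym / 2
  }
  if (has_stable_ordered(hi, q, variant)) {
    stop("ordered states persist at p ~ 1; unexpected", call. = FALSE)
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (has_stable_ordered(mid, q, variant)) lo <- mid else hi <- mid
  }
  p_upper <- (lo + hi) / 2

  discontinuous <- (p_upper - p_sym) > 5e-5
  list(q = q, p_star = p_star, p_upper = p_upper,
       type = if (discontinuous) "discontinuous" else "continuous",
       metastable = if (discontinuous) c(p_star, p_upper) else NULL)
}

#' Mean-field phase diagram over a (q, p) grid
#'
#' Tabulates the pair-state stationary branches (with dissonance and
#' public-private correlation) for every combination of the supplied panel
#' sizes and independence levels.
#'
#' @param qs integer vector of panel sizes.
#' @param ps numeric vector of independence probabilities.
#' @param ordering `"AT"` or `"TA"`.
#' @param stable_only drop unstable/saddle branches if `TRUE`.
#' @return data frame with columns `q`, `p`, `branch`, `c_S`, `c_sigma`,
#'   `d`, `rho`, `stability`.
#' @export
phase_diagram <- function(qs, ps, ordering = "AT", stable_only = FALSE) {
  rows <- list()
  for (q in qs) {
    for (p in ps) {
      fp <- stationary_states(model_params(q, p, ordering = ordering),
                              variant = "pairstate")
      if (stable_only) fp <- fp[fp$stability == "stable", , drop = FALSE]
      if (nrow(fp) == 0) next
      rows[[length(rows) + 1]] <-
        data.frame(q = q, p = p, branch = fp$branch, c_S = fp$c_S,
                   c_sigma = fp$c_sigma, d = fp$d, rho = fp$rho,
                   stability = fp$stability)
    }
  }
  do.call(rbind, rows)
}
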