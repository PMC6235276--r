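#' Validate a spin value
#'
#' Opinions at both levels are Ising-like spins taking values -1 or +1.
#' `as_spin()` checks and returns its argument; vectors are allowed so the
#' same validator serves single opinions and whole panels.
#'
#' @param x numeric vector expected to contain only -1 and +1.
#' @param what label used in error messages.
#' @return `x` as an integer vector of -1/+1.
#' @export
as_spin <- function(x, what = "spin") {
  if (length(x) == 0L) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || !all(x == 1L | x == -1L)) {
    stop(what, " must only contain -1 or +1", call. = FALSE)
  }
  as.integer(x)
}

#' Model parameters for the two-level q-voter model
#'
#' @param q size of the influence group (q-panel); positive integer.
#' @param p probability of independent (non-conformist) behaviour, in
#'   `[0, 1]`. Each level draws its own independence decision.
#' @param ordering per-step updating order: `"AT"` (act then think; the
#'   public opinion is updated first) or `"TA"` (think then act; the private
#'   opinion is updated first).
#' @param flip_prob probability that an independent agent flips its private
#'   opinion. Fixed at 1/2: the flip probability only rescales the
#'   independence axis, so it is frozen rather than exposed as a free dial.
#' @return an object of class `"qv_params"`.
#' @export
model_params <- function(q, p, ordering = c("AT", "TA"), flip_prob = 0.5) {
  ordering <- match.arg(ordering)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 1 || q != round(q)) {
    stop("q must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(as.numeric(flip_prob), 0.5)) {
    stop("flip_prob is fixed at 1/2", call. = FALSE)
  }
  structure(
    list(q = as.integer(q), p = as.numeric(p), ordering = ordering,
         flip_prob = 0.5),
    class = "qv_params"
  )
}

#' @export
print.qv_params <- function(x, ...) {
  cat(sprintf("two-level q-voter parameters: q = %d, p = %.4g, ordering = %s\n",
              x$q, x$p, x$ordering))
  invisible(x)
}

#' Conformity rule on the public level
#'
#' The focal agent is exposed to the public opinions of a q-panel. If the
#' agent is in internal conflict (public != private), it switches its public
#' opinion to its private one as soon as at least one panel member publicly
#' supports that private opinion. If the agent is in internal harmony
#' (public == private), it is harder to move: the panel must be unanimous,
#' and then the agent adopts the panel's common public opinion.
#'
#' @param s current public opinion (-1 or +1).
#' @param sigma current private opinion (-1 or +1).
#' @param panel integer vector of the q panel members' public opinions.
#' @return the new public opinion.
#' @export
conformity_public <- function(s, sigma, panel) {
  s <- as_spin(s, "public opinion")
  sigma <- as_spin(sigma, "private opinion")
  panel <- as_spin(panel, "panel")
  if (s != sigma) {
    if (any(panel == sigma)) sigma else s
  } else {
    if (all(panel == panel[1L])) panel[1L] else s
  }
}

#' Conformity rule on the private level
#'
#' Beliefs are harder to change than behaviours: on the private level the
#' panel must be unanimous regardless of the agent's internal state, and the
#' agent then adopts the panel's common public opinion as its new private
#' opinion.
#'
#' @param sigma current private opinion.
#' @param panel integer vector of the q panel members' public opinions.
#' @return the new private opinion.
#' @export
conformity_private <- function(sigma, panel) {
  sigma <- as_spin(sigma, "private opinion")
  panel <- as_spin(panel, "panel")
  if (all(panel == panel[1L])) panel[1L] else sigma
}

#' Independence rule on the public level
#'
#' An independent agent expresses its private opinion publicly: the public
#' opinion is replaced by the private one, whatever it currently is.
#'
#' @param sigma current private opinion.
#' @return the new public opinion (equal to `sigma`).
#' @export
independence_public <- function(sigma) {
  as_spin(sigma, "private opinion")
}

#' Independence rule on the private level
#'
#' An independent agent reconsiders its private opinion regardless of its
#' neighbours: the opinion is flipped with probability 1/2. The random draw
#' is passed in explicitly so the rule itself stays a pure function.
#'
#' @param sigma current private opinion.
#' @param coin a uniform draw in `[0, 1)`; the flip happens iff `coin < 1/2`.
#' @return the new private opinion.
#' @export
independence_private <- function(sigma, coin) {
  sigma <- as_spin(sigma, "private opinion")
  if (!is.numeric(coin) || length(coin) != 1L || is.na(coin) ||
      coin < 0 || coin >= 1) {
    stop("coin must lie in [0, 1)", call. = FALSE)
  }
  if (coin < 0.5) -sigma else sigma
}

#' One elementary update of a single agent
#'
#' Applies one full update of the focal agent's two opinions, in the order
#' selected by `params$ordering`:
#' \describe{
#'   \item{AT (act then think)}{the public level is updated first, using the
#'     agent's *current* private opinion; the private level is updated
#'     second.}
#'   \item{TA (think then act)}{the private level is updated first; the
#'     public level is then updated using the *already updated* private
#'     opinion.}
#' }
#' At each level the agent acts independently with probability `p`
#' (comparing that level's independence coin against `p`) and conforms to
#' its q-panel otherwise. The two levels use separately drawn panels and
#' separate coins; all randomness is supplied by the caller, which makes the
#' update a deterministic, testable function.
#'
#' @param state list with elements `public` and `private` (spins).
#' @param params a [model_params()] object.
#' @param panels list of two integer vectors: the panel of public opinions
#'   used by the public-level step and the one used by the private-level
#'   step (each of length `q`).
#' @param coins numeric vector of three uniform draws in `[0, 1)`: the
#'   public-level independence coin, the private-level independence coin,
#'   and the private flip coin.
#' @return list with elements `public` and `private`: the updated state.
#' @export
elementary_update <- function(state, params, panels, coins) {
  stopifnot(inherits(params, "qv_params"))
  s <- as_spin(state$public, "public opinion")
  sigma <- as_spin(state$private, "private opinion")
  if (!is.list(panels) || length(panels) != 2L) {
    stop("panels must be a list of two panels", call. = FALSE)
  }
  if (!is.numeric(coins) || length(coins) != 3L || anyNA(coins) ||
      any(coins < 0 | coins >= 1)) {
    stop("coins must be three uniform draws in [0, 1)", call. = FALSE)
  }
  if (length(panels[[1L]]) != params$q || length(panels[[2L]]) != params$q) {
    stop("each panel must have exactly q members", call. = FALSE)
  }

  update_public <- function(s, sigma) {
    if (coins[1L] < params$p) {
      independence_public(sigma)
    } else {
      conformity_public(s, sigma, panels[[1L]])
    }
  }
  update_private <- function(sigma) {
    if (coins[2L] < params$p) {
      independence_private(sigma, coins[3L])
    } else {
      conformity_private(sigma, panels[[2L]])
    }
  }

  if (params$ordering == "AT") {
    s_new <- update_public(s, sigma)
    sigma_new <- update_private(sigma)
  } else {
    sigma_new <- update_private(sigma)
    s_new <- update_public(s, sigma_new)
  }
  list(public = s_new, private = sigma_new)
}
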