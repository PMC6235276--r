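#' Willis code of a single-level response triplet
#'
#' A social-influence trial at one opinion level is summarised by three
#' signs: the target's pre-influence position, the position advocated by
#' the source, and the target's post-influence position. The four basic
#' response patterns are conformity `C` (moving to the source's position
#' from disagreement), independence `I` (keeping one's position despite
#' disagreement), anticonformity `A` (moving away from an agreeing
#' source), and uniformity `U` (agreement before and after).
#'
#' @param pre,source,post spins (-1/+1); vectors are recycled to a common
#'   length.
#' @return character vector of codes `"C"`, `"I"`, `"A"`, `"U"`.
#' @export
willis_code <- function(pre, source, post) {
  n <- max(length(pre), length(source), length(post))
  pre <- rep_len(as_spin(pre, "pre"), n)
  source <- rep_len(as_spin(source, "source"), n)
  post <- rep_len(as_spin(post, "post"), n)
  ifelse(pre == source,
         ifelse(post == source, "U", "A"),
         ifelse(post == source, "C", "I"))
}

#' The sixteen response patterns of the four-dimensional taxonomy
#'
#' Each pattern is one equivalence class (under global sign flip) of the
#' 32 combinations of pre- and post-influence positions at the public and
#' private levels relative to the source's publicly visible position. The
#' canonical representative fixes the source at +1.
#'
#' @return data frame with columns `id`, `name`, and the canonical
#'   `pub_pre`, `pub_post`, `priv_pre`, `priv_post` spins (source = +1),
#'   plus the derived public and private Willis codes.
#' @export
response_patterns <- function() {
  tab <- data.frame(
    id = 1:16,
    name = c("Congruence", "Paradoxical Compliance", "Anticompliance",
             "Anticonversion", "Compliance/Conversion",
             "Continued Compliance", "Reversed Anticompliance",
             "Disinhibitory Anticonversion", "Disinhibitory Contagion",
             "Reversed Compliance", "Inhibitory Independence",
             "Anticontagion", "Conversion", "Compliance",
             "Paradoxical Anticompliance", "Independence"),
    pub_pre  = c( 1,  1,  1,  1,  1,  1,  1,  1, -1, -1, -1, -1, -1, -1, -1, -1),
    pub_post = c( 1,  1, -1, -1,  1,  1, -1, -1,  1,  1, -1, -1,  1,  1, -1, -1),
    priv_pre = c( 1,  1,  1,  1, -1, -1, -1, -1,  1,  1,  1,  1, -1, -1, -1, -1),
    priv_post= c( 1, -1,  1, -1,  1, -1,  1, -1,  1, -1,  1, -1,  1, -1,  1, -1),
    stringsAsFactors = FALSE
  )
  tab$pub_code <- willis_code(tab$pub_pre, 1L, tab$pub_post)
  tab$priv_code <- willis_code(tab$priv_pre, 1L, tab$priv_post)
  tab
}

#' Classify a two-level influence trial into one of the 16 patterns
#'
#' Takes the Willis triplets of the same trial at the two levels and maps
#' them to the unique pattern of the four-dimensional taxonomy. Both
#' triplets must share the source position (only the source's public
#' position is visible to the target), and a trial and its global sign
#' mirror map to the same pattern.
#'
#' @param pub,priv length-3 spin vectors `(pre, source, post)` for the
#'   public and private level.
#' @return a one-row data frame: the matching row of
#'   [response_patterns()].
#' @export
classify_pattern <- function(pub, priv) {
  pub <- as_spin(pub, "public triplet")
  priv <- as_spin(priv, "private triplet")
  if (length(pub) != 3L || length(priv) != 3L) {
    stop("triplets must have length 3 (pre, source, post)", call. = FALSE)
  }
  if (pub[2L] != priv[2L]) {
    stop("public and private triplets must share the source position",
         call. = FALSE)
  }
  flip <- pub[2L]  # canonicalise so the source is +1
  pub <- pub * flip
  priv <- priv * flip
  tab <- response_patterns()
  hit <- tab$pub_pre == pub[1L] & tab$pub_post == pub[3L] &
    tab$priv_pre == priv[1L] & tab$priv_post == priv[3L]
  tab[hit, , drop = FALSE]
}

#' Tally influence events into response-pattern frequencies
#'
#' Applies [classify_pattern()] to a batch of influence events, e.g. the
#' ones recorded by [run_trajectory()] with `record_events > 0`. An event
#' carries the pre- and post-update opinions at both levels and, when at
#' least one level acted through conformity, the source's exerted public
#' position; events without a source (both levels acted independently)
#' cannot be placed in the taxonomy and are counted in the unclassifiable
#' bucket.
#'
#' @param events data frame with integer columns `pre_pub`, `pre_priv`,
#'   `post_pub`, `post_priv` and `source` (`NA` when no source exists).
#' @return data frame with one row per pattern id 1-16 plus a final
#'   unclassifiable row (`id = NA`), with columns `id`, `name`, `count`,
#'   `fraction`; counts sum to `nrow(events)`.
#' @export
tally_events <- function(events) {
  tab <- response_patterns()
  counts <- integer(16)
  unclassifiable <- 0L
  n <- if (is.null(events)) 0L else nrow(events)
  for (i in seq_len(n)) {
    src <- events$source[i]
    if (is.na(src)) {
      unclassifiable <- unclassifiable + 1L
      next
    }
    hit <- classify_pattern(c(events$pre_pub[i], src, events$post_pub[i]),
                            c(events$pre_priv[i], src, events$post_priv[i]))
    counts[hit$id] <- counts[hit$id] + 1L
  }
  out <- data.frame(id = c(tab$id, NA_integer_),
                    name = c(tab$name, "unclassifiable"),
                    count = c(counts, unclassifiable))
  out$fraction <- if (n > 0) out$count / n else 0
  out
}
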