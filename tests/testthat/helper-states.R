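# random points on the 3-simplex (four class fractions summing to 1)
random_simplex_states <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- stats::rexp(4)
    x / sum(x)
  })
}

# all 2^k sign combinations as rows
sign_grid <- function(k) {
  as.matrix(expand.grid(rep(list(c(-1L, 1L)), k)))
}

ordered_counts <- function(N) class_counts(N, 0, 0, 0)
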