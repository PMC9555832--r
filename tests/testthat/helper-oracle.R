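# Independent brute-force oracle for the neutral death-birth kernel on tiny
# fully occupied grids: enumerate every allele assignment, build the exact
# one-event transition matrix by direct summation over (target, parent)
# pairs, and solve the absorbing chain.  Nothing here touches the package's
# stepping code.

# Moore adjacency built from first principles (Chebyshev distance 1).
oracle_moore_adj <- function(rows, cols) {
  n <- rows * cols
  lapply(seq_len(n) - 1L, function(i) {
    r <- i %/% cols; c <- i %% cols
    out <- integer(0)
    for (rr in (r - 1):(r + 1)) {
      for (cc in (c - 1):(c + 1)) {
        if (rr == r && cc == c) next
        if (rr < 0 || rr >= rows || cc < 0 || cc >= cols) next
        out <- c(out, rr * cols + cc)
      }
    }
    out + 1L  # 1-based for R indexing
  })
}

# Exact chain for mu = 0 on a fully occupied graph: target uniform over all
# n cells, parent uniform over the target's neighbours (all occupied).
# Returns fixation probabilities per allele and the expected number of
# events to absorption, both from the given start.
oracle_voter_chain <- function(adj, init_alleles) {
  n <- length(adj)
  alleles <- sort(unique(init_alleles))
  A <- length(alleles)
  n_states <- A^n
  # State id: 1 + sum over cells of (allele index - 1) * A^(cell - 1).
  encode <- function(s) 1L + sum((match(s, alleles) - 1L) * A^(seq_len(n) - 1L))
  decode <- function(id) alleles[((id - 1L) %/% A^(seq_len(n) - 1L)) %% A + 1L]
  P <- matrix(0, n_states, n_states)
  for (id in seq_len(n_states)) {
    s <- decode(id)
    for (t in seq_len(n)) {
      deg <- length(adj[[t]])
      for (p in adj[[t]]) {
        s2 <- s
        s2[t] <- s[p]
        P[id, encode(s2)] <- P[id, encode(s2)] + 1 / (n * deg)
      }
    }
  }
  mono <- vapply(seq_len(n_states), function(id) {
    s <- decode(id)
    all(s == s[1])
  }, logical(1))
  trans <- which(!mono)
  absorb <- which(mono)
  Q <- P[trans, trans, drop = FALSE]
  R <- P[trans, absorb, drop = FALSE]
  Nf <- solve(diag(length(trans)) - Q)
  B <- Nf %*% R                      # absorption probabilities
  t_abs <- Nf %*% rep(1, length(trans))  # expected events to absorption
  start <- encode(init_alleles)
  if (mono[start]) {
    fix <- setNames(as.numeric(alleles == init_alleles[1]), alleles)
    return(list(fix_prob = fix, mean_events = 0))
  }
  i <- match(start, trans)
  absorb_allele <- vapply(absorb, function(id) decode(id)[1], alleles[1])
  fp <- setNames(numeric(A), alleles)
  for (j in seq_along(absorb)) {
    fp[as.character(absorb_allele[j])] <- fp[as.character(absorb_allele[j])] + B[i, j]
  }
  list(fix_prob = fp, mean_events = as.numeric(t_abs[i]))
}

# Closed-form expected number of distinct alleles in an Ewens sample.
ewens_expected_k <- function(n, theta) sum(theta / (theta + 0:(n - 1)))

# Sum of Moore degrees of a rows x cols grid, from the adjacency above.
oracle_degree_sum <- function(rows, cols) {
  sum(lengths(oracle_moore_adj(rows, cols)))
}
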