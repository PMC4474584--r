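# Independent reference implementations used as oracles. Deliberately
# straightforward (loops and exhaustive enumeration), no shared code with
# the package internals.

oracle_ap <- function(ids, relevant) {
  hits <- 0; s <- 0
  for (r in seq_along(ids)) {
    if (ids[r] %in% relevant) {
      hits <- hits + 1
      s <- s + hits / r
    }
  }
  s / length(unique(relevant))
}

oracle_p_at_k <- function(ids, relevant, k) {
  n <- 0
  for (r in seq_len(k)) {
    if (r <= length(ids) && ids[r] %in% relevant) n <- n + 1
  }
  n / k
}

oracle_rprec <- function(ids, relevant) {
  R <- length(unique(relevant))
  oracle_p_at_k(ids, relevant, R) # precision at rank R by definition
}

# Brute-force maximum over all one-to-one note pairings; pairs with
# non-positive similarity may be left unmatched (they contribute nothing).
oracle_assignment_score <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  if (nr > nc) return(oracle_assignment_score(t(S)))
  best <- 0
  cols <- seq_len(nc)
  rec <- function(row, avail, acc) {
    if (row > nr) {
      best <<- max(best, acc)
      return(invisible())
    }
    for (j in avail) # pair row with j (only profitable pairs pay)
      rec(row + 1L, setdiff(avail, j), acc + max(S[row, j], 0))
  }
  rec(1L, cols, 0)
  2 * best / (nr + nc)
}

# Brute-force maximum over all strictly order-preserving partial matchings.
oracle_alignment_score <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  best <- 0
  rec <- function(i, j, acc) {
    best <<- max(best, acc)
    if (i > nr || j > nc) return(invisible())
    for (ii in i:nr) for (jj in j:nc)
      if (S[ii, jj] > 0) rec(ii + 1L, jj + 1L, acc + S[ii, jj])
  }
  rec(1L, 1L, 0)
  2 * best / (nr + nc)
}
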