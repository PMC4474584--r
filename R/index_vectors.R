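#' Random-indexing configuration
#'
#' Parameters of the sparse ternary index vectors and the RI trainers.
#' Defaults follow the standard small-scale random-indexing setup for
#' clinical text: dimensionality 800, 4 nonzero entries per index vector, a
#' narrow 5+5 context window with distance weights `b^(1-d)` and direction
#' vectors realized as a one-coordinate rotation.
#'
#' @param dim Vector dimensionality.
#' @param n_nonzero Nonzero entries per index vector (even; half +1, half -1).
#' @param window One-sided context width for the word-context trainer.
#' @param distance_weight_base Base `b` of the neighbour weight `b^(1-d)`.
#' @param use_direction_shift Rotate left/right-context index vectors by one
#'   coordinate before summation.
#' @param seed Integer seed controlling the index-vector assignment.
#' @return An object of class `ri_config`.
#' @export
ri_config <- function(dim = 800L, n_nonzero = 4L, window = 5L,
                      distance_weight_base = 2, use_direction_shift = TRUE,
                      seed = 1L) {
  dim <- as.integer(dim); n_nonzero <- as.integer(n_nonzero)
  window <- as.integer(window)
  stopifnot(n_nonzero %% 2L == 0L, n_nonzero < dim, window >= 1L,
            distance_weight_base > 0)
  structure(list(dim = dim, n_nonzero = n_nonzero, window = window,
                 distance_weight_base = distance_weight_base,
                 use_direction_shift = isTRUE(use_direction_shift),
                 seed = as.integer(seed)),
            class = "ri_config")
}

# Deterministic 31-bit string hash (FNV-style polynomial), exact in doubles.
hash_key <- function(key, seed) {
  h <- (as.numeric(seed) * 2654435761) %% 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  expr
}

#' Create the sparse ternary index vector of a key
#'
#' Every word, note or ICD-taxonomy node is assigned a fixed sparse random
#' signature: `n_nonzero` distinct coordinates, half set to +1 and half to
#' -1. The vector is a pure deterministic function of the key string and the
#' configuration seed, so no vector table needs to be stored.
#'
#' @param key Key string.
#' @param cfg An [ri_config()].
#' @return An object of class `index_vector` with fields `dim`, `positions`
#'   (1-based) and `signs`.
#' @export
make_index_vector <- function(key, cfg = ri_config()) {
  with_preserved_rng({
    set.seed(hash_key(key, cfg$seed))
    pos <- sample.int(cfg$dim, cfg$n_nonzero)
    signs <- rep(c(1, -1), each = cfg$n_nonzero %/% 2L)
    structure(list(dim = cfg$dim, positions = pos, signs = signs),
              class = "index_vector")
  })
}

#' Rotate an index vector one coordinate left or right
#'
#' Direction vectors: before being summed into a context vector, the index
#' vector of a left-context neighbour is rotated one coordinate left and
#' that of a right-context neighbour one coordinate right, so that word
#' order is (weakly) encoded. Rotation is circular; shifting left then right
#' restores the original vector.
#'
#' @param v An `index_vector`.
#' @param direction `"left"` or `"right"`.
#' @return The rotated `index_vector`.
#' @export
shift_vector <- function(v, direction = c("left", "right")) {
  direction <- match.arg(direction)
  p <- v$positions
  v$positions <- if (direction == "right") p %% v$dim + 1L
                 else (p - 2L) %% v$dim + 1L
  v
}

as_dense <- function(v) {
  out <- numeric(v$dim)
  out[v$positions] <- v$signs
  out
}

# Sparse matrix whose rows are the index vectors of `keys` (in order).
index_matrix <- function(keys, cfg) {
  n <- length(keys)
  k <- cfg$n_nonzero
  pos <- matrix(0L, n, k)
  with_preserved_rng({
    for (i in seq_len(n)) {
      set.seed(hash_key(keys[[i]], cfg$seed))
      pos[i, ] <- sample.int(cfg$dim, k)
    }
  })
  signs <- rep(rep(c(1, -1), each = k %/% 2L), times = n)
  Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(pos)),
                       x = signs, dims = c(n, cfg$dim))
}

# Column rotation of an index matrix: "right" moves coordinate p to p+1.
rotate_columns <- function(m, direction) {
  d <- ncol(m)
  if (direction == "right") m[, c(d, seq_len(d - 1L)), drop = FALSE]
  else m[, c(seq_len(d)[-1L], 1L), drop = FALSE]
}
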