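# Global pairwise alignment (Gotoh, affine gaps) used for template-chain
# assignment and for mapping template residues onto merged positions.
#
# Scoring: match = 1, mismatch = 0, and a gap run of length L costs
# open + L * extend (defaults 0.5 and 0.1). The optimum is taken
# lexicographically as (score, number of identical aligned positions) so
# that the reported identity is deterministic under co-optimal alignments.
# Scores are multiples of 0.1, which allows the pair to be packed into a
# single number: value = round(10 * score) * 1e4 + matches. Sequence
# lengths are capped at 5000 so `matches` never overflows its slot.

GS_NEG_INF <- -1e15
GS_PACK <- 1e4

pack_val <- function(score10, matches) score10 * GS_PACK + matches
unpack_matches <- function(v) v - floor(v / GS_PACK) * GS_PACK
unpack_score <- function(v) floor(v / GS_PACK) / 10

#' Global alignment of two amino-acid sequences
#'
#' @param a,b Non-empty one-letter amino-acid strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters. `gap_open`
#'   and `gap_extend` are positive costs; a gap run of length L costs
#'   `gap_open + L * gap_extend`. All must be multiples of 0.1.
#' @return A list with `score`, `matches` (identical aligned positions under
#'   the lexicographic (score, matches) optimum), `identity`
#'   (= matches / length of the shorter sequence) and `pairs`, a two-column
#'   matrix of aligned (position in `a`, position in `b`) index pairs.
#' @export
align_global <- function(a, b, match = 1, mismatch = 0,
                         gap_open = 0.5, gap_extend = 0.1) {
  assert_aa_string(a, "sequence a")
  assert_aa_string(b, "sequence b")
  av <- seq_chars(a); bv <- seq_chars(b)
  n <- length(av); m <- length(bv)
  if (n > 5000L || m > 5000L)
    stop("sequences longer than 5000 residues are not supported", call. = FALSE)
  sc <- function(x) {
    x10 <- round(10 * x)
    if (abs(x10 - 10 * x) > 1e-9)
      stop("scoring parameters must be multiples of 0.1", call. = FALSE)
    as.numeric(x10)
  }
  mt10 <- sc(match); mm10 <- sc(mismatch)
  go10 <- sc(gap_open); ge10 <- sc(gap_extend)
  d_open <- -(go10 + ge10) * GS_PACK    # first residue of a gap run
  d_ext <- -ge10 * GS_PACK              # each further residue

  # state matrices over (0..n) x (0..m); M = aligned pair at (i,j),
  # X = gap in b (consumes a[i]), Y = gap in a (consumes b[j])
  M <- matrix(GS_NEG_INF, n + 1L, m + 1L)
  X <- matrix(GS_NEG_INF, n + 1L, m + 1L)
  Y <- matrix(GS_NEG_INF, n + 1L, m + 1L)
  # traceback: which state provided the max entering each cell (0 none)
  tbM <- matrix(0L, n + 1L, m + 1L)
  tbX <- matrix(0L, n + 1L, m + 1L)
  tbY <- matrix(0L, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1L, 1L] <- d_open + (i - 1L) * d_ext
    tbX[i + 1L, 1L] <- if (i == 1L) 1L else 2L
  }
  for (j in seq_len(m)) {
    Y[1L, j + 1L] <- d_open + (j - 1L) * d_ext
    tbY[1L, j + 1L] <- if (j == 1L) 1L else 3L
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- av[i] == bv[j]
      sub <- pack_val(if (hit) mt10 else mm10, if (hit) 1 else 0)
      cand <- c(M[i, j], X[i, j], Y[i, j])
      k <- which.max(cand)
      M[i + 1L, j + 1L] <- cand[k] + sub
      tbM[i + 1L, j + 1L] <- k
      cand <- c(M[i, j + 1L] + d_open, X[i, j + 1L] + d_ext,
                Y[i, j + 1L] + d_open)
      k <- which.max(cand)
      X[i + 1L, j + 1L] <- cand[k]
      tbX[i + 1L, j + 1L] <- k
      cand <- c(M[i + 1L, j] + d_open, X[i + 1L, j] + d_open,
                Y[i + 1L, j] + d_ext)
      k <- which.max(cand)
      Y[i + 1L, j + 1L] <- cand[k]
      tbY[i + 1L, j + 1L] <- k
    }
  }
  fin <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- which.max(fin)
  best <- fin[state]
  # traceback to recover aligned index pairs
  pairs <- matrix(0L, 0L, 2L)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      pairs <- rbind(c(i, j), pairs)
      prev <- tbM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      prev <- tbX[i + 1L, j + 1L]
      i <- i - 1L
    } else {
      prev <- tbY[i + 1L, j + 1L]
      j <- j - 1L
    }
    state <- prev
  }
  matches <- unpack_matches(best)
  list(score = unpack_score(best), matches = as.integer(matches),
       identity = matches / min(n, m), pairs = pairs)
}

#' Pairwise sequence identity
#'
#' Identical aligned positions from a global alignment, normalised by the
#' length of the shorter sequence. Symmetric in its arguments.
#'
#' @inheritParams align_global
#' @return A fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b, match = 1, mismatch = 0,
                              gap_open = 0.5, gap_extend = 0.1) {
  align_global(a, b, match, mismatch, gap_open, gap_extend)$identity
}
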