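# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (enumeration, explicit loops, repeated scans) and
# share no code with the implementation paths they check.

# --- exhaustive global-alignment oracle (tiny strings only) -----------------
# Enumerates every global alignment as an op string (M = aligned pair,
# A = gap in b consuming a, B = gap in a consuming b), scores it with
# match/mismatch plus affine gap runs costing open + len * ext, and returns
# the lexicographic (score, matches) optimum.
oracle_align <- function(a, b, match = 1, mismatch = 0,
                         open = 0.5, ext = 0.1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- c(score = -Inf, matches = -Inf)
  score_ops <- function(ops) {
    i <- 0L; j <- 0L; sc <- 0; mt <- 0L; run <- ""
    for (op in ops) {
      if (op == "M") {
        i <- i + 1L; j <- j + 1L
        if (av[i] == bv[j]) { sc <- sc + match; mt <- mt + 1L }
        else sc <- sc + mismatch
        run <- ""
      } else {
        i <- i + (op == "A"); j <- j + (op == "B")
        sc <- sc - ext - if (run == op) 0 else open
        run <- op
      }
    }
    c(score = sc, matches = mt)
  }
  recurse <- function(i, j, ops) {
    if (i == length(av) && j == length(bv)) {
      s <- score_ops(ops)
      if (s["score"] > best["score"] + 1e-9 ||
          (abs(s["score"] - best["score"]) < 1e-9 &&
           s["matches"] > best["matches"]))
        best <<- s
      return(invisible())
    }
    if (i < length(av) && j < length(bv)) recurse(i + 1L, j + 1L, c(ops, "M"))
    if (i < length(av)) recurse(i + 1L, j, c(ops, "A"))
    if (j < length(bv)) recurse(i, j + 1L, c(ops, "B"))
  }
  recurse(0L, 0L, character(0))
  c(best, identity = unname(best["matches"]) / min(length(av), length(bv)))
}

# --- independent greedy-assignment oracle -----------------------------------
# Repeated argmax scan (no sorting), with explicit tie-breaks: highest
# identity, then lowest target index, then lexicographically first chain.
oracle_greedy <- function(m, chain_ids = colnames(m)) {
  nt <- nrow(m); nc <- ncol(m)
  free_t <- rep(TRUE, nt); free_c <- rep(TRUE, nc)
  pairs <- list()
  repeat {
    best <- NULL
    for (t in seq_len(nt)) {
      if (!free_t[t]) next
      for (c in seq_len(nc)) {
        if (!free_c[c]) next
        better <- is.null(best) ||
          m[t, c] > best$id + 1e-15 ||
          (m[t, c] == best$id &&
           (t < best$t || (t == best$t && chain_ids[c] < chain_ids[best$c])))
        if (better) best <- list(t = t, c = c, id = m[t, c])
      }
    }
    if (is.null(best)) break
    free_t[best$t] <- FALSE; free_c[best$c] <- FALSE
    pairs[[length(pairs) + 1L]] <- best
  }
  pairs <- pairs[order(vapply(pairs, `[[`, numeric(1), "t"))]
  data.frame(target_index = vapply(pairs, `[[`, numeric(1), "t"),
             template_chain_id = chain_ids[vapply(pairs, `[[`, numeric(1),
                                                  "c")],
             identity = vapply(pairs, `[[`, numeric(1), "id"),
             stringsAsFactors = FALSE)
}

# Optimal (Hungarian-equivalent) assignment by permutation enumeration;
# returns the maximal total identity for square-ish matrices up to 4x4.
oracle_optimal_total <- function(m) {
  k <- min(nrow(m), ncol(m))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- -Inf
  if (nrow(m) <= ncol(m)) {
    for (p in perms(seq_len(ncol(m)))) {
      tot <- sum(m[cbind(seq_len(k), p[seq_len(k)])])
      best <- max(best, tot)
    }
  } else {
    for (p in perms(seq_len(nrow(m)))) {
      tot <- sum(m[cbind(p[seq_len(k)], seq_len(k))])
      best <- max(best, tot)
    }
  }
  best
}

# --- brute-force distogram integration oracle -------------------------------
# Explicit per-bin loop, no vectorization shared with the implementation.
oracle_contact_prob <- function(probs_vec, edges, cutoff) {
  nb <- length(edges) + 1L
  total <- 0
  for (k in seq_len(nb)) {
    lo <- if (k == 1L) -Inf else edges[k - 1L]
    hi <- if (k == nb) Inf else edges[k]
    if (k == 1L) {
      # open lower bin always counts fully
      total <- total + probs_vec[k]
    } else if (hi <= cutoff) {
      total <- total + probs_vec[k]
    } else if (lo < cutoff && is.finite(hi)) {
      total <- total + probs_vec[k] * (cutoff - lo) / (hi - lo)
    }
  }
  total
}

# Random normalized symmetric distogram over random strictly increasing
# edges; returns a gs_distogram.
random_distogram <- function(L = 4L, nb = 8L, edge_lo = 2, edge_hi = 20) {
  edges <- sort(runif(nb - 1L, edge_lo, edge_hi))
  while (any(diff(edges) < 1e-3))
    edges <- sort(runif(nb - 1L, edge_lo, edge_hi))
  probs <- array(0, dim = c(L, L, nb))
  for (i in seq_len(L)) for (j in i:L) {
    v <- rexp(nb); v <- v / sum(v)
    probs[i, j, ] <- v
    probs[j, i, ] <- v
  }
  new_distogram(probs, edges)
}

# --- misc -------------------------------------------------------------------
contact_key_df <- function(cs)
  paste(cs$chain_a, cs$res_a, cs$chain_b, cs$res_b, sep = "|")

# Tiny hand-built two-chain complex with exactly known contacts.
micro_complex <- function(dab = 7.0) {
  # chain A: three residues along x; chain B: three residues offset in y
  caA <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  caB <- rbind(c(0, dab, 0), c(4, dab, 0), c(80, dab, 0))
  a <- new_chain_record("A", "AGV", 1:3, ca = caA)
  b <- new_chain_record("B", "KGL", 1:3, ca = caB)
  new_complex(list(a, b))
}
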