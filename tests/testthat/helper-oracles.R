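# Independent oracles and fixture builders used across the suite.

# quick fingerprint matrix from row vectors
fp <- function(..., ids = NULL) {
  m <- rbind(...)
  if (is.null(ids)) ids <- paste0("m", seq_len(nrow(m)))
  fingerprint_matrix(m, ids)
}

# hand-built ranked_list over a database, from ids in best-first order
mk_ranked <- function(ids_in_order, coefficient = "x", reference = "ref") {
  positions <- seq_along(ids_in_order)
  names(positions) <- ids_in_order
  structure(list(ids = ids_in_order,
                 positions = positions[sort(names(positions))],
                 coefficient = coefficient, reference_id = reference),
            class = "ranked_list")
}

# brute-force Condorcet winner: enumerate every pairwise contest
condorcet_brute <- function(points) {
  m <- ncol(points)
  for (i in seq_len(m)) {
    ok <- TRUE
    for (j in seq_len(m)[-i]) {
      wi <- sum(points[, i] > points[, j])
      wj <- sum(points[, j] > points[, i])
      if (wi <= wj) { ok <- FALSE; break }
    }
    if (ok) return(colnames(points)[i])
  }
  NA_character_
}

# random voting profile: rows derived from random scores (ties possible)
rand_profile <- function(m, V) {
  pts <- t(sapply(seq_len(V), function(i) {
    s <- sample.int(m + 1L, m, replace = TRUE)   # small range forces ties
    rank(s, ties.method = "average")
  }))
  if (V == 1L) pts <- matrix(pts, nrow = 1L)
  colnames(pts) <- paste0("S", seq_len(m))
  voting_profile(pts, topn = V)
}

# independent transcription of the BEDROC formula, scalar arithmetic only
bedroc_oracle <- function(active_ranks, N, alpha) {
  A <- length(active_ranks)
  s <- 0
  for (r in active_ranks) s <- s + exp(-alpha * r / N)
  rie_denom <- (1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rie <- (s / A) / rie_denom
  Ra <- A / N
  f1 <- Ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra))
  f2 <- 1 / (1 - exp(alpha * (1 - Ra)))
  rie * f1 + f2
}

# pair-counting AUC: fraction of (active, inactive) pairs ranked correctly
auc_pairs <- function(active_ranks, N) {
  inact <- setdiff(seq_len(N), active_ranks)
  good <- 0
  for (a in active_ranks) for (d in inact) if (a < d) good <- good + 1
  good / (length(active_ranks) * length(inact))
}

# plain character ranking of N molecules with actives at given positions
ranking_with_actives <- function(N, active_positions) {
  ids <- sprintf("d%04d", seq_len(N))
  actives <- sprintf("a%04d", seq_along(active_positions))
  ids[active_positions] <- actives
  list(ranking = ids, actives = actives)
}

# random sparse count-vector pair sharing at least some support
rand_count_pair <- function(M = 32L) {
  repeat {
    a <- ifelse(runif(M) < 0.4, sample(0:5, M, replace = TRUE), 0)
    b <- ifelse(runif(M) < 0.4, sample(0:5, M, replace = TRUE), 0)
    if (sum(a) > 0 && sum(b) > 0) return(list(a = as.numeric(a),
                                              b = as.numeric(b)))
  }
}
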