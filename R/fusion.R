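# Borda-count / Condorcet election of a winner similarity coefficient.
#
# A voting profile is a voters x measures points matrix. Each voter awards
# every measure a number of points: with m candidate measures the best
# measure receives m points and the worst receives 1; measures that tie
# share the average of the points they span, so every row always sums to
# m(m+1)/2. The Borda total of a measure is its column sum; the Condorcet
# winner (when one exists) is the measure that beats every other measure in
# pairwise voter-majority contests.

#' Construct a voting profile from an explicit points matrix
#'
#' @param points numeric voters x measures matrix; each row must be a
#'   permutation of 1..m, or its tie-averaged equivalent (row sums
#'   m(m+1)/2, entries within \[1, m\])
#' @param measure_ids column names; default taken from `colnames(points)`
#' @param topn the top-n committee size the profile was built from (kept as
#'   metadata; defaults to `nrow(points)`)
#' @param basis `"rank"`, `"value"`, or `"direct"` for hand-built profiles
#' @return a `voting_profile`
#' @export
voting_profile <- function(points, measure_ids = colnames(points),
                           topn = nrow(points), basis = "direct") {
  points <- as.matrix(points)
  m <- ncol(points); v <- nrow(points)
  if (m < 2L) stop("a voting profile needs at least 2 measures")
  if (v < 1L) stop("a voting profile needs at least 1 voter")
  if (is.null(measure_ids)) measure_ids <- paste0("S", seq_len(m))
  if (anyDuplicated(measure_ids)) stop("duplicate measure ids")
  target <- m * (m + 1) / 2
  if (any(abs(rowSums(points) - target) > 1e-8))
    stop("invalid profile: every row must sum to m(m+1)/2 = ", target)
  if (any(points < 1 - 1e-8) || any(points > m + 1e-8))
    stop("invalid profile: points must lie within [1, m]")
  colnames(points) <- measure_ids
  structure(list(points = points, measure_ids = measure_ids,
                 topn = as.integer(topn), basis = basis),
            class = "voting_profile")
}

#' @export
print.voting_profile <- function(x, ...) {
  cat(sprintf("voting_profile: %d voters x %d measures (basis: %s, topn: %d)\n",
              nrow(x$points), ncol(x$points), x$basis, x$topn))
  print(head(x$points, 6L))
  if (nrow(x$points) > 6L) cat("...\n")
  invisible(x)
}

#' Build a voting profile from per-coefficient search results
#'
#' Two readings of "the top retrieved structures are the voters" are
#' provided:
#'
#' * `basis = "rank"` (default, scale-free): the voters are the molecules in
#'   the union of the m per-coefficient top-n lists. For each voter the m
#'   measures are ordered by the rank position they assign that molecule in
#'   their full rankings; the measure placing it best receives m points, the
#'   worst 1 point, with ties sharing averaged points.
#' * `basis = "value"`: the voters are the retrieval positions 1..topn. For
#'   position i each measure contributes the min-max-normalized similarity
#'   value (normalized within that measure's own top-n; distance coefficients
#'   reversed so that larger always means more similar) of the structure it
#'   retrieved at position i, and measures are awarded points by those
#'   normalized values. A measure whose top-n scores are all equal
#'   contributes the neutral value 0.5 at every position.
#'
#' @param ranked_lists named list of `ranked_list` objects, one per measure,
#'   all over the same database; names are the measure ids
#' @param topn committee size; at most the database size
#' @param basis `"rank"` or `"value"`
#' @param raw_scores named list of `similarity_scores` parallel to
#'   `ranked_lists`; required for `basis = "value"`
#' @return a `voting_profile`
#' @export
build_voting_profile <- function(ranked_lists, topn,
                                 basis = c("rank", "value"),
                                 raw_scores = NULL) {
  basis <- match.arg(basis)
  m <- length(ranked_lists)
  if (m < 2L) stop("need at least 2 measures to hold an election")
  measure_ids <- names(ranked_lists)
  if (is.null(measure_ids) || any(measure_ids == ""))
    stop("ranked_lists must be a named list (names = measure ids)")
  ns <- vapply(ranked_lists, function(r) length(r$ids), integer(1))
  if (length(unique(ns)) != 1L)
    stop("all ranked lists must cover the same database")
  topn <- as.integer(topn)
  if (topn < 1L) stop("topn must be >= 1")
  if (topn > ns[1L]) stop("topn (", topn, ") exceeds database size (", ns[1L], ")")
  base_ids <- sort(ranked_lists[[1L]]$ids)
  for (r in ranked_lists)
    if (!identical(sort(r$ids), base_ids))
      stop("ranked lists are over different databases")

  if (basis == "rank") {
    voters <- unique(unlist(lapply(ranked_lists,
                                   function(r) r$ids[seq_len(topn)])))
    P <- vapply(ranked_lists,
                function(r) unname(r$positions[voters]),
                numeric(length(voters)))
    P <- matrix(P, nrow = length(voters), ncol = m,
                dimnames = list(voters, measure_ids))
    pts <- t(apply(P, 1L, function(p) m + 1 - rank(p, ties.method = "average")))
  } else {
    if (is.null(raw_scores))
      stop("basis = \"value\" requires raw_scores")
    if (!identical(names(raw_scores), measure_ids))
      stop("raw_scores must be named like ranked_lists")
    vals <- vapply(measure_ids, function(id) {
      r <- ranked_lists[[id]]; s <- raw_scores[[id]]
      v <- unname(s$scores[r$ids[seq_len(topn)]])
      rng <- range(v)
      if (diff(rng) == 0) return(rep(0.5, topn))
      v <- (v - rng[1L]) / diff(rng)
      if (s$polarity == "distance") v <- 1 - v
      v
    }, numeric(topn))
    vals <- matrix(vals, nrow = topn, ncol = m,
                   dimnames = list(paste0("pos", seq_len(topn)), measure_ids))
    pts <- t(apply(vals, 1L, function(v) rank(v, ties.method = "average")))
  }
  if (m == 2L) pts <- matrix(pts, ncol = 2L,
                             dimnames = list(rownames(pts), measure_ids))
  voting_profile(pts, measure_ids, topn = topn, basis = basis)
}

#' Borda totals of a voting profile
#'
#' The total Borda score of each measure is the sum of the points it received
#' from all voters (the column sum of the profile).
#'
#' @param profile a `voting_profile`
#' @return named numeric vector of per-measure totals
#' @export
borda_totals <- function(profile) {
  stopifnot(inherits(profile, "voting_profile"))
  colSums(profile$points)
}

#' Pairwise-win matrix of a voting profile
#'
#' Entry `[i, j]` counts the voters that strictly prefer measure i over
#' measure j (award it strictly more points). For every pair,
#' `wins[i,j] + wins[j,i] + ties = V`.
#'
#' @param profile a `voting_profile`
#' @return m x m integer matrix with measure ids as dimnames
#' @export
pairwise_wins <- function(profile) {
  stopifnot(inherits(profile, "voting_profile"))
  p <- profile$points; m <- ncol(p)
  W <- matrix(0L, m, m, dimnames = list(profile$measure_ids,
                                        profile$measure_ids))
  for (i in seq_len(m))
    for (j in seq_len(m))
      if (i != j) W[i, j] <- sum(p[, i] > p[, j])
  W
}

condorcet_from_wins <- function(W) {
  m <- nrow(W)
  for (i in seq_len(m)) {
    beats <- vapply(seq_len(m)[-i], function(j) W[i, j] > W[j, i], logical(1))
    if (all(beats)) return(rownames(W)[i])
  }
  NA_character_
}

#' Condorcet winner of a voting profile
#'
#' The measure that strictly beats every other measure in pairwise
#' voter-majority contests. No such measure need exist (the Condorcet
#' paradox: cyclic majorities), in which case `NA` is returned.
#'
#' @param profile a `voting_profile`
#' @return measure id, or `NA_character_` when no Condorcet winner exists
#' @export
condorcet_winner <- function(profile) {
  condorcet_from_wins(pairwise_wins(profile))
}

#' Elect the winner measure of a voting profile
#'
#' The Condorcet winner when one exists; otherwise the Borda-count winner
#' (largest points total). A level Borda total is resolved by the order of
#' the profile's columns, which the pipeline keeps in the canonical
#' coefficient listing order.
#'
#' @param profile a `voting_profile`
#' @return a `fusion_result`: list with `borda_totals`, `pairwise_wins`,
#'   `condorcet_winner`, `borda_winner`, `winner`, `method_used`
#' @export
select_winner <- function(profile) {
  totals <- borda_totals(profile)
  W <- pairwise_wins(profile)
  cw <- condorcet_from_wins(W)
  bw <- profile$measure_ids[which.max(totals)]   # first max = column-order tie-break
  winner <- if (!is.na(cw)) cw else bw
  structure(list(borda_totals = totals, pairwise_wins = W,
                 condorcet_winner = cw, borda_winner = bw, winner = winner,
                 method_used = if (!is.na(cw)) "condorcet" else "borda_fallback"),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("fusion_result\n")
  cat("  winner:", x$winner, sprintf("(%s)\n", x$method_used))
  cat("  Borda totals:\n")
  print(x$borda_totals)
  invisible(x)
}

#' Worked voting-profile example
#'
#' A small 3-voter, 11-measure profile illustrating the election: measure S3
#' collects the highest Borda total (30 points) and also beats each of the
#' other ten measures in pairwise contests, so both routes elect S3.
#'
#' @return a `voting_profile` with measures S1..S11
#' @export
example_voting_profile <- function() {
  pts <- rbind(c(11, 9, 10, 1, 3, 7, 6, 4, 8, 2, 5),
               c(9, 8, 11, 4, 5, 3, 1, 2, 7, 6, 10),
               c(7, 3, 9, 1, 8, 4, 11, 6, 2, 5, 10))
  voting_profile(pts, paste0("S", 1:11), topn = 3L, basis = "direct")
}

#' Write / read a voting profile as CSV for audit
#'
#' Rows are voters, columns are measure ids, mirroring the worked-example
#' table layout.
#'
#' @param profile a `voting_profile`
#' @param path file path
#' @return `path` (write) or a `voting_profile` (read)
#' @export
write_voting_profile <- function(profile, path) {
  df <- data.frame(voter = rownames(profile$points) %||%
                     paste0("v", seq_len(nrow(profile$points))),
                   profile$points, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_voting_profile
#' @export
read_voting_profile <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(pts) <- df[[1L]]
  voting_profile(pts, colnames(pts), basis = "direct")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
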