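# The eleven similarity/distance coefficients over count fingerprints.
#
# All coefficients use the "continuous" (count) forms. Writing, for two
# count vectors a and b of common length M,
#   A = sum(a^2),  B = sum(b^2),  C = sum(a*b),
# the adopted forms are:
#
#   association (higher = more similar)
#     tanimoto        C / (A + B - C)
#     cosine          C / sqrt(A * B)
#     sokal_sneath1   C / (2A + 2B - 3C)          (= T/(2 - T), monotone in
#                                                  tanimoto: identical rankings)
#     kulczynski2     C (A + B) / (2 A B)
#     forbes          M C / (A B)
#     fossum          M (C - 1/2)^2 / (A B)
#     simpson         C / min(A, B)
#   distance (lower = more similar)
#     mean_euclidean  sqrt( sum((a-b)^2) / M )
#     mean_canberra   (1/M) sum |a-b| / (a+b)     (0/0 terms contribute 0)
#     divergence      (1/M) sum (a-b)^2 / (a+b)^2 (0/0 terms contribute 0)
#     bray_curtis     sum |a-b| / sum (a+b)
#
# The continuous Forbes/Fossum normalization constant (the factor M, the
# folded fingerprint length) varies across the literature; it is a positive
# constant per search, so it never changes a ranking. It is kept here as the
# single leading factor of each of those two forms.
#
# Zero-denominator feature terms in mean_canberra/divergence (both molecules
# lack the feature) contribute 0: the standard continuous-coefficient
# convention, and the one that keeps all values finite.

.COEFFICIENTS <- data.frame(
  id = c("tanimoto", "cosine", "sokal_sneath1", "kulczynski2", "forbes",
         "fossum", "simpson",
         "mean_euclidean", "mean_canberra", "divergence", "bray_curtis"),
  name = c("Jaccard/Tanimoto", "Ochiai/Cosine", "Sokal/Sneath(1)",
           "Kulczynski(2)", "Forbes", "Fossum", "Simpson",
           "Mean Euclidean", "Mean Canberra", "Divergence", "Bray/Curtis"),
  polarity = c(rep("similarity", 7L), rep("distance", 4L)),
  stringsAsFactors = FALSE
)

#' The eleven supported similarity coefficients
#'
#' Canonical ordering (index 1..11) follows the field's customary listing:
#' the seven association coefficients first, then the four distance
#' coefficients. This order is also the deterministic tie-break used when a
#' Borda election ends level.
#'
#' @return data frame with columns `id`, `name`, `polarity`
#' @export
coefficient_info <- function() .COEFFICIENTS

#' @rdname coefficient_info
#' @export
coefficient_ids <- function() .COEFFICIENTS$id

#' Polarity of a coefficient
#' @param id coefficient id
#' @return `"similarity"` (higher = better) or `"distance"` (lower = better)
#' @export
coefficient_polarity <- function(id) {
  i <- match(id, .COEFFICIENTS$id)
  if (anyNA(i)) stop("unsupported coefficient id: ", id[which(is.na(i))[1L]])
  .COEFFICIENTS$polarity[i]
}

check_count_vector <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric")
  if (any(!is.finite(x)) || any(x < 0)) stop(what, " must be non-negative and finite")
  if (sum(x) == 0) stop(what, " is a zero vector: coefficient undefined")
  invisible(x)
}

#' Coefficient value for one pair of count fingerprints
#'
#' @param ref,mol non-negative count vectors of equal length, each with at
#'   least one nonzero entry
#' @param coefficient coefficient id (see [coefficient_info()])
#' @return scalar coefficient value. All eleven forms are symmetric in
#'   `(ref, mol)`.
#' @examples
#' coefficient_value(c(1, 2, 0), c(2, 1, 0), "tanimoto")  # 4 / 6
#' coefficient_value(c(1, 2), c(2, 1), "cosine")          # 0.8
#' @export
coefficient_value <- function(ref, mol, coefficient) {
  coefficient <- match.arg(coefficient, .COEFFICIENTS$id)
  if (length(ref) != length(mol))
    stop("fingerprint length mismatch: ", length(ref), " vs ", length(mol))
  check_count_vector(ref, "ref")
  check_count_vector(mol, "mol")
  M <- length(ref)
  A <- sum(ref * ref); B <- sum(mol * mol); C <- sum(ref * mol)
  switch(coefficient,
    tanimoto      = C / (A + B - C),
    cosine        = C / sqrt(A * B),
    sokal_sneath1 = C / (2 * A + 2 * B - 3 * C),
    kulczynski2   = C * (A + B) / (2 * A * B),
    forbes        = M * C / (A * B),
    fossum        = M * (C - 0.5)^2 / (A * B),
    simpson       = C / min(A, B),
    mean_euclidean = sqrt(sum((ref - mol)^2) / M),
    mean_canberra = {
      s <- ref + mol
      sum(ifelse(s > 0, abs(ref - mol) / s, 0)) / M
    },
    divergence = {
      s <- (ref + mol)^2
      sum(ifelse(s > 0, (ref - mol)^2 / s, 0)) / M
    },
    bray_curtis   = sum(abs(ref - mol)) / sum(ref + mol)
  )
}

#' Score every database molecule against a single reference structure
#'
#' Vectorized equivalent of calling [coefficient_value()] for the reference
#' against each database row (the reference itself included; the screening
#' pipeline decides whether to exclude it).
#'
#' @param db a [fingerprint_matrix()]
#' @param ref_id molecule id of the reference structure; must be present in
#'   `db`
#' @param coefficient coefficient id
#' @return a `similarity_scores` object: list with `coefficient`, `polarity`,
#'   `reference_id` and a named numeric `scores` vector (one value per
#'   database molecule, in database row order)
#' @export
score_database <- function(db, ref_id, coefficient) {
  coefficient <- match.arg(coefficient, .COEFFICIENTS$id)
  idx <- match(ref_id, rownames(db))
  if (is.na(idx)) stop("unknown reference id: ", ref_id)
  X <- unclass(db)
  r <- X[idx, ]
  check_count_vector(r, "reference fingerprint")
  M <- ncol(X)
  A <- sum(r * r)
  Bv <- rowSums(X * X)
  Cv <- drop(X %*% r)
  scores <- switch(coefficient,
    tanimoto      = Cv / (A + Bv - Cv),
    cosine        = Cv / sqrt(A * Bv),
    sokal_sneath1 = Cv / (2 * A + 2 * Bv - 3 * Cv),
    kulczynski2   = Cv * (A + Bv) / (2 * A * Bv),
    forbes        = M * Cv / (A * Bv),
    fossum        = M * (Cv - 0.5)^2 / (A * Bv),
    simpson       = Cv / pmin(A, Bv),
    mean_euclidean = sqrt((A + Bv - 2 * Cv) / M),
    mean_canberra = {
      D <- abs(sweep(X, 2L, r, "-")); S <- sweep(X, 2L, r, "+")
      D[S <= 0] <- 0; S[S <= 0] <- 1
      rowSums(D / S) / M
    },
    divergence = {
      D <- sweep(X, 2L, r, "-")^2; S <- sweep(X, 2L, r, "+")^2
      D[S <= 0] <- 0; S[S <= 0] <- 1
      rowSums(D / S) / M
    },
    bray_curtis = rowSums(abs(sweep(X, 2L, r, "-"))) / (rowSums(X) + sum(r))
  )
  names(scores) <- rownames(db)
  structure(list(coefficient = coefficient,
                 polarity = coefficient_polarity(coefficient),
                 reference_id = ref_id, scores = scores),
            class = "similarity_scores")
}

#' @export
print.similarity_scores <- function(x, ...) {
  cat(sprintf("similarity_scores: %s (%s) vs reference '%s', %d molecules\n",
              x$coefficient, x$polarity, x$reference_id, length(x$scores)))
  invisible(x)
}

#' Rank a database from similarity scores
#'
#' Produces a total ordering of the scored molecules: descending score for
#' association coefficients, ascending for distance coefficients. Ties are
#' broken by ascending input (database row) index, making every ranking
#' deterministic. Reported rank positions are 1-based: position 1 is the most
#' similar structure.
#'
#' @param scores a `similarity_scores` object from [score_database()]
#' @return a `ranked_list`: list with `ids` (molecule ids, best first),
#'   `positions` (named integer vector, position by id), `coefficient`,
#'   `reference_id`
#' @export
rank_database <- function(scores) {
  stopifnot(inherits(scores, "similarity_scores"))
  s <- scores$scores
  if (any(is.na(s)) || any(!is.finite(s)))
    stop("non-finite similarity score; cannot rank")
  key <- if (scores$polarity == "similarity") -s else s
  ord <- order(key, seq_along(s))   # stable: ties fall back to input index
  positions <- integer(length(s)); positions[ord] <- seq_along(s)
  names(positions) <- names(s)
  structure(list(ids = names(s)[ord], positions = positions,
                 coefficient = scores$coefficient,
                 reference_id = scores$reference_id),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list (%s vs '%s'): %d molecules; top: %s\n",
              x$coefficient, x$reference_id, length(x$ids),
              paste(head(x$ids, 5L), collapse = " > ")))
  invisible(x)
}

# molecule ids in rank order, from a ranked_list or a plain character vector
ranked_ids <- function(ranking) {
  if (inherits(ranking, "ranked_list")) ranking$ids
  else if (is.character(ranking)) ranking
  else stop("ranking must be a ranked_list or a character vector of ids")
}
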