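# Evaluation statistics: recall at a percentage cutoff, enrichment factor,
# BEDROC, ROC AUC, class diversity, Kendall's W with tie correction, and
# Friedman's test over a classes x methods recall table.

#' Number of molecules retrieved at a percentage cutoff
#'
#' `ceiling(percent/100 * N)` with a floor of one molecule, so a cutoff set
#' is never empty.
#'
#' @param N database size
#' @param percent cutoff percentage in (0, 100]
#' @return integer retrieval count
#' @examples
#' cutoff_count(1030, 5)  # 52
#' @export
cutoff_count <- function(N, percent) {
  if (N < 1L) stop("N must be >= 1")
  if (percent <= 0 || percent > 100) stop("percent must lie in (0, 100]")
  # tiny epsilon guards against 0.1*3 style floating error at exact integers
  max(1L, as.integer(ceiling(percent * N / 100 - 1e-9)))
}

active_positions <- function(ranking, actives) {
  ids <- ranked_ids(ranking)
  if (length(actives) == 0L) stop("empty active set")
  pos <- match(actives, ids)
  if (anyNA(pos))
    stop("active id not present in ranking: ", actives[which(is.na(pos))[1L]])
  pos
}

#' Recall of actives in the top x% of a ranking
#'
#' @param ranking a `ranked_list` (or a character vector of ids, best first)
#' @param actives character vector of active molecule ids
#' @param percent cutoff percentage (default 5)
#' @return recall as a percentage in \[0, 100\]
#' @export
recall_at_percent <- function(ranking, actives, percent = 5) {
  pos <- active_positions(ranking, actives)
  n <- cutoff_count(length(ranked_ids(ranking)), percent)
  100 * sum(pos <= n) / length(actives)
}

#' Enrichment factor at a percentage cutoff
#'
#' The active rate inside the cutoff set divided by the database-wide active
#' rate: `(a / n_cut) / (A / N)`. 1 is the random expectation; the maximum is
#' `N / A` capped by `n_cut`.
#'
#' @inheritParams recall_at_percent
#' @param percent cutoff percentage (default 1)
#' @return enrichment factor (>= 0)
#' @export
enrichment_factor <- function(ranking, actives, percent = 1) {
  pos <- active_positions(ranking, actives)
  N <- length(ranked_ids(ranking))
  n <- cutoff_count(N, percent)
  (sum(pos <= n) / n) / (length(actives) / N)
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC: exponentially early-weighted
#' enrichment, computed from the rank-independent enrichment (RIE)
#' \deqn{RIE = \frac{\frac{1}{A}\sum_i e^{-\alpha r_i / N}}
#'                  {\frac{1}{N}\,\frac{1 - e^{-\alpha}}{e^{\alpha/N} - 1}}}
#' and mapped onto \[0, 1\]:
#' \deqn{BEDROC = RIE \cdot \frac{R_a \sinh(\alpha/2)}
#'   {\cosh(\alpha/2) - \cosh(\alpha/2 - \alpha R_a)}
#'   + \frac{1}{1 - e^{\alpha (1 - R_a)}}}
#' with \eqn{R_a = A/N}. Large `alpha` concentrates the weight on the very
#' top of the ranking; `alpha = 20` puts roughly 80% of it in the first 8%.
#'
#' @inheritParams recall_at_percent
#' @param alpha early-recognition parameter (> 0), default 20
#' @return BEDROC value in \[0, 1\]
#' @export
bedroc <- function(ranking, actives, alpha = 20) {
  if (alpha <= 0) stop("alpha must be positive")
  pos <- active_positions(ranking, actives)
  N <- length(ranked_ids(ranking)); A <- length(actives)
  if (A >= N) stop("BEDROC needs at least one inactive (A < N)")
  Ra <- A / N
  rie <- (sum(exp(-alpha * pos / N)) / A) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' ROC AUC of a ranking
#'
#' Rank-sum (Mann-Whitney) area under the ROC curve: the probability that a
#' randomly chosen active is ranked above a randomly chosen inactive. The
#' rankings produced here are total orders (deterministic tie-breaks), so no
#' midranks arise; the rank-sum form handles them implicitly if a caller
#' supplies a pre-tied order.
#'
#' @inheritParams recall_at_percent
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(ranking, actives) {
  pos <- active_positions(ranking, actives)
  N <- length(ranked_ids(ranking)); A <- length(actives)
  if (A >= N) stop("AUC needs both actives and inactives present")
  (sum(N + 1 - pos) - A * (A + 1) / 2) / (A * (N - A))
}

#' Mean pairwise Tanimoto similarity of a set of fingerprints
#'
#' The structural-diversity statistic for an activity class: the continuous
#' Tanimoto coefficient averaged over all unordered distinct pairs of
#' molecules. Values near 1 mean a homogeneous (low-diversity) class.
#'
#' @param class_fps a [fingerprint_matrix()] with at least 2 molecules
#' @return mean pairwise Tanimoto in \[0, 1\]
#' @export
mean_pairwise_similarity <- function(class_fps) {
  X <- unclass(as.matrix(class_fps))
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 molecules to measure diversity")
  C <- tcrossprod(X)
  a <- diag(C)
  TT <- C / (outer(a, a, "+") - C)
  mean(TT[upper.tri(TT)])
}

#' Rank a recall table within judges
#'
#' Converts a judges x objects matrix of raw values (e.g. activity classes x
#' search methods recall) to within-judge ranks, higher value = higher rank,
#' tied values sharing the average of the ranks they span.
#'
#' @param values numeric judges x objects matrix
#' @return matrix of the same shape containing ranks
#' @export
rank_recalls <- function(values) {
  values <- as.matrix(values)
  t(apply(values, 1L, rank, ties.method = "average"))
}

# per-judge tie correction: Tj = sum over tie groups of (t^3 - t)
tie_correction <- function(ranks_row) {
  t_i <- table(ranks_row)
  sum(t_i^3 - t_i)
}

#' Kendall's coefficient of concordance (W) with tie correction
#'
#' Agreement among k judges each ranking the same n objects:
#' \deqn{W = \frac{12 S}{k^2 (n^3 - n) - k \sum_j T_j}}
#' where S is the sum of squared deviations of the object rank sums from
#' their mean and \eqn{T_j = \sum_i (t_i^3 - t_i)} is judge j's correction
#' for tie groups of sizes \eqn{t_i}. W = 1 means perfect concordance. The
#' significance level comes from the chi-square approximation
#' \eqn{\chi^2 = k (n - 1) W} on n - 1 degrees of freedom.
#'
#' @param ranks judges x objects matrix of ranks (rows as produced by
#'   [rank_recalls()]: each row ranks 1..n with average-shared ties)
#' @return list with `W`, `chisq`, `df`, `p`, `k`, `n`
#' @export
kendall_w <- function(ranks) {
  ranks <- as.matrix(ranks)
  k <- nrow(ranks); n <- ncol(ranks)
  if (k < 2L || n < 2L) stop("need at least 2 judges and 2 objects")
  expected <- n * (n + 1) / 2
  if (any(abs(rowSums(ranks) - expected) > 1e-8))
    stop("each judge's row must be a (tie-averaged) ranking of 1..n")
  Rj <- colSums(ranks)
  S <- sum((Rj - mean(Rj))^2)
  Tsum <- sum(apply(ranks, 1L, tie_correction))
  denom <- k^2 * (n^3 - n) - k * Tsum
  if (denom <= 0) stop("all objects tied for every judge: W undefined")
  W <- 12 * S / denom
  chisq <- k * (n - 1) * W
  p <- stats::pchisq(chisq, df = n - 1, lower.tail = FALSE)
  list(W = W, chisq = chisq, df = n - 1L, p = p, k = k, n = n)
}

#' Friedman's test over a judges x methods recall table
#'
#' Within-judge ranks are assigned from the raw values (higher value = higher
#' rank, ties averaged); the chi-square statistic is computed through its
#' identity with Kendall's W, \eqn{\chi^2_F = k (n - 1) W}, so the two tests
#' are mutually consistent including the tie correction. An exact
#' (Monte-Carlo permutation) p-value is available for small tables.
#'
#' @param recalls numeric judges x methods matrix of raw values
#' @param exact if `TRUE`, estimate the p-value by permuting method labels
#'   within each judge instead of the chi-square approximation
#' @param n_perm number of permutations for `exact = TRUE`
#' @param seed seed for the permutation draw
#' @return list with `p`, `chisq`, `df`, `mean_ranks` (named, higher = better
#'   method), `W`, `method` (`"chisq"` or `"permutation"`)
#' @export
friedman_test <- function(recalls, exact = FALSE, n_perm = 2000L, seed = 1L) {
  recalls <- as.matrix(recalls)
  if (is.null(colnames(recalls)))
    colnames(recalls) <- paste0("method", seq_len(ncol(recalls)))
  ranks <- rank_recalls(recalls)
  kw <- kendall_w(ranks)
  mean_ranks <- colMeans(ranks)
  p <- kw$p; method <- "chisq"
  if (isTRUE(exact)) {
    obs <- kw$chisq
    stat_of <- function(rk) {
      Rj <- colSums(rk)
      S <- sum((Rj - mean(Rj))^2)
      Tsum <- sum(apply(rk, 1L, tie_correction))
      den <- nrow(rk)^2 * (ncol(rk)^3 - ncol(rk)) - nrow(rk) * Tsum
      if (den <= 0) return(0)
      nrow(rk) * (ncol(rk) - 1) * 12 * S / den
    }
    exceed <- withr::with_seed(seed, {
      sum(replicate(n_perm, {
        perm <- t(apply(ranks, 1L, sample))
        stat_of(perm) >= obs - 1e-12
      }))
    })
    p <- (1 + exceed) / (n_perm + 1)
    method <- "permutation"
  }
  list(p = p, chisq = kw$chisq, df = kw$df, mean_ranks = mean_ranks,
       W = kw$W, method = method)
}

#' Format a method ranking string from mean ranks
#'
#' @param mean_ranks named numeric vector (higher = better)
#' @return single string like `"Top100 > Top50 > Top20 > Top10 > TAN"`
#' @export
method_ranking_string <- function(mean_ranks) {
  paste(names(sort(mean_ranks, decreasing = TRUE)), collapse = " > ")
}
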