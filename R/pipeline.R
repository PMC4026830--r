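# End-to-end per-class screening: single-reference searches under every
# configured coefficient, voting-profile construction, winner election per
# activity class, re-search with the winner, and metric evaluation.
#
# Conventions (standard LBVS practice; configurable nowhere on purpose):
#   * the reference structure is excluded from its own ranking and from the
#     active count when recall is computed;
#   * per-class aggregation sums Borda totals and pairwise-win matrices over
#     all reference searches of the class before electing one class winner
#     (per_reference = TRUE elects per reference instead and reports the
#     modal winner);
#   * class metrics are arithmetic means over the class's reference searches.

#' Search one reference with every configured coefficient and build its
#' voting profile
#'
#' The reference structure is removed from the database before scoring, so it
#' can never vote for, or be retrieved by, its own search.
#'
#' @param ref_id reference molecule id
#' @param db a [fingerprint_matrix()] containing `ref_id`
#' @param config a [run_config()]
#' @return a `voting_profile` over `config$coefficients`
#' @export
screen_reference <- function(ref_id, db, config) {
  res <- reference_search(ref_id, db, config$coefficients)
  if (config$topn > length(res$rankings[[1L]]$ids))
    stop("topn (", config$topn, ") must be smaller than the database size")
  build_voting_profile(res$rankings, topn = config$topn,
                       basis = config$voting_basis, raw_scores = res$scores)
}

# score + rank the database (minus the reference) under each coefficient
reference_search <- function(ref_id, db, coefficients) {
  if (!ref_id %in% rownames(db)) stop("unknown reference id: ", ref_id)
  keep <- setdiff(rownames(db), ref_id)
  # score the full database against the reference, then drop the reference's
  # own row before ranking: it never appears in its own retrieval list
  scores <- lapply(coefficients, function(cf) {
    full <- score_database(db, ref_id, cf)
    full$scores <- full$scores[keep]
    full
  })
  names(scores) <- coefficients
  rankings <- lapply(scores, rank_database)
  list(scores = scores, rankings = rankings)
}

#' Screen one activity class and elect its winner coefficient
#'
#' Runs a single-reference search for every member of the class (each member
#' in turn is the reference; the remaining members are the actives sought),
#' pools the election evidence over references, elects the class winner, then
#' re-runs every reference search with the winner alone and evaluates it.
#'
#' @param class_label activity-class label in `activities`
#' @param db a [fingerprint_matrix()]
#' @param activities an [activity_table()] cross-valid against `db`
#' @param config a [run_config()]
#' @param per_reference if `TRUE`, elect a winner per reference search and
#'   use the modal winner (first-in-canonical-order on ties) as the class
#'   winner instead of pooling votes
#' @param keep_profiles if `TRUE`, retain the per-reference voting profiles
#'   in the result (memory grows with class size)
#' @return a `class_screen_result`: list with `class_label`, `winner`,
#'   `method_used`, `borda_totals`, `recall_at_cutoff`, `ef`, `bedroc`,
#'   `auc`, `tan_recall` (single-coefficient Tanimoto baseline recall),
#'   `per_reference` (data frame of per-reference metrics), and optionally
#'   `profiles`
#' @export
screen_class <- function(class_label, db, activities, config,
                         per_reference = FALSE, keep_profiles = FALSE) {
  validate_activities(activities, db, min_class_size = 2L)
  members <- class_members(activities, class_label)
  m <- length(config$coefficients)
  totals <- stats::setNames(numeric(m), config$coefficients)
  wins <- matrix(0L, m, m, dimnames = list(config$coefficients,
                                           config$coefficients))
  per_ref_winner <- character(length(members))
  profiles <- if (keep_profiles) vector("list", length(members)) else NULL

  searches <- vector("list", length(members))
  names(searches) <- members
  for (i in seq_along(members)) {
    ref <- members[i]
    res <- reference_search(ref, db, config$coefficients)
    searches[[i]] <- res
    if (config$topn > length(res$rankings[[1L]]$ids))
      stop("topn (", config$topn, ") must be smaller than the database size")
    if (m >= 2L) {
      prof <- build_voting_profile(res$rankings, topn = config$topn,
                                   basis = config$voting_basis,
                                   raw_scores = res$scores)
      totals <- totals + borda_totals(prof)
      wins <- wins + pairwise_wins(prof)
      per_ref_winner[i] <- select_winner(prof)$winner
      if (keep_profiles) profiles[[i]] <- prof
    } else {
      per_ref_winner[i] <- config$coefficients
    }
  }

  if (m == 1L) {
    winner <- config$coefficients; method <- "degenerate"
  } else if (per_reference) {
    tab <- table(factor(per_ref_winner, levels = config$coefficients))
    winner <- names(tab)[which.max(tab)]
    method <- "per_reference_mode"
  } else {
    cw <- condorcet_from_wins(wins)
    if (!is.na(cw)) {
      winner <- cw; method <- "condorcet"
    } else {
      winner <- config$coefficients[which.max(totals)]
      method <- "borda_fallback"
    }
  }

  metric_one <- function(ranking, actives) {
    c(recall = recall_at_percent(ranking, actives, config$cutoff_percent),
      ef = enrichment_factor(ranking, actives, config$ef_percent),
      bedroc = bedroc(ranking, actives, config$bedroc_alpha),
      auc = roc_auc(ranking, actives))
  }
  rows <- lapply(seq_along(members), function(i) {
    ref <- members[i]
    actives <- setdiff(members, ref)
    res <- searches[[i]]
    fin <- if (winner %in% names(res$rankings)) res$rankings[[winner]]
           else rank_database(score_database(db, ref, winner))
    met <- metric_one(fin, actives)
    tan <- if ("tanimoto" %in% names(res$rankings)) res$rankings[["tanimoto"]]
           else {
             s <- score_database(db, ref, "tanimoto")
             s$scores <- s$scores[setdiff(rownames(db), ref)]
             rank_database(s)
           }
    c(met, tan_recall = recall_at_percent(tan, actives, config$cutoff_percent))
  })
  per_ref <- as.data.frame(do.call(rbind, rows))
  per_ref$reference <- members

  out <- list(class_label = class_label, winner = winner,
              method_used = method, borda_totals = totals,
              pairwise_wins = wins,
              per_reference_winners = per_ref_winner,
              recall_at_cutoff = mean(per_ref$recall),
              ef = mean(per_ref$ef), bedroc = mean(per_ref$bedroc),
              auc = mean(per_ref$auc), tan_recall = mean(per_ref$tan_recall),
              per_reference = per_ref)
  if (keep_profiles) out$profiles <- profiles
  class(out) <- "class_screen_result"
  out
}

#' @export
print.class_screen_result <- function(x, ...) {
  cat(sprintf("class '%s': winner %s (%s)\n", x$class_label, x$winner,
              x$method_used))
  cat(sprintf("  recall@cutoff %.2f%%  EF %.2f  BEDROC %.3f  AUC %.3f  (TAN recall %.2f%%)\n",
              x$recall_at_cutoff, x$ef, x$bedroc, x$auc, x$tan_recall))
  invisible(x)
}

#' Screen every activity class of a dataset
#'
#' @inheritParams screen_class
#' @return a `screen_report` data frame, one row per class: `class`,
#'   `n_actives`, `diversity` (mean pairwise Tanimoto within the class),
#'   `winner`, `method`, `recall_fused`, `recall_tan`, `ef`, `bedroc`, `auc`
#' @export
screen_dataset <- function(db, activities, config, per_reference = FALSE) {
  labels <- unique(activities$class)
  rows <- lapply(labels, function(lb) {
    members <- class_members(activities, lb)
    cls <- unclass(db)[members, , drop = FALSE]
    res <- screen_class(lb, db, activities, config,
                        per_reference = per_reference)
    data.frame(class = lb, n_actives = length(members),
               diversity = mean_pairwise_similarity(cls),
               winner = res$winner, method = res$method_used,
               recall_fused = res$recall_at_cutoff,
               recall_tan = res$tan_recall,
               ef = res$ef, bedroc = res$bedroc, auc = res$auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Mean recall of a single coefficient over a class's reference searches
#'
#' The no-fusion baseline: search each class member as reference with one
#' fixed coefficient and average recall at the cutoff.
#'
#' @inheritParams screen_class
#' @param coefficient one coefficient id
#' @return mean recall percentage
#' @export
single_coefficient_recall <- function(class_label, db, activities,
                                      coefficient, cutoff_percent = 5) {
  members <- class_members(activities, class_label)
  mean(vapply(members, function(ref) {
    res <- reference_search(ref, db, coefficient)
    recall_at_percent(res$rankings[[1L]], setdiff(members, ref),
                      cutoff_percent)
  }, numeric(1)))
}

#' Compare the Tanimoto baseline with fused winners at several committee sizes
#'
#' Builds the classes x methods recall table (columns `TAN`, `Top<n>` for each
#' requested committee size), then runs the concordance analyses over it:
#' activity classes are the judges, search methods the objects.
#'
#' @inheritParams screen_class
#' @param topns integer vector of committee sizes (default `c(10, 20, 50, 100)`)
#' @return list with `recalls` (classes x methods matrix), `kendall`
#'   (from [kendall_w()]), `friedman` (from [friedman_test()]), and
#'   `ranking` (string like `"Top100 > ... > TAN"`)
#' @export
run_benchmark <- function(db, activities, topns = c(10L, 20L, 50L, 100L),
                          config = run_config()) {
  labels <- unique(activities$class)
  tan <- vapply(labels, function(lb)
    single_coefficient_recall(lb, db, activities, "tanimoto",
                              config$cutoff_percent), numeric(1))
  fused <- vapply(topns, function(tn) {
    cfg <- config; cfg$topn <- as.integer(tn)
    vapply(labels, function(lb)
      screen_class(lb, db, activities, cfg)$recall_at_cutoff, numeric(1))
  }, numeric(length(labels)))
  recalls <- cbind(TAN = tan, matrix(fused, ncol = length(topns),
                                     dimnames = list(labels,
                                                     paste0("Top", topns))))
  kw <- kendall_w(rank_recalls(recalls))
  fr <- friedman_test(recalls)
  list(recalls = recalls, kendall = kw, friedman = fr,
       ranking = method_ranking_string(fr$mean_ranks))
}
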