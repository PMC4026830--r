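test_that("cutoff counts use ceiling with a floor of one", {
  expect_equal(cutoff_count(100, 5), 5L)
  expect_equal(cutoff_count(1030, 5), 52L)   # ceil(51.5)
  expect_equal(cutoff_count(10, 5), 1L)      # floor would give 0
  expect_error(cutoff_count(100, 0), "0, 100")
  expect_error(cutoff_count(0, 5), ">= 1")
})

test_that("recall at a percentage cutoff counts actives inside the cutoff", {
  rw <- ranking_with_actives(1000, 1:10)
  expect_equal(recall_at_percent(rw$ranking, rw$actives, 5), 100)
  rw2 <- ranking_with_actives(1000, 991:1000)
  expect_equal(recall_at_percent(rw2$ranking, rw2$actives, 5), 0)
  rw3 <- ranking_with_actives(100, c(1, 2, 3, 5, 11:16))   # 4 of 10 in top 5
  expect_equal(recall_at_percent(rw3$ranking, rw3$actives, 5), 40)
  expect_error(recall_at_percent(rw$ranking, character(0)), "empty")
  expect_error(recall_at_percent(rw$ranking, "nope"), "not present")
})

test_that("enrichment factor reproduces its closed form", {
  # 5 of 10 actives inside the 1% cutoff of N=1000: (5/10)/(10/1000) = 50
  rw <- ranking_with_actives(1000, c(1:5, 501:505))
  expect_equal(enrichment_factor(rw$ranking, rw$actives, 1), 50)
  # all actives ranked last -> 0
  rw2 <- ranking_with_actives(1000, 991:1000)
  expect_equal(enrichment_factor(rw2$ranking, rw2$actives, 1), 0)
})

test_that("enrichment of uniformly spread actives is near the null value 1", {
  set.seed(31)
  A <- 100; N <- 2000
  efs <- replicate(100, {
    rw <- ranking_with_actives(N, sort(sample.int(N, A)))
    enrichment_factor(rw$ranking, rw$actives, 1)
  })
  expect_lt(abs(mean(efs) - 1), 3 / sqrt(A))
})

test_that("BEDROC saturates at its limits and matches the oracle transcription", {
  rw <- ranking_with_actives(5000, 1:10)
  expect_lt(abs(bedroc(rw$ranking, rw$actives, 20) - 1), 1e-3)
  rw2 <- ranking_with_actives(5000, 4991:5000)
  expect_lt(abs(bedroc(rw2$ranking, rw2$actives, 20) - 0), 1e-3)
  # fixed small rankings against the independent transcription
  cases <- list(list(N = 100, pos = 1:5), list(N = 100, pos = c(2, 30, 77)),
                list(N = 250, pos = c(1, 9, 40, 200, 250)),
                list(N = 50, pos = seq(5, 50, by = 5)))
  for (cs in cases) {
    rw <- ranking_with_actives(cs$N, cs$pos)
    for (alpha in c(5, 20, 80.5)) {
      expect_equal(bedroc(rw$ranking, rw$actives, alpha),
                   bedroc_oracle(cs$pos, cs$N, alpha), tolerance = 1e-12)
    }
  }
  expect_error(bedroc(c("a", "b"), c("a", "b")), "inactive")
})

test_that("BEDROC is monotone when an active moves up the ranking", {
  rw <- ranking_with_actives(200, c(20, 90, 150))
  b0 <- bedroc(rw$ranking, rw$actives, 20)
  for (newpos in c(120, 60, 10, 1)) {
    rw2 <- ranking_with_actives(200, sort(c(20, 90, newpos)))
    b1 <- bedroc(rw2$ranking, rw2$actives, 20)
    expect_gte(b1, b0 - 1e-12)
    b0 <- b1
  }
})

test_that("ROC AUC equals the pair-counting oracle", {
  rw <- ranking_with_actives(10, 1:4)
  expect_equal(roc_auc(rw$ranking, rw$actives), 1)
  rw2 <- ranking_with_actives(10, 7:10)
  expect_equal(roc_auc(rw2$ranking, rw2$actives), 0)
  rw3 <- ranking_with_actives(4, c(1, 3))   # active, decoy, active, decoy
  expect_equal(roc_auc(rw3$ranking, rw3$actives), 0.75)
  # exhaustive small instances
  for (N in 2:8) {
    subsets <- lapply(seq_len(2^N - 2), function(code)
      which(bitwAnd(code, 2^(seq_len(N) - 1)) > 0))
    for (pos in subsets) {
      if (length(pos) == 0 || length(pos) == N) next
      rw <- ranking_with_actives(N, pos)
      expect_equal(roc_auc(rw$ranking, rw$actives), auc_pairs(pos, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("class diversity is the mean pairwise continuous Tanimoto", {
  expect_equal(mean_pairwise_similarity(fp(c(1, 2, 0), c(1, 2, 0))), 1)
  expect_equal(mean_pairwise_similarity(fp(c(1, 2, 0), c(2, 1, 0))), 4 / 6)
  m3 <- fp(c(1, 2, 0), c(2, 1, 0), c(0, 1, 3))
  pairs <- combn(3, 2)
  want <- mean(apply(pairs, 2, function(ij)
    coefficient_value(unclass(m3)[ij[1], ], unclass(m3)[ij[2], ], "tanimoto")))
  expect_equal(mean_pairwise_similarity(m3), want, tolerance = 1e-12)
  expect_error(mean_pairwise_similarity(fp(c(1, 1))), "at least 2")
})

test_that("Kendall W spans perfect concordance to perfect discordance", {
  same <- rbind(1:4, 1:4, 1:4)
  expect_equal(kendall_w(same)$W, 1)
  rev2 <- rbind(1:4, 4:1)
  expect_equal(kendall_w(rev2)$W, 0)
  # k=3 judges, n=3 objects: direct formula, no ties (sum Tj = 0)
  ranks <- rbind(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3))
  kw <- kendall_w(ranks)
  Rj <- colSums(ranks); S <- sum((Rj - mean(Rj))^2)
  expect_equal(kw$W, 12 * S / (9 * (27 - 3)))
  expect_equal(kw$W, 7 / 9, tolerance = 1e-12)
  expect_equal(kw$chisq, 3 * 2 * kw$W)
  expect_error(kendall_w(rbind(c(1.5, 1.5), c(1.5, 1.5))), "tied")
  expect_error(kendall_w(rbind(c(1, 3), c(1, 2))), "ranking")
})

test_that("tie correction matches the printed Tj = sum(t^3 - t) form", {
  # one judge has a tie group of 2: Tj = 2^3 - 2 = 6
  vals <- rbind(c(10, 10, 5, 1), c(9, 7, 5, 1), c(8, 6, 4, 2))
  ranks <- rank_recalls(vals)
  expect_equal(unname(ranks[1, ]), c(3.5, 3.5, 2, 1))
  kw <- kendall_w(ranks)
  Rj <- colSums(ranks); S <- sum((Rj - mean(Rj))^2)
  k <- 3; n <- 4
  expect_equal(kw$W, 12 * S / (k^2 * (n^3 - n) - k * 6), tolerance = 1e-12)
  # and a tie-free table gives the uncorrected value
  vals2 <- rbind(c(4, 3, 2, 1), c(3, 4, 1, 2))
  kw2 <- kendall_w(rank_recalls(vals2))
  Rj2 <- colSums(rank_recalls(vals2)); S2 <- sum((Rj2 - mean(Rj2))^2)
  expect_equal(kw2$W, 12 * S2 / (4 * (64 - 4)))
})

test_that("Friedman test agrees with the stats reference implementation", {
  set.seed(13)
  for (i in 1:10) {
    m <- matrix(stats::rnorm(6 * 5), 6, 5)   # continuous -> tie-free
    ft <- stats::friedman.test(m)
    mine <- friedman_test(m)
    expect_equal(mine$chisq, unname(ft$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ft$p.value, tolerance = 1e-10)
  }
})

test_that("a uniformly best method earns the top mean rank significantly", {
  set.seed(3)
  base <- matrix(stats::runif(20), 10, 2)
  best <- apply(base, 1, max) + 1
  recalls <- cbind(A = base[, 1], B = best, C = base[, 2])
  fr <- friedman_test(recalls)
  expect_equal(unname(fr$mean_ranks["B"]), 3)
  expect_lt(fr$p, 0.05)
  expect_match(method_ranking_string(fr$mean_ranks), "^B > ")
})

test_that("Friedman mean ranks are equivariant under column permutation", {
  set.seed(17)
  recalls <- matrix(stats::runif(24), 6, 4,
                    dimnames = list(NULL, c("w", "x", "y", "z")))
  fr <- friedman_test(recalls)
  perm <- c(3, 1, 4, 2)
  fr2 <- friedman_test(recalls[, perm])
  expect_equal(fr2$mean_ranks, fr$mean_ranks[perm])
  expect_equal(fr2$p, fr$p)
  # duplicated methods share a mean rank
  dup <- cbind(recalls, w2 = recalls[, "w"])
  fr3 <- friedman_test(dup)
  expect_equal(unname(fr3$mean_ranks["w"]), unname(fr3$mean_ranks["w2"]))
})

test_that("the permutation p-value tracks the chi-square approximation", {
  set.seed(29)
  base <- matrix(stats::runif(18), 6, 3)
  base[, 2] <- base[, 2] + 0.8   # a clearly better method
  fr_chi <- friedman_test(base)
  fr_perm <- friedman_test(base, exact = TRUE, n_perm = 400, seed = 99)
  expect_equal(fr_perm$method, "permutation")
  expect_gt(fr_perm$p, 0); expect_lt(fr_perm$p, 1)
  expect_lt(abs(fr_perm$p - fr_chi$p), 0.1)
  # seeded: reproducible
  fr_perm2 <- friedman_test(base, exact = TRUE, n_perm = 400, seed = 99)
  expect_equal(fr_perm$p, fr_perm2$p)
})

test_that("recall/EF are unaffected by reshuffling below the cutoff", {
  set.seed(41)
  rw <- ranking_with_actives(200, c(2, 5, 9, 120, 180))
  cut <- cutoff_count(200, 5)
  below <- rw$ranking[(cut + 1):200]
  shuffled <- c(rw$ranking[1:cut], sample(below))
  expect_equal(recall_at_percent(shuffled, rw$actives, 5),
               recall_at_percent(rw$ranking, rw$actives, 5))
  cut1 <- cutoff_count(200, 1)
  shuffled1 <- c(rw$ranking[1:cut1], sample(rw$ranking[(cut1 + 1):200]))
  expect_equal(enrichment_factor(shuffled1, rw$actives, 1),
               enrichment_factor(rw$ranking, rw$actives, 1))
})
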