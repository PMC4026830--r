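test_that("class generation is deterministic under a fixed seed", {
  sp <- class_spec("A", 10, 0.6, seed = 77)
  m1 <- generate_class(sp, M = 256)
  m2 <- generate_class(sp, M = 256)
  expect_identical(unclass(m1), unclass(m2))
  m3 <- generate_class(class_spec("A", 10, 0.6, seed = 78), M = 256)
  expect_false(identical(unclass(m1), unclass(m3)))
  expect_equal(dim(m3), dim(m1))
})

test_that("a diversity target of 1 yields identical members", {
  m <- generate_class(class_spec("A", 8, 1.0, seed = 5), M = 128)
  expect_equal(mean_pairwise_similarity(m), 1)
  expect_true(all(apply(unclass(m), 2, function(col) length(unique(col)) == 1)))
})

test_that("bisection hits the target diversity", {
  m <- generate_class(class_spec("A", 50, 0.6, seed = 123), M = 1024)
  d <- mean_pairwise_similarity(m)
  expect_gte(d, 0.55); expect_lte(d, 0.65)
  m2 <- generate_class(class_spec("B", 30, 0.35, seed = 9), M = 1024)
  expect_lt(abs(mean_pairwise_similarity(m2) - 0.35), 0.05)
})

test_that("unreachable diversity targets raise an error", {
  # independent members at density 0.3 on a short fingerprint still share
  # substantial overlap, so 0.02 cannot be reached
  expect_error(generate_class(class_spec("A", 10, 0.02,
                                         feature_density = 0.3, seed = 1),
                              M = 64),
               "unreachable")
})

test_that("datasets concatenate classes with an unlabeled background", {
  spec <- dataset_spec(list(class_spec("A", 10, 0.7),
                            class_spec("B", 10, 0.5)),
                       n_background = 100, M = 256, seed = 42)
  ds <- generate_dataset(spec)
  expect_equal(n_molecules(ds$fingerprints), 120L)
  expect_equal(unname(class_sizes(ds$activities)), c(10L, 10L))
  expect_true(all(ds$activities$id %in% rownames(ds$fingerprints)))
  expect_equal(sum(grepl("^bg_", rownames(ds$fingerprints))), 100L)
  # same master seed -> identical dataset; different -> different counts
  ds2 <- generate_dataset(spec)
  expect_identical(unclass(ds$fingerprints), unclass(ds2$fingerprints))
  spec3 <- dataset_spec(list(class_spec("A", 10, 0.7),
                             class_spec("B", 10, 0.5)),
                        n_background = 100, M = 256, seed = 43)
  ds3 <- generate_dataset(spec3)
  expect_false(identical(unclass(ds$fingerprints), unclass(ds3$fingerprints)))
  expect_equal(dim(ds3$fingerprints), dim(ds$fingerprints))
})

test_that("classes are internally more similar than they are to background", {
  spec <- dataset_spec(list(class_spec("A", 12, 0.6)), n_background = 60,
                       M = 512, seed = 7)
  ds <- generate_dataset(spec)
  X <- unclass(ds$fingerprints)
  cls <- X[grepl("^A_", rownames(X)), ]
  bg <- X[grepl("^bg_", rownames(X)), ]
  internal <- mean_pairwise_similarity(fingerprint_matrix(cls))
  cross <- mean(sapply(seq_len(nrow(cls)), function(i)
    sapply(seq_len(nrow(bg)), function(j)
      coefficient_value(cls[i, ], bg[j, ], "tanimoto"))))
  expect_gt(internal, cross)
})

test_that("scaled-geometry classes spread count magnitudes and hit the target", {
  sp <- class_spec("s", 15, 0.5, geometry = "scaled", seed = 8)
  m <- generate_class(sp, M = 512)
  expect_lt(abs(mean_pairwise_similarity(m) - 0.5), 0.05)
  magnitudes <- rowSums(unclass(m))
  expect_gt(max(magnitudes) / min(magnitudes), 2)   # genuine magnitude series
  # direction is preserved: cosine to the class centroid stays high
  cen <- colMeans(unclass(m))
  cosines <- apply(unclass(m), 1, function(x) coefficient_value(x, cen, "cosine"))
  expect_gt(min(cosines), 0.7)
  expect_error(generate_class(class_spec("s", 10, 0.9, geometry = "scaled")),
               "unreachable")
})

test_that("related background molecules are harder decoys than random ones", {
  base <- list(class_spec("A", 12, 0.7, seed = 2))
  easy <- generate_dataset(dataset_spec(base, n_background = 200, M = 512,
                                        background_related_frac = 0, seed = 6))
  hard <- generate_dataset(dataset_spec(base, n_background = 200, M = 512,
                                        background_related_frac = 1, seed = 6))
  r_easy <- single_coefficient_recall("A", easy$fingerprints, easy$activities,
                                      "tanimoto", 5)
  r_hard <- single_coefficient_recall("A", hard$fingerprints, hard$activities,
                                      "tanimoto", 5)
  expect_lte(r_hard, r_easy)
  # related decoys sit closer to the class than independent background
  Xe <- unclass(easy$fingerprints); Xh <- unclass(hard$fingerprints)
  ref <- Xh["A_001", ]
  sim_to <- function(X) mean(apply(X[grepl("^bg_", rownames(X)), ], 1,
                                   function(x) coefficient_value(ref, x,
                                                                 "tanimoto")))
  expect_gt(sim_to(Xh), sim_to(Xe))
  expect_error(dataset_spec(base, 10, background_related_frac = 2), "0, 1")
})

test_that("planted-winner construction is seeded and rejects infeasible ids", {
  spec <- dataset_spec(list(class_spec("act", 8, 0.7)), n_background = 50,
                       M = 256, seed = 31)
  p1 <- generate_planted_winner(spec, "tanimoto")
  p2 <- generate_planted_winner(spec, "tanimoto")
  expect_identical(unclass(p1$fingerprints), unclass(p2$fingerprints))
  expect_equal(unname(class_sizes(p1$activities)), 8L)
  expect_error(generate_planted_winner(spec, "sokal_sneath1"),
               "ranks identically")
  expect_error(generate_planted_winner(spec, "cosine"), "infeasible")
})

test_that("the planted coefficient out-retrieves every other coefficient", {
  spec <- dataset_spec(list(class_spec("act", 12, 0.7)), n_background = 120,
                       M = 512, seed = 11)
  pl <- generate_planted_winner(spec, "tanimoto")
  recalls <- vapply(coefficient_ids(), function(cf)
    single_coefficient_recall("act", pl$fingerprints, pl$activities, cf, 5),
    numeric(1))
  # sokal_sneath1 always matches tanimoto (monotone transform); everything
  # else must do strictly worse or equal
  expect_equal(recalls[["sokal_sneath1"]], recalls[["tanimoto"]])
  expect_true(all(recalls <= recalls[["tanimoto"]] + 1e-9))
  # and the scale-fooled quartet must do strictly worse
  fooled <- c("cosine", "kulczynski2", "fossum", "simpson")
  expect_gt(recalls[["tanimoto"]], max(recalls[fooled]))
})

test_that("the pipeline elects the planted coefficient", {
  spec <- dataset_spec(list(class_spec("act", 14, 0.7)), n_background = 120,
                       M = 512, seed = 201)
  pl <- generate_planted_winner(spec, "tanimoto")
  out <- screen_class("act", pl$fingerprints, pl$activities,
                      run_config(topn = 10))
  expect_equal(out$winner, "tanimoto")
})
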