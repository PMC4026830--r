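# Seeded synthetic count-fingerprint generator.
#
# Emulates ECFC-style folded count fingerprints: sparse vectors of small
# integer counts. An activity class is built from a prototype vector; members
# are derived by per-feature resampling whose rate is calibrated by bisection
# so that the realized mean pairwise Tanimoto similarity of the class matches
# a target diversity. The mutation mask and the resampled values are drawn
# ONCE per class and reused across bisection iterations, which makes the
# realized diversity a deterministic, monotone step function of the mutation
# rate - bisection then converges without resampling noise.
#
# Stream discipline: every generated object derives its RNG state from an
# explicit integer seed via withr::with_seed (class i of a dataset uses
# seed + i, the background uses seed + 1000), so datasets are reproducible
# molecule-for-molecule and classes are independent substreams.

# sparse small-integer count vector(s): nonzero with prob `density`,
# counts 1 + Geometric(0.6), capped at 9 (ECFC-like sparsity)
rcounts <- function(n, M, density, cap = 9L) {
  nz <- matrix(stats::runif(n * M) < density, n, M)
  val <- matrix(pmin(1L + stats::rgeom(n * M, 0.6), cap), n, M)
  out <- ifelse(nz, val, 0)
  matrix(as.numeric(out), n, M)
}

ensure_nonzero <- function(X) {
  zero <- rowSums(X) == 0
  if (any(zero)) X[zero, sample.int(ncol(X), 1L)] <- 1
  X
}

#' Specification of one synthetic activity class
#'
#' @param label class label (also the id prefix of its members)
#' @param n_actives number of molecules in the class (>= 2)
#' @param target_diversity intended mean pairwise Tanimoto of the class, in
#'   (0, 1]; 1 means identical members, values near 0.3 emulate highly
#'   heterogeneous classes
#' @param feature_density expected fraction of nonzero fingerprint positions
#'   in the class prototype (default 0.1)
#' @param geometry `"mutation"` (default): members differ from the prototype
#'   by feature resampling - the regime where overlap-normalized measures
#'   such as Tanimoto excel. `"scaled"`: members are additionally rescaled
#'   in overall count magnitude (series of analogues with varying size),
#'   the regime where direction-based measures such as Cosine excel.
#' @param seed integer seed of this class's RNG substream
#' @return a `class_spec` list
#' @export
class_spec <- function(label, n_actives, target_diversity,
                       feature_density = 0.1,
                       geometry = c("mutation", "scaled"), seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_actives < 2L) stop("n_actives must be >= 2")
  if (target_diversity <= 0 || target_diversity > 1)
    stop("target_diversity must lie in (0, 1]")
  if (feature_density <= 0 || feature_density > 1)
    stop("feature_density must lie in (0, 1]")
  structure(list(label = as.character(label),
                 n_actives = as.integer(n_actives),
                 target_diversity = target_diversity,
                 feature_density = feature_density,
                 geometry = geometry,
                 seed = as.integer(seed)),
            class = "class_spec")
}

#' Specification of a synthetic screening dataset
#'
#' @param classes list of [class_spec()] objects; classes without an explicit
#'   seed distinct from the default inherit `seed + index`
#' @param n_background number of unlabeled (inactive) background molecules
#' @param M fingerprint length (default 1024, the usual folded size)
#' @param background_density expected nonzero fraction for background
#'   molecules (default 0.05)
#' @param background_related_frac fraction of the background drawn as
#'   high-mutation derivatives of class members (default 0): screening
#'   databases contain inactive structural neighbours of the actives, and
#'   this is what makes retrieval at a percentage cutoff imperfect. The
#'   remaining background is fully independent.
#' @param seed master seed
#' @return a `dataset_spec` list
#' @export
dataset_spec <- function(classes, n_background, M = 1024L,
                         background_density = 0.05,
                         background_related_frac = 0, seed = 1L) {
  if (!length(classes) || !all(vapply(classes, inherits, logical(1),
                                      "class_spec")))
    stop("classes must be a non-empty list of class_spec objects")
  labels <- vapply(classes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate class labels")
  if (n_background < 0L) stop("n_background must be >= 0")
  if (background_related_frac < 0 || background_related_frac > 1)
    stop("background_related_frac must lie in [0, 1]")
  structure(list(classes = classes, n_background = as.integer(n_background),
                 M = as.integer(M), background_density = background_density,
                 background_related_frac = background_related_frac,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Generate one activity class calibrated to a target diversity
#'
#' Members are copies of a class prototype in which each feature is, with
#' probability mu, replaced by an independent draw from the sparse count
#' marginal. The mutation rate mu is found by bisection (at most 30
#' iterations) against the realized mean pairwise Tanimoto, which is required
#' to land within 0.05 of `spec$target_diversity`. A target of 1 forces
#' mu = 0 and identical members.
#'
#' @param spec a [class_spec()]
#' @param M fingerprint length
#' @return a [fingerprint_matrix()] of `spec$n_actives` molecules with ids
#'   `<label>_001`, `<label>_002`, ...
#' @export
generate_class <- function(spec, M = 1024L) {
  stopifnot(inherits(spec, "class_spec"))
  n <- spec$n_actives
  mats <- withr::with_seed(spec$seed, {
    proto <- ensure_nonzero(rcounts(1L, M, spec$feature_density))[1L, ]
    U <- matrix(stats::runif(n * M), n, M)       # mutation mask thresholds
    V <- rcounts(n, M, spec$feature_density)     # replacement values
    k <- if (identical(spec$geometry, "scaled"))
      stats::runif(n, 0.5, 3) else rep(1, n)     # per-member magnitude
    list(proto = proto, U = U, V = V, k = k)
  })
  members_at <- function(mu) {
    X <- matrix(rep(mats$proto, each = n), n, M)
    X <- round(X * mats$k)                       # magnitude series (no-op
    if (mu > 0) X[mats$U < mu] <- mats$V[mats$U < mu]  # for "mutation")
    ensure_nonzero2(X, mats$proto)
  }
  realize <- function(mu) {
    X <- members_at(mu)
    list(X = X, d = mean_pairwise_similarity(X))
  }
  tol <- 0.045   # stop inside the +/-0.05 contract with headroom
  if (identical(spec$geometry, "scaled") && spec$target_diversity > 0.6)
    stop("target diversity ", spec$target_diversity, " unreachable for the ",
         "scaled geometry: the magnitude spread alone caps mean pairwise ",
         "Tanimoto near 0.6")
  if (spec$target_diversity >= 1) {
    res <- realize(0)
    ids <- sprintf("%s_%03d", spec$label, seq_len(n))
    return(fingerprint_matrix(res$X, ids))
  }
  lo <- 0; hi <- 1
  floor_d <- realize(1)$d
  if (spec$target_diversity < floor_d - 0.05)
    stop(sprintf(paste0("target diversity %.2f unreachable: fully independent ",
                        "members still share diversity %.2f (raise M or lower ",
                        "feature_density)"),
                 spec$target_diversity, floor_d))
  best <- NULL
  for (it in seq_len(30L)) {
    mid <- (lo + hi) / 2
    res <- realize(mid)
    if (is.null(best) ||
        abs(res$d - spec$target_diversity) < abs(best$d - spec$target_diversity))
      best <- res
    if (abs(res$d - spec$target_diversity) <= tol) break
    if (res$d > spec$target_diversity) lo <- mid else hi <- mid
  }
  if (abs(best$d - spec$target_diversity) > 0.05)
    stop(sprintf("diversity calibration failed: target %.2f, achieved %.3f",
                 spec$target_diversity, best$d))
  ids <- sprintf("%s_%03d", spec$label, seq_len(n))
  fingerprint_matrix(best$X, ids)
}

# keep every member nonzero without fresh RNG draws: a fully-mutated-to-zero
# row falls back to the prototype's first nonzero feature
ensure_nonzero2 <- function(X, proto) {
  zero <- rowSums(X) == 0
  if (any(zero)) X[zero, which(proto > 0)[1L]] <- 1
  X
}

#' Generate a full synthetic screening dataset
#'
#' Concatenates the generated activity classes with an independent sparse
#' background; only class members appear in the activity table, so the
#' background molecules form the inactive pool.
#'
#' @param spec a [dataset_spec()]
#' @return list with `fingerprints` (a [fingerprint_matrix()]) and
#'   `activities` (an [activity_table()])
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  classes <- spec$classes
  for (i in seq_along(classes))
    if (classes[[i]]$seed == formals(class_spec)$seed)
      classes[[i]]$seed <- spec$seed + i
  mats <- lapply(classes, generate_class, M = spec$M)
  bg <- NULL
  if (spec$n_background > 0L) {
    n_rel <- round(spec$background_related_frac * spec$n_background)
    n_ind <- spec$n_background - n_rel
    bg <- withr::with_seed(spec$seed + 1000L, {
      ind <- if (n_ind > 0L)
        ensure_nonzero(rcounts(n_ind, spec$M, spec$background_density))
      rel <- NULL
      if (n_rel > 0L) {
        pool <- do.call(rbind, lapply(mats, unclass))
        rel <- t(vapply(seq_len(n_rel), function(i) {
          x <- pool[sample.int(nrow(pool), 1L), ]
          mu <- stats::runif(1L, 0.25, 0.7)   # near-neighbour to far relative
          mut <- stats::runif(spec$M) < mu
          x[mut] <- rcounts(1L, sum(mut), spec$background_density)[1L, ]
          if (sum(x) == 0) x[1L] <- 1
          x
        }, numeric(spec$M)))
      }
      rbind(ind, rel)
    })
    rownames(bg) <- sprintf("bg_%05d", seq_len(spec$n_background))
  }
  all_counts <- do.call(rbind, c(lapply(mats, unclass), list(bg)))
  fps <- fingerprint_matrix(all_counts)
  acts <- activity_table(
    unlist(lapply(mats, rownames)),
    rep(vapply(classes, `[[`, character(1), "label"),
        vapply(mats, nrow, integer(1))))
  list(fingerprints = fps, activities = acts)
}

#' Generate a dataset with a planted winner coefficient
#'
#' Builds a class of genuinely similar actives together with decoy families
#' tuned to the sensitivities of the non-planted coefficients, so that the
#' planted coefficient retrieves the actives more effectively than any other
#' and the per-class election recovers it:
#'
#' * scaled-down decoys (half-magnitude copies of the class prototype)
#'   deceive the scale-sensitive measures - cosine, Kulczynski(2), Forbes,
#'   Fossum, Simpson score them at or above genuine actives, and they sit
#'   closer than actives under Mean Euclidean and Divergence;
#' * scaled-up decoys (triple-magnitude copies) reinforce the deception of
#'   cosine/Kulczynski(2)/Fossum/Simpson;
#' * "boost" decoys (the prototype with one feature count massively
#'   inflated) deceive Mean Canberra and Bray/Curtis, which penalize support
#'   changes far more than magnitude changes.
#'
#' Only `winner_id = "tanimoto"` is constructible. Sokal/Sneath(1) is a
#' strictly monotone transform of Tanimoto (SS1 = T/(2-T)) and therefore
#' always induces the identical ranking: no dataset can make either strictly
#' beat the other in a Condorcet contest, and their Borda totals always tie
#' (resolved by the canonical listing order, where Tanimoto comes first).
#' Plantings for the remaining coefficients would need decoy families this
#' geometry cannot express and are rejected with an error.
#'
#' @param spec a [dataset_spec()]; the FIRST class spec provides the active
#'   class (its `target_diversity` is ignored: the construction fixes the
#'   mutation rate), `n_background` sizes the inactive pool
#' @param winner_id the coefficient to plant (`"tanimoto"`)
#' @param mu active mutation rate (construction knob; default 0.10)
#' @param n_down,n_up,n_boost decoy family sizes
#' @return list with `fingerprints`, `activities` as [generate_dataset()]
#' @export
generate_planted_winner <- function(spec, winner_id = "tanimoto",
                                    mu = 0.10, n_down = 6L, n_up = 4L,
                                    n_boost = 3L) {
  stopifnot(inherits(spec, "dataset_spec"))
  winner_id <- match.arg(winner_id, coefficient_ids())
  if (winner_id == "sokal_sneath1")
    stop("construction infeasible: sokal_sneath1 ranks identically to ",
         "tanimoto (SS1 = T/(2-T)), so it can never strictly win an election")
  if (winner_id != "tanimoto")
    stop("construction infeasible for '", winner_id, "': the decoy-family ",
         "geometry implemented here only separates tanimoto from the other ",
         "ten measures")
  cls <- spec$classes[[1L]]
  n_a <- cls$n_actives
  M <- spec$M
  density <- max(cls$feature_density, 0.15)   # needs a solid shared support
  n_sd <- as.integer(n_down); n_su <- as.integer(n_up)
  n_bo <- as.integer(n_boost)

  parts <- withr::with_seed(spec$seed, {
    # prototype with EVEN counts so half-magnitude decoys stay integral
    nz <- stats::runif(M) < density
    proto <- ifelse(nz, 2 * sample(1:3, M, replace = TRUE), 0)
    if (sum(proto) == 0) proto[1L] <- 2
    support <- which(proto > 0)

    actives <- t(vapply(seq_len(n_a), function(i) {
      x <- proto
      mut <- stats::runif(M) < mu
      x[mut] <- rcounts(1L, sum(mut), density)[1L, ]
      if (sum(x) == 0) x[support[1L]] <- 2
      x
    }, numeric(M)))

    jitter_support <- function(x, rate = 0.04) {
      # tiny count perturbation on the support for seed-to-seed variety
      j <- support[stats::runif(length(support)) < rate]
      x[j] <- pmax(x[j] + sample(c(-1, 1), length(j), replace = TRUE), 1)
      x
    }
    scaled_down <- t(vapply(seq_len(n_sd), function(i)
      jitter_support(proto / 2), numeric(M)))
    scaled_up <- t(vapply(seq_len(n_su), function(i)
      jitter_support(proto * 3), numeric(M)))
    boost <- t(vapply(seq_len(n_bo), function(i) {
      x <- jitter_support(proto)
      j <- sample(support, 1L)
      x[j] <- x[j] + 15 * mean(proto[support])
      x
    }, numeric(M)))

    bg <- ensure_nonzero(rcounts(spec$n_background, M,
                                 spec$background_density))
    list(actives = actives, scaled_down = scaled_down,
         scaled_up = scaled_up, boost = boost, bg = bg)
  })

  rownames(parts$actives) <- sprintf("%s_%03d", cls$label, seq_len(n_a))
  rownames(parts$scaled_down) <- sprintf("dk_down_%02d", seq_len(n_sd))
  rownames(parts$scaled_up) <- sprintf("dk_up_%02d", seq_len(n_su))
  rownames(parts$boost) <- sprintf("dk_boost_%02d", seq_len(n_bo))
  rownames(parts$bg) <- sprintf("bg_%05d", seq_len(nrow(parts$bg)))

  fps <- fingerprint_matrix(do.call(rbind, parts))
  acts <- activity_table(rownames(parts$actives),
                         rep(cls$label, n_a))
  list(fingerprints = fps, activities = acts)
}
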