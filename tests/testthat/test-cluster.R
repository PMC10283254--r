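test_that("spectral clustering recovers exact block-diagonal partitions", {
  W <- planted_affinity(c(3, 3), within = 1, between = 0)
  ca <- spectral_cluster(W, 2, seed = 1)
  expect_equal(adjusted_rand(ca$labels, attr(W, "labels")), 1)
  # canonical numbering: cluster 1 holds the lexicographically first subject
  expect_equal(unname(ca$labels["S001"]), 1L)
})

test_that("spectral clustering is deterministic under a fixed seed", {
  W <- planted_affinity(c(4, 4), within = 1, between = 0.2, noise = 0.1)
  a <- spectral_cluster(W, 7, seed = 42)
  b <- spectral_cluster(W, 7, seed = 42)
  expect_identical(a$labels, b$labels)
  expect_error(spectral_cluster(W, 8, seed = 1), "k must")
})

test_that("planted two-block structure survives cross-block noise", {
  hits <- vapply(1:20, function(seed) {
    W <- planted_affinity(c(10, 10), within = 1, between = 0.05,
                          noise = 0.05, seed = seed)
    ca <- spectral_cluster(W, 2, seed = seed)
    adjusted_rand(ca$labels, attr(W, "labels"))
  }, 0)
  expect_gte(mean(hits >= 0.95), 0.95)
})

test_that("consensus on perfect blocks is the 0/1 co-membership matrix", {
  W <- planted_affinity(c(4, 4), within = 1, between = 0)
  cc <- consensus_cluster(W, 2, iterations = 30, ratio = 0.8, seed = 3)
  lab <- attr(W, "labels")
  same <- outer(lab, lab, "==")
  expect_true(all(cc$consensus[same] == 1))
  expect_true(all(cc$consensus[!same] == 0))
  # degenerate configuration: one iteration at full ratio equals one run
  cc1 <- consensus_cluster(W, 2, iterations = 1, ratio = 1, seed = 5)
  single <- spectral_cluster(W, 2, seed = snfsubtypes:::derive_seed(5, 100001L))
  expect_true(all(cc1$consensus %in% c(0, 1)))
  expect_equal(unname(cc1$consensus),
               unname(outer(single$labels, single$labels, "==") * 1))
})

test_that("consensus labels agree with single-run spectral labels", {
  agreement <- vapply(1:5, function(seed) {
    W <- planted_affinity(c(12, 12), within = 1, between = 0.1,
                          noise = 0.08, seed = seed)
    cc <- consensus_cluster(W, 2, iterations = 50, ratio = 0.8, seed = seed)
    single <- spectral_cluster(W, 2, seed = seed)
    matched <- match_labels(cc$assignment$labels, single$labels)
    mean(matched == single$labels)
  }, 0)
  expect_true(all(agreement >= 0.95))
})

test_that("consensus entries concentrate as iterations grow", {
  W <- planted_affinity(c(12, 12), within = 1, between = 0.15, noise = 0.15,
                        seed = 2)
  lab <- attr(W, "labels")
  truthM <- outer(lab, lab, "==") * 1
  err <- vapply(c(100, 1000), function(it) {
    cc <- consensus_cluster(W, 2, iterations = it, ratio = 0.8, seed = 7)
    mean(abs(cc$consensus - truthM))
  }, 0)
  expect_lte(err[2], err[1] + 0.01)
})

test_that("silhouette profile is maximal for perfect blocks and ~0 without structure", {
  W <- planted_affinity(c(5, 5), within = 1, between = 0)
  prof <- silhouette_profile(W, 2:4, iterations = 20, ratio = 0.8, seed = 1)
  expect_equal(unname(prof$scores["2"]), 1)
  expect_equal(select_k(prof), 2L)
  # structureless consensus: silhouette ~ 0 at every k
  flat <- matrix(0.5, 12, 12); diag(flat) <- 1
  lab <- setNames(rep(1:2, 6), sprintf("S%03d", 1:12))
  expect_lt(abs(mean_silhouette(lab, 1 - flat)), 1e-10)
})

test_that("silhouette-based selection finds a planted three-cluster structure", {
  found <- vapply(1:10, function(seed) {
    W <- planted_affinity(c(8, 8, 8), within = 1, between = 0.05,
                          noise = 0.05, seed = seed)
    prof <- silhouette_profile(W, 2:6, iterations = 25, ratio = 0.8,
                               seed = seed)
    select_k(prof)
  }, 0L)
  expect_gte(sum(found == 3L), 9)
})

test_that("NMI matches hand-computed values and its invariances", {
  expect_equal(nmi(c(a = 1, b = 1, c = 2, d = 2), c(a = 2, b = 2, c = 1, d = 1)), 1)
  expect_equal(nmi(c(a = 1, b = 1, c = 2, d = 2), c(a = 1, b = 2, c = 1, d = 2)), 0)
  expect_equal(nmi(c(a = 1, b = 1, c = 1, d = 2), c(a = 1, b = 1, c = 2, d = 2)),
               0.3456, tolerance = 1e-3)
  # symmetry and permutation invariance over random labelings
  set.seed(10)
  for (i in 1:20) {
    a <- setNames(sample(1:3, 30, TRUE), sprintf("s%02d", 1:30))
    b <- setNames(sample(1:4, 30, TRUE), sprintf("s%02d", 1:30))
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
    perm <- setNames(sample(1:3), 1:3)
    expect_equal(nmi(setNames(perm[as.character(a)], names(a)), b),
                 nmi(a, b), tolerance = 1e-12)
  }
  # both single-cluster: defined as 1; one single-cluster: 0
  expect_equal(nmi(c(x = 1, y = 1), c(x = 2, y = 2)), 1)
  expect_equal(nmi(c(x = 1, y = 1), c(x = 1, y = 2)), 0)
  expect_error(nmi(c(x = 1, y = 2), c(x = 1, z = 2)), "mismatch")
})

test_that("adjusted_rand agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (i in 1:20) {
    a <- sample(1:3, 40, TRUE)
    b <- sample(1:3, 40, TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand(1:2, 2:1), 1)
})

test_that("modality contribution separates signal from noise modalities", {
  # two signal-bearing blocks plus one pure-noise block, the structure the
  # analysis assumes
  set.seed(3)
  lab <- setNames(rep(1:2, each = 20), sprintf("S%03d", 1:40))
  mk <- function(m, modality) {
    rownames(m) <- names(lab); colnames(m) <- sprintf("F%03d", 1:ncol(m))
    standardize_features(omics_block(m, modality))
  }
  sig <- function() {
    m <- matrix(rnorm(40 * 40), 40, 40)
    m[, 1:10] <- m[, 1:10] + outer(ifelse(lab == 1, 1.5, -1.5), rep(1, 10))
    m
  }
  ds <- align_subjects(list(mk(sig(), "protein"), mk(sig(), "mirna"),
                            mk(matrix(rnorm(40 * 40), 40, 40), "torna")))
  params <- snf_params(K = 8, t_iter = 10)
  fused <- snf(ds, params)
  cc <- consensus_cluster(fused$W, 2, iterations = 30, seed = 4)
  expect_gte(adjusted_rand(cc$assignment$labels, lab), 0.9)
  contrib <- modality_contribution(ds, cc$assignment, 2, params,
                                   iterations = 30, seed = 9)
  expect_gt(contrib[["protein"]], 0.6)
  expect_gt(contrib[["mirna"]], 0.6)
  expect_lt(contrib[["torna"]], 0.2)
})
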