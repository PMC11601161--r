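test_that("identical sequences align full length without gaps", {
  mats <- toy_matrices(m11 = 2, m22 = 1.5, m12 = -1)
  q <- toy_dfv(c(1, 2, 1, 1, 2, 2))
  a <- smith_waterman(q, q, mats)
  expect_equal(nrow(a$columns), 6L)
  expect_equal(a$columns$q_pos, 1:6)
  expect_equal(a$columns$t_pos, 1:6)
  expect_equal(a$score, 2 * 3 + 1.5 * 3)
})

test_that("all-negative scores give the empty alignment with score zero", {
  mats <- toy_matrices(m11 = -1, m22 = -2, m12 = -3)
  a <- smith_waterman(toy_dfv(c(1, 2, 1)), toy_dfv(c(2, 1, 2)), mats)
  expect_equal(a$score, 0)
  expect_equal(nrow(a$columns), 0L)
})

test_that("DP equals exhaustive local-alignment enumeration on all short pairs", {
  M <- matrix(c(1.5, -1.1, -1.1, 0.9), 2, 2)
  mats <- toy_matrices(1.5, 0.9, -1.1)
  params <- align_params(gap_open = 1.0, gap_extend = 0.4)
  oracle <- enumerate_local_best(M, 1.0, 0.4, max_len = 5L)
  enc <- function(bits) sum(bits * 2^(rev(seq_along(bits)) - 1)) + 1
  for (la in 1:5) for (lb in 1:5) {
    best <- oracle[[paste(la, lb)]]
    # every sequence pair of these lengths over the 2-letter alphabet
    for (qi in seq_len(2^la)) {
      qbits <- as.integer(intToBits(qi - 1))[la:1]
      for (ti in seq_len(2^lb)) {
        tbits <- as.integer(intToBits(ti - 1))[lb:1]
        got <- smith_waterman(toy_dfv(qbits + 1L), toy_dfv(tbits + 1L),
                              mats, params)$score
        want <- best[enc(qbits), enc(tbits)]
        if (abs(got - want) > 1e-9)
          fail(sprintf("mismatch at la=%d lb=%d q=%s t=%s: dp=%g oracle=%g",
                       la, lb, paste(qbits, collapse = ""),
                       paste(tbits, collapse = ""), got, want))
      }
    }
  }
  succeed()
})

test_that("returned alignments re-evaluate to their DP score", {
  tabs <- test_tables()
  set <- test_bench_set()
  ids <- withr::with_seed(4, sample(names(set$chains), 8))
  for (i in 1:4) {
    q <- set$chains[[ids[i]]]; t <- set$chains[[ids[i + 4]]]
    qd <- discretize_chain(extract_features(q, tabs$feature_params),
                           tabs$alphabets)
    td <- discretize_chain(extract_features(t, tabs$feature_params),
                           tabs$alphabets)
    a <- smith_waterman(qd, td, tabs$matrices, tabs$align_params)
    expect_equal(eval_alignment_score(a, qd, td, tabs$matrices,
                                      tabs$align_params),
                 a$score, tolerance = 1e-6)
    expect_true(all(diff(a$columns$q_pos) > 0))
    expect_true(all(diff(a$columns$t_pos) > 0))
    # score symmetry
    b <- smith_waterman(td, qd, tabs$matrices, tabs$align_params)
    expect_equal(b$score, a$score, tolerance = 1e-9)
  }
})

test_that("eval_alignment_score applies the affine gap formula", {
  # 3 columns scoring 1.0, 2.0, 0.5 with one internal gap of length 2
  mats <- structure(list(feature_order = "f1", matrices = list(f1 = structure(
    list(feature_name = "f1", size = 4L,
         matrix = diag(c(1.0, 2.0, 0.5, 0)), weight = 1),
    class = "score_matrix"))), class = "score_matrix_set")
  q <- toy_dfv(c(1, 2, 3)); colnames(q) <- "f1"
  t <- matrix(c(1L, 2L, 4L, 3L, 3L), ncol = 1, dimnames = list(NULL, "f1"))
  a <- new_alignment_result_for_test(c(1, 2, 3), c(1, 2, 5), 0)
  p <- align_params(gap_open = 1, gap_extend = 0.5)
  expect_equal(eval_alignment_score(a, q, t, mats, p), 3.5 - 1.5)
  # no gaps: plain sum
  b <- new_alignment_result_for_test(c(1, 2), c(1, 2), 0)
  expect_equal(eval_alignment_score(b, q, t, mats, p), 3.0)
  # gap of length 1 costs exactly gap_open
  d <- new_alignment_result_for_test(c(1, 2, 3), c(1, 2, 4), 0)
  expect_equal(eval_alignment_score(d, q, t, mats, p), 3.5 - 1)
  # crossing columns are rejected
  bad <- new_alignment_result_for_test(c(1, 3), c(2, 1), 0)
  expect_error(eval_alignment_score(bad, q, t, mats, p), "increasing")
})

test_that("raising the gap-open penalty never raises the optimal score", {
  tabs <- test_tables()
  set <- test_bench_set()
  q <- set$chains[[1L]]; t <- set$chains[[2L]]
  qd <- discretize_chain(extract_features(q, tabs$feature_params),
                         tabs$alphabets)
  td <- discretize_chain(extract_features(t, tabs$feature_params),
                         tabs$alphabets)
  scores <- sapply(c(0.5, 1, 2, 4, 8), function(go)
    smith_waterman(qd, td, tabs$matrices,
                   align_params(gap_open = go, gap_extend = 0.5))$score)
  expect_true(all(diff(scores) <= 1e-9))
})

test_that("reversed-chain self score behaves as a null correction", {
  tabs <- test_tables()
  ch <- test_bench_set()$chains[[3L]]
  s_rev <- reversed_score(ch, tabs)
  expect_gte(s_rev, 0)
  expect_equal(reversed_score(ch, tabs), s_rev)  # deterministic
  # palindromic collinear coordinates: reversal is a symmetry, so s_rev
  # equals the self-alignment score (4.0 spacing keeps distances binary-exact
  # so neighbour ties break identically in both directions)
  pal <- chain_structure("pal", rep("A", 9), cbind(4.0 * (0:8), 0, 0))
  pd <- discretize_chain(extract_features(pal, tabs$feature_params),
                         tabs$alphabets)
  self_score <- smith_waterman(pd, pd, tabs$matrices, tabs$align_params)$score
  expect_equal(reversed_score(pal, tabs), self_score, tolerance = 1e-6)
  # self score dominates the reversed score for a folded chain
  cd <- discretize_chain(extract_features(ch, tabs$feature_params),
                         tabs$alphabets)
  expect_gte(smith_waterman(cd, cd, tabs$matrices, tabs$align_params)$score,
             s_rev)
})

test_that("Kabsch superposition is exact on rigid copies and optimal vs a grid", {
  pts <- withr::with_seed(12, matrix(rnorm(30), ncol = 3)) * 5
  s0 <- kabsch_superpose(pts, pts)
  expect_lt(s0$rmsd, 1e-9)
  expect_lt(max(abs(s0$rotation - diag(3))), 1e-9)

  R <- random_rotation_oracle(1, seed = 5)[[1L]]
  moved <- pts %*% t(R) + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  s1 <- kabsch_superpose(pts, moved)
  expect_lt(s1$rmsd, 1e-6)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-6)
  back <- moved %*% t(s1$rotation) +
    matrix(s1$translation, 10, 3, byrow = TRUE)
  expect_lt(max(abs(back - pts)), 1e-6)

  # optimality: no rotation from a large random grid beats the SVD solution
  q <- withr::with_seed(31, matrix(rnorm(30), ncol = 3))
  t2 <- withr::with_seed(32, matrix(rnorm(30), ncol = 3))
  sv <- kabsch_superpose(q, t2)
  grid <- random_rotation_oracle(10000, seed = 33)
  grid_best <- min(vapply(grid, function(Rg) rmsd_at_rotation(q, t2, Rg),
                          numeric(1)))
  expect_lte(sv$rmsd, grid_best + 1e-12)

  # near-planar inputs still return a proper rotation
  flat <- cbind(withr::with_seed(8, matrix(rnorm(20), ncol = 2)), 1e-9)
  mirror <- flat %*% diag(c(-1, 1, 1))
  sp <- kabsch_superpose(flat, mirror)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-6)

  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("independent implementation agrees with bio3d's least-squares fit", {
  q <- withr::with_seed(21, matrix(rnorm(36), ncol = 3)) * 4
  t2 <- withr::with_seed(22, matrix(rnorm(36), ncol = 3)) * 4
  sp <- kabsch_superpose(q, t2)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(q)),
                                            mobile = as.numeric(t(t2))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - q)^2)))
  expect_equal(sp$rmsd, ref_rmsd, tolerance = 1e-6)
})
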