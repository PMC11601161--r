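toy_alignment <- function(q_letters, t_letters, pairs) {
  list(q = toy_dfv(q_letters), t = toy_dfv(t_letters),
       pairs = tibble::tibble(a = pairs[, 1L], b = pairs[, 2L]))
}

test_that("pair counts are symmetrized and match hand enumeration", {
  al <- toy_alignment(c(2, 1), c(1, 2), cbind(1:2, 1:2))
  cnt <- accumulate_counts(list(al), "f1", 2)
  # columns: (2,1) and (1,2); both orders counted
  expect_equal(cnt$joint, matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(sum(cnt$joint), 2 * 2)

  one <- toy_alignment(2, 5, cbind(1, 1))
  cnt6 <- accumulate_counts(list(one), "f1", 6)
  expect_equal(cnt6$joint[2, 5], 1)
  expect_equal(cnt6$joint[5, 2], 1)
  expect_equal(sum(cnt6$joint), 2)

  # 5-column toy alignment, counted by hand
  al5 <- toy_alignment(c(1, 1, 2, 2, 1), c(1, 2, 2, 1, 1),
                       cbind(1:5, 1:5))
  c5 <- accumulate_counts(list(al5), "f1", 2)
  # column pairs (1,1)x2, (1,2), (2,2), (2,1); symmetrized doubles the total
  expect_equal(c5$joint, matrix(c(4, 2, 2, 2), 2, 2))
  expect_error(accumulate_counts(list(toy_alignment(3, 1, cbind(1, 1))),
                                 "f1", 2), "out of range")
})

test_that("log-odds training reproduces the defining frequency arithmetic", {
  # independence: joint proportional to p_i * p_j gives the zero matrix
  p <- c(0.3, 0.7)
  cnt <- structure(list(feature_name = "f1",
                        joint = 1000 * outer(p, p)),
                   class = "pair_counts")
  M0 <- train_logodds(cnt, pseudocount = 0)
  expect_lt(max(abs(M0$matrix)), 1e-9)

  # hand-computed instance: pairs {(0,0) x2, (0,1) x1, (1,1) x1} (1-based: 1/2)
  joint <- matrix(c(4, 1, 1, 2), 2, 2)  # already symmetrized, total 8
  cnt2 <- structure(list(feature_name = "f1", joint = joint),
                    class = "pair_counts")
  M <- train_logodds(cnt2, pseudocount = 0)$matrix
  P <- joint / 8
  pm <- rowSums(P)
  expect_equal(M, log2(P / outer(pm, pm)))
  expect_equal(M, t(M))

  # diagonal-only counts: positive diagonal, negative off-diagonal
  cnt3 <- structure(list(feature_name = "f1", joint = diag(c(10, 14, 8))),
                    class = "pair_counts")
  M3 <- train_logodds(cnt3, pseudocount = 0.5)$matrix
  expect_true(all(diag(M3) > 0))
  expect_true(all(M3[row(M3) != col(M3)] < 0))
})

test_that("expected pair score under independent letter draws is non-positive", {
  # E_p[M] <= 0 when letters are drawn independently from training marginals
  set <- test_train_set()
  tabs <- test_tables()
  dfvs <- lapply(set$chains, function(ch)
    discretize_chain(extract_features(ch, tabs$feature_params), tabs$alphabets))
  alns <- lapply(family_alignments(set), function(al)
    list(q = dfvs[[al$id_a]], t = dfvs[[al$id_b]], pairs = al$pairs))
  for (f in c("aa", "conf_self", "dist_ren")) {
    cnt <- accumulate_counts(alns, f, tabs$alphabets$sizes[[f]])
    M <- train_logodds(cnt, pseudocount = 0.5)$matrix
    p <- rowSums(cnt$joint + 0.5) / sum(cnt$joint + 0.5)
    draws <- withr::with_seed(11, cbind(
      sample.int(length(p), 1e4, replace = TRUE, prob = p),
      sample.int(length(p), 1e4, replace = TRUE, prob = p)))
    expect_lte(mean(M[draws]), 0.05)
  }
})

test_that("pair scores are symmetric weighted sums over features", {
  mats <- toy_matrices(m11 = 2.0, m22 = 2.0, m12 = -1.0)
  u <- toy_dfv(1); v <- toy_dfv(1)
  expect_equal(pair_score(u, v, mats), 2.0)
  mats0 <- toy_matrices(); mats0$matrices$f1$weight <- 0
  expect_equal(pair_score(u, v, mats0), 0)

  tabs <- test_tables()
  ch <- test_bench_set()$chains[[1L]]
  dfv <- discretize_chain(extract_features(ch, tabs$feature_params),
                          tabs$alphabets)
  idx <- withr::with_seed(3, cbind(sample(nrow(dfv), 100, TRUE),
                                   sample(nrow(dfv), 100, TRUE)))
  for (k in seq_len(nrow(idx))) {
    s1 <- pair_score(dfv[idx[k, 1L], , drop = FALSE],
                     dfv[idx[k, 2L], , drop = FALSE], tabs$matrices)
    s2 <- pair_score(dfv[idx[k, 2L], , drop = FALSE],
                     dfv[idx[k, 1L], , drop = FALSE], tabs$matrices)
    expect_equal(s1, s2)
  }
})

test_that("trained score matrices are symmetric with reward on the diagonal", {
  tabs <- test_tables()
  for (m in tabs$matrices$matrices) {
    expect_equal(m$matrix, t(m$matrix))
    expect_true(all(is.finite(m$matrix)))
    expect_gt(mean(diag(m$matrix)), mean(m$matrix[row(m$matrix) != col(m$matrix)]))
  }
})

test_that("mega-alphabet size is the exact product of feature alphabet sizes", {
  expect_equal(mega_alphabet_size(c(20, rep(16, 8))), 85899345920)
  expect_equal(mega_alphabet_size(c(4, 4)), 16)
  expect_equal(mega_alphabet_size(7), 7)
  expect_error(mega_alphabet_size(numeric(0)), "empty")
})
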