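test_that("scalar alphabet training follows the equal-bin threshold rule", {
  a <- train_scalar_alphabet(1:8, 4)
  expect_equal(a$thresholds, c(2.5, 4.5, 6.5))
  b <- train_scalar_alphabet(c(4, 1, 3, 2), 2)   # order must not matter
  expect_equal(b$thresholds, 2.5)
  expect_error(train_scalar_alphabet(rep(c(1, 2), 10), 4), "degenerate")
})

test_that("letter assignment counts thresholds strictly below the value", {
  a <- train_scalar_alphabet(1:8, 4)
  expect_equal(assign_scalar_letter(5, a), 3L)     # letters are 1-based
  expect_equal(assign_scalar_letter(-1e6, a), 1L)
  expect_equal(assign_scalar_letter(1e6, a), 4L)
  expect_equal(assign_scalar_letter(2.5, a), 1L)   # exact threshold: lower bin
  expect_error(assign_scalar_letter(NaN, a), "non-finite")
  # assign-after-train consistency: training values get their bin back
  vals <- withr::with_seed(5, rnorm(4000))
  a16 <- train_scalar_alphabet(vals, 16)
  letters <- assign_scalar_letter(vals, a16)
  srt <- sort(vals)
  expect_equal(letters[order(vals)], rep(1:16, each = 250))
})

test_that("equal-frequency property holds on continuous training data", {
  vals <- withr::with_seed(42, rnorm(1e4))
  a <- train_scalar_alphabet(vals, 16)
  freq <- tabulate(assign_scalar_letter(vals, a), nbins = 16) / length(vals)
  expect_true(all(abs(freq - 1 / 16) <= 0.01))
})

test_that("K-means alphabets recover well-separated clusters deterministically", {
  X <- withr::with_seed(7, rbind(matrix(rnorm(500 * 3), ncol = 3),
                                 matrix(rnorm(500 * 3, mean = 20), ncol = 3)))
  a <- train_vector_alphabet(X, 2, seed = 3)
  cen <- a$centroids[order(a$centroids[, 1L]), ]
  expect_lt(max(abs(cen[1L, ] - colMeans(X[1:500, ]))), 0.1)
  expect_lt(max(abs(cen[2L, ] - colMeans(X[501:1000, ]))), 0.1)
  b <- train_vector_alphabet(X, 2, seed = 3)
  expect_equal(b$centroids, a$centroids)
  # K == n: every point is its own centroid
  small <- matrix(c(0, 0, 10, 0, 0, 10), ncol = 2, byrow = TRUE)
  k3 <- train_vector_alphabet(small, 3, seed = 1)
  expect_equal(sort(assign_vector_letter(small, k3)), 1:3)
  d <- rowSums((k3$centroids[assign_vector_letter(small, k3), ] - small)^2)
  expect_lt(max(d), 1e-12)
})

test_that("vector letter assignment is exhaustive nearest-centroid search", {
  a <- train_vector_alphabet(withr::with_seed(1, matrix(rnorm(200 * 5), ncol = 5)),
                             8, seed = 2)
  V <- withr::with_seed(9, matrix(rnorm(100 * 5), ncol = 5))
  got <- assign_vector_letter(V, a)
  for (k in seq_len(nrow(V))) {
    d <- apply(a$centroids, 1L, function(cen) sum((V[k, ] - cen)^2))
    expect_equal(got[k], which.min(d))
  }
  expect_equal(assign_vector_letter(a$centroids[3L, ], a), 3L)
  # equidistant vector: smallest centroid index wins
  two <- structure(list(feature_name = "f", size = 2L,
                        centroids = rbind(c(-1, 0), c(1, 0))),
                   class = "vector_alphabet")
  expect_equal(assign_vector_letter(c(0, 5), two), 1L)
  expect_error(assign_vector_letter(c(1, 2, 3), two), "dimension")
})

test_that("chain discretization produces in-range letters deterministically", {
  tabs <- test_tables()
  ch <- test_bench_set()$chains[[1L]]
  ft <- extract_features(ch, tabs$feature_params)
  dfv <- discretize_chain(ft, tabs$alphabets)
  expect_equal(colnames(dfv), feature_order())
  for (f in feature_order()) {
    expect_gte(min(dfv[, f]), 1L)
    expect_lte(max(dfv[, f]), tabs$alphabets$sizes[[f]])
  }
  expect_identical(discretize_chain(ft, tabs$alphabets), dfv)
  # non-constant features use more than one letter
  expect_gt(length(unique(dfv[, "dist_nen"])), 1L)
  # 'X' maps to the first amino-acid slot, with a warning
  chx <- chain_structure("x", c("X", "G", "L", "V"),
                         cbind(3.8 * (0:3), 0, 0))
  ftx <- extract_features(chx, tabs$feature_params)
  expect_warning(dfvx <- discretize_chain(ftx, tabs$alphabets), "X")
  expect_equal(dfvx[1L, "aa"], c(aa = 1L))
})

test_that("alphabet sets survive a JSON round trip", {
  tabs <- test_tables()
  f <- withr::local_tempfile(fileext = ".json")
  write_alphabets(tabs$alphabets, f)
  back <- read_alphabets(f)
  expect_equal(back$sizes, tabs$alphabets$sizes)
  for (nm in names(tabs$alphabets$alphabets)) {
    a <- tabs$alphabets$alphabets[[nm]]
    b <- back$alphabets[[nm]]
    if (inherits(a, "scalar_alphabet"))
      expect_equal(b$thresholds, a$thresholds)
    else expect_equal(b$centroids, a$centroids, ignore_attr = TRUE)
  }
  ch <- test_bench_set()$chains[[2L]]
  ft <- extract_features(ch, tabs$feature_params)
  expect_identical(discretize_chain(ft, back),
                   discretize_chain(ft, tabs$alphabets))
})
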