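labels_of <- function(ids, fams) tibble::tibble(id = ids, family = fams)

test_that("all-vs-all search emits one ordered hit per pair with sane fields", {
  tabs <- test_tables_calibrated()
  db <- test_bench_set()$chains[1:5]
  hits <- search_all_vs_all(db, tabs)
  expect_equal(nrow(hits), 5 * 4)
  expect_true(all(hits$query_id != hits$target_id))
  expect_true(all(hits$aq > 0 & hits$aq < 1))
  expect_true(all(hits$evalue >= 0))
  # sorted by E-value within query
  for (q in unique(hits$query_id))
    expect_true(all(diff(hits$evalue[hits$query_id == q]) >= 0))
  # an exact copy under a new id ranks first for its twin
  db2 <- db
  db2$twin <- chain_structure("twin", db[[1L]]$aa, db[[1L]]$xyz)
  hits2 <- search_all_vs_all(db2, tabs)
  top <- hits2[hits2$query_id == names(db)[1L], ][1L, ]
  expect_equal(top$target_id, "twin")
  expect_error(search_all_vs_all(db, test_tables()), "calibrat")
})

test_that("CVE counting matches hand-computed fractions on a toy hit table", {
  hits <- tibble::tibble(
    query_id = c("q1", "q1", "q2", "q2"),
    target_id = c("a", "b", "a", "b"),
    evalue = c(0.01, 0.5, 0.05, 2))
  labels <- labels_of(c("q1", "q2", "a", "b"),
                      c("f1", "f2", "f1", "f2"))
  # homolog ordered pairs from labels: (q1,a),(a,q1),(q2,b),(b,q2) -> 4
  cve <- cve_curve(hits, labels, n_queries = 2)
  at <- function(thr) cve[cve$threshold == thr, ]
  expect_equal(at(0.5)$tpr, 1 / 4)         # only q1-a is found below 0.5
  expect_equal(at(0.5)$fpepq, 1 / 2)       # q2-a is the one FP below 0.5
  expect_equal(at(Inf)$tpr, 2 / 4)         # both scored homolog pairs found
  expect_equal(at(Inf)$fpepq, 2 / 2)
  # counting oracle: curve values times denominators are integers
  expect_true(all(abs(cve$tpr * 4 - round(cve$tpr * 4)) < 1e-9))
  expect_true(all(abs(cve$fpepq * 2 - round(cve$fpepq * 2)) < 1e-9))
  expect_error(cve_curve(hits, labels[-1, ], 2), "q1")
})

test_that("CVE and CatE curves are monotone under threshold relaxation", {
  tabs <- test_tables_calibrated()
  set <- test_bench_set()
  hits <- search_all_vs_all(set$chains[1:12], tabs)
  labels <- set$labels[set$labels$id %in% names(set$chains)[1:12], ]
  cve <- cve_curve(hits, labels, 12)
  expect_true(all(diff(cve$tpr) >= 0))
  expect_true(all(diff(cve$fpepq) >= 0))
  cate <- cate_curve(hits, labels, 12)
  expect_true(all(diff(cate$fcr) >= 0))
})

test_that("top-hit category counting matches hand enumeration", {
  hits <- tibble::tibble(
    query_id = c("q1", "q1", "q2", "q2", "q3", "q3"),
    target_id = c("h1", "d1", "d2", "h2", "h3", "d3"),
    evalue = c(0.01, 0.2, 0.03, 0.5, 5, 8))
  labels <- labels_of(c("q1", "q2", "q3", "h1", "h2", "h3", "d1", "d2", "d3"),
                      c("A", "B", "C", "A", "B", "C", "x", "y", "z"))
  cate <- cate_curve(hits, labels, 3)
  at <- function(thr) cate[cate$threshold == thr, ]
  # threshold 0.2: top hits passing are q1 (homolog) and q2 (decoy)
  expect_equal(at(0.2)$top_hit_accuracy, 1 / 2)
  expect_equal(at(0.2)$fcr, 1 / 3)
  # everything passes at Inf; q3's top hit is homologous
  expect_equal(at(Inf)$top_hit_accuracy, 2 / 3)
  expect_equal(at(Inf)$fcr, 1 / 3)
  # all top hits homologous: accuracy 1, fcr 0 everywhere
  good <- tibble::tibble(query_id = c("q1", "q2"), target_id = c("h1", "h2"),
                         evalue = c(0.1, 0.2))
  cg <- cate_curve(good, labels, 2)
  expect_true(all(cg$top_hit_accuracy[!is.na(cg$top_hit_accuracy)] == 1))
  expect_true(all(cg$fcr == 0))
})

test_that("sensitivity-at-FPEPQ reads the step function correctly", {
  cve <- tibble::tibble(threshold = c(0.01, 0.1, 1, 10),
                        tpr = c(0.2, 0.5, 0.7, 0.9),
                        fpepq = c(0, 0.05, 0.8, 5))
  expect_equal(sens_at_fpepq(cve, 1), 0.7)
  expect_equal(sens_at_fpepq(cve, 0.05), 0.5)
  expect_equal(sens_at_fpepq(cve, 100), 0.9)   # above all observed errors
  expect_equal(sens_at_fpepq(cve, 1e-9), 0.2)  # below the smallest achievable
})

test_that("measured FPEPQ is zero on empty hits and non-decreasing in E", {
  labels <- labels_of(c("a", "b"), c("f", "g"))
  empty <- tibble::tibble(query_id = character(), target_id = character(),
                          evalue = numeric())
  ec <- evalue_vs_fpepq(empty, labels, 2)
  expect_true(all(ec$fpepq == 0))
  tabs <- test_tables_calibrated()
  set <- test_bench_set()
  hits <- search_all_vs_all(set$chains[1:8], tabs)
  ec2 <- evalue_vs_fpepq(hits, set$labels, 8,
                         thresholds = c(0.01, 0.1, 1, 10, 100))
  expect_true(all(diff(ec2$fpepq) >= 0))
})

test_that("curve plots build without error", {
  cve <- structure(tibble::tibble(threshold = c(0.1, 1), tpr = c(0.5, 0.8),
                                  fpepq = c(0.1, 2)),
                   class = c("cve_curve", class(tibble::tibble())))
  expect_s3_class(ggplot2::autoplot(cve), "ggplot")
  ec <- structure(tibble::tibble(e_threshold = c(0.1, 1), fpepq = c(0.2, 1.1)),
                  class = c("evcal_curve", class(tibble::tibble())))
  expect_s3_class(ggplot2::autoplot(ec), "ggplot")
})
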