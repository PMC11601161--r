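#' All-vs-all structure search
#'
#' Aligns every ordered pair of distinct database chains and reports one hit
#' per pair with its score, alignment quality and E-value (database size
#' `N - 1` comparisons per query). Alignments are computed once per unordered
#' pair; the two ordered hits differ through the query's reversed-alignment
#' score. Hits are sorted by increasing E-value within each query.
#'
#' @param db Named list of [chain_structure()] with distinct ids.
#' @param tables A calibrated [train_tables()] bundle.
#' @param prefilter If `TRUE`, skip pairs sharing no 4-mer of the reduced
#'   (amino acid, self-conformation) letter projection; off by default.
#' @return A tibble of class `hit_table`: `query_id`, `target_id`, `score`,
#'   `delta_lddt`, `aq`, `evalue`.
#' @export
search_all_vs_all <- function(db, tables, prefilter = FALSE) {
  stopifnot(inherits(tables, "staln_tables"))
  if (is.null(tables$calibration))
    stop("tables are not calibrated; run calibrate_evalues() first",
         call. = FALSE)
  if (is.null(names(db)) || any(!nzchar(names(db))))
    names(db) <- vapply(db, function(ch) ch$id, character(1L))
  if (anyDuplicated(names(db)))
    stop("database chain ids must be distinct", call. = FALSE)
  n <- length(db)
  ids <- names(db)
  prof <- lapply(db, chain_profile, tables = tables)
  rev_dfv <- lapply(db, function(ch)
    discretize_chain(extract_features(reverse_chain(ch),
                                      tables$feature_params),
                     tables$alphabets))
  s_rev <- vapply(seq_len(n), function(i)
    smith_waterman(prof[[i]]$dfv, rev_dfv[[i]], tables$matrices,
                   tables$align_params)$score, numeric(1L))
  kmers <- if (prefilter) lapply(prof, seed_kmers) else NULL
  qp <- tables$quality_params
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (prefilter && length(intersect(kmers[[i]], kmers[[j]])) == 0L) next
      aln <- smith_waterman(prof[[i]]$dfv, prof[[j]]$dfv, tables$matrices,
                            tables$align_params)
      dl <- lddt_mu(aln, prof[[i]]$chain, prof[[j]]$chain)
      li <- prof[[i]]$chain$length; lj <- prof[[j]]$chain$length
      aq_ij <- aq_statistic(dl, aln$score, s_rev[i], li, lj, qp)$aq
      aq_ji <- aq_statistic(dl, aln$score, s_rev[j], lj, li, qp)$aq
      rows[[length(rows) + 1L]] <- tibble::tibble(
        query_id = c(ids[i], ids[j]), target_id = c(ids[j], ids[i]),
        score = aln$score, delta_lddt = dl, aq = c(aq_ij, aq_ji))
    }
  }
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0L)
    hits <- tibble::tibble(query_id = character(), target_id = character(),
                           score = numeric(), delta_lddt = numeric(),
                           aq = numeric())
  hits$evalue <- if (nrow(hits)) evalue_of(hits$aq, tables$calibration, n - 1L)
                 else numeric(0)
  hits <- dplyr::arrange(hits, .data$query_id, .data$evalue, .data$target_id)
  class(hits) <- c("hit_table", class(hits))
  hits
}

# 4-mers of the reduced (aa, conf_self) letter projection, for seeding
seed_kmers <- function(profile, k = 4L) {
  dfv <- profile$dfv
  proj <- (dfv[, "aa"] - 1L) * 16L + dfv[, "conf_self"]
  n <- length(proj)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  unique(vapply(starts, function(s)
    paste(proj[s:(s + k - 1L)], collapse = "."), character(1L)))
}

check_labels <- function(hits, labels) {
  lab <- stats::setNames(labels[[2L]], labels[[1L]])
  miss <- setdiff(unique(c(hits$query_id, hits$target_id)), names(lab))
  if (length(miss))
    stop("no family label for id '", miss[1L], "'", call. = FALSE)
  lab
}

total_homolog_pairs <- function(labels) {
  m <- table(labels[[2L]])
  sum(m * (m - 1L))  # ordered pairs, self excluded
}

#' Coverage-versus-error curve
#'
#' Sweeps an E-value threshold over the observed values and reports, at each
#' threshold, the true positive rate (fraction of all ordered homolog pairs
#' with `E` strictly below the threshold) and the false-positive errors per
#' query (non-homolog pairs below the threshold divided by the number of
#' queries). Homology means same family/superfamily label; self-hits are
#' excluded by construction of the hit table.
#'
#' @param hits A [search_all_vs_all()] hit table (or any tibble with
#'   `query_id`, `target_id`, `evalue`).
#' @param labels Two-column table mapping id to family label.
#' @param n_queries Number of queries (default: distinct query ids in
#'   `hits`).
#' @return A tibble of class `cve_curve`: `threshold`, `tpr`, `fpepq`.
#' @export
cve_curve <- function(hits, labels, n_queries = NULL) {
  lab <- check_labels(hits, labels)
  n_queries <- n_queries %||% length(unique(hits$query_id))
  hom <- lab[hits$query_id] == lab[hits$target_id]
  denom <- total_homolog_pairs(labels)
  thr <- c(sort(unique(hits$evalue)), Inf)
  tpr <- vapply(thr, function(x) sum(hom & hits$evalue < x) / denom,
                numeric(1L))
  fpepq <- vapply(thr, function(x) sum(!hom & hits$evalue < x) / n_queries,
                  numeric(1L))
  out <- tibble::tibble(threshold = thr, tpr = tpr, fpepq = fpepq)
  class(out) <- c("cve_curve", class(out))
  out
}

#' Top-hit category curve
#'
#' For each E-value threshold: among queries whose top hit (lowest E) passes
#' the threshold, the fraction whose top hit is a homolog (top-hit accuracy),
#' and the false category rate, i.e. queries with a non-homologous passing
#' top hit divided by the number of queries.
#'
#' @inheritParams cve_curve
#' @return A tibble of class `cate_curve`: `threshold`, `top_hit_accuracy`
#'   (NA when no top hit passes), `fcr`.
#' @export
cate_curve <- function(hits, labels, n_queries = NULL) {
  lab <- check_labels(hits, labels)
  n_queries <- n_queries %||% length(unique(hits$query_id))
  top <- hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::slice_min(.data$evalue, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  top_hom <- lab[top$query_id] == lab[top$target_id]
  thr <- c(sort(unique(hits$evalue)), Inf)
  acc <- numeric(length(thr)); fcr <- numeric(length(thr))
  for (k in seq_along(thr)) {
    pass <- top$evalue < thr[k]
    acc[k] <- if (any(pass)) mean(top_hom[pass]) else NA_real_
    fcr[k] <- sum(pass & !top_hom) / n_queries
  }
  out <- tibble::tibble(threshold = thr, top_hit_accuracy = acc, fcr = fcr)
  class(out) <- c("cate_curve", class(out))
  out
}

#' Measured error rate at nominal E-value thresholds
#'
#' Reports the measured false-positive errors per query at each requested
#' E-value threshold; for a well-calibrated E-value the measured FPEPQ equals
#' the threshold.
#'
#' @inheritParams cve_curve
#' @param thresholds Nominal E-value thresholds.
#' @return A tibble of class `evcal_curve`: `e_threshold`, `fpepq`.
#' @export
evalue_vs_fpepq <- function(hits, labels, n_queries = NULL,
                            thresholds = c(0.1, 1, 10)) {
  n_queries <- n_queries %||% length(unique(hits$query_id))
  if (nrow(hits) == 0L) {
    out <- tibble::tibble(e_threshold = thresholds,
                          fpepq = rep(0, length(thresholds)))
    class(out) <- c("evcal_curve", class(out))
    return(out)
  }
  lab <- check_labels(hits, labels)
  hom <- lab[hits$query_id] == lab[hits$target_id]
  fpepq <- vapply(thresholds, function(x)
    sum(!hom & hits$evalue < x) / n_queries, numeric(1L))
  out <- tibble::tibble(e_threshold = thresholds, fpepq = fpepq)
  class(out) <- c("evcal_curve", class(out))
  out
}

#' Sensitivity at a target error rate
#'
#' Step-function reading of a coverage-versus-error curve: the TPR at the
#' largest threshold whose FPEPQ does not exceed `x`; if no threshold
#' achieves `x`, the TPR at the most stringent threshold.
#'
#' @param cve A [cve_curve()] result.
#' @param x Target false-positive errors per query.
#' @return Numeric TPR.
#' @export
sens_at_fpepq <- function(cve, x) {
  stopifnot(nrow(cve) > 0L)
  ok <- which(cve$fpepq <= x)
  if (!length(ok)) return(cve$tpr[which.min(cve$threshold)])
  max(cve$tpr[ok])
}

#' Run the full benchmark on a labeled database
#'
#' Convenience wrapper: all-vs-all search, then the coverage-versus-error
#' curve, top-hit category curve, E-value calibration curve and
#' sensitivity-at-FPEPQ summaries.
#'
#' @param db Named list of [chain_structure()].
#' @param labels Two-column id-to-family table.
#' @param tables A calibrated [train_tables()] bundle.
#' @param sens_at FPEPQ levels for the sensitivity summary.
#' @return A list of class `benchmark_curves`: `hits`, `cve`, `cate`,
#'   `evcal`, `sens_at` (named numeric vector).
#' @export
run_benchmark <- function(db, labels, tables, sens_at = c(0.1, 1, 10)) {
  hits <- search_all_vs_all(db, tables)
  nq <- length(db)
  cve <- cve_curve(hits, labels, nq)
  cate <- cate_curve(hits, labels, nq)
  evcal <- evalue_vs_fpepq(hits, labels, nq, thresholds = sens_at)
  sens <- stats::setNames(vapply(sens_at, function(x) sens_at_fpepq(cve, x),
                                 numeric(1L)),
                          paste0("sens_", sens_at))
  structure(list(hits = hits, cve = cve, cate = cate, evcal = evcal,
                 sens_at = sens),
            class = "benchmark_curves")
}

#' @export
print.benchmark_curves <- function(x, ...) {
  cat("<benchmark_curves>", nrow(x$hits), "hits\n")
  for (nm in names(x$sens_at))
    cat(sprintf("  %s: %.3f\n", nm, x$sens_at[[nm]]))
  invisible(x)
}

#' Write a hit table as TSV
#'
#' @param hits A [search_all_vs_all()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
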