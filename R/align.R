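#' Alignment parameters
#'
#' Affine gap penalties in bits: a gap of length `len` costs
#' `gap_open + (len - 1) * gap_extend`; terminal gaps are free (local
#' alignment). Defaults were tuned on the package's simulated benchmark.
#'
#' @param gap_open Gap-open penalty (bits), `>= gap_extend`.
#' @param gap_extend Gap-extension penalty (bits), `>= 0`.
#' @return A list of class `align_params`.
#' @export
align_params <- function(gap_open = 3.0, gap_extend = 0.5) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 mode = "local"),
            class = "align_params")
}

new_alignment_result <- function(q_cols, t_cols, score) {
  structure(list(columns = tibble::tibble(q_pos = as.integer(q_cols),
                                          t_pos = as.integer(t_cols)),
                 score = score),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", nrow(x$columns), " columns, score ",
      format(x$score, digits = 6), " bits\n", sep = "")
  invisible(x)
}

#' Optimal gapped local alignment of two discretized chains
#'
#' Smith-Waterman / Gotoh dynamic programming over the per-residue pair
#' scores implied by the trained per-feature log-odds matrices, with affine
#' gap penalties. Returns the empty alignment with score 0 when no
#' positive-scoring local alignment exists. Traceback ties break preferring a
#' diagonal step, then a gap in the target, then a gap in the query.
#'
#' @param q_dfv,t_dfv [discretize_chain()] matrices for query and target.
#' @param matrices A [train_score_matrices()] result.
#' @param params An [align_params()].
#' @return An `alignment_result`: `columns` (tibble of aligned 1-based
#'   positions, strictly increasing in both coordinates) and `score` (bits).
#' @export
smith_waterman <- function(q_dfv, t_dfv, matrices, params = align_params()) {
  stopifnot(nrow(q_dfv) >= 1L, nrow(t_dfv) >= 1L,
            inherits(params, "align_params"))
  S <- pair_score_matrix(q_dfv, t_dfv, matrices)
  res <- gotoh_align(S, params$gap_open, params$gap_extend)
  new_alignment_result(res$q_cols, res$t_cols, res$score)
}

#' Re-evaluate an alignment score from its columns
#'
#' Independent evaluation of the gapped local alignment score: the sum of
#' pair scores over aligned columns minus `gap_open + (len - 1) * gap_extend`
#' for every internal run of unaligned residues in either chain. Used as the
#' invariant check for [smith_waterman()].
#'
#' @param a An `alignment_result` (or anything with a `columns` tibble).
#' @param q_dfv,t_dfv DFV matrices the alignment refers to.
#' @param matrices A [train_score_matrices()] result.
#' @param params An [align_params()].
#' @return Numeric score in bits.
#' @export
eval_alignment_score <- function(a, q_dfv, t_dfv, matrices,
                                 params = align_params()) {
  cols <- a$columns
  if (nrow(cols) == 0L) return(0)
  if (any(cols$q_pos < 1L) || any(cols$q_pos > nrow(q_dfv)) ||
      any(cols$t_pos < 1L) || any(cols$t_pos > nrow(t_dfv)))
    stop("alignment columns out of range", call. = FALSE)
  if (nrow(cols) > 1L &&
      (any(diff(cols$q_pos) <= 0L) || any(diff(cols$t_pos) <= 0L)))
    stop("alignment columns must be strictly increasing in both chains",
         call. = FALSE)
  S <- pair_score_matrix(q_dfv, t_dfv, matrices)
  match_sum <- sum(S[cbind(cols$q_pos, cols$t_pos)])
  gap_pen <- function(lens) {
    lens <- lens[lens > 0L]
    if (!length(lens)) 0 else
      sum(params$gap_open + (lens - 1L) * params$gap_extend)
  }
  pen <- gap_pen(diff(cols$q_pos) - 1L) + gap_pen(diff(cols$t_pos) - 1L)
  match_sum - pen
}

#' Gaps of an alignment
#'
#' Internal runs of unaligned residues between consecutive aligned columns,
#' reported per chain.
#' @param a An `alignment_result`.
#' @return Tibble with columns `chain` (`"q"`/`"t"`), `after_column`, `length`.
#' @export
alignment_gaps <- function(a) {
  cols <- a$columns
  if (nrow(cols) < 2L)
    return(tibble::tibble(chain = character(), after_column = integer(),
                          length = integer()))
  gq <- diff(cols$q_pos) - 1L
  gt <- diff(cols$t_pos) - 1L
  tibble::tibble(
    chain = c(rep("q", sum(gq > 0L)), rep("t", sum(gt > 0L))),
    after_column = c(which(gq > 0L), which(gt > 0L)),
    length = c(gq[gq > 0L], gt[gt > 0L]))
}

#' Alignment score of a chain against its own reversed copy
#'
#' Extracts and discretizes features for the chain and for its
#' coordinate-reversed copy (features are recomputed on the reversed
#' coordinates, not copied), then aligns the two. This reversed-alignment
#' score `s_rev` is the null-like correction entering the alignment-quality
#' statistic.
#'
#' @param q_chain A [chain_structure()].
#' @param tables A [train_tables()] bundle (alphabets, matrices, parameters).
#' @return Numeric score in bits (>= 0).
#' @export
reversed_score <- function(q_chain, tables) {
  stopifnot(inherits(tables, "staln_tables"))
  q_dfv <- discretize_chain(extract_features(q_chain, tables$feature_params),
                            tables$alphabets)
  r_chain <- reverse_chain(q_chain)
  r_dfv <- discretize_chain(extract_features(r_chain, tables$feature_params),
                            tables$alphabets)
  smith_waterman(q_dfv, r_dfv, tables$matrices, tables$align_params)$score
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `coords_t` onto `coords_q` over paired points, via the SVD of the
#' cross-covariance with the usual reflection guard (the returned rotation
#' always has determinant +1).
#'
#' @param coords_q,coords_t Numeric matrices of paired points (n x 3,
#'   n >= 3, not all collinear).
#' @return An object of class `superposition`: `rotation` (3 x 3),
#'   `translation` (length 3, so the transform is `R x + t`), and `rmsd`
#'   (Angstroms).
#' @export
kabsch_superpose <- function(coords_q, coords_t) {
  coords_q <- as.matrix(coords_q); coords_t <- as.matrix(coords_t)
  n <- nrow(coords_q)
  if (n != nrow(coords_t) || ncol(coords_q) != 3L || ncol(coords_t) != 3L)
    stop("coords_q and coords_t must be equal-size n x 3 matrices",
         call. = FALSE)
  if (n < 3L) stop("superposition needs at least 3 paired points", call. = FALSE)
  mu_q <- colMeans(coords_q); mu_t <- colMeans(coords_t)
  q0 <- sweep(coords_q, 2L, mu_q); t0 <- sweep(coords_t, 2L, mu_t)
  if (svd(q0)$d[2L] < 1e-8 || svd(t0)$d[2L] < 1e-8)
    stop("degenerate (collinear) point configuration", call. = FALSE)
  H <- crossprod(t0, q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- t0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - q0)^2)))
  trans <- as.numeric(mu_q - R %*% mu_t)
  structure(list(rotation = R, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd", format(x$rmsd, digits = 4), "A\n")
  invisible(x)
}
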