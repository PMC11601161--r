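#' Accumulate symmetrized aligned-letter pair counts for one feature
#'
#' Walks reference alignments and counts the letter pair of every aligned
#' column for the given feature; both orders are counted so the count matrix
#' is symmetric and its total is twice the number of aligned columns. Gap
#' columns never appear (alignments are given as aligned index pairs).
#'
#' @param alignments List of entries `list(q, t, pairs)` where `q` and `t` are
#'   [discretize_chain()] matrices and `pairs` is a two-column table of
#'   aligned 1-based positions (query, target).
#' @param feature Feature name (a column of the DFV matrices).
#' @param L Alphabet size for the feature.
#' @return An object of class `pair_counts` with the `L x L` `joint` count
#'   matrix.
#' @export
accumulate_counts <- function(alignments, feature, L) {
  stopifnot(length(alignments) > 0L, L >= 2L)
  joint <- matrix(0, L, L)
  for (al in alignments) {
    pr <- as.matrix(al$pairs)
    iq <- al$q[pr[, 1L], feature]
    jt <- al$t[pr[, 2L], feature]
    if (any(iq < 1L | iq > L | jt < 1L | jt > L))
      stop("letter out of range [1, ", L, "] for feature '", feature, "'",
           call. = FALSE)
    tab <- tabulate((jt - 1L) * L + iq, nbins = L * L)
    joint <- joint + matrix(tab, L, L)
  }
  joint <- joint + t(joint)
  structure(list(feature_name = feature, joint = joint),
            class = "pair_counts")
}

#' Train a log-odds score matrix from pair counts
#'
#' Estimates the joint aligned-pair frequencies `P[i, j]` and letter
#' frequencies `p[i]` from the (pseudocount-smoothed) counts, and returns the
#' matrix of log-odds scores `log2(P[i, j] / (p[i] p[j]))` in bits. If the
#' counts factorize into their marginals the matrix is identically zero.
#'
#' @param c A [accumulate_counts()] result.
#' @param pseudocount Added to every joint cell before normalizing (default
#'   0.5); guarantees finite scores when rare letter pairs are unobserved.
#' @param weight Relative weight of this feature in the pair score.
#' @return An object of class `score_matrix` (fields `feature_name`, `size`,
#'   `matrix` in bits, `weight`).
#' @export
train_logodds <- function(c, pseudocount = 0.5, weight = 1.0) {
  stopifnot(inherits(c, "pair_counts"), pseudocount >= 0, weight >= 0)
  joint <- c$joint + pseudocount
  total <- sum(joint)
  if (total <= 0) stop("no aligned pair counts for feature '",
                       c$feature_name, "'", call. = FALSE)
  P <- joint / total
  p <- rowSums(P)
  if (any(p <= 0))
    stop("zero-frequency letter for feature '", c$feature_name,
         "'; increase the pseudocount", call. = FALSE)
  M <- log2(P / outer(p, p))
  M <- (M + t(M)) / 2  # numerically exact symmetry
  structure(list(feature_name = c$feature_name, size = nrow(M),
                 matrix = M, weight = weight),
            class = "score_matrix")
}

#' Score one aligned residue pair
#'
#' The weighted sum over features of the per-feature log-odds score of the
#' two residues' letters; symmetric in its arguments.
#'
#' @param u,v Single DFV rows (named integer vectors or 1-row matrices).
#' @param matrices A [train_score_matrices()] result (or its `matrices`
#'   list).
#' @return Numeric score in bits.
#' @export
pair_score <- function(u, v, matrices) {
  ms <- if (inherits(matrices, "score_matrix_set")) matrices$matrices else matrices
  u <- drop_dfv_row(u); v <- drop_dfv_row(v)
  s <- 0
  for (m in ms) {
    f <- m$feature_name
    if (!f %in% names(u) || !f %in% names(v))
      stop("DFV is missing feature '", f, "'", call. = FALSE)
    if (u[[f]] > m$size || v[[f]] > m$size)
      stop("letter out of range for feature '", f, "'", call. = FALSE)
    s <- s + m$weight * m$matrix[u[[f]], v[[f]]]
  }
  s
}

drop_dfv_row <- function(u) {
  if (is.matrix(u)) stats::setNames(as.integer(u[1L, ]), colnames(u)) else u
}

#' Size of the factored mega-alphabet
#'
#' The Cartesian product of the per-feature alphabets: `h = prod(A_f)`. With
#' the default configuration (20 amino-acid letters and eight 16-letter
#' structural features) this is `20 * 16^8 = 85,899,345,920` states.
#'
#' @param alphabet_sizes Vector of per-feature alphabet sizes (all >= 1).
#' @return The exact product as a double (exact below 2^53).
#' @export
#' @examples
#' mega_alphabet_size(c(20, rep(16, 8)))
mega_alphabet_size <- function(alphabet_sizes) {
  if (length(alphabet_sizes) == 0L)
    stop("empty alphabet size list", call. = FALSE)
  sizes <- as.numeric(alphabet_sizes)
  stopifnot(all(sizes >= 1))
  prod(sizes)
}

#' Train log-odds matrices for every configured feature
#'
#' @param alignments As in [accumulate_counts()].
#' @param aset An [train_alphabets()] result (provides sizes and order).
#' @param pseudocount Smoothing added to every joint cell.
#' @param weights Optional named numeric vector of per-feature weights
#'   (default 1 for every feature).
#' @return An object of class `score_matrix_set`.
#' @export
train_score_matrices <- function(alignments, aset, pseudocount = 0.5,
                                 weights = NULL) {
  stopifnot(inherits(aset, "alphabet_set"))
  w <- stats::setNames(rep(1.0, length(aset$feature_order)), aset$feature_order)
  if (!is.null(weights)) w[names(weights)] <- weights
  mats <- lapply(aset$feature_order, function(f) {
    cnt <- accumulate_counts(alignments, f, aset$sizes[[f]])
    train_logodds(cnt, pseudocount = pseudocount, weight = w[[f]])
  })
  names(mats) <- aset$feature_order
  structure(list(feature_order = aset$feature_order, matrices = mats,
                 pseudocount = pseudocount),
            class = "score_matrix_set")
}

#' @export
print.score_matrix_set <- function(x, ...) {
  cat("<score_matrix_set>", length(x$matrices), "feature matrices:",
      paste(x$feature_order, collapse = ", "), "\n")
  invisible(x)
}

# n x m matrix of pair scores between two discretized chains
pair_score_matrix <- function(q_dfv, t_dfv, matrices) {
  ms <- if (inherits(matrices, "score_matrix_set")) matrices$matrices else matrices
  S <- matrix(0, nrow(q_dfv), nrow(t_dfv))
  for (m in ms) {
    f <- m$feature_name
    if (!f %in% colnames(q_dfv) || !f %in% colnames(t_dfv))
      stop("DFV is missing feature '", f, "'", call. = FALSE)
    qv <- q_dfv[, f]; tv <- t_dfv[, f]
    if (max(qv, tv) > m$size || min(qv, tv) < 1L)
      stop("letter out of range for feature '", f, "'", call. = FALSE)
    if (m$weight != 0)
      S <- S + m$weight * m$matrix[qv, tv, drop = FALSE]
  }
  S
}
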