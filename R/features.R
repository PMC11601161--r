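#' Feature-extraction parameters
#'
#' @param kappa Half-width of the local-conformation window; the window spans
#'   `2 * kappa + 1` residues. Default 3.
#' @param min_chain_sep Minimum chain separation `|i - j|` for a residue `j`
#'   to count as a Euclidean neighbour of `i` (default 2; immediate chain
#'   neighbours are trivially near in space and carry no signal).
#' @param offset_clip Maximum absolute chain offset recorded for the
#'   nearest/reverse Euclidean neighbour; larger offsets are clipped (default
#'   32).
#' @param sentinel_dist Distance (Angstroms) recorded when a residue has no
#'   eligible neighbour (default 20).
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(kappa = 3L, min_chain_sep = 2L, offset_clip = 32L,
                           sentinel_dist = 20.0) {
  stopifnot(kappa >= 1, min_chain_sep >= 1, offset_clip >= min_chain_sep,
            sentinel_dist > 0)
  structure(list(kappa = as.integer(kappa),
                 min_chain_sep = as.integer(min_chain_sep),
                 offset_clip = as.integer(offset_clip),
                 sentinel_dist = sentinel_dist),
            class = "feature_params")
}

# eligibility-masked squared-distance matrix: entries with |i-j| < sep are Inf
eligible_dist <- function(xyz, sep) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  off <- abs(outer(seq_len(n), seq_len(n), `-`))
  d[off < sep] <- Inf
  d
}

#' Nearest Euclidean neighbour of a residue
#'
#' Returns the index `j` minimizing the C-alpha distance to residue `i`
#' subject to the chain-separation constraint `|i - j| >= min_chain_sep`;
#' ties break toward smaller `j`.
#'
#' @param s A [chain_structure()].
#' @param i 1-based residue index.
#' @param p A [feature_params()].
#' @return Integer index, or `NA` if no residue is eligible.
#' @export
find_nen <- function(s, i, p = feature_params()) {
  check_index(s, i)
  d <- eligible_dist(s$xyz, p$min_chain_sep)[i, ]
  if (all(is.infinite(d))) return(NA_integer_)
  as.integer(unname(which.min(d)))
}

#' Reverse Euclidean neighbour of a residue
#'
#' The nearest eligible neighbour on the opposite chain side of `i` from its
#' nearest Euclidean neighbour: if `nen > i` the search is over
#' `j <= i - min_chain_sep`, otherwise over `j >= i + min_chain_sep`.
#'
#' @inheritParams find_nen
#' @param nen The index returned by [find_nen()] for `(s, i)`.
#' @return Integer index, or `NA` if that side of the chain is empty.
#' @export
find_ren <- function(s, i, nen, p = feature_params()) {
  check_index(s, i)
  if (is.na(nen)) return(NA_integer_)
  d <- eligible_dist(s$xyz, p$min_chain_sep)[i, ]
  j <- seq_len(s$length)
  side <- if (nen > i) j < i else j > i
  d[!side] <- Inf
  if (all(is.infinite(d))) return(NA_integer_)
  as.integer(unname(which.min(d)))
}

check_index <- function(s, i) {
  stopifnot(inherits(s, "chain_structure"))
  if (length(i) != 1L || i < 1L || i > s$length)
    stop("residue index out of range: ", i, call. = FALSE)
}

# Mirror-reflect an index vector into 1..n (reflection across the termini),
# so terminal windows stay full-dimensional.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  repeat {
    below <- idx < 1L
    above <- idx > n
    if (!any(below) && !any(above)) return(idx)
    idx[below] <- 2L - idx[below]
    idx[above] <- 2L * n - idx[above]
  }
}

# window-slot pairs (a, b), a < b, excluding adjacent slots, lexicographic
conf_pairs <- function(kappa) {
  w <- 2L * kappa + 1L
  pr <- utils::combn(w, 2L)
  pr[, pr[2L, ] - pr[1L, ] >= 2L, drop = FALSE]
}

#' Local-conformation window distances at a residue
#'
#' All-vs-all pairwise C-alpha distances among the `2 * kappa + 1` positions
#' centred at `i`, excluding the `2 * kappa` adjacent pairs (whose spacing is
#' effectively constant). Windows overhanging a terminus are mirror-padded so
#' every residue yields a vector of the same dimension
#' `choose(2 * kappa + 1, 2) - 2 * kappa`.
#'
#' @inheritParams find_nen
#' @param kappa Window half-width.
#' @return Numeric vector of distances (Angstroms), pairs in lexicographic
#'   window-slot order.
#' @export
conf_window <- function(s, i, kappa = 3L) {
  check_index(s, i)
  if (s$length < 2L) stop("conf_window needs a chain of length >= 2", call. = FALSE)
  idx <- reflect_index(i + seq(-kappa, kappa), s$length)
  pts <- s$xyz[idx, , drop = FALSE]
  pr <- conf_pairs(kappa)
  sqrt(rowSums((pts[pr[1L, ], , drop = FALSE] - pts[pr[2L, ], , drop = FALSE])^2))
}

#' Per-residue feature vectors of a chain
#'
#' Computes, for every residue: the amino acid; the nearest Euclidean
#' neighbour (NEN) and reverse Euclidean neighbour (REN) with their distances
#' and clipped signed chain offsets; the distance to the second-nearest
#' eligible neighbour; and the local-conformation window distances at the
#' residue, its NEN and its REN. When a residue has no eligible NEN or REN,
#' the sentinel distance is recorded, the offset is set to `offset_clip`, and
#' the residue's own window stands in for the missing context window.
#'
#' @param s A [chain_structure()] of length at least 2.
#' @param p A [feature_params()].
#' @return A tibble with one row per residue: columns `idx`, `aa`,
#'   `nen_index`, `ren_index`, `dist_nen`, `dist_ren`, `dist_n2`,
#'   `nen_offset`, `ren_offset`, and list-columns `conf_self`, `conf_nen`,
#'   `conf_ren`.
#' @export
extract_features <- function(s, p = feature_params()) {
  stopifnot(inherits(s, "chain_structure"))
  if (s$length < 2L) stop("feature extraction needs a chain of length >= 2",
                          call. = FALSE)
  n <- s$length
  d <- eligible_dist(s$xyz, p$min_chain_sep)
  j_seq <- seq_len(n)

  nen <- integer(n); ren <- integer(n)
  dist_nen <- numeric(n); dist_ren <- numeric(n); dist_n2 <- numeric(n)
  for (i in j_seq) {
    di <- d[i, ]
    if (all(is.infinite(di))) {
      nen[i] <- NA_integer_
      dist_nen[i] <- p$sentinel_dist
      dist_n2[i] <- p$sentinel_dist
    } else {
      nen[i] <- as.integer(unname(which.min(di)))
      dist_nen[i] <- di[nen[i]]
      d2 <- di; d2[nen[i]] <- Inf
      dist_n2[i] <- if (all(is.infinite(d2))) p$sentinel_dist else min(d2)
    }
    if (is.na(nen[i])) {
      ren[i] <- NA_integer_
      dist_ren[i] <- p$sentinel_dist
    } else {
      side <- if (nen[i] > i) j_seq < i else j_seq > i
      dr <- d[i, ]
      dr[!side] <- Inf
      if (all(is.infinite(dr))) {
        ren[i] <- NA_integer_
        dist_ren[i] <- p$sentinel_dist
      } else {
        ren[i] <- as.integer(unname(which.min(dr)))
        dist_ren[i] <- dr[ren[i]]
      }
    }
  }
  clip <- function(x) pmin(pmax(x, -p$offset_clip), p$offset_clip)
  nen_offset <- ifelse(is.na(nen), p$offset_clip, clip(nen - j_seq))
  ren_offset <- ifelse(is.na(ren), p$offset_clip, clip(ren - j_seq))

  conf_self <- lapply(j_seq, function(i) conf_window(s, i, p$kappa))
  conf_at <- function(ctx, i) if (is.na(ctx)) conf_self[[i]] else conf_self[[ctx]]
  conf_nen <- lapply(j_seq, function(i) conf_at(nen[i], i))
  conf_ren <- lapply(j_seq, function(i) conf_at(ren[i], i))

  tibble::tibble(idx = j_seq, aa = s$aa,
                 nen_index = nen, ren_index = ren,
                 dist_nen = dist_nen, dist_ren = dist_ren, dist_n2 = dist_n2,
                 nen_offset = as.numeric(nen_offset),
                 ren_offset = as.numeric(ren_offset),
                 conf_self = conf_self, conf_nen = conf_nen,
                 conf_ren = conf_ren)
}

#' Canonical feature order of the discrete feature vector
#'
#' The amino acid plus the eight structural features, in the fixed order used
#' for alphabets, matrices and serialization.
#' @return Character vector of feature names.
#' @export
feature_order <- function() {
  c("aa", "conf_self", "conf_nen", "conf_ren",
    "dist_nen", "dist_ren", "nen_offset", "ren_offset", "dist_n2")
}

scalar_feature_names <- function() {
  c("dist_nen", "dist_ren", "nen_offset", "ren_offset", "dist_n2")
}

vector_feature_names <- function() {
  c("conf_self", "conf_nen", "conf_ren")
}
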