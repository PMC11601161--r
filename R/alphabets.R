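#' Train an equal-frequency alphabet for a scalar feature
#'
#' Sorts the training values and divides them into `L` contiguous bins of
#' equal size (sizes differ by at most one when the count is not divisible by
#' `L`); the threshold between bin `B` and `B + 1` is the mean of the maximum
#' of bin `B` and the minimum of bin `B + 1`. Equal-frequency bins maximize
#' the entropy of the alphabet. When ties in the data collapse thresholds,
#' the same rule is re-applied to the distinct values, trading exact
#' equal-frequency for strictly increasing thresholds.
#'
#' @param values Numeric training values (finite), at least `L` of them.
#' @param L Alphabet size (>= 2).
#' @param feature_name Name stored with the alphabet.
#' @return An object of class `scalar_alphabet` with fields `feature_name`,
#'   `size` and `thresholds` (`L - 1` strictly increasing reals).
#' @export
#' @examples
#' train_scalar_alphabet(1:8, 4)$thresholds  # 2.5 4.5 6.5
train_scalar_alphabet <- function(values, L, feature_name = "scalar") {
  values <- as.numeric(values)
  L <- as.integer(L)
  stopifnot(L >= 2L, length(values) >= L, all(is.finite(values)))
  if (length(unique(values)) < L)
    stop("degenerate alphabet: fewer than ", L, " distinct training values ",
         "for feature '", feature_name, "'", call. = FALSE)
  thr <- equal_bin_thresholds(sort(values), L)
  if (any(diff(thr) <= 0)) # heavy ties: rebuild from distinct values
    thr <- equal_bin_thresholds(sort(unique(values)), L)
  structure(list(feature_name = feature_name, size = L, thresholds = thr),
            class = "scalar_alphabet")
}

equal_bin_thresholds <- function(sorted, L) {
  n <- length(sorted)
  sizes <- rep(n %/% L, L)
  rem <- n %% L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  cut <- cumsum(sizes)[-L]
  (sorted[cut] + sorted[cut + 1L]) / 2
}

#' Assign a scalar value to its alphabet letter
#'
#' The letter is the lowest bin whose threshold the value exceeds: with
#' 1-based letters, `1 + #\{thresholds strictly below x\}`. A value exactly on
#' a threshold falls in the lower bin.
#'
#' @param x Numeric value(s), finite.
#' @param a A [train_scalar_alphabet()] result.
#' @return Integer letter(s) in `[1, L]`.
#' @export
assign_scalar_letter <- function(x, a) {
  stopifnot(inherits(a, "scalar_alphabet"))
  if (any(!is.finite(x)))
    stop("non-finite value for scalar feature '", a$feature_name, "'",
         call. = FALSE)
  if (length(x) == 1L) return(1L + sum(a$thresholds < x))
  1L + as.integer(rowSums(outer(x, a$thresholds, `>`)))
}

#' Train a K-means centroid alphabet for a vector feature
#'
#' Clusters the training vectors into `K` centroids with seeded K-means
#' (Hartigan-Wong, 10 restarts, 300 iterations); letters are later assigned
#' by nearest centroid. Deterministic given `seed`.
#'
#' @param vectors Numeric matrix, one training vector per row.
#' @param K Alphabet size (>= 2).
#' @param seed Integer seed.
#' @param feature_name Name stored with the alphabet.
#' @return An object of class `vector_alphabet` with a `K x d` `centroids`
#'   matrix.
#' @export
train_vector_alphabet <- function(vectors, K, seed = 1L,
                                  feature_name = "vector") {
  vectors <- as.matrix(vectors)
  K <- as.integer(K)
  stopifnot(K >= 2L, nrow(vectors) >= K, all(is.finite(vectors)))
  if (nrow(vectors) == K) {  # exact solution: every point is its own centroid
    if (anyDuplicated(vectors))
      stop("K-means failed for feature '", feature_name,
           "': duplicated training vectors with K equal to the sample size",
           call. = FALSE)
    return(structure(list(feature_name = feature_name, size = K,
                          centroids = unname(vectors)),
                     class = "vector_alphabet"))
  }
  fit <- with_seed(seed, {
    for (attempt in 1:5) {
      res <- tryCatch(stats::kmeans(vectors, centers = K, nstart = 10L,
                                    iter.max = 300L),
                      error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop("K-means failed for feature '", feature_name, "'", call. = FALSE)
    res
  })
  cen <- unname(fit$centers)
  structure(list(feature_name = feature_name, size = K, centroids = cen),
            class = "vector_alphabet")
}

#' Assign a feature vector to its nearest-centroid letter
#'
#' @param v Numeric vector (or matrix of row vectors) matching the centroid
#'   dimension.
#' @param a A [train_vector_alphabet()] result.
#' @return Integer letter(s) in `[1, K]`; Euclidean nearest centroid, ties to
#'   the smallest index.
#' @export
assign_vector_letter <- function(v, a) {
  stopifnot(inherits(a, "vector_alphabet"))
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (ncol(V) != ncol(a$centroids))
    stop("vector dimension ", ncol(V), " does not match centroid dimension ",
         ncol(a$centroids), " for feature '", a$feature_name, "'",
         call. = FALSE)
  d2 <- outer(rowSums(V^2), rep(1, nrow(a$centroids))) +
    outer(rep(1, nrow(V)), rowSums(a$centroids^2)) -
    2 * V %*% t(a$centroids)
  out <- max.col(-d2, ties.method = "first")
  if (!is.matrix(v)) out[[1L]] else out
}

#' Train the full alphabet set from chains
#'
#' Extracts features from every chain and trains one alphabet per configured
#' feature: equal-frequency bins for the scalar features, K-means centroids
#' for the local-conformation window features. The amino-acid feature keeps
#' the fixed 20-letter alphabet. Sentinel values injected for residues with
#' no eligible neighbour participate in training, so their letters are
#' well-defined at assignment time.
#'
#' @param chains List of [chain_structure()] (or a list of precomputed
#'   feature tibbles via `features`).
#' @param sizes Named integer vector of alphabet sizes for structural
#'   features; default 16 for all eight.
#' @param p A [feature_params()].
#' @param seed Integer seed for K-means.
#' @param features Optional list of precomputed [extract_features()] tibbles.
#' @return An object of class `alphabet_set`.
#' @export
train_alphabets <- function(chains, sizes = NULL, p = feature_params(),
                            seed = 1L, features = NULL) {
  if (is.null(features))
    features <- lapply(chains, extract_features, p = p)
  structural <- setdiff(feature_order(), "aa")
  def <- stats::setNames(rep(16L, length(structural)), structural)
  if (!is.null(sizes)) def[names(sizes)] <- as.integer(sizes)
  alphabets <- list()
  for (f in scalar_feature_names()) {
    vals <- unlist(lapply(features, function(ft) ft[[f]]))
    alphabets[[f]] <- train_scalar_alphabet(vals, def[[f]], feature_name = f)
  }
  for (f in vector_feature_names()) {
    mat <- do.call(rbind, lapply(features, function(ft) do.call(rbind, ft[[f]])))
    alphabets[[f]] <- train_vector_alphabet(mat, def[[f]], seed = seed,
                                            feature_name = f)
  }
  structure(list(feature_order = feature_order(),
                 sizes = c(aa = 20L, def[structural]),
                 alphabets = alphabets,
                 feature_params = p,
                 seed = as.integer(seed)),
            class = "alphabet_set")
}

#' @export
print.alphabet_set <- function(x, ...) {
  cat("<alphabet_set> features:", paste(x$feature_order, collapse = ", "), "\n")
  cat("  sizes:", paste(x$sizes, collapse = " x "),
      "=> mega-alphabet", format(mega_alphabet_size(x$sizes), big.mark = ","),
      "states\n")
  invisible(x)
}

#' Condense per-residue features into discrete feature vectors
#'
#' Maps every residue's feature vector to its per-feature letters: the
#' amino acid by the fixed alphabetical table (A = 1 ... Y = 20, `X` mapped
#' to letter 1 with a warning), scalars by threshold comparison, vectors by
#' nearest centroid. The row of letters is the residue's mega-letter.
#'
#' @param features An [extract_features()] tibble.
#' @param aset An [train_alphabets()] result.
#' @return Integer matrix, one row per residue, one column per feature in
#'   canonical order; entry `[i, f]` lies in `[1, A_f]`.
#' @export
discretize_chain <- function(features, aset) {
  stopifnot(inherits(aset, "alphabet_set"))
  n <- nrow(features)
  out <- matrix(NA_integer_, n, length(aset$feature_order),
                dimnames = list(NULL, aset$feature_order))
  aa_idx <- match(features$aa, AA_LETTERS)
  if (anyNA(aa_idx)) {
    warning(sum(is.na(aa_idx)), " residue(s) with letter 'X' assigned to the ",
            "'A' slot of the amino-acid alphabet")
    aa_idx[is.na(aa_idx)] <- 1L
  }
  out[, "aa"] <- aa_idx
  for (f in scalar_feature_names()) {
    a <- aset$alphabets[[f]]
    if (is.null(a)) stop("no trained alphabet for feature '", f, "'",
                         call. = FALSE)
    out[, f] <- assign_scalar_letter(features[[f]], a)
  }
  for (f in vector_feature_names()) {
    a <- aset$alphabets[[f]]
    if (is.null(a)) stop("no trained alphabet for feature '", f, "'",
                         call. = FALSE)
    out[, f] <- assign_vector_letter(do.call(rbind, features[[f]]), a)
  }
  out
}

#' Write or read an alphabet set as JSON
#'
#' @param aset An `alphabet_set`.
#' @param path JSON file path.
#' @return `read_alphabets()` returns the `alphabet_set`; `write_alphabets()`
#'   returns `path` invisibly.
#' @export
write_alphabets <- function(aset, path) {
  stopifnot(inherits(aset, "alphabet_set"))
  payload <- list(
    feature_order = aset$feature_order,
    sizes = as.list(aset$sizes),
    feature_params = unclass(aset$feature_params),
    seed = aset$seed,
    alphabets = lapply(aset$alphabets, function(a) {
      if (inherits(a, "scalar_alphabet"))
        list(type = "scalar", feature_name = a$feature_name, size = a$size,
             thresholds = a$thresholds)
      else
        list(type = "vector", feature_name = a$feature_name, size = a$size,
             centroids = a$centroids)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_alphabets
#' @export
read_alphabets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  alphabets <- lapply(raw$alphabets, function(a) {
    if (a$type == "scalar")
      structure(list(feature_name = a$feature_name, size = as.integer(a$size),
                     thresholds = as.numeric(a$thresholds)),
                class = "scalar_alphabet")
    else
      structure(list(feature_name = a$feature_name, size = as.integer(a$size),
                     centroids = as.matrix(a$centroids)),
                class = "vector_alphabet")
  })
  fp <- raw$feature_params
  structure(list(feature_order = raw$feature_order,
                 sizes = unlist(raw$sizes),
                 alphabets = alphabets,
                 feature_params = feature_params(fp$kappa, fp$min_chain_sep,
                                                 fp$offset_clip, fp$sentinel_dist),
                 seed = as.integer(raw$seed)),
            class = "alphabet_set")
}
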