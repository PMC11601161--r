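#' Simulation parameters
#'
#' Parameters for the synthetic-backbone generator. Synthetic chains are
#' idealized C-alpha traces (helix / strand / coil segments with ~3.8 A
#' consecutive spacing); homologs are derived from a founder by single-residue
#' indels, amino-acid substitutions and isotropic coordinate jitter. These
#' defaults define the study conditions used throughout the package's tests
#' and calibration.
#'
#' @param seed Integer seed; all randomness of a generator call flows from it.
#' @param n_residues Target chain length when `segment_spec` is `NULL`.
#' @param noise_sigma Standard deviation (Angstroms) of isotropic coordinate
#'   jitter applied to derived homologs.
#' @param indel_rate Per-residue probability of an insertion or deletion when
#'   deriving a homolog; must be below 0.5.
#' @param sub_rate Per-residue probability of an amino-acid substitution when
#'   deriving a homolog.
#' @param segment_spec Optional list of `c(kind, length)` pairs, kind one of
#'   `"helix"`, `"strand"`, `"coil"`; e.g. `list(c("helix", 12), c("coil", 4))`.
#'   When `NULL`, a random segment layout totalling about `n_residues` is drawn.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_residues = 60L, noise_sigma = 0.5,
                       indel_rate = 0.05, sub_rate = 0.05,
                       segment_spec = NULL) {
  stopifnot(noise_sigma >= 0, indel_rate >= 0, indel_rate < 0.5,
            sub_rate >= 0, sub_rate <= 1, n_residues >= 1)
  if (!is.null(segment_spec)) {
    for (seg in segment_spec) {
      kind <- seg[[1L]]
      len <- as.integer(seg[[2L]])
      if (!kind %in% c("helix", "strand", "coil") || len < 1L)
        stop("segment_spec entries must be (helix|strand|coil, length >= 1)",
             call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_residues = as.integer(n_residues),
                 noise_sigma = noise_sigma, indel_rate = indel_rate,
                 sub_rate = sub_rate, segment_spec = segment_spec),
            class = "sim_params")
}

# Run expr with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

runit <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

rand_rotation <- function() {
  # rotation from a random quaternion
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

CA_STEP <- 3.8      # canonical consecutive C-alpha spacing, Angstroms
MIN_CLEARANCE <- 3.0 # self-avoidance radius for coil placement, Angstroms

helix_template <- function(len) {
  k <- seq_len(len) - 1L
  th <- k * 100 * pi / 180  # ~100 degrees turn per residue
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * k)
}

strand_template <- function(len) {
  k <- seq_len(len) - 1L
  cbind(3.3 * k, 0.95 * (-1)^k, 0)  # near-extended zig-zag, 3.3 A rise
}

min_dist_to <- function(coords, p) {
  if (is.null(coords) || nrow(coords) == 0L) return(Inf)
  sqrt(min(rowSums((coords - matrix(p, nrow(coords), 3L, byrow = TRUE))^2)))
}

# Append a rigid segment template after existing coordinates, choosing a
# random orientation that keeps every new point >= MIN_CLEARANCE from the
# existing trace (the 3.8 A junction pair is exempt).
attach_segment <- function(coords, tpl, retries = 80L) {
  if (is.null(coords)) {
    rot <- rand_rotation()
    return(tpl %*% t(rot))
  }
  prev <- coords[nrow(coords), ]
  prior <- coords[-nrow(coords), , drop = FALSE]
  for (r in seq_len(retries)) {
    rot <- rand_rotation()
    seg <- sweep(tpl, 2L, tpl[1L, ]) %*% t(rot)
    # centroid pull anneals to 0 so crowded folds can still be completed
    pull <- if (r <= retries %/% 2L) 0.7 else 0
    start <- prev + CA_STEP * compact_dir(coords, prev, pull)
    seg <- sweep(seg, 2L, start, `+`)
    d_prior <- if (nrow(prior) == 0L) Inf else
      min(proxy_min_dists(seg, prior))
    d_prev <- if (nrow(seg) > 1L)
      min(sqrt(rowSums((seg[-1L, , drop = FALSE] -
                          matrix(prev, nrow(seg) - 1L, 3L, byrow = TRUE))^2)))
    else Inf
    if (d_prior >= MIN_CLEARANCE && d_prev >= MIN_CLEARANCE)
      return(rbind(coords, seg))
  }
  stop("chain generation failed: could not place a segment without clashes",
       call. = FALSE)
}

# random unit direction biased back toward the centroid of the trace so far,
# so chains fold into compact globules with genuine tertiary contacts
compact_dir <- function(coords, prev, pull = 0.7) {
  u <- runit()
  if (pull <= 0 || is.null(coords) || nrow(coords) < 8L) return(u)
  towards <- colMeans(coords) - prev
  nt <- sqrt(sum(towards^2))
  if (nt < 1e-8) return(u)
  v <- u + pull * towards / nt
  v / sqrt(sum(v^2))
}

proxy_min_dists <- function(a, b) {
  # per-row minimum Euclidean distance from rows of a to rows of b
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

coil_extend <- function(coords, len, retries = 120L) {
  for (k in seq_len(len)) {
    if (is.null(coords)) {  # chain starts with a coil: seed it at the origin
      coords <- matrix(c(0, 0, 0), 1L, 3L)
      next
    }
    prev <- coords[nrow(coords), ]
    placed <- FALSE
    for (r in seq_len(retries)) {
      pull <- if (r <= retries %/% 2L) 0.7 else 0
      p <- prev + CA_STEP * compact_dir(coords, prev, pull)
      others <- if (is.null(coords)) NULL else coords[-nrow(coords), , drop = FALSE]
      if (is.null(others) || nrow(others) == 0L ||
          min_dist_to(others, p) >= MIN_CLEARANCE) {
        coords <- rbind(coords, p)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("chain generation failed: self-avoiding coil placement exhausted retries",
           call. = FALSE)
  }
  coords
}

random_segment_spec <- function(n_target) {
  spec <- list()
  total <- 0L
  while (total < n_target) {
    kind <- sample(c("helix", "strand", "coil"), 1L, prob = c(0.4, 0.3, 0.3))
    len <- switch(kind,
                  helix = sample(8:14, 1L),
                  strand = sample(5:10, 1L),
                  coil = sample(3:6, 1L))
    len <- min(len, n_target - total)
    if (len >= 1L) spec[[length(spec) + 1L]] <- list(kind, len)
    total <- total + len
  }
  spec
}

synth_chain_impl <- function(p, id = "synth", restarts = 10L) {
  spec <- p$segment_spec %||% random_segment_spec(p$n_residues)
  build <- function() {
    coords <- NULL
    for (seg in spec) {
      kind <- seg[[1L]]
      len <- as.integer(seg[[2L]])
      coords <- switch(kind,
                       helix = attach_segment(coords, helix_template(len)),
                       strand = attach_segment(coords, strand_template(len)),
                       coil = coil_extend(coords, len))
    }
    coords
  }
  coords <- NULL
  for (r in seq_len(restarts)) {  # bounded whole-chain restarts
    coords <- tryCatch(build(), error = function(e) NULL)
    if (!is.null(coords)) break
  }
  if (is.null(coords))
    stop("chain generation failed: self-avoiding placement exhausted retries",
         call. = FALSE)
  n <- nrow(coords)
  if (p$noise_sigma > 0)
    coords <- coords + matrix(stats::rnorm(3L * n, sd = p$noise_sigma), n, 3L)
  aa <- sample(AA_LETTERS, n, replace = TRUE)
  chain_structure(id, aa, coords)
}

#' Generate a synthetic C-alpha backbone
#'
#' Builds an idealized backbone from helix, strand and coil segments:
#' helices use ~100 degrees turn per residue, 1.5 A rise and 2.3 A radius;
#' strands are a near-extended 3.3 A-rise zig-zag; coils are self-avoiding
#' random walks with a fixed 3.8 A step. Consecutive C-alpha spacing is
#' 3.8 +/- 0.1 A before jitter. Deterministic given `p$seed`.
#'
#' @param p A [sim_params()] object.
#' @param id Identifier for the generated chain.
#' @return A [chain_structure()].
#' @export
#' @examples
#' ch <- synth_chain(sim_params(seed = 7, segment_spec = list(c("helix", 12))))
#' ch$length
synth_chain <- function(p, id = "synth") {
  stopifnot(inherits(p, "sim_params"))
  with_seed(p$seed, synth_chain_impl(p, id))
}

derive_homolog_impl <- function(s, p, id = paste0(s$id, "_hom")) {
  n <- s$length
  new_xyz <- list()
  new_aa <- character(0)
  truth_q <- integer(0)  # position in the founder
  truth_t <- integer(0)  # position in the derived homolog
  pos <- 0L
  for (i in seq_len(n)) {
    ev <- stats::runif(1L)
    if (p$indel_rate > 0 && ev < p$indel_rate) {
      if (stats::runif(1L) < 0.5) next  # deletion: residue i dropped
      # insertion: a perturbed midpoint precedes residue i
      anchor <- if (i == 1L) s$xyz[1L, ] - c(CA_STEP, 0, 0) else s$xyz[i - 1L, ]
      mid <- (anchor + s$xyz[i, ]) / 2 + stats::rnorm(3L, sd = 0.5)
      pos <- pos + 1L
      new_xyz[[pos]] <- mid
      new_aa[pos] <- sample(AA_LETTERS, 1L)
    }
    pos <- pos + 1L
    new_xyz[[pos]] <- s$xyz[i, ]
    aa_i <- s$aa[i]
    if (p$sub_rate > 0 && stats::runif(1L) < p$sub_rate)
      aa_i <- sample(AA_LETTERS, 1L)
    new_aa[pos] <- aa_i
    truth_q <- c(truth_q, i)
    truth_t <- c(truth_t, pos)
  }
  xyz <- do.call(rbind, new_xyz)
  if (p$noise_sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(3L * nrow(xyz), sd = p$noise_sigma),
                        nrow(xyz), 3L)
  list(chain = chain_structure(id, new_aa, xyz),
       true_alignment = tibble::tibble(q_pos = truth_q, t_pos = truth_t))
}

#' Derive a homolog from a chain with known residue correspondence
#'
#' Applies single-residue insertions/deletions, amino-acid substitutions and
#' isotropic coordinate jitter to a chain, returning the mutated copy together
#' with the ground-truth residue correspondence (1-based positions in the
#' original and derived chain). The correspondence is what log-odds matrix
#' training and alignment-recovery tests consume.
#'
#' @param s Founder [chain_structure()].
#' @param p A [sim_params()]; `noise_sigma`, `indel_rate`, `sub_rate` and
#'   `seed` are used.
#' @param id Identifier for the derived chain.
#' @return List with `chain` (the homolog) and `true_alignment` (a tibble of
#'   `q_pos`, `t_pos` aligned index pairs).
#' @export
derive_homolog <- function(s, p, id = paste0(s$id, "_hom")) {
  stopifnot(inherits(s, "chain_structure"), inherits(p, "sim_params"))
  with_seed(p$seed, derive_homolog_impl(s, p, id))
}

#' Generate a labeled benchmark set of synthetic families
#'
#' Each family has an independently generated founder backbone; members are
#' homologs derived from the founder under `p`. The returned label table maps
#' structure id to family id, and `truth` keeps each member's ground-truth
#' correspondence to its founder so that within-family pairwise alignments
#' can be reconstructed (see [family_alignments()]).
#'
#' @param n_families Number of families (>= 2).
#' @param members_per_family Members per family (>= 1).
#' @param p A [sim_params()]; `p$seed` seeds the whole set.
#' @return List with `chains` (named list of [chain_structure()]), `labels`
#'   (tibble of `id`, `family`), `founders` (named list) and `truth` (named
#'   list of founder-to-member alignment tibbles).
#' @export
make_benchmark_set <- function(n_families, members_per_family, p) {
  stopifnot(n_families >= 2, members_per_family >= 1, inherits(p, "sim_params"))
  with_seed(p$seed, {
    chains <- list()
    founders <- list()
    truth <- list()
    ids <- character(0)
    fams <- character(0)
    for (f in seq_len(n_families)) {
      fam <- sprintf("fam%02d", f)
      fp <- p
      fp$segment_spec <- p$segment_spec %||% random_segment_spec(p$n_residues)
      founder <- synth_chain_impl(fp, id = paste0(fam, "_founder"))
      founders[[fam]] <- founder
      for (m in seq_len(members_per_family)) {
        id <- sprintf("%s_m%d", fam, m)
        hom <- derive_homolog_impl(founder, p, id = id)
        chains[[id]] <- hom$chain
        truth[[id]] <- hom$true_alignment
        ids <- c(ids, id)
        fams <- c(fams, fam)
      }
    }
    list(chains = chains,
         labels = tibble::tibble(id = ids, family = fams),
         founders = founders,
         truth = truth)
  })
}

#' Ground-truth within-family pairwise alignments of a benchmark set
#'
#' Joins each pair of same-family members through their founder
#' correspondence, yielding the set of trusted pairwise alignments used to
#' train log-odds matrices.
#'
#' @param set Result of [make_benchmark_set()].
#' @return A list of entries `list(id_a, id_b, pairs)` where `pairs` is a
#'   tibble of aligned 1-based positions (`a_pos`, `b_pos`), one entry per
#'   unordered within-family pair.
#' @export
family_alignments <- function(set) {
  out <- list()
  for (fam in unique(set$labels$family)) {
    ids <- set$labels$id[set$labels$family == fam]
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        ta <- set$truth[[ids[i]]]
        tb <- set$truth[[ids[j]]]
        m <- merge(ta, tb, by = "q_pos", suffixes = c("_a", "_b"))
        out[[length(out) + 1L]] <- list(
          id_a = ids[i], id_b = ids[j],
          pairs = tibble::tibble(a_pos = m$t_pos_a, b_pos = m$t_pos_b))
      }
    }
  }
  out
}
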