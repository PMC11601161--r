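# Independent oracles, kept free of the implementation paths they check.

# Exhaustive local-alignment enumeration over ALL monotone column sets, for
# every pair of sequences of length <= max_len over a 2-letter alphabet.
# Scores are computed from the 2x2 matrix M (bilinear in the 0/1 letters) and
# the affine gap rule; returns, per length pair, the matrix of best scores for
# all 2^la x 2^lb sequence pairs (rows/cols indexed by binary encoding).
#
# Works because any 2x2 matrix satisfies
#   M[a+1, b+1] = c0 + c1*a + c2*b + c3*a*b  for a, b in {0, 1}.
enumerate_local_best <- function(M, gopen, gext, max_len = 6L) {
  c0 <- M[1, 1]
  c1 <- M[2, 1] - M[1, 1]
  c2 <- M[1, 2] - M[1, 1]
  c3 <- M[2, 2] - M[2, 1] - M[1, 2] + M[1, 1]
  all_seqs <- function(len) {
    # 2^len x len matrix of 0/1 letters
    do.call(cbind, lapply(seq_len(len), function(pos)
      rep(rep(0:1, each = 2^(len - pos)), length.out = 2^len)))
  }
  gap_cost <- function(idx) {
    g <- diff(idx) - 1L
    g <- g[g > 0L]
    if (!length(g)) 0 else sum(gopen + (g - 1L) * gext)
  }
  out <- list()
  for (la in seq_len(max_len)) {
    Q <- all_seqs(la)
    for (lb in seq_len(max_len)) {
      T_ <- all_seqs(lb)
      best <- matrix(0, nrow(Q), nrow(T_))
      for (k in seq_len(min(la, lb))) {
        qsets <- utils::combn(la, k)
        tsets <- utils::combn(lb, k)
        for (qi in seq_len(ncol(qsets))) {
          qidx <- qsets[, qi]
          Sq <- Q[, qidx, drop = FALSE]
          pq <- gap_cost(qidx)
          rs_q <- rowSums(Sq)
          for (ti in seq_len(ncol(tsets))) {
            tidx <- tsets[, ti]
            St <- T_[, tidx, drop = FALSE]
            cross <- Sq %*% t(St)
            sc <- k * c0 + c1 * rs_q + c3 * cross
            sc <- sweep(sc, 2L, c2 * rowSums(St), `+`)
            sc <- sc - (pq + gap_cost(tidx))
            best <- pmax(best, sc)
          }
        }
      }
      out[[paste(la, lb)]] <- best
    }
  }
  out
}

# brute-force nearest eligible neighbour scan
brute_nen <- function(chain, i, sep = 2L) {
  n <- chain$length
  best <- NA_integer_; bestd <- Inf
  for (j in seq_len(n)) {
    if (abs(i - j) < sep) next
    d <- sqrt(sum((chain$xyz[i, ] - chain$xyz[j, ])^2))
    if (d < bestd) { bestd <- d; best <- j }
  }
  best
}

# RMSD after optimal translation for a FIXED rotation R applied to t
rmsd_at_rotation <- function(q, t, R) {
  tr <- t %*% t(R)
  diff <- sweep(q, 2L, colMeans(q)) - sweep(tr, 2L, colMeans(tr))
  sqrt(mean(rowSums(diff^2)))
}

random_rotation_oracle <- function(n_rot, seed) {
  withr::with_seed(seed, lapply(seq_len(n_rot), function(k) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
          c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
          c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  }))
}

rigid_transform_chain <- function(chain, R, tvec) {
  chain_structure(chain$id, chain$aa,
                  chain$xyz %*% t(R) +
                    matrix(tvec, chain$length, 3, byrow = TRUE))
}
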