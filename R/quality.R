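#' Alignment-quality parameters
#'
#' Constants of the alignment-quality statistic
#' `t = delta * D + (alpha * s - beta * s_rev) / (L + lambda)` and
#' `AQ = 1 / (1 + 0.5 * 10^((a + b * t) / 10))`, where `D` is the symmetrized
#' local-distance-difference score of the alignment, `s` the alignment score,
#' `s_rev` the reversed-alignment score of the query, and
#' `L = (|Q| + |T|) / 2` the mean chain length. `lambda` damps the growth of
#' `t` for anomalously short queries; `b < 0` makes AQ increase with `t`.
#' Defaults were calibrated on the package's simulated benchmark so that
#' AQ < 0.5 suggests a spurious alignment.
#'
#' @param delta Weight of the local-distance-difference term.
#' @param alpha,beta Weights of the alignment and reversed-alignment scores.
#' @param lambda Length damping (residues), `>= 0`.
#' @param a,b Sigmoid location/slope; `b` must be negative.
#' @return A list of class `quality_params`.
#' @export
quality_params <- function(delta = 10, alpha = 0.2, beta = 0.2, lambda = 10,
                           a = 14, b = -2) {
  stopifnot(delta >= 0, alpha >= 0, beta >= 0, lambda >= 0, b < 0)
  structure(list(delta = delta, alpha = alpha, beta = beta, lambda = lambda,
                 a = a, b = b),
            class = "quality_params")
}

#' Symmetrized local-distance-difference score of an alignment
#'
#' A superposition-free measure of how well the alignment preserves local
#' geometry. For each aligned column, reference pairs are the other aligned
#' columns within an inclusion radius of 15 A in the reference structure and
#' at chain separation >= 2; a pair is preserved at tolerance `tau` if the
#' two structures' inter-residue distances differ by less than `tau`. The
#' per-column score is the preserved fraction averaged over
#' `tau = 0.5, 1, 2, 4` A; columns with no reference pairs contribute 0. The
#' final score averages over columns with each structure taken as reference
#' in turn, so it is symmetric in the two chains and invariant under rigid
#' motions. Empty alignments score 0.
#'
#' @param a An `alignment_result`.
#' @param q,t The two [chain_structure()]s the alignment refers to.
#' @param r0 Inclusion radius (Angstroms).
#' @param taus Preservation tolerances (Angstroms).
#' @return A number in `[0, 1]`.
#' @export
lddt_mu <- function(a, q, t, r0 = 15, taus = c(0.5, 1, 2, 4)) {
  cols <- a$columns
  m <- nrow(cols)
  if (m == 0L) return(0)
  if (any(cols$q_pos > q$length) || any(cols$t_pos > t$length))
    stop("alignment column index out of range", call. = FALSE)
  if (m == 1L) return(0)  # no pairs at all
  dq <- as.matrix(stats::dist(q$xyz[cols$q_pos, , drop = FALSE]))
  dt <- as.matrix(stats::dist(t$xyz[cols$t_pos, , drop = FALSE]))
  dd <- abs(dq - dt)
  sep_q <- abs(outer(cols$q_pos, cols$q_pos, `-`)) >= 2L
  sep_t <- abs(outer(cols$t_pos, cols$t_pos, `-`)) >= 2L
  col_frac <- function(ref_d, sep) {
    mask <- sep & ref_d <= r0
    denom <- rowSums(mask)
    pres <- rowSums(sapply(taus, function(tau) rowSums(mask & dd < tau)))
    frac <- ifelse(denom > 0, pres / (length(taus) * denom), 0)
    frac
  }
  mean((col_frac(dq, sep_q) + col_frac(dt, sep_t)) / 2)
}

#' Alignment-quality statistic
#'
#' Combines the local-distance-difference score, alignment score,
#' reversed-alignment score and mean chain length into the test statistic
#' `t`, then maps it through the sigmoid to AQ in (0, 1). AQ is symmetric
#' under swapping the two chains' lengths.
#'
#' @param delta_lddt Local-distance-difference score in `[0, 1]`.
#' @param s Alignment score (bits).
#' @param s_rev Reversed-alignment score of the query (bits).
#' @param len_q,len_t Chain lengths (>= 1).
#' @param p A [quality_params()].
#' @return A one-row tibble of class `quality_result`: `delta_lddt`, `s`,
#'   `s_rev`, `mean_length`, `t`, `aq`.
#' @export
#' @examples
#' # a + b * t = 0 gives AQ = 2/3
#' p <- quality_params(a = 0, b = -2)
#' aq_statistic(0, 0, 0, 50, 50, p)$aq
aq_statistic <- function(delta_lddt, s, s_rev, len_q, len_t,
                         p = quality_params()) {
  stopifnot(inherits(p, "quality_params"), len_q >= 1, len_t >= 1)
  L <- (len_q + len_t) / 2
  t_stat <- p$delta * delta_lddt + (p$alpha * s - p$beta * s_rev) / (L + p$lambda)
  aq <- 1 / (1 + 0.5 * 10^((p$a + p$b * t_stat) / 10))
  structure(tibble::tibble(delta_lddt = delta_lddt, s = s, s_rev = s_rev,
                           mean_length = L, t = t_stat, aq = aq),
            class = c("quality_result", "tbl_df", "tbl", "data.frame"))
}

#' Fit an empirical E-value calibration from decoy AQ values
#'
#' Models the null tail of AQ by a linear fit of `log10` empirical exceedance
#' probability against AQ over the upper half of the decoy distribution
#' (at least 50 points). Decoys are typically reversed-chain alignments
#' generated from the search database itself.
#'
#' @param decoy_aqs Numeric vector of at least 100 decoy AQ values.
#' @param n_decoy_comparisons Number of decoy comparisons the values came
#'   from (stored as the reference database size).
#' @return An object of class `evalue_calibration` with `intercept`, `slope`
#'   (negative), `aq_median`, `n_decoys` and `n_ref`.
#' @export
fit_evalue <- function(decoy_aqs, n_decoy_comparisons = length(decoy_aqs)) {
  decoy_aqs <- as.numeric(decoy_aqs)
  n <- length(decoy_aqs)
  if (n < 100L)
    stop("E-value calibration needs at least 100 decoy AQ values, got ", n,
         call. = FALSE)
  srt <- sort(decoy_aqs, decreasing = TRUE)
  exceed <- seq_len(n) / n           # P(AQ >= srt[k]) = k / n
  med <- stats::median(decoy_aqs)
  keep <- srt >= med
  if (sum(keep) < 50L) keep[seq_len(50L)] <- TRUE
  fit <- stats::lm(log10(exceed[keep]) ~ srt[keep])
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("degenerate decoy AQ distribution: fitted tail slope is not negative",
         call. = FALSE)
  structure(list(intercept = unname(stats::coef(fit)[1L]), slope = slope,
                 aq_median = med, n_decoys = n,
                 n_ref = as.integer(n_decoy_comparisons)),
            class = "evalue_calibration")
}

#' @export
print.evalue_calibration <- function(x, ...) {
  cat("<evalue_calibration> log10 P(AQ' >= aq) ~ ",
      format(x$intercept, digits = 4), " + ", format(x$slope, digits = 4),
      " * aq (", x$n_decoys, " decoys)\n", sep = "")
  invisible(x)
}

#' E-value of an AQ score
#'
#' `E = db_size * P_null(AQ' >= aq)` with the null exceedance probability
#' from the fitted tail, floored at 0.5 below the decoy median and capped at
#' 1, so `E` is non-increasing in `aq`, scales linearly in the database size,
#' and never exceeds it.
#'
#' @param aq Numeric AQ value(s).
#' @param cal An [fit_evalue()] calibration.
#' @param db_size Number of database comparisons per query.
#' @return Numeric E-value(s) in `[0, db_size]`.
#' @export
evalue_of <- function(aq, cal, db_size) {
  stopifnot(inherits(cal, "evalue_calibration"), db_size >= 0)
  p <- 10^(cal$intercept + cal$slope * aq)
  p[aq < cal$aq_median] <- pmax(p[aq < cal$aq_median], 0.5)
  p <- pmin(pmax(p, 0), 1)
  db_size * p
}
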