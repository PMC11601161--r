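#' Train the complete table bundle from chains and trusted alignments
#'
#' One call that produces everything pairwise alignment needs: per-feature
#' alphabets trained on the chains' features, and per-feature log-odds
#' matrices trained on the supplied reference alignments. The bundle also
#' carries the feature, gap and quality parameters, and (after
#' [calibrate_evalues()]) the E-value calibration.
#'
#' @param chains Named list of [chain_structure()] used for alphabet
#'   training.
#' @param alignments Trusted pairwise alignments: a list of entries
#'   `list(id_a, id_b, pairs)` with `pairs` a table of aligned 1-based
#'   positions, as produced by [family_alignments()] or read from a TSV of
#'   `(id_a, id_b, pos_a, pos_b)` rows.
#' @param sizes Optional named alphabet sizes (default 16 per structural
#'   feature).
#' @param fp A [feature_params()].
#' @param ap An [align_params()].
#' @param qp A [quality_params()].
#' @param pseudocount Log-odds smoothing.
#' @param weights Optional named per-feature weights.
#' @param seed Integer seed (K-means initialization).
#' @return An object of class `staln_tables`.
#' @export
train_tables <- function(chains, alignments, sizes = NULL,
                         fp = feature_params(), ap = align_params(),
                         qp = quality_params(), pseudocount = 0.5,
                         weights = NULL, seed = 1L) {
  if (is.null(names(chains)) || any(!nzchar(names(chains))))
    names(chains) <- vapply(chains, function(ch) ch$id, character(1L))
  feats <- lapply(chains, extract_features, p = fp)
  aset <- train_alphabets(chains, sizes = sizes, p = fp, seed = seed,
                          features = feats)
  dfvs <- lapply(feats, discretize_chain, aset = aset)
  count_alns <- lapply(alignments, function(al) {
    if (!al$id_a %in% names(dfvs) || !al$id_b %in% names(dfvs))
      stop("alignment refers to unknown chain id '",
           setdiff(c(al$id_a, al$id_b), names(dfvs))[1L], "'", call. = FALSE)
    list(q = dfvs[[al$id_a]], t = dfvs[[al$id_b]], pairs = al$pairs)
  })
  mats <- train_score_matrices(count_alns, aset, pseudocount = pseudocount,
                               weights = weights)
  structure(list(alphabets = aset, matrices = mats,
                 feature_params = fp, align_params = ap, quality_params = qp,
                 calibration = NULL,
                 meta = list(seed = as.integer(seed),
                             n_chains = length(chains),
                             n_alignments = length(alignments))),
            class = "staln_tables")
}

#' @export
print.staln_tables <- function(x, ...) {
  cat("<staln_tables> trained on", x$meta$n_chains, "chains /",
      x$meta$n_alignments, "alignments;",
      if (is.null(x$calibration)) "uncalibrated" else "E-values calibrated",
      "\n")
  invisible(x)
}

# features + DFV for one chain under a table bundle
chain_profile <- function(chain, tables) {
  ft <- extract_features(chain, tables$feature_params)
  list(chain = chain, features = ft,
       dfv = discretize_chain(ft, tables$alphabets))
}

#' Calibrate E-values against reversed-chain decoys
#'
#' Aligns every chain of the database against the coordinate-reversed copies
#' of the other chains, computes decoy AQ values, and fits the empirical null
#' tail. Reversal preserves composition and local geometry statistics while
#' destroying homologous correspondence, giving a null matched to the
#' database itself.
#'
#' @param tables A [train_tables()] bundle.
#' @param db_chains Named list of [chain_structure()].
#' @param max_decoys Cap on the number of decoy comparisons (sampled
#'   deterministically if exceeded).
#' @return The bundle with `calibration` filled in.
#' @export
calibrate_evalues <- function(tables, db_chains, max_decoys = 5000L) {
  stopifnot(inherits(tables, "staln_tables"))
  n <- length(db_chains)
  if (n < 2L) stop("calibration needs at least 2 database chains", call. = FALSE)
  prof <- lapply(db_chains, chain_profile, tables = tables)
  rev_prof <- lapply(db_chains, function(ch)
    chain_profile(reverse_chain(ch), tables))
  s_rev <- vapply(seq_len(n), function(i)
    smith_waterman(prof[[i]]$dfv, rev_prof[[i]]$dfv, tables$matrices,
                   tables$align_params)$score, numeric(1L))
  pairs <- expand.grid(q = seq_len(n), t = seq_len(n))
  pairs <- pairs[pairs$q != pairs$t, , drop = FALSE]
  if (nrow(pairs) > max_decoys)
    pairs <- pairs[seq(1L, nrow(pairs), length.out = max_decoys), , drop = FALSE]
  aqs <- vapply(seq_len(nrow(pairs)), function(k) {
    qi <- pairs$q[k]; ti <- pairs$t[k]
    aln <- smith_waterman(prof[[qi]]$dfv, rev_prof[[ti]]$dfv,
                          tables$matrices, tables$align_params)
    dl <- lddt_mu(aln, prof[[qi]]$chain, rev_prof[[ti]]$chain)
    aq_statistic(dl, aln$score, s_rev[qi],
                 prof[[qi]]$chain$length, rev_prof[[ti]]$chain$length,
                 tables$quality_params)$aq
  }, numeric(1L))
  tables$calibration <- fit_evalue(aqs, nrow(pairs))
  tables
}

#' Align two structures end to end
#'
#' The full pipeline for one pair: feature extraction, discretization, local
#' alignment, reversed-alignment score of the query, local-distance-difference
#' score, alignment quality, E-value (when the bundle is calibrated), and
#' optionally the rigid superposition implied by the alignment.
#'
#' @param q_chain,t_chain [chain_structure()] query and target.
#' @param tables A [train_tables()] bundle.
#' @param db_size Database size for the E-value (default: the calibration's
#'   stored reference size, if calibrated).
#' @param superpose If `TRUE` and the alignment has at least 3 columns,
#'   attach the Kabsch superposition of the target onto the query.
#' @return An object of class `pair_alignment`; see [tidy.pair_alignment()]
#'   and [glance.pair_alignment()].
#' @export
align_pair <- function(q_chain, t_chain, tables, db_size = NULL,
                       superpose = FALSE) {
  stopifnot(inherits(tables, "staln_tables"))
  qp <- chain_profile(q_chain, tables)
  tp <- chain_profile(t_chain, tables)
  aln <- smith_waterman(qp$dfv, tp$dfv, tables$matrices, tables$align_params)
  s_rev <- reversed_score(q_chain, tables)
  dl <- lddt_mu(aln, q_chain, t_chain)
  qual <- aq_statistic(dl, aln$score, s_rev, q_chain$length, t_chain$length,
                       tables$quality_params)
  ev <- NA_real_
  if (!is.null(tables$calibration)) {
    nref <- db_size %||% tables$calibration$n_ref
    ev <- evalue_of(qual$aq, tables$calibration, nref)
  }
  sup <- NULL
  if (superpose && nrow(aln$columns) >= 3L) {
    sup <- tryCatch(
      kabsch_superpose(q_chain$xyz[aln$columns$q_pos, , drop = FALSE],
                       t_chain$xyz[aln$columns$t_pos, , drop = FALSE]),
      error = function(e) NULL)
  }
  structure(list(query = q_chain, target = t_chain, alignment = aln,
                 quality = qual, evalue = ev, superposition = sup),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  g <- glance(x)
  cat("<pair_alignment> ", x$query$id, " vs ", x$target$id, "\n", sep = "")
  cat(sprintf("  score %.2f bits over %d columns; lddt %.3f; AQ %.3f",
              g$score, g$n_columns, g$delta_lddt, g$aq))
  if (!is.na(g$evalue)) cat(sprintf("; E = %.3g", g$evalue))
  cat("\n")
  if (!is.null(x$superposition))
    cat(sprintf("  superposition rmsd %.2f A\n", x$superposition$rmsd))
  invisible(x)
}

#' Tidy the aligned columns of a pair alignment
#'
#' @param x A [align_pair()] result.
#' @param ... Unused.
#' @return Tibble with one row per aligned column: 1-based positions and the
#'   two amino-acid letters.
#' @method tidy pair_alignment
#' @export
tidy.pair_alignment <- function(x, ...) {
  cols <- x$alignment$columns
  tibble::tibble(q_pos = cols$q_pos, t_pos = cols$t_pos,
                 q_aa = x$query$aa[cols$q_pos],
                 t_aa = x$target$aa[cols$t_pos])
}

#' One-row summary of a pair alignment
#'
#' @param x A [align_pair()] result.
#' @param ... Unused.
#' @return One-row tibble: ids, lengths, alignment length, score, lddt,
#'   reversed score, `t`, AQ, E-value and superposition rmsd (NA if absent).
#' @export
glance.pair_alignment <- function(x, ...) {
  tibble::tibble(query_id = x$query$id, target_id = x$target$id,
                 len_q = x$query$length, len_t = x$target$length,
                 n_columns = nrow(x$alignment$columns),
                 score = x$alignment$score,
                 delta_lddt = x$quality$delta_lddt,
                 s_rev = x$quality$s_rev,
                 t = x$quality$t, aq = x$quality$aq,
                 evalue = x$evalue,
                 rmsd = if (is.null(x$superposition)) NA_real_
                        else x$superposition$rmsd)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write or read a trained table bundle
#'
#' The bundle is stored as a directory of JSON files (`alphabets.json`,
#' `matrices.json`, `params.json`, and `calibration.json` when calibrated).
#'
#' @param tables A `staln_tables` bundle.
#' @param dir Directory path.
#' @return `read_tables()` returns the bundle; `write_tables()` returns `dir`
#'   invisibly.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "staln_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alphabets(tables$alphabets, file.path(dir, "alphabets.json"))
  mats <- lapply(tables$matrices$matrices, function(m)
    list(feature_name = m$feature_name, size = m$size, weight = m$weight,
         matrix = m$matrix))
  jsonlite::write_json(list(feature_order = tables$matrices$feature_order,
                            pseudocount = tables$matrices$pseudocount,
                            matrices = mats),
                       file.path(dir, "matrices.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(align_params = unclass(tables$align_params),
                            quality_params = unclass(tables$quality_params),
                            meta = tables$meta),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(tables$calibration))
    jsonlite::write_json(unclass(tables$calibration),
                         file.path(dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_tables
#' @export
read_tables <- function(dir) {
  aset <- read_alphabets(file.path(dir, "alphabets.json"))
  mraw <- jsonlite::read_json(file.path(dir, "matrices.json"),
                              simplifyVector = TRUE)
  mats <- lapply(mraw$matrices, function(m)
    structure(list(feature_name = m$feature_name, size = as.integer(m$size),
                   matrix = as.matrix(m$matrix), weight = as.numeric(m$weight)),
              class = "score_matrix"))
  names(mats) <- vapply(mats, function(m) m$feature_name, character(1L))
  praw <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  ap <- align_params(praw$align_params$gap_open, praw$align_params$gap_extend)
  qpr <- praw$quality_params
  qp <- quality_params(qpr$delta, qpr$alpha, qpr$beta, qpr$lambda, qpr$a, qpr$b)
  cal <- NULL
  cal_path <- file.path(dir, "calibration.json")
  if (file.exists(cal_path)) {
    craw <- jsonlite::read_json(cal_path, simplifyVector = TRUE)
    cal <- structure(list(intercept = craw$intercept, slope = craw$slope,
                          aq_median = craw$aq_median,
                          n_decoys = as.integer(craw$n_decoys),
                          n_ref = as.integer(craw$n_ref)),
                     class = "evalue_calibration")
  }
  structure(list(alphabets = aset,
                 matrices = structure(list(feature_order = mraw$feature_order,
                                           matrices = mats,
                                           pseudocount = mraw$pseudocount),
                                      class = "score_matrix_set"),
                 feature_params = aset$feature_params,
                 align_params = ap, quality_params = qp,
                 calibration = cal,
                 meta = as.list(praw$meta)),
            class = "staln_tables")
}

#' Read trusted alignments from a TSV of aligned position pairs
#'
#' Expected columns: `id_a`, `id_b`, `pos_a`, `pos_b` (1-based positions),
#' one aligned residue pair per row.
#'
#' @param path TSV path.
#' @return A list of `list(id_a, id_b, pairs)` entries.
#' @export
read_alignment_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id_a", "id_b", "pos_a", "pos_b")
  if (!all(need %in% names(df)))
    stop("alignment TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  keys <- paste(df$id_a, df$id_b, sep = "\r")
  lapply(split(df, keys), function(g)
    list(id_a = g$id_a[1L], id_b = g$id_b[1L],
         pairs = tibble::tibble(a_pos = as.integer(g$pos_a),
                                b_pos = as.integer(g$pos_b))))
}

#' Write trusted alignments as a TSV of aligned position pairs
#'
#' @param alignments A list of `list(id_a, id_b, pairs)` entries.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignments, path) {
  rows <- lapply(alignments, function(al)
    data.frame(id_a = al$id_a, id_b = al$id_b,
               pos_a = al$pairs[[1L]], pos_b = al$pairs[[2L]]))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
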