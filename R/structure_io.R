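#' Read protein chains from a PDB or mmCIF file
#'
#' Reads the C-alpha trace of every selected chain into
#' [chain_structure()] records. Only `ATOM` records with atom name `CA`,
#' alternate-location blank or `'A'`, from the first model are used;
#' `HETATM` records are ignored. Three-letter residue names are mapped to
#' one-letter codes (`MSE` to `M`); anything unrecognized becomes `X`.
#'
#' Gaps in author residue numbering are treated as consecutive residues:
#' the chain is the ordered list of C-alpha atoms as they appear.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @param format_hint Optional `"pdb"` or `"cif"`; by default the format is
#'   taken from the file extension.
#' @param chain Optional single chain identifier; by default all chains are
#'   returned.
#' @return A list of [chain_structure()], one per chain, ids formed as
#'   `"<file stem>_<chain id>"`.
#' @export
read_structures <- function(path, format_hint = NULL, chain = NULL) {
  if (!file.exists(path))
    stop("structure file not found: ", path, call. = FALSE)
  fmt <- format_hint %||% guess_format(path)
  pdb <- tryCatch(
    switch(fmt,
           pdb = bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
           cif = bio3d::read.cif(path, verbose = FALSE),
           stop("unknown structure format '", fmt, "'", call. = FALSE)),
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no atoms parsed from '", path, "'", call. = FALSE)
  is_atom <- at$type == "ATOM"
  alt_ok <- is.na(at$alt) | at$alt %in% c("", "A")
  sel <- is_atom & alt_ok & at$elety == "CA"
  ca <- at[sel, , drop = FALSE]
  # residues present as ATOM records but with no CA are skipped, with notice
  res_all <- unique(paste(at$chain[is_atom], at$resno[is_atom], at$insert[is_atom]))
  res_ca <- unique(paste(ca$chain, ca$resno, ca$insert))
  n_noca <- length(setdiff(res_all, res_ca))
  if (n_noca > 0L)
    warning("'", basename(path), "': skipped ", n_noca,
            " residue(s) without a C-alpha atom")
  if (nrow(ca) == 0L)
    stop("no C-alpha atoms in '", path, "'", call. = FALSE)
  # one CA per residue: keep the first record (altloc 'A' sorts before 'B')
  key <- paste(ca$chain, ca$resno, ca$insert)
  ca <- ca[!duplicated(key), , drop = FALSE]
  stem <- sub("\\.(pdb|ent|cif)$", "", basename(path), ignore.case = TRUE)
  chains <- unique(ca$chain)
  if (!is.null(chain)) {
    if (!chain %in% chains)
      stop("chain '", chain, "' not found in '", path, "'", call. = FALSE)
    chains <- chain
  }
  lapply(chains, function(ch) {
    rows <- ca[ca$chain == ch, , drop = FALSE]
    aa <- suppressWarnings(bio3d::aa321(rows$resid))
    aa[is.na(aa) | !nzchar(aa)] <- "X"
    cid <- if (is.na(ch) || !nzchar(ch)) stem else paste0(stem, "_", ch)
    chain_structure(cid, aa, cbind(rows$x, rows$y, rows$z))
  })
}

guess_format <- function(path) {
  if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a rigidly transformed C-alpha trace as a PDB file
#'
#' Applies a rigid-body transformation `R x + t` to every C-alpha
#' coordinate and writes the result as a CA-only PDB file, typically to
#' visualize the superposition implied by an alignment.
#'
#' @param s A [chain_structure()].
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det +1).
#' @param translation Numeric length-3 translation vector (Angstroms).
#' @param path Output file path.
#' @return Invisibly, the transformed coordinate matrix.
#' @export
write_superposed <- function(s, rotation, translation, path) {
  stopifnot(inherits(s, "chain_structure"))
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation is not a proper rotation matrix (orthonormal, det +1)",
         call. = FALSE)
  new_xyz <- s$xyz %*% t(rotation) +
    matrix(translation, nrow = s$length, ncol = 3L, byrow = TRUE)
  resid3 <- aa_one_to_three(s$aa)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(new_xyz)),
                   type = rep("ATOM", s$length),
                   resno = seq_len(s$length),
                   resid = resid3,
                   elety = rep("CA", s$length),
                   chain = rep("A", s$length))
  invisible(new_xyz)
}

aa_one_to_three <- function(aa) {
  out <- suppressWarnings(bio3d::aa123(aa))
  out[is.na(out) | aa == "X"] <- "UNK"
  out
}
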