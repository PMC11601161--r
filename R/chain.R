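#' Chain structure records
#'
#' A `chain_structure` is the package's representation of one protein chain
#' or domain: an identifier, one amino-acid letter per residue, and the
#' corresponding C-alpha coordinates in Angstroms. All downstream feature
#' extraction works on this record alone; side chains and non-CA atoms are
#' never kept.
#'
#' @param id Character label, e.g. `"d1qmha1"` or `"1abc_A"`.
#' @param aa Character vector of one-letter amino-acid codes (uppercase,
#'   standard 20 letters or `"X"`).
#' @param xyz Numeric matrix with one row per residue and columns x, y, z
#'   (Angstroms).
#'
#' @return An object of class `chain_structure`: a list with elements
#'   `id`, `aa`, `xyz` and `length`.
#' @export
#' @examples
#' ch <- chain_structure("toy", c("A", "G"), rbind(c(0, 0, 0), c(3.8, 0, 0)))
#' ch$length
chain_structure <- function(id, aa, xyz) {
  stopifnot(is.character(id), length(id) == 1L)
  aa <- toupper(as.character(aa))
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (is.null(dim(xyz)) || ncol(xyz) != 3L)
    stop("xyz must be an n x 3 coordinate matrix", call. = FALSE)
  n <- nrow(xyz)
  if (n < 1L) stop("a chain must contain at least one residue", call. = FALSE)
  if (length(aa) != n)
    stop("aa and xyz describe different numbers of residues", call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("non-finite C-alpha coordinates in chain '", id, "'", call. = FALSE)
  bad <- !aa %in% c(AA_LETTERS, "X")
  if (any(bad)) {
    warning("chain '", id, "': ", sum(bad),
            " nonstandard residue letter(s) mapped to 'X'")
    aa[bad] <- "X"
  }
  if (n >= 2L) {
    step <- sqrt(rowSums((xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
    if (any(step <= 0))
      stop("chain '", id, "': zero-length C-alpha step (duplicated coordinates)",
           call. = FALSE)
  }
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, aa = aa, xyz = xyz, length = n),
            class = "chain_structure")
}

#' The 20 standard amino-acid letters, alphabetical
#' @noRd
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @export
print.chain_structure <- function(x, ...) {
  cat("<chain_structure> ", x$id, ": ", x$length, " residues\n", sep = "")
  invisible(x)
}

#' @export
length.chain_structure <- function(x) x$length

#' Reverse the residue order of a chain
#'
#' Returns the same chain with residues in reverse order: coordinates and
#' amino-acid letters move together. The reversed copy of a query is the
#' null-like partner used for the reversed-alignment score `s_rev`.
#'
#' @param s A [chain_structure()].
#' @return A `chain_structure` with the residue list reversed and the id
#'   suffixed `"_rev"` (reversing twice strips the suffix again).
#' @export
#' @examples
#' ch <- chain_structure("toy", c("A", "G"), rbind(c(0, 0, 0), c(3.8, 0, 0)))
#' reverse_chain(ch)$xyz[1, ]
reverse_chain <- function(s) {
  stopifnot(inherits(s, "chain_structure"))
  idx <- rev(seq_len(s$length))
  new_id <- if (endsWith(s$id, "_rev")) sub("_rev$", "", s$id) else paste0(s$id, "_rev")
  chain_structure(new_id, s$aa[idx], s$xyz[idx, , drop = FALSE])
}
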